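# Quadrant classification, promoter medians, the delta-beta/fold-change
# correlation and enhancer-gene pairing.

mk_dm <- function(ids, delta, significant = TRUE) {
  significant <- rep_len(significant, length(ids))
  dir <- ifelse(delta > 0, "hyper", "hypo")
  dir[!significant] <- "none"
  data.frame(probe_id = ids, p_raw = 0.001, p_adj = 0.01,
             delta_beta = delta, direction = dir,
             significant = significant, stringsAsFactors = FALSE)
}

mk_de <- function(ids, lfc, significant = TRUE) {
  significant <- rep_len(significant, length(ids))
  dir <- ifelse(lfc > 0, "up", "down")
  dir[!significant] <- "none"
  data.frame(gene_id = ids, log2fc = lfc, p_raw = 0.001,
             p_adj = ifelse(significant, 0.01, 0.5), significant = significant,
             direction = dir, stringsAsFactors = FALSE)
}

test_that("quadrants pair significant concordant probe-gene combinations", {
  ann <- rbind(
    tiny_annotation("p1", genic = "promoter", gene = "GA"),
    tiny_annotation("p2", genic = "promoter", gene = "GB"),
    tiny_annotation("p3", genic = "body", gene = "GC"),
    tiny_annotation("p4", genic = "body", gene = "GD"),
    tiny_annotation("p5", genic = "promoter", gene = "GE"),
    tiny_annotation("p6", genic = "promoter", gene = "GF"))
  dm <- mk_dm(paste0("p", 1:6), c(-0.4, 0.4, 0.4, -0.4, -0.4, 0.4))
  de <- mk_de(c("GA", "GB", "GC", "GD", "GE", "GF"),
              c(2, -2, 2, -2, 2, 2),
              significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  quad <- promoter_quadrants(dm, de, ann)
  got <- setNames(quad$pairs$quadrant, quad$pairs$probe_id)
  expect_equal(got[["p1"]], "promoter_hypo_up")
  expect_equal(got[["p2"]], "promoter_hyper_down")
  expect_equal(got[["p3"]], "body_hyper_up")
  expect_equal(got[["p4"]], "body_hypo_down")
  expect_false("p5" %in% names(got))  # gene not significant
  expect_false("p6" %in% names(got))  # discordant: promoter hyper with up gene
  expect_equal(quad$n_discordant, 1)
  expect_equal(quad$n_unpaired, 1)
  expect_equal(quad$counts$n_probes[quad$counts$quadrant == "promoter_hypo_up"], 1L)
})

test_that("per-gene promoter delta-beta is the median over significant probes", {
  ann <- rbind(
    tiny_annotation("q1", genic = "promoter", gene = "G1"),
    tiny_annotation(c("q2", "q3", "q4"), genic = "promoter", gene = "G2"),
    tiny_annotation(c("q5", "q6"), genic = "promoter", gene = "G3"))
  dm <- mk_dm(paste0("q", 1:6), c(0.4, -0.4, -0.5, -0.6, 0.3, 0.5))
  out <- promoter_median_delta_beta(dm, ann)
  val <- setNames(out$delta_beta, out$gene_id)
  expect_equal(val[["G1"]], 0.4)    # singleton
  expect_equal(val[["G2"]], -0.5)   # odd-count median
  expect_equal(val[["G3"]], 0.4)    # even-count midpoint
})

test_that("promoter correlation handles collinear and degenerate inputs", {
  gd <- data.frame(gene_id = c("A", "B", "C"),
                   delta_beta = c(-0.4, -0.3, -0.5))
  de <- mk_de(c("A", "B", "C"), c(2, 1.5, 2.5))
  res <- correlate_promoter_fc(gd, de)
  expect_equal(res$r, -1, tolerance = 1e-9)
  expect_equal(res$n, 3)
  # affine rescaling of an axis leaves r unchanged
  de2 <- de; de2$log2fc <- 10 * de2$log2fc + 1
  expect_equal(correlate_promoter_fc(gd, de2)$r, res$r, tolerance = 1e-12)
  expect_error(correlate_promoter_fc(gd[1:2, ], de), ">= 3 matched")
  gd_const <- gd; gd_const$delta_beta <- -0.4
  expect_error(correlate_promoter_fc(gd_const, de), "zero variance")
})

test_that("label swap maps quadrants onto their mirror images", {
  cfg <- small_config(seed = 23)
  sim <- simulate_study(cfg)
  suppressMessages(bf <- filter_probes(sim$beta, sim$manifest))
  dm <- call_dm(bf, sim$sheet)
  de <- test_de(sim$counts, sim$sheet)
  quad <- promoter_quadrants(dm, de, sim$manifest)
  swapped <- sim$sheet
  swapped$group <- ifelse(swapped$group == "tumor", "normal", "tumor")
  dm_sw <- call_dm(bf, swapped)
  de_sw <- test_de(sim$counts, swapped)
  quad_sw <- promoter_quadrants(dm_sw, de_sw, sim$manifest)
  key <- function(q, lab) {
    p <- q$pairs[q$pairs$quadrant == lab, ]
    sort(paste(p$probe_id, p$gene_id))
  }
  expect_equal(key(quad_sw, "promoter_hyper_down"), key(quad, "promoter_hypo_up"))
  expect_equal(key(quad_sw, "promoter_hypo_up"), key(quad, "promoter_hyper_down"))
  expect_equal(key(quad_sw, "body_hypo_down"), key(quad, "body_hyper_up"))
  expect_equal(key(quad_sw, "body_hyper_up"), key(quad, "body_hypo_down"))
})

test_that("enhancer pairing locks direction and respects the window", {
  # one enhancer probe 10 kb from gene GA (up) and one hyper probe near GB (up)
  ann <- probe_annotation(data.frame(
    probe_id = c("e1", "e2", "pa", "pb"),
    chromosome = "chr1",
    position = c(110000, 310000, 100200, 300200),
    island_relation = "open_sea",
    genic_relation = c("intergenic", "intergenic", "promoter", "promoter"),
    gene_symbol = c(NA, NA, "GA", "GB"),
    enhancer_flag = c(TRUE, TRUE, FALSE, FALSE),
    cross_reactive_flag = FALSE, maf_over_5pct_flag = FALSE,
    stringsAsFactors = FALSE))
  sheet <- tiny_sheet(5, 4)
  dm <- mk_dm(c("e1", "e2"), c(-0.5, 0.5))
  lx <- rbind(GA = c(rep(8, 5), rep(2, 4)),   # clearly up in tumors
              GB = c(rep(8, 5), rep(2, 4)))
  colnames(lx) <- sheet$case_id
  pairs <- enhancer_pairs(dm, lx, ann, sheet, window = 50000)
  expect_equal(pairs$probe_id, "e1")
  expect_equal(pairs$gene_id, "GA")
  expect_equal(pairs$gene_direction, "up")
  expect_lt(pairs$distance, 15000)
  # hyper probe e2 near the up gene GB is never paired (direction lock)
  expect_false("e2" %in% pairs$probe_id)
  # no gene inside the window: no pair
  pairs2 <- enhancer_pairs(dm, lx, ann, sheet, window = 5000)
  expect_equal(nrow(pairs2), 0)
})

test_that("planted enhancer pairs are recovered on synthetic data", {
  cfg <- small_config(seed = 29)
  sim <- simulate_study(cfg)
  suppressMessages(bf <- filter_probes(sim$beta, sim$manifest))
  dm <- call_dm(bf, sim$sheet)
  keep <- filter_expressed(cpm(sim$counts), sim$sheet)
  lx <- log_cpm(sim$counts[keep, ])
  pairs <- enhancer_pairs(dm, lx, sim$manifest, sim$sheet)
  truth <- sim$truth$pairs[sim$truth$pairs$quadrant == "enhancer_hypo_up", ]
  expect_gt(nrow(truth), 0)
  got <- paste(pairs$probe_id, pairs$gene_id)
  want <- paste(truth$probe_id, truth$gene_id)
  expect_gte(mean(want %in% got), 0.8)
  expect_true(all(pairs$gene_direction[pairs$probe_direction == "hypo"] == "up"))
  expect_true(all(abs(pairs$distance) <= 500000))
})
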