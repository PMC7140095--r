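# Expression filtering, the NB Wald test, signature scores, ORA and PCA.

test_that("CPM normalizes columns to one million", {
  cm <- count_matrix(matrix(c(7, 999993, 10, 90),
                            2, 2, dimnames = list(c("g1", "g2"), c("A", "B"))))
  x <- cpm(cm)
  expect_equal(x["g1", "A"], 7)  # library of exactly 1e6
  expect_equal(unname(colSums(x)), c(1e6, 1e6))
  doubled <- cm
  doubled[, "B"] <- doubled[, "B"] * 2
  expect_equal(cpm(doubled)[, "B"], x[, "B"])  # scale invariance
  zero <- count_matrix(matrix(c(1, 0), 1, 2,
                              dimnames = list("g1", c("A", "B"))))
  expect_error(cpm(zero), "zero library")
})

test_that("expressed-gene filter requires >80% of one group strictly", {
  sheet <- tiny_sheet(10, 4)
  mk <- function(n_t, n_n) {
    # CPM 5 in the first n_t tumors / n_n normals, 0.5 elsewhere
    c(rep(5, n_t), rep(0.5, 10 - n_t), rep(5, n_n), rep(0.5, 4 - n_n))
  }
  cpm_m <- rbind(all_t = mk(10, 0), edge = mk(8, 3), norm_only = mk(0, 4))
  colnames(cpm_m) <- sheet$case_id
  kept <- filter_expressed(cpm_m, sheet)
  expect_true("all_t" %in% kept)      # 10/10 tumors
  expect_false("edge" %in% kept)      # 80% and 75%: neither strictly >80%
  expect_true("norm_only" %in% kept)  # 4/4 normals
})

test_that("identical counts give zero fold change and no call", {
  sheet <- tiny_sheet(5, 3)
  cm <- count_matrix(matrix(50, 3, 8,
                            dimnames = list(paste0("g", 1:3), sheet$case_id)))
  de <- test_de(cm, sheet)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p_raw, rep(1, 3))
  expect_true(all(de$direction == "none"))
})

test_that("near-Poisson planted genes recover the closed-form fold change", {
  cfg <- sim_config(n_probes = 100, n_genes = 300, nb_dispersion = 1e-4,
                    seed = 21)
  sim <- simulate_study(cfg)
  de <- test_de(sim$counts, sim$sheet)
  truth <- setNames(sim$truth$genes$gene_label, sim$truth$genes$gene_id)
  sf <- methx:::size_factors(sim$counts)
  norm <- sweep(sim$counts, 2, sf, "/")
  is_t <- grepl("^T", colnames(norm))
  closed <- log2(rowMeans(norm[, is_t]) / rowMeans(norm[, !is_t]))
  big <- rowMeans(norm) >= 100 & truth[rownames(norm)] == "up"
  expect_true(all(abs(de$log2fc[match(names(which(big)), de$gene_id)] -
                        closed[big]) < 0.25))
  expect_lt(abs(mean(de$log2fc[match(names(which(big)), de$gene_id)]) -
                  cfg$lfc_effect), 0.2)
})

test_that("thyroid differentiation score centers on the normal group", {
  sheet <- tiny_sheet(3, 3)
  lx <- matrix(rnorm(6 * 5, mean = 5), 5, 6,
               dimnames = list(paste0("g", 1:5), sheet$case_id))
  sig <- c("g1", "g2", "g3")
  tds <- thyroid_differentiation_score(lx, sig, sheet)
  normals <- grepl("^N", tds$sample_id)
  expect_equal(mean(tds$score[normals]), 0, tolerance = 1e-12)
  # a sample equal to the normal mean scores exactly 0
  lx2 <- lx
  lx2[, "T01"] <- rowMeans(lx[, sheet$case_id[sheet$group == "normal"]])
  tds2 <- thyroid_differentiation_score(lx2, sig, sheet)
  expect_equal(tds2$score[tds2$sample_id == "T01"], 0, tolerance = 1e-12)
  # halving signature expression (-1 in log2) lowers the score by 1
  lx3 <- lx
  lx3[sig, "T02"] <- lx[sig, "T02"] - 1
  tds3 <- thyroid_differentiation_score(lx3, sig, sheet)
  expect_equal(tds3$score[tds3$sample_id == "T02"],
               tds$score[tds$sample_id == "T02"] - 1)
  # invariant to non-signature genes and to gene order
  lx4 <- rbind(lx[sample(nrow(lx)), ], extra = rnorm(6))
  tds4 <- thyroid_differentiation_score(lx4, sig, sheet)
  expect_equal(tds4$score, tds$score)
  expect_error(thyroid_differentiation_score(lx, c("absent"), sheet),
               "no signature genes")
})

test_that("BRAF-RAS score classifies centroid-identical samples", {
  set.seed(4)
  genes <- paste0("g", 1:20)
  cen <- data.frame(gene_id = genes, braf = rnorm(20, 5), ras = rnorm(20, 5),
                    stringsAsFactors = FALSE)
  sheet <- tiny_sheet(3, 2)
  lx <- matrix(rnorm(20 * 5, 5), 20, 5, dimnames = list(genes, sheet$case_id))
  lx[, "T01"] <- cen$braf
  lx[, "T02"] <- cen$ras
  lx[, "T03"] <- 2 * cen$ras + 3  # affine image of the RAS centroid
  lx[, "N1"] <- 7                 # constant vector: class NA
  brs <- braf_ras_score(lx, cen, sheet)
  get <- function(id, col) brs[[col]][brs$sample_id == id]
  expect_lt(get("T01", "score"), 0)
  expect_equal(get("T01", "class"), "BRAF_like")
  expect_gt(get("T02", "score"), 0)
  expect_equal(get("T02", "class"), "RAS_like")
  expect_equal(get("T03", "score"), get("T02", "score"), tolerance = 1e-12)
  expect_true(is.na(get("N1", "class")))
  expect_error(braf_ras_score(lx[1:2, ], cen, sheet), ">= 3 centroid genes")
})

test_that("over-representation p-values equal the hypergeometric tail", {
  universe <- paste0("g", 1:20)
  query <- paste0("g", 1:5)
  coll <- list(hit = paste0("g", c(1:4, 10, 11)),   # overlap 4 of set 6
               none = paste0("g", 15:20))           # overlap 0
  res <- ora(query, universe, coll)
  manual <- sum(dhyper(4:5, 6, 14, 5))
  expect_equal(res$p_raw[res$set_name == "hit"], manual, tolerance = 1e-12)
  expect_equal(res$p_raw[res$set_name == "none"],
               sum(dhyper(0:5, 6, 14, 5)), tolerance = 1e-12)
  # degenerate: query = set = universe
  res2 <- ora(universe, universe, list(s = universe))
  expect_equal(res2$overlap, 20)
  expect_equal(res2$p_raw, 1)
  expect_error(ora(c("g1", "zz"), universe, coll), "outside the universe")
  # random cases against explicit pmf summation
  set.seed(8)
  for (i in 1:25) {
    uni <- paste0("u", 1:30)
    q <- sample(uni, sample(3:10, 1))
    s <- sample(uni, sample(3:12, 1))
    k <- length(intersect(q, s))
    expected <- sum(dhyper(k:min(length(q), length(s)), length(s),
                           30 - length(s), length(q)))
    got <- ora(q, uni, list(x = s))$p_raw
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("PCA embedding is deterministic and separates the groups", {
  cfg <- small_config(seed = 17)
  sim <- simulate_study(cfg)
  lx <- log_cpm(sim$counts)
  e1 <- pca_embed(lx, n_components = 2, n_features = 200)
  e2 <- pca_embed(lx, n_components = 2, n_features = 200)
  expect_identical(e1, e2)
  is_t <- grepl("^T", rownames(e1))
  sep <- abs(mean(e1[is_t, 1]) - mean(e1[!is_t, 1]))
  spread <- max(sd(e1[is_t, 1]), sd(e1[!is_t, 1]))
  expect_gt(sep, spread)
  # identical samples land on identical coordinates
  m <- cbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  rownames(m) <- paste0("f", 1:4)
  e3 <- pca_embed(m, n_components = 1, n_features = 4)
  expect_equal(e3["A", 1], e3["B", 1], tolerance = 1e-12)
})
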