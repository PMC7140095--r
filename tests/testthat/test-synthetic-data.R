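# The synthetic study generator: determinism, planted-effect fidelity,
# degenerate configurations.

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 3)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$beta, b$beta)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("manifest respects context proportions and position invariants", {
  cfg_island <- small_config(island_props = c(island = 1, shore = 0,
                                              shelf = 0, open_sea = 0))
  man <- simulate_manifest(cfg_island)
  expect_true(all(man$island_relation == "island"))

  man2 <- simulate_manifest(small_config())
  genic <- man2$genic_relation != "intergenic"
  expect_true(all(!is.na(man2$gene_symbol[genic])))
  expect_true(all(is.na(man2$gene_symbol[!genic])))
  by_chr <- split(man2$position, man2$chromosome)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  expect_error(sim_config(island_props = c(island = 0.5, shore = 0.1,
                                           shelf = 0.1, open_sea = 0.1)),
               "sum to 1")
})

test_that("zero effect size plants no labels and groups agree", {
  cfg <- small_config(frac_hyper = 0, frac_hypo = 0, delta_effect = 0)
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  expect_true(all(meth$truth$probe_label == "null"))
  med_t <- apply(meth$beta[, 1:cfg$n_tumor], 1, median)
  med_n <- apply(meth$beta[, cfg$n_tumor + seq_len(cfg$n_normal)], 1, median)
  expect_lt(median(abs(med_t - med_n)), 0.05)
})

test_that("noiseless limit gives exact mean-shifted beta values", {
  cfg <- small_config(beta_precision = Inf, delta_effect = 0.7)
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  hyper <- meth$truth$probe_id[meth$truth$probe_label == "hyper"]
  b <- meth$beta[hyper, , drop = FALSE]
  tum <- b[, 1:cfg$n_tumor, drop = FALSE]
  nor <- b[, cfg$n_tumor + seq_len(cfg$n_normal), drop = FALSE]
  expect_true(all(abs(tum - (nor[, 1] + 0.7)) < 1e-12))
  expect_true(all(nor >= 0.02 & nor <= 0.28))
})

test_that("beta values stay in [0,1] across configurations", {
  for (d in c(0, 0.3, 0.9)) {
    cfg <- small_config(delta_effect = d, beta_precision = 5)
    meth <- simulate_methylation(cfg, simulate_manifest(cfg))
    expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  }
  expect_error(sim_config(delta_effect = 0.97), "incompatible")
})

test_that("planted delta-beta is recovered within 0.05 at high precision", {
  cfg <- sim_config(n_probes = 1000, n_genes = 100, beta_precision = 300,
                    seed = 5)
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  lab <- meth$truth$probe_label
  med_t <- apply(meth$beta[, 1:cfg$n_tumor], 1, median)
  med_n <- apply(meth$beta[, cfg$n_tumor + seq_len(cfg$n_normal)], 1, median)
  d <- med_t - med_n
  expect_lt(abs(mean(d[lab == "hyper"]) - cfg$delta_effect), 0.05)
  expect_lt(abs(mean(-d[lab == "hypo"]) - cfg$delta_effect), 0.05)
})

test_that("planted fold change is recovered within 0.3 log2 units", {
  cfg <- sim_config(n_probes = 100, n_genes = 1000, seed = 5)
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  expr <- simulate_counts(cfg, man, meth$truth)
  sf <- methx:::size_factors(expr$counts)
  norm <- sweep(expr$counts, 2, sf, "/")
  is_t <- grepl("^T", colnames(norm))
  lfc <- log2(rowMeans(norm[, is_t]) / rowMeans(norm[, !is_t]))
  lab <- expr$gene_truth$gene_label
  base_ok <- rowMeans(norm) >= 50
  up <- lab == "up" & base_ok
  down <- lab == "down" & base_ok
  expect_lt(abs(mean(lfc[up]) - cfg$lfc_effect), 0.3)
  expect_lt(abs(mean(lfc[down]) + cfg$lfc_effect), 0.3)
})

test_that("Poisson limit shifts means by the planted fold", {
  cfg <- small_config(nb_dispersion = 0, lfc_effect = 1,
                      frac_de_up = 0.2, frac_de_down = 0)
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  expr <- simulate_counts(cfg, man, meth$truth)
  sf <- methx:::size_factors(expr$counts)
  norm <- sweep(expr$counts, 2, sf, "/")
  is_t <- grepl("^T", colnames(norm))
  up <- expr$gene_truth$gene_label == "up" & rowMeans(norm) >= 50
  ratio <- rowMeans(norm[, is_t]) / rowMeans(norm[, !is_t])
  expect_lt(abs(mean(ratio[up]) - 2), 0.25)
})

test_that("empty linkage and zero fold change plant no gene labels", {
  cfg <- small_config(lfc_effect = 0, frac_de_up = 0, frac_de_down = 0,
                      linkage_table = list(promoter_hypo_up = 0,
                                           promoter_hyper_down = 0,
                                           body_hyper_up = 0,
                                           body_hypo_down = 0,
                                           enhancer_hypo_up = 0))
  man <- simulate_manifest(cfg)
  meth <- simulate_methylation(cfg, man)
  expr <- simulate_counts(cfg, man, meth$truth)
  expect_true(all(expr$gene_truth$gene_label == "null"))
  expect_equal(nrow(expr$pairs), 0)
})

test_that("study writer produces readable files with seed headers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_probes = 60, n_genes = 40, seed = 9)
  sim <- simulate_study(cfg, dir = dir)
  expect_equal(read_beta_matrix(file.path(dir, "beta.tsv")), sim$beta,
               tolerance = 1e-7)
  expect_equal(read_count_matrix(file.path(dir, "counts.tsv")), sim$counts)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man, sim$manifest)
  expect_equal(read_sample_sheet(file.path(dir, "samples.csv")), sim$sheet)
  expect_match(readLines(file.path(dir, "beta.tsv"), n = 1), "seed=9")
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})
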