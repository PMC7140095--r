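# Orchestration: a single validated run configuration and an end-to-end
# pipeline driver (select samples -> filter probes -> differential methylation
# -> differential expression -> signature scores -> integration quadrants ->
# enhancer pairs -> report). Differential calls for the integration stage are
# recomputed on the paired-sample subset (cases with both assays), mirroring
# how headline methylation and expression analyses use their own, larger
# cohorts.

CONFIG_DEFAULTS <- list(
  beta = NULL, counts = NULL, manifest = NULL, samples = NULL,
  signature = NULL, centroids = NULL, gene_sets = NULL,
  out_dir = NULL,
  alpha = 0.05, min_delta_beta = 0.3, bin_edges = c(0.3, 0.7),
  cpm_threshold = 1, expressed_fraction = 0.8,
  enhancer_window = 500000, enhancer_k = 10,
  pca_features = 1000, seed = 1)

#' Build and validate a run configuration
#'
#' @param ... Named overrides of the defaults: input paths (`beta`, `counts`,
#'   `manifest`, `samples`, optional `signature`, `centroids`, `gene_sets`,
#'   `out_dir`) and thresholds (`alpha`, `min_delta_beta`, `bin_edges`,
#'   `cpm_threshold`, `expressed_fraction`, `enhancer_window`, `enhancer_k`,
#'   `pca_features`, `seed`). Unknown keys are rejected.
#' @return Classed list of validated settings.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    stop_mx("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1)
    stop_mx("alpha out of range [0,1]")
  if (cfg$min_delta_beta < 0 || cfg$min_delta_beta > 1)
    stop_mx("min_delta_beta out of range [0,1]")
  edges <- as.numeric(cfg$bin_edges)
  if (length(edges) != 2 || any(edges < 0 | edges > 1) || edges[1] >= edges[2])
    stop_mx("bin_edges must be two increasing values in [0,1]")
  cfg$bin_edges <- edges
  if (cfg$cpm_threshold < 0) stop_mx("cpm_threshold must be >= 0")
  if (cfg$expressed_fraction < 0 || cfg$expressed_fraction > 1)
    stop_mx("expressed_fraction out of range [0,1]")
  if (cfg$enhancer_window <= 0) stop_mx("enhancer_window must be positive")
  if (cfg$enhancer_k < 1) stop_mx("enhancer_k must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "methx_run_config"
  cfg
}

#' Read and validate a run configuration file
#'
#' YAML or JSON mapping of the keys accepted by [run_config()]. An empty file
#' yields all defaults; unknown keys and out-of-range thresholds are errors
#' naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Classed list from [run_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_mx("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_mx("config must be a mapping of keys to values")
  do.call(run_config, raw)
}

#' Run the full integration pipeline
#'
#' Executes every stage on the configured inputs and returns a run report
#' whose counts equal the cardinality of each stage's output. When `out_dir`
#' is set, stage outputs (`dm.tsv`, `de.tsv`, `context_island.tsv`,
#' `context_genic.tsv`, `scores.tsv`, `quadrants.tsv`, `quadrant_pairs.tsv`,
#' `enhancer_pairs.tsv`, `report.tsv`, `report.json`) are written there.
#'
#' @param config From [run_config()] or [validate_config()].
#' @return List: the run report (selection counts, filter tallies, DM/DE
#'   counts, quadrant and enhancer counts, score table) plus the stage outputs
#'   under `results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "methx_run_config"))
  for (key in c("beta", "counts", "manifest", "samples")) {
    if (is.null(config[[key]])) stop_mx("config is missing input path '%s'", key)
    if (!file.exists(config[[key]]))
      stop_mx("input file for '%s' not found: %s", key, config[[key]])
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_mx("stage '%s' failed: %s", name, conditionMessage(e)))
    mx_log("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  inputs <- stage("load", {
    list(beta = read_beta_matrix(config$beta),
         counts = read_count_matrix(config$counts),
         manifest = read_manifest(config$manifest),
         sheet = read_sample_sheet(config$samples))
  })
  sheet <- inputs$sheet

  sel <- stage("select", {
    list(meth = select_samples(sheet, require_methylation = TRUE),
         expr = select_samples(sheet, require_expression = TRUE),
         paired = select_samples(sheet, require_expression = TRUE,
                                 require_methylation = TRUE))
  })
  subset_sheet <- function(s) sheet[sheet$case_id %in% c(s$tumors, s$normals), ]

  n_before <- nrow(inputs$beta)
  beta_f <- stage("filter", filter_probes(inputs$beta, inputs$manifest))

  dm <- stage("diffmeth", {
    call_dm(beta_f[, intersect(colnames(beta_f),
                               c(sel$meth$tumors, sel$meth$normals)), drop = FALSE],
            subset_sheet(sel$meth), alpha = config$alpha,
            min_delta_beta = config$min_delta_beta, edges = config$bin_edges)
  })
  context <- stage("context", summarize_context(dm, inputs$manifest))

  cpm_all <- cpm(inputs$counts)
  expr_ids <- intersect(colnames(inputs$counts),
                        c(sel$expr$tumors, sel$expr$normals))
  expressed <- stage("filterexpr", {
    filter_expressed(cpm_all[, expr_ids, drop = FALSE], subset_sheet(sel$expr),
                     cpm_threshold = config$cpm_threshold,
                     min_fraction = config$expressed_fraction)
  })
  de <- stage("diffexpr", {
    test_de(inputs$counts[expressed, expr_ids, drop = FALSE],
            subset_sheet(sel$expr), alpha = config$alpha)
  })

  logexpr <- log_cpm(inputs$counts[expressed, , drop = FALSE])
  scores <- stage("scores", {
    out <- list()
    if (!is.null(config$signature)) {
      sig <- utils::read.table(config$signature, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#")[[1]]
      out$tds <- thyroid_differentiation_score(
        logexpr[, expr_ids, drop = FALSE], sig, subset_sheet(sel$expr))
    }
    if (!is.null(config$centroids)) {
      cen <- utils::read.table(config$centroids, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#")
      out$brs <- braf_ras_score(logexpr[, expr_ids, drop = FALSE], cen,
                                subset_sheet(sel$expr))
    }
    out
  })

  # integration runs on cases carrying both assays
  paired_ids <- c(sel$paired$tumors, sel$paired$normals)
  paired_sheet <- subset_sheet(sel$paired)
  dm_paired <- stage("diffmeth7", {
    call_dm(beta_f[, intersect(colnames(beta_f), paired_ids), drop = FALSE],
            paired_sheet, alpha = config$alpha,
            min_delta_beta = config$min_delta_beta, edges = config$bin_edges)
  })
  de_paired <- stage("diffexpr7", {
    test_de(inputs$counts[expressed,
                          intersect(colnames(inputs$counts), paired_ids),
                          drop = FALSE],
            paired_sheet, alpha = config$alpha)
  })
  quad <- stage("integrate",
                promoter_quadrants(dm_paired, de_paired, inputs$manifest))
  gene_delta <- promoter_median_delta_beta(dm_paired, inputs$manifest)
  corr <- tryCatch(correlate_promoter_fc(gene_delta, de_paired),
                   error = function(e) list(r = NA_real_, n = nrow(gene_delta)))
  pairs <- stage("enhancer", {
    enhancer_pairs(dm_paired,
                   logexpr[, intersect(colnames(logexpr), paired_ids), drop = FALSE],
                   inputs$manifest, paired_sheet,
                   window = config$enhancer_window, k_nearest = config$enhancer_k,
                   alpha = config$alpha)
  })

  report <- list(
    samples = list(
      methylation_tumors = length(sel$meth$tumors),
      methylation_normals = length(sel$meth$normals),
      expression_tumors = length(sel$expr$tumors),
      expression_normals = length(sel$expr$normals),
      paired_tumors = length(sel$paired$tumors),
      paired_normals = length(sel$paired$normals)),
    probes = list(input = n_before, retained = nrow(beta_f),
                  removed = n_before - nrow(beta_f), tested = nrow(dm)),
    dm = list(significant = sum(dm$significant),
              hyper = sum(dm$direction == "hyper"),
              hypo = sum(dm$direction == "hypo")),
    genes = list(input = nrow(inputs$counts), expressed = length(expressed),
                 tested = nrow(de)),
    de = list(significant = sum(de$significant),
              up = sum(de$direction == "up"),
              down = sum(de$direction == "down")),
    quadrants = quad$counts,
    promoter_fc_correlation = corr,
    enhancer = list(pairs = nrow(pairs)),
    seed = config$seed)

  results <- list(dm = dm, context = context, de = de, scores = scores,
                  dm_paired = dm_paired, de_paired = de_paired,
                  quadrants = quad, gene_delta = gene_delta,
                  enhancer_pairs = pairs)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(dm, "dm.tsv"); wt(de, "de.tsv")
    wt(context$island, "context_island.tsv")
    wt(context$genic, "context_genic.tsv")
    if (!is.null(scores$tds)) wt(scores$tds, "scores_tds.tsv")
    if (!is.null(scores$brs)) wt(scores$brs, "scores_brs.tsv")
    wt(quad$counts, "quadrants.tsv"); wt(quad$pairs, "quadrant_pairs.tsv")
    wt(pairs, "enhancer_pairs.tsv")
    flat <- report
    flat$quadrants <- NULL
    summary_df <- data.frame(key = names(unlist(flat)),
                             value = unname(unlist(flat)),
                             stringsAsFactors = FALSE)
    wt(summary_df, "report.tsv")
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  c(report, list(results = results))
}
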