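# Expression side: CPM normalization, expressed-gene filtering, a
# negative-binomial Wald differential-expression test, thyroid differentiation
# and BRAF-RAS signature scores, hypergeometric over-representation analysis,
# and PCA plumbing.

#' Counts per million
#'
#' @param counts Count matrix.
#' @return Matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop_mx("zero library size for sample(s): %s",
            paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' log2 CPM with pseudocount 1
#' @param counts Count matrix.
#' @return log2(CPM + 1) matrix.
#' @export
log_cpm <- function(counts) log2(cpm(counts) + 1)

#' Filter to expressed genes
#'
#' A gene counts as expressed in a sample when its CPM exceeds 1; it is
#' retained when, in at least one group, strictly more than
#' `min_fraction` of that group's samples express it.
#'
#' @param cpm_matrix CPM matrix from [cpm()].
#' @param sheet Sample sheet; tumor/normal ids must appear among the columns.
#' @param cpm_threshold Expression threshold on CPM (default 1, exclusive).
#' @param min_fraction Required fraction of a group's samples (default 0.8,
#'   exclusive).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(cpm_matrix, sheet, cpm_threshold = 1,
                             min_fraction = 0.8) {
  sheet <- sample_sheet(sheet)
  tum <- intersect(sheet$case_id[sheet$group == "tumor"], colnames(cpm_matrix))
  nor <- intersect(sheet$case_id[sheet$group == "normal"], colnames(cpm_matrix))
  if (length(tum) == 0 || length(nor) == 0)
    stop_mx("both groups must be represented in the CPM matrix")
  expressed <- cpm_matrix > cpm_threshold
  frac_t <- rowMeans(expressed[, tum, drop = FALSE])
  frac_n <- rowMeans(expressed[, nor, drop = FALSE])
  rownames(cpm_matrix)[frac_t > min_fraction | frac_n > min_fraction]
}

# Median-of-ratios size factors (guards the offset against composition bias
# from asymmetric differential expression); falls back to total-count scaling
# when no gene is positive in all samples.
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (sum(use) >= 10) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(x) {
      stats::median(exp(log(x[x > 0]) - loggeo[use][x > 0]))
    })
  } else {
    sf <- colSums(counts)
  }
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion from library-size-normalized counts,
# pooled across groups, floored.
mom_dispersion <- function(norm_counts, is_tumor, floor = 1e-8) {
  disp_group <- function(x) {
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (stats::var(x) - m) / m^2
  }
  d <- apply(norm_counts, 1, function(x) {
    vals <- c(disp_group(x[is_tumor]), disp_group(x[!is_tumor]))
    if (all(is.na(vals))) return(floor)
    mean(vals, na.rm = TRUE)
  })
  pmax(d, floor)
}

#' Negative-binomial Wald differential-expression test
#'
#' A self-contained stand-in for a full differential-expression package: per
#' gene, a negative-binomial generalized linear model with a group covariate
#' and a log library-size offset is fit (library sizes as median-of-ratios
#' size factors, which are robust to composition bias from asymmetric
#' differential expression); the gene-wise dispersion comes from a
#' method-of-moments estimate on size-factor-normalized counts (pooled over
#' the two groups, floored at 1e-8); the Wald statistic on the group
#' coefficient is referred to a t distribution with residual degrees of
#' freedom (a small-sample choice); p-values are BH-adjusted across genes.
#' `log2fc` is the group coefficient divided by ln 2. The contract is
#' controlled type-I error and BH-significant calls, not equivalence with any
#' specific external tool.
#'
#' @param counts Count matrix, pre-filtered with [filter_expressed()].
#' @param sheet Sample sheet (>= 2 samples per group among the columns).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame with `gene_id`, `log2fc`, `p_raw`, `p_adj`,
#'   `significant`, `direction`, `converged`.
#' @export
test_de <- function(counts, sheet, alpha = 0.05) {
  counts <- count_matrix(counts)
  sheet <- sample_sheet(sheet)
  tum <- intersect(sheet$case_id[sheet$group == "tumor"], colnames(counts))
  nor <- intersect(sheet$case_id[sheet$group == "normal"], colnames(counts))
  if (length(tum) < 2 || length(nor) < 2)
    stop_mx("need >= 2 samples per group (found %d tumor, %d normal)",
            length(tum), length(nor))
  sub <- counts[, c(tum, nor), drop = FALSE]
  is_tumor <- colnames(sub) %in% tum
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  disp <- mom_dispersion(norm, is_tumor)
  group <- factor(ifelse(is_tumor, "tumor", "normal"), levels = c("normal", "tumor"))
  off <- log(sf)
  df_resid <- ncol(sub) - 2L

  fit_gene <- function(y, theta) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ group + offset(off),
                                  family = MASS::negative.binomial(theta = theta))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_, 0))
    sm <- summary(fit)$coefficients
    c(sm["grouptumor", "Estimate"], sm["grouptumor", "Std. Error"], 1)
  }
  res <- t(vapply(seq_len(nrow(sub)), function(i) {
    y <- sub[i, ]
    if (stats::var(y) == 0 && all(abs(diff(sf)) < 1e-12)) {
      return(c(0, NA_real_, 1))
    }
    fit_gene(y, 1 / disp[i])
  }, numeric(3)))
  beta_hat <- res[, 1]; se <- res[, 2]; converged <- res[, 3] == 1
  stat <- beta_hat / se
  p_raw <- 2 * stats::pt(-abs(stat), df = df_resid)
  # degenerate fits: identical counts or non-convergence
  p_raw[is.na(p_raw) | se == 0] <- 1
  p_raw[!converged] <- 1
  beta_hat[!converged] <- 0
  if (any(!converged))
    mx_log("test_de: %d gene(s) did not converge; p set to 1", sum(!converged))
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)
  p_adj <- bh_adjust(p_raw)
  log2fc <- beta_hat / log(2)
  significant <- p_adj < alpha
  direction <- ifelse(significant & log2fc > 0, "up",
                      ifelse(significant & log2fc < 0, "down", "none"))
  data.frame(gene_id = rownames(sub), log2fc = log2fc, p_raw = p_raw,
             p_adj = p_adj, significant = significant, direction = direction,
             converged = converged, stringsAsFactors = FALSE)
}

#' Thyroid differentiation score
#'
#' Mean, over the signature genes present in the matrix, of each sample's
#' log2 expression centered on the normal-group mean. Normal samples therefore
#' average to a score of 0; negative scores indicate dedifferentiation.
#' Signature genes missing from the matrix are skipped with a log message.
#'
#' @param logexpr log2 expression matrix (genes x samples), e.g. [log_cpm()].
#' @param signature Character vector of signature gene ids.
#' @param sheet Sample sheet (>= 2 normal samples among the columns).
#' @return Data frame with `sample_id` and `score`.
#' @export
thyroid_differentiation_score <- function(logexpr, signature, sheet) {
  sheet <- sample_sheet(sheet)
  nor <- intersect(sheet$case_id[sheet$group == "normal"], colnames(logexpr))
  if (length(nor) < 2) stop_mx("need >= 2 normal samples")
  present <- intersect(signature, rownames(logexpr))
  if (length(present) == 0) stop_mx("no signature genes present in the matrix")
  if (length(present) < length(signature))
    mx_log("thyroid_differentiation_score: %d signature gene(s) missing, skipped",
           length(signature) - length(present))
  ids <- intersect(sheet$case_id, colnames(logexpr))
  sub <- logexpr[present, ids, drop = FALSE]
  centered <- sub - rowMeans(sub[, nor, drop = FALSE])
  data.frame(sample_id = ids, score = colMeans(centered),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' BRAF-RAS score
#'
#' Correlation-based signature score: for each sample, the Pearson correlation
#' with the RAS-like centroid minus the correlation with the BRAF-like
#' centroid, over the centroid genes present in the matrix. Negative scores
#' classify the sample as BRAF-like, non-negative as RAS-like, matching the
#' convention that negative scores are BRAF-V600E-like. Samples with a
#' constant expression vector over the shared genes get class `NA`.
#'
#' @param logexpr log2 expression matrix (genes x samples).
#' @param centroids Data frame with columns `gene_id`, `braf`, `ras` holding
#'   the two reference profiles.
#' @param sheet Sample sheet (used only to order/select samples).
#' @return Data frame with `sample_id`, `score`, `class`.
#' @export
braf_ras_score <- function(logexpr, centroids, sheet) {
  sheet <- sample_sheet(sheet)
  req <- c("gene_id", "braf", "ras")
  if (!all(req %in% names(centroids)))
    stop_mx("centroids must have columns: %s", paste(req, collapse = ", "))
  shared <- intersect(centroids$gene_id, rownames(logexpr))
  if (length(shared) < 3) stop_mx("need >= 3 centroid genes present in the matrix")
  cen <- centroids[match(shared, centroids$gene_id), ]
  ids <- intersect(sheet$case_id, colnames(logexpr))
  sub <- logexpr[shared, ids, drop = FALSE]
  score <- vapply(seq_along(ids), function(j) {
    x <- sub[, j]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, cen$ras) - stats::cor(x, cen$braf)
  }, numeric(1))
  cls <- ifelse(is.na(score), NA_character_,
                ifelse(score < 0, "BRAF_like", "RAS_like"))
  data.frame(sample_id = ids, score = score, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation of each gene set in a query list against a
#' gene universe: the p-value is the upper hypergeometric tail
#' P(overlap >= observed) with set membership restricted to the universe; BH
#' adjustment across sets.
#'
#' @param query Character vector of genes of interest (must lie in universe).
#' @param universe Character vector of background genes.
#' @param collection Named list of gene sets ([read_gmt()]).
#' @return Data frame with `set_name`, `set_size` (in universe), `overlap`,
#'   `expected`, `fold`, `p_raw`, `p_adj`.
#' @export
ora <- function(query, universe, collection) {
  query <- unique(query); universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop_mx("query gene(s) outside the universe: %s",
            paste(utils::head(outside, 5), collapse = ", "))
  if (length(collection) == 0)
    return(data.frame(set_name = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      fold = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(members, query))
    m <- length(members)
    expected <- m * length(query) / length(universe)
    p <- stats::phyper(k - 1, m, length(universe) - m, length(query),
                       lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, overlap = k, expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(pmin(pmax(out$p_raw, .Machine$double.xmin), 1))
  out
}

#' PCA embedding of samples
#'
#' Centered principal-component analysis of the samples over the
#' `n_features` highest-variance features, with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param matrix Numeric matrix, features x samples.
#' @param n_components Number of components (default 2).
#' @param n_features Number of top-variance features used (default 1000).
#' @return Matrix of sample coordinates (samples x components).
#' @export
pca_embed <- function(matrix, n_components = 2, n_features = 1000) {
  if (ncol(matrix) < 2) stop_mx("need >= 2 samples")
  v <- apply(matrix, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_features, nrow(matrix)))]
  x <- t(matrix[keep, , drop = FALSE])
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores
}
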