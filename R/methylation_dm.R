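# Differential-methylation caller. Beta values are binned into three
# methylation states (low <= 0.3, moderate in between, high >= 0.7); each
# probe's 2 (group) x 3 (bin) table is tested with a two-sided exact
# multivariate-hypergeometric test; p-values are BH-adjusted across all tested
# probes; probes with adjusted p < alpha and |median delta-beta| >= 0.3 are
# called hyper- or hypomethylated by the sign of delta-beta.

BIN_LEVELS <- c("low", "moderate", "high")

#' Filter probes before differential-methylation testing
#'
#' Removes probes flagged as cross-reactive, probes overlapping common
#' polymorphisms (minor allele frequency > 5%), and probes on the sex
#' chromosomes (chrX/chrY). Removal counts per reason are logged.
#'
#' @param beta Beta matrix.
#' @param annotation Probe annotation covering every probe in `beta`.
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(beta, annotation) {
  beta <- beta_matrix(beta)
  annotation <- probe_annotation(annotation)
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx))
    stop_mx("probes absent from annotation: %s",
            paste(utils::head(rownames(beta)[is.na(idx)], 5), collapse = ", "))
  ann <- annotation[idx, ]
  sex <- ann$chromosome %in% c("chrX", "chrY")
  drop <- ann$cross_reactive_flag | ann$maf_over_5pct_flag | sex
  mx_log("filter_probes: removed %d cross-reactive, %d MAF>5%%, %d sex-chromosome (%d probes retained)",
         sum(ann$cross_reactive_flag), sum(ann$maf_over_5pct_flag), sum(sex),
         sum(!drop))
  beta[!drop, , drop = FALSE]
}

#' Bin beta values into methylation states
#'
#' Low methylation is beta <= `edges[1]` (default 0.3), high is beta >=
#' `edges[2]` (default 0.7), moderate lies strictly between. Both boundaries
#' are closed towards the outer bins, as the thresholds are defined.
#'
#' @param value Numeric vector of beta values in \[0, 1\].
#' @param edges Two increasing bin edges.
#' @return Character vector in \{low, moderate, high\}.
#' @export
bin_beta <- function(value, edges = c(0.3, 0.7)) {
  if (length(edges) != 2 || edges[1] >= edges[2])
    stop_mx("bin edges must be two increasing values")
  if (any(is.na(value)) || any(value < 0 | value > 1))
    stop_mx("beta values must lie in [0,1] and be non-missing")
  ifelse(value <= edges[1], "low", ifelse(value >= edges[2], "high", "moderate"))
}

#' Two-sided exact test for a 2x3 contingency table
#'
#' Exact test under the multivariate hypergeometric null with fixed margins:
#' the two-sided p-value is the total probability of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (ties counted as extreme within a relative tolerance of 1e-12). The
#' enumeration runs over the two free cells of the first row in log-gamma
#' arithmetic.
#'
#' @param table 2x3 matrix of non-negative integer counts; both row sums must
#'   be at least 1.
#' @return The two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x3 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 3))) stop_mx("expected a 2x3 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop_mx("table cells must be non-negative integers")
  r <- rowSums(tab); cs <- colSums(tab)
  if (any(r < 1)) stop_mx("both row sums must be >= 1")
  n <- sum(tab)
  # log P(table) = sum(lchoose-free form): prod(row!)prod(col!)/(n! prod(cell!))
  log_const <- sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  log_p_table <- function(a, b) {
    cc <- r[1] - a - b
    log_const - (lgamma(a + 1) + lgamma(b + 1) + lgamma(cc + 1) +
                   lgamma(cs[1] - a + 1) + lgamma(cs[2] - b + 1) +
                   lgamma(cs[3] - cc + 1))
  }
  obs <- log_p_table(tab[1, 1], tab[1, 2])
  a <- rep(0:min(r[1], cs[1]), each = min(r[1], cs[2]) + 1)
  b <- rep(0:min(r[1], cs[2]), times = min(r[1], cs[1]) + 1)
  cc <- r[1] - a - b
  ok <- cc >= 0 & cc <= cs[3]
  lp <- log_p_table(a[ok], b[ok])
  # include tables at most as probable as observed; tolerate float ties
  p <- sum(exp(lp[lp <= obs + log1p(1e-12)]))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across the supplied p-values
#' (delegating to [stats::p.adjust()]); returns values in input order,
#' elementwise no smaller than the input and capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop_mx("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated probes
#'
#' Per probe: each retained sample's beta value is binned, the group x bin
#' table is tested with [fisher_exact_2x3()], p-values are BH-adjusted across
#' all tested probes, and delta-beta is the tumor median beta minus the normal
#' median beta. A probe is significant iff adjusted p < `alpha` and
#' |delta-beta| >= `min_delta_beta`; significant probes are called `hyper`
#' (delta-beta > 0) or `hypo` (delta-beta < 0). Probes with a missing value in
#' any retained sample are dropped (with a logged count) before testing;
#' zero-variance probes are still tested (their table is degenerate and yields
#' p = 1), keeping the adjustment denominator stable.
#'
#' @param beta Beta matrix, pre-filtered with [filter_probes()].
#' @param sheet Sample sheet; its tumor/normal case ids must appear among the
#'   beta matrix columns (at least 2 per group).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param min_delta_beta Minimum |delta-beta| effect (default 0.3).
#' @param edges Bin edges passed to [bin_beta()].
#' @return Data frame with columns `probe_id`, counts per group and bin,
#'   `p_raw`, `p_adj`, `delta_beta`, `direction`, `significant`.
#' @export
call_dm <- function(beta, sheet, alpha = 0.05, min_delta_beta = 0.3,
                    edges = c(0.3, 0.7)) {
  beta <- beta_matrix(beta)
  sheet <- sample_sheet(sheet)
  tum <- intersect(sheet$case_id[sheet$group == "tumor"], colnames(beta))
  nor <- intersect(sheet$case_id[sheet$group == "normal"], colnames(beta))
  if (length(tum) < 2 || length(nor) < 2)
    stop_mx("need >= 2 samples per group (found %d tumor, %d normal)",
            length(tum), length(nor))
  sub <- beta[, c(tum, nor), drop = FALSE]
  has_na <- rowSums(is.na(sub)) > 0
  if (any(has_na)) {
    mx_log("call_dm: dropped %d probe(s) with missing values", sum(has_na))
    sub <- sub[!has_na, , drop = FALSE]
  }
  n_probe <- nrow(sub)
  if (n_probe == 0) stop_mx("no probes left to test")

  bins <- matrix(bin_beta(sub, edges = edges), nrow = n_probe)
  is_t <- colnames(sub) %in% tum
  count_bins <- function(bm) {
    vapply(BIN_LEVELS, function(lv) rowSums(bm == lv), numeric(n_probe))
  }
  tum_counts <- count_bins(bins[, is_t, drop = FALSE])
  nor_counts <- count_bins(bins[, !is_t, drop = FALSE])
  if (n_probe == 1) {
    tum_counts <- matrix(tum_counts, nrow = 1, dimnames = list(NULL, BIN_LEVELS))
    nor_counts <- matrix(nor_counts, nrow = 1, dimnames = list(NULL, BIN_LEVELS))
  }

  p_raw <- vapply(seq_len(n_probe), function(i) {
    fisher_exact_2x3(rbind(tum_counts[i, ], nor_counts[i, ]))
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  delta <- apply(sub[, is_t, drop = FALSE], 1, stats::median) -
    apply(sub[, !is_t, drop = FALSE], 1, stats::median)
  significant <- p_adj < alpha & abs(delta) >= min_delta_beta
  direction <- ifelse(significant & delta > 0, "hyper",
                      ifelse(significant & delta < 0, "hypo", "none"))
  out <- data.frame(probe_id = rownames(sub),
                    tumor_low = tum_counts[, "low"],
                    tumor_moderate = tum_counts[, "moderate"],
                    tumor_high = tum_counts[, "high"],
                    normal_low = nor_counts[, "low"],
                    normal_moderate = nor_counts[, "moderate"],
                    normal_high = nor_counts[, "high"],
                    p_raw = p_raw, p_adj = p_adj, delta_beta = delta,
                    direction = direction, significant = significant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize genomic context of differentially methylated probes
#'
#' For the hypermethylated set, the hypomethylated set and the background (all
#' tested probes), computes the proportion of probes in each island-relation
#' category (island/shore/shelf/open sea) and each genic-relation category
#' (promoter/body/intergenic). Each proportion vector sums to 1.
#'
#' @param dm Output of [call_dm()].
#' @param annotation Probe annotation covering all tested probes.
#' @return List with data frames `island` and `genic`; rows are the categories,
#'   columns `hyper`, `hypo`, `background`.
#' @export
summarize_context <- function(dm, annotation) {
  annotation <- probe_annotation(annotation)
  idx <- match(dm$probe_id, annotation$probe_id)
  if (anyNA(idx))
    stop_mx("tested probes absent from annotation: %s",
            paste(utils::head(dm$probe_id[is.na(idx)], 5), collapse = ", "))
  ann <- annotation[idx, ]
  prop_tab <- function(values, levels, sel) {
    if (sum(sel) == 0) return(stats::setNames(rep(NA_real_, length(levels)), levels))
    tab <- table(factor(values[sel], levels = levels))
    as.numeric(tab) / sum(tab)
  }
  build <- function(values, levels) {
    data.frame(category = levels,
               hyper = prop_tab(values, levels, dm$direction == "hyper"),
               hypo = prop_tab(values, levels, dm$direction == "hypo"),
               background = prop_tab(values, levels, rep(TRUE, nrow(dm))),
               stringsAsFactors = FALSE)
  }
  list(island = build(ann$island_relation, ISLAND_LEVELS),
       genic = build(ann$genic_relation, GENIC_LEVELS))
}
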