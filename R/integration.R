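# Integration of differential methylation with differential expression:
# promoter/gene-body quadrant classification, per-gene promoter median
# delta-beta, the delta-beta versus fold-change correlation, and a supervised
# enhancer-gene pairing stage.

QUADRANT_LEVELS <- c("promoter_hypo_up", "promoter_hyper_down",
                     "body_hyper_up", "body_hypo_down")

# Gene reference positions derived from the probe annotation: the TSS is
# proxied by the median position of the gene's promoter probes, falling back
# to the gene's minimum probe position when it has no promoter probe.
gene_positions <- function(annotation) {
  annotation <- probe_annotation(annotation)
  ann <- annotation[!is.na(annotation$gene_symbol), ]
  if (nrow(ann) == 0)
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      position = numeric(0), stringsAsFactors = FALSE))
  split_idx <- split(seq_len(nrow(ann)), ann$gene_symbol)
  rows <- lapply(names(split_idx), function(g) {
    sub <- ann[split_idx[[g]], ]
    prom <- sub$position[sub$genic_relation == "promoter"]
    pos <- if (length(prom) > 0) stats::median(prom) else min(sub$position)
    data.frame(gene_id = g, chromosome = sub$chromosome[1], position = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Nearest gene (same chromosome) for every enhancer-flagged probe.
nearest_gene_table <- function(annotation) {
  annotation <- probe_annotation(annotation)
  gp <- gene_positions(annotation)
  enh <- annotation[annotation$enhancer_flag, ]
  if (nrow(enh) == 0 || nrow(gp) == 0)
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(enh)), function(i) {
    cand <- gp[gp$chromosome == enh$chromosome[i], ]
    if (nrow(cand) == 0)
      return(data.frame(probe_id = enh$probe_id[i], gene_id = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    d <- abs(cand$position - enh$position[i])
    j <- which.min(d)
    data.frame(probe_id = enh$probe_id[i], gene_id = cand$gene_id[j],
               distance = d[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Promoter and gene-body integration quadrants
#'
#' Pairs each significant differentially methylated probe in a promoter or
#' gene body with its mapped gene's differential-expression record and assigns
#' the pair to one of four quadrants when both calls are significant and the
#' directions are concordant with the quadrant's biology: promoter
#' hypomethylation with increased expression, promoter hypermethylation with
#' decreased expression, gene-body hypermethylation with increased expression,
#' gene-body hypomethylation with decreased expression. Pairs whose gene is
#' significant in the opposite direction are counted as discordant; probes
#' whose gene is absent from the DE table or not significant are counted as
#' unpaired. Quadrant counts are reported both as probe counts and as distinct
#' gene counts.
#'
#' @param dm [call_dm()] output.
#' @param de [test_de()] output.
#' @param annotation Probe annotation.
#' @return List with `pairs` (probe_id, gene_id, quadrant), `counts`
#'   (quadrant, n_probes, n_genes), `n_discordant`, `n_unpaired`.
#' @export
promoter_quadrants <- function(dm, de, annotation) {
  annotation <- probe_annotation(annotation)
  sig <- dm[dm$significant, , drop = FALSE]
  idx <- match(sig$probe_id, annotation$probe_id)
  if (anyNA(idx))
    stop_mx("significant probes absent from annotation")
  ann <- annotation[idx, , drop = FALSE]
  in_gene <- ann$genic_relation %in% c("promoter", "body")
  sig <- sig[in_gene, , drop = FALSE]
  ann <- ann[in_gene, , drop = FALSE]
  de_dir <- stats::setNames(de$direction, de$gene_id)
  gene_dir <- de_dir[ann$gene_symbol]
  expected <- ifelse(ann$genic_relation == "promoter",
                     ifelse(sig$direction == "hypo", "up", "down"),
                     ifelse(sig$direction == "hyper", "up", "down"))
  paired <- !is.na(gene_dir) & gene_dir != "none"
  concordant <- paired & gene_dir == expected
  quadrant <- paste0(ifelse(ann$genic_relation == "promoter", "promoter_", "body_"),
                     sig$direction, "_", gene_dir)
  pairs <- data.frame(probe_id = sig$probe_id[concordant],
                      gene_id = ann$gene_symbol[concordant],
                      quadrant = quadrant[concordant],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  counts <- data.frame(
    quadrant = QUADRANT_LEVELS,
    n_probes = vapply(QUADRANT_LEVELS,
                      function(q) sum(pairs$quadrant == q), integer(1)),
    n_genes = vapply(QUADRANT_LEVELS,
                     function(q) length(unique(pairs$gene_id[pairs$quadrant == q])),
                     integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(pairs = pairs, counts = counts,
       n_discordant = sum(paired & !concordant),
       n_unpaired = sum(!paired))
}

#' Per-gene promoter median delta-beta
#'
#' For each gene with at least one significant promoter probe, the median of
#' those probes' delta-beta values.
#'
#' @param dm [call_dm()] output.
#' @param annotation Probe annotation.
#' @return Data frame with `gene_id`, `delta_beta`, `n_probes`.
#' @export
promoter_median_delta_beta <- function(dm, annotation) {
  annotation <- probe_annotation(annotation)
  sig <- dm[dm$significant, , drop = FALSE]
  idx <- match(sig$probe_id, annotation$probe_id)
  ann <- annotation[idx, , drop = FALSE]
  keep <- ann$genic_relation == "promoter" & !is.na(ann$gene_symbol)
  if (sum(keep) == 0)
    return(data.frame(gene_id = character(0), delta_beta = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  by_gene <- split(sig$delta_beta[keep], ann$gene_symbol[keep])
  data.frame(gene_id = names(by_gene),
             delta_beta = vapply(by_gene, stats::median, numeric(1)),
             n_probes = vapply(by_gene, length, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate promoter methylation change with expression fold change
#'
#' Pearson correlation between per-gene promoter delta-beta
#' ([promoter_median_delta_beta()]) and the matched genes' log2 fold changes.
#'
#' @param gene_delta Data frame with `gene_id` and `delta_beta`.
#' @param de [test_de()] output.
#' @return List with `r` (Pearson correlation) and `n` (matched genes).
#' @export
correlate_promoter_fc <- function(gene_delta, de) {
  m <- merge(gene_delta[, c("gene_id", "delta_beta")],
             de[, c("gene_id", "log2fc")], by = "gene_id")
  if (nrow(m) < 3)
    stop_mx("need >= 3 matched genes to correlate (found %d)", nrow(m))
  if (stats::sd(m$delta_beta) == 0 || stats::sd(m$log2fc) == 0)
    stop_mx("correlation undefined: zero variance in one of the axes")
  list(r = stats::cor(m$delta_beta, m$log2fc), n = nrow(m))
}

#' Supervised enhancer-gene pairing
#'
#' A simplified supervised enhancer analysis: every significant differentially
#' methylated probe carrying the enhancer flag is paired with its `k_nearest`
#' genes within `window` base pairs on the same chromosome; for each candidate
#' pair a one-sided Wilcoxon rank-sum test asks whether the gene's expression
#' differs between tumors and normals in the direction anti-concordant with
#' the methylation change (hypomethylated probes can only pair with
#' upregulated genes, hypermethylated only with downregulated ones); p-values
#' are BH-adjusted across all candidate pairs and pairs with adjusted p below
#' `alpha` are retained.
#'
#' @param dm [call_dm()] output (computed on the paired-sample subset).
#' @param logexpr log2 expression matrix (genes x samples).
#' @param annotation Probe annotation with positions and enhancer flags.
#' @param sheet Sample sheet; tumor/normal ids must appear in `logexpr`.
#' @param window Maximum probe-gene distance in base pairs (default 500000).
#' @param k_nearest Number of nearest genes considered per probe (default 10).
#' @param alpha Adjusted-p cutoff for retained pairs (default 0.05).
#' @return Data frame with `probe_id`, `gene_id`, `probe_direction`,
#'   `gene_direction`, `distance`, `p_raw`, `p_adj`.
#' @export
enhancer_pairs <- function(dm, logexpr, annotation, sheet,
                           window = 500000, k_nearest = 10, alpha = 0.05) {
  annotation <- probe_annotation(annotation)
  sheet <- sample_sheet(sheet)
  tum <- intersect(sheet$case_id[sheet$group == "tumor"], colnames(logexpr))
  nor <- intersect(sheet$case_id[sheet$group == "normal"], colnames(logexpr))
  if (length(tum) < 2 || length(nor) < 2)
    stop_mx("need >= 2 samples per group in the expression matrix")
  if (anyNA(annotation$position)) stop_mx("annotation lacks probe positions")
  gp <- gene_positions(annotation)
  gp <- gp[gp$gene_id %in% rownames(logexpr), , drop = FALSE]

  sig <- dm[dm$significant, , drop = FALSE]
  idx <- match(sig$probe_id, annotation$probe_id)
  ann <- annotation[idx, , drop = FALSE]
  enh <- which(ann$enhancer_flag)
  cand <- list()
  for (i in enh) {
    g <- gp[gp$chromosome == ann$chromosome[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(g$position - ann$position[i])
    in_win <- d <= window
    if (!any(in_win)) next
    ord <- order(d[in_win])[seq_len(min(k_nearest, sum(in_win)))]
    g <- g[in_win, , drop = FALSE][ord, , drop = FALSE]
    cand[[length(cand) + 1L]] <- data.frame(
      probe_id = sig$probe_id[i],
      gene_id = g$gene_id,
      probe_direction = sig$direction[i],
      distance = d[in_win][ord],
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(probe_id = character(0), gene_id = character(0),
                      probe_direction = character(0), gene_direction = character(0),
                      distance = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)

  # one-sided rank-sum per unique (gene, direction); hypo locks to "greater in
  # tumor" (gene up), hyper to "less in tumor" (gene down)
  keys <- unique(cand[, c("gene_id", "probe_direction")])
  pk <- vapply(seq_len(nrow(keys)), function(j) {
    y_t <- logexpr[keys$gene_id[j], tum]
    y_n <- logexpr[keys$gene_id[j], nor]
    alt <- if (keys$probe_direction[j] == "hypo") "greater" else "less"
    suppressWarnings(stats::wilcox.test(y_t, y_n, alternative = alt,
                                        exact = TRUE)$p.value)
  }, numeric(1))
  key_id <- paste(keys$gene_id, keys$probe_direction)
  cand$p_raw <- pk[match(paste(cand$gene_id, cand$probe_direction), key_id)]
  cand$p_adj <- bh_adjust(pmin(pmax(cand$p_raw, .Machine$double.xmin), 1))
  out <- cand[cand$p_adj < alpha, , drop = FALSE]
  out$gene_direction <- ifelse(out$probe_direction == "hypo", "up", "down")
  rownames(out) <- NULL
  out[, c("probe_id", "gene_id", "probe_direction", "gene_direction",
          "distance", "p_raw", "p_adj")]
}
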