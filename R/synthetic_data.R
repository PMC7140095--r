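# Synthetic study generator: probe manifests, bimodal beta matrices with
# planted hyper/hypo probes, negative-binomial counts with planted fold
# changes, and probe-gene linkage so that every downstream stage has a ground
# truth to recover. The default configuration emulates a small
# tumor-versus-normal array study: 10 tumors, 4 normals, 2,000 probes and
# 2,000 genes with 10% planted effects in each direction.

#' Simulation configuration
#'
#' Builds the full parameter set for the synthetic study generator. Defaults
#' emulate the small tumor/normal design the package targets: 10 tumor and 4
#' normal samples, bimodal beta baselines, planted |delta-beta| effects of 0.6
#' at a Beta noise concentration of 300, and 4-fold (log2FC = 2) expression
#' effects on 10% of genes in each direction.
#'
#' @param n_probes Number of array probes.
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Group sizes (each >= 2).
#' @param frac_hyper,frac_hypo Fractions of eligible probes planted as
#'   hyper-/hypomethylated (summing to at most 1).
#' @param delta_effect Planted mean beta shift (tumor minus normal).
#' @param beta_precision Concentration of the Beta noise around each probe
#'   mean; `Inf` gives noiseless values equal to the mean.
#' @param frac_de_up,frac_de_down Target fractions of genes planted up/down.
#' @param lfc_effect Planted log2 fold change for up/down genes.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-12 give Poisson counts.
#' @param linkage_table Named list of probabilities that a planted
#'   differentially methylated probe's mapped gene receives the concordant
#'   expression label, one entry per quadrant
#'   (`promoter_hypo_up`, `promoter_hyper_down`, `body_hyper_up`,
#'   `body_hypo_down`, `enhancer_hypo_up`).
#' @param island_props Named island-context proportions (must sum to 1).
#' @param genic_props Named genic-context proportions (must sum to 1).
#' @param frac_enhancer Fraction of intergenic probes flagged as enhancers.
#' @param frac_cross_reactive,frac_maf Fractions of probes flagged as
#'   cross-reactive / common-SNP-overlapping (exercises probe filtering).
#' @param frac_sex_genes Fraction of gene loci placed on chrX (their probes
#'   are removed by the sex-chromosome filter).
#' @param seed Base seed; each generator stage draws from its own named
#'   substream so stages do not perturb one another.
#' @return A classed list of validated parameters.
#' @export
sim_config <- function(n_probes = 2000, n_genes = 2000,
                       n_tumor = 10, n_normal = 4,
                       frac_hyper = 0.1, frac_hypo = 0.1,
                       delta_effect = 0.6, beta_precision = 300,
                       frac_de_up = 0.1, frac_de_down = 0.1,
                       lfc_effect = 2, nb_dispersion = 0.1,
                       linkage_table = list(promoter_hypo_up = 0.5,
                                            promoter_hyper_down = 0.5,
                                            body_hyper_up = 0.5,
                                            body_hypo_down = 0.5,
                                            enhancer_hypo_up = 0.5),
                       island_props = c(island = 0.15, shore = 0.15,
                                        shelf = 0.10, open_sea = 0.60),
                       genic_props = c(promoter = 0.25, body = 0.35,
                                       intergenic = 0.40),
                       frac_enhancer = 0.30,
                       frac_cross_reactive = 0.02, frac_maf = 0.02,
                       frac_sex_genes = 0.03,
                       seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              frac_hyper = frac_hyper, frac_hypo = frac_hypo,
              delta_effect = delta_effect, beta_precision = beta_precision,
              frac_de_up = frac_de_up, frac_de_down = frac_de_down,
              lfc_effect = lfc_effect, nb_dispersion = nb_dispersion,
              linkage_table = linkage_table,
              island_props = island_props, genic_props = genic_props,
              frac_enhancer = frac_enhancer,
              frac_cross_reactive = frac_cross_reactive, frac_maf = frac_maf,
              frac_sex_genes = frac_sex_genes,
              seed = as.integer(seed))
  fracs <- c(frac_hyper = frac_hyper, frac_hypo = frac_hypo,
             frac_de_up = frac_de_up, frac_de_down = frac_de_down,
             frac_enhancer = frac_enhancer,
             frac_cross_reactive = frac_cross_reactive, frac_maf = frac_maf,
             frac_sex_genes = frac_sex_genes,
             unlist(linkage_table))
  if (any(fracs < 0 | fracs > 1))
    stop_mx("fractions must lie in [0,1]: %s",
            paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (frac_hyper + frac_hypo > 1)
    stop_mx("frac_hyper + frac_hypo must be <= 1")
  if (cfg$n_tumor < 2 || cfg$n_normal < 2)
    stop_mx("need at least 2 samples per group")
  if (abs(sum(island_props) - 1) > 1e-8)
    stop_mx("island_props must sum to 1 (got %g)", sum(island_props))
  if (abs(sum(genic_props) - 1) > 1e-8)
    stop_mx("genic_props must sum to 1 (got %g)", sum(genic_props))
  if (!setequal(names(island_props), ISLAND_LEVELS))
    stop_mx("island_props must name exactly: %s", paste(ISLAND_LEVELS, collapse = ", "))
  if (!setequal(names(genic_props), GENIC_LEVELS))
    stop_mx("genic_props must name exactly: %s", paste(GENIC_LEVELS, collapse = ", "))
  if (delta_effect < 0 || delta_effect > 0.96)
    stop_mx("delta_effect %g incompatible with the [0.02, 0.98] baseline support",
            delta_effect)
  req <- c("promoter_hypo_up", "promoter_hyper_down", "body_hyper_up",
           "body_hypo_down", "enhancer_hypo_up")
  miss <- setdiff(req, names(linkage_table))
  if (length(miss) > 0)
    stop_mx("linkage_table missing entries: %s", paste(miss, collapse = ", "))
  class(cfg) <- "methx_sim_config"
  cfg
}

# Gene loci are laid out on a deterministic grid: up to 100 genes per
# chromosome, TSS every 100 kb. Offsets per probe category are drawn without
# replacement from disjoint ranges so positions are unique and strictly
# increasing after sorting.
GENE_SPACING <- 100000L
GENES_PER_CHR <- 100L

gene_layout <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  chr_idx <- (seq_len(n) - 1L) %/% GENES_PER_CHR + 1L
  n_sex <- round(config$frac_sex_genes * n)
  # chrX genes occupy the final block so autosomal spacing is untouched
  chrom <- paste0("chr", chr_idx)
  if (n_sex > 0) chrom[(n - n_sex + 1L):n] <- "chrX"
  local_idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  data.frame(gene_id = gene_id, chromosome = chrom,
             tss = local_idx * GENE_SPACING, stringsAsFactors = FALSE)
}

#' Simulate a probe annotation manifest
#'
#' Probes are laid out along gene loci spaced 100 kb apart: promoter probes
#' within 2 kb upstream of a TSS, body probes within 20 kb downstream,
#' intergenic probes in the gaps (a configurable fraction of them flagged as
#' enhancers, placed 20-60 kb from their anchor gene). Island context is drawn
#' i.i.d. from `island_props`. Positions are strictly increasing per
#' chromosome.
#'
#' @param config From [sim_config()].
#' @return Probe annotation data frame (see [probe_annotation()]).
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "methx_sim_config"))
  if (config$n_probes < 10) stop_mx("need at least 10 probes")
  with_substream(config$seed, "manifest", {
    genes <- gene_layout(config)
    n <- config$n_probes
    n_prom <- round(config$genic_props[["promoter"]] * n)
    n_body <- round(config$genic_props[["body"]] * n)
    n_inter <- n - n_prom - n_body
    n_enh <- round(config$frac_enhancer * n_inter)

    assign_genes <- function(k) {
      # round-robin over a shuffled gene order spreads probes across genes
      ord <- sample.int(nrow(genes))
      genes$gene_id[ord[(seq_len(k) - 1L) %% nrow(genes) + 1L]]
    }
    offsets_for <- function(anchors, range) {
      # unique offsets within each anchor gene's own window
      out <- integer(length(anchors))
      for (g in unique(anchors)) {
        idx <- which(anchors == g)
        if (length(idx) > length(range))
          stop_mx("too many probes for gene '%s' offset window", g)
        out[idx] <- sample(range, length(idx))
      }
      out
    }

    prom_g <- assign_genes(n_prom)
    body_g <- assign_genes(n_body)
    int_g  <- assign_genes(n_inter)
    enh_flag_int <- c(rep(TRUE, n_enh), rep(FALSE, n_inter - n_enh))

    prom_off <- -offsets_for(prom_g, seq(50L, 1950L, by = 10L))
    body_off <- offsets_for(body_g, seq(2000L, 19990L, by = 10L))
    int_off <- integer(n_inter)
    int_off[enh_flag_int]  <- offsets_for(int_g[enh_flag_int],  seq(20000L, 59995L, by = 5L))
    int_off[!enh_flag_int] <- offsets_for(int_g[!enh_flag_int], seq(60000L, 95995L, by = 5L))

    df <- data.frame(
      gene_anchor = c(prom_g, body_g, int_g),
      genic_relation = rep(c("promoter", "body", "intergenic"),
                           c(n_prom, n_body, n_inter)),
      offset = c(prom_off, body_off, int_off),
      enhancer_flag = c(rep(FALSE, n_prom + n_body), enh_flag_int),
      stringsAsFactors = FALSE)
    gi <- match(df$gene_anchor, genes$gene_id)
    df$chromosome <- genes$chromosome[gi]
    df$position <- genes$tss[gi] + df$offset
    df$island_relation <- sample(names(config$island_props), n, replace = TRUE,
                                 prob = config$island_props)
    df$cross_reactive_flag <- stats::runif(n) < config$frac_cross_reactive
    df$maf_over_5pct_flag <- stats::runif(n) < config$frac_maf
    df$gene_symbol <- ifelse(df$genic_relation == "intergenic",
                             NA_character_, df$gene_anchor)
    ord <- order(df$chromosome, df$position)
    df <- df[ord, ]
    df$probe_id <- sprintf("cg%07d", seq_len(n))
    probe_annotation(df)
  })
}

# Probes eligible for planted effects: the ones the filtering stage retains.
eligible_probes <- function(annotation) {
  !(annotation$chromosome %in% c("chrX", "chrY")) &
    !annotation$cross_reactive_flag & !annotation$maf_over_5pct_flag
}

# Truncated-Beta draw by inverse CDF, preserving the requested support.
rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  plo <- stats::pbeta(lo, shape1, shape2)
  phi <- stats::pbeta(hi, shape1, shape2)
  stats::qbeta(stats::runif(n, plo, phi), shape1, shape2)
}

#' Simulate a beta-value matrix with planted differential methylation
#'
#' Null probes draw both groups from a common probe-specific baseline whose
#' prior is a 50/50 mixture of a low (mean 0.15) and a high (mean 0.85) Beta
#' mode, matching typical array bimodality. Planted hyper probes start from
#' the low mode and shift the tumor mean up by `delta_effect`; hypo probes
#' start high and shift down. Baselines are truncated so the shifted mean
#' stays inside \[0.02, 0.98\], making `delta_effect` an exact mean shift.
#' Noise is Beta with concentration `beta_precision` (`Inf` = noiseless).
#' Probes that the filtering stage would remove (sex chromosomes, flagged
#' probes) are never planted.
#'
#' @param config From [sim_config()].
#' @param manifest From [simulate_manifest()].
#' @return List with `beta` (matrix) and `truth` (data frame `probe_id`,
#'   `probe_label` in \{null, hyper, hypo\}).
#' @export
simulate_methylation <- function(config, manifest) {
  stopifnot(inherits(config, "methx_sim_config"))
  manifest <- probe_annotation(manifest)
  with_substream(config$seed, "methylation", {
    n <- nrow(manifest)
    eligible <- eligible_probes(manifest)
    labels <- rep("null", n)

    # Planting units: promoter probes of one gene move together (linkage is a
    # gene-level property); every other probe is its own unit.
    unit_key <- ifelse(manifest$genic_relation == "promoter" & eligible,
                       paste0("gene:", manifest$gene_symbol),
                       paste0("probe:", manifest$probe_id))
    unit_key[!eligible] <- NA
    units <- split(which(eligible), unit_key[eligible])
    units <- units[sample.int(length(units))]
    n_elig <- sum(eligible)
    target_hyper <- round(config$frac_hyper * n_elig)
    target_hypo <- round(config$frac_hypo * n_elig)
    n_hyper <- 0L; n_hypo <- 0L
    for (u in units) {
      if (n_hyper < target_hyper) {
        labels[u] <- "hyper"; n_hyper <- n_hyper + length(u)
      } else if (n_hypo < target_hypo) {
        labels[u] <- "hypo"; n_hypo <- n_hypo + length(u)
      } else break
    }

    d <- config$delta_effect
    baseline <- numeric(n)
    is_null <- labels == "null"
    low_mode <- stats::runif(n) < 0.5
    baseline[is_null & low_mode] <- stats::rbeta(sum(is_null & low_mode), 1.5, 8.5)
    baseline[is_null & !low_mode] <- stats::rbeta(sum(is_null & !low_mode), 8.5, 1.5)
    baseline[labels == "hyper"] <- rbeta_trunc(sum(labels == "hyper"), 1.5, 8.5,
                                               0.02, 0.98 - d)
    baseline[labels == "hypo"] <- rbeta_trunc(sum(labels == "hypo"), 8.5, 1.5,
                                              0.02 + d, 0.98)
    baseline <- pmin(pmax(baseline, 0.02), 0.98)

    tumor_mean <- baseline + d * (labels == "hyper") - d * (labels == "hypo")
    tumor_mean <- pmin(pmax(tumor_mean, 0.02), 0.98)

    sample_ids <- c(sprintf("T%02d", seq_len(config$n_tumor)),
                    sprintf("N%d", seq_len(config$n_normal)))
    mu <- cbind(matrix(tumor_mean, n, config$n_tumor),
                matrix(baseline, n, config$n_normal))
    if (is.infinite(config$beta_precision)) {
      vals <- mu
    } else {
      conc <- config$beta_precision
      vals <- matrix(stats::rbeta(length(mu), mu * conc, (1 - mu) * conc),
                     nrow = n)
    }
    dimnames(vals) <- list(manifest$probe_id, sample_ids)
    list(beta = beta_matrix(vals),
         truth = data.frame(probe_id = manifest$probe_id,
                            probe_label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a count matrix with planted differential expression and linkage
#'
#' Gene labels come from two sources. First, linkage: each planted
#' differentially methylated probe nominates its mapped gene for the
#' concordant expression label (promoter hypo -> up, promoter hyper -> down,
#' body hyper -> up, body hypo -> down, enhancer hypo -> nearest gene up) and
#' the nomination is accepted with the per-quadrant probability in
#' `linkage_table`. Second, free differential expression: additional genes are
#' drawn so that about `frac_de_up`/`frac_de_down` of all genes carry each
#' label. Counts are negative binomial with log-normal baseline means,
#' log-uniform library-size factors over a 3-fold range, and a `lfc_effect`
#' log2 shift in tumors for planted genes.
#'
#' @param config From [sim_config()].
#' @param manifest From [simulate_manifest()].
#' @param meth_truth `truth` component of [simulate_methylation()].
#' @return List with `counts` (matrix), `gene_truth` (data frame `gene_id`,
#'   `gene_label`) and `pairs` (data frame of ground-truth probe-gene quadrant
#'   pairs consistent with the planted labels).
#' @export
simulate_counts <- function(config, manifest, meth_truth) {
  stopifnot(inherits(config, "methx_sim_config"))
  manifest <- probe_annotation(manifest)
  with_substream(config$seed, "counts", {
    genes <- gene_layout(config)
    gene_ids <- genes$gene_id
    gene_label <- stats::setNames(rep("null", length(gene_ids)), gene_ids)

    lab <- stats::setNames(meth_truth$probe_label, meth_truth$probe_id)[manifest$probe_id]
    nearest <- nearest_gene_table(manifest)

    candidate_sets <- list(
      promoter_hypo_up = unique(stats::na.omit(
        manifest$gene_symbol[manifest$genic_relation == "promoter" & lab == "hypo"])),
      promoter_hyper_down = unique(stats::na.omit(
        manifest$gene_symbol[manifest$genic_relation == "promoter" & lab == "hyper"])),
      body_hyper_up = unique(stats::na.omit(
        manifest$gene_symbol[manifest$genic_relation == "body" & lab == "hyper"])),
      body_hypo_down = unique(stats::na.omit(
        manifest$gene_symbol[manifest$genic_relation == "body" & lab == "hypo"])),
      enhancer_hypo_up = unique(stats::na.omit(
        nearest$gene_id[match(manifest$probe_id[manifest$enhancer_flag & lab == "hypo"],
                              nearest$probe_id)])))
    target_label <- c(promoter_hypo_up = "up", promoter_hyper_down = "down",
                      body_hyper_up = "up", body_hypo_down = "down",
                      enhancer_hypo_up = "up")
    for (q in names(candidate_sets)) {
      cand <- candidate_sets[[q]]
      cand <- cand[gene_label[cand] == "null"]
      take <- cand[stats::runif(length(cand)) < config$linkage_table[[q]]]
      gene_label[take] <- target_label[[q]]
    }

    n_up_target <- round(config$frac_de_up * length(gene_ids))
    n_down_target <- round(config$frac_de_down * length(gene_ids))
    free <- names(gene_label)[gene_label == "null"]
    free <- free[sample.int(length(free))]
    need_up <- max(0L, n_up_target - sum(gene_label == "up"))
    need_down <- max(0L, n_down_target - sum(gene_label == "down"))
    if (need_up > 0) gene_label[free[seq_len(need_up)]] <- "up"
    if (need_down > 0)
      gene_label[free[need_up + seq_len(need_down)]] <- "down"

    base_mean <- stats::rlnorm(length(gene_ids), meanlog = log(150), sdlog = 1)
    n_s <- config$n_tumor + config$n_normal
    size_factor <- exp(stats::runif(n_s, 0, log(3)))
    is_tumor <- c(rep(TRUE, config$n_tumor), rep(FALSE, config$n_normal))
    lfc <- config$lfc_effect * ((gene_label == "up") - (gene_label == "down"))
    mu <- outer(base_mean, size_factor)
    mu[, is_tumor] <- mu[, is_tumor] * 2^lfc
    if (config$nb_dispersion < 1e-12) {
      cnt <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    } else {
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / config$nb_dispersion),
                    nrow = nrow(mu))
    }
    dimnames(cnt) <- list(gene_ids,
                          c(sprintf("T%02d", seq_len(config$n_tumor)),
                            sprintf("N%d", seq_len(config$n_normal))))

    pairs <- truth_pairs(manifest, meth_truth,
                         data.frame(gene_id = gene_ids,
                                    gene_label = unname(gene_label),
                                    stringsAsFactors = FALSE),
                         nearest)
    list(counts = count_matrix(cnt),
         gene_truth = data.frame(gene_id = gene_ids,
                                 gene_label = unname(gene_label),
                                 stringsAsFactors = FALSE),
         pairs = pairs)
  })
}

# All probe-gene pairs whose planted labels are consistent with a quadrant:
# the evaluation ground truth for the integration stage.
truth_pairs <- function(manifest, meth_truth, gene_truth, nearest = NULL) {
  lab <- stats::setNames(meth_truth$probe_label, meth_truth$probe_id)[manifest$probe_id]
  glab <- stats::setNames(gene_truth$gene_label, gene_truth$gene_id)
  rows <- list()
  quads <- list(
    promoter_hypo_up = list(ctx = "promoter", probe = "hypo", gene = "up"),
    promoter_hyper_down = list(ctx = "promoter", probe = "hyper", gene = "down"),
    body_hyper_up = list(ctx = "body", probe = "hyper", gene = "up"),
    body_hypo_down = list(ctx = "body", probe = "hypo", gene = "down"))
  for (q in names(quads)) {
    z <- quads[[q]]
    sel <- manifest$genic_relation == z$ctx & lab == z$probe &
      !is.na(manifest$gene_symbol) &
      glab[manifest$gene_symbol] == z$gene
    sel[is.na(sel)] <- FALSE
    if (any(sel)) {
      rows[[q]] <- data.frame(probe_id = manifest$probe_id[sel],
                              gene_id = manifest$gene_symbol[sel],
                              quadrant = q, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(nearest)) {
    enh <- manifest$enhancer_flag & lab == "hypo"
    g <- nearest$gene_id[match(manifest$probe_id[enh], nearest$probe_id)]
    ok <- !is.na(g) & glab[g] == "up"
    ok[is.na(ok)] <- FALSE
    if (any(ok)) {
      rows[["enhancer_hypo_up"]] <- data.frame(
        probe_id = manifest$probe_id[enh][ok], gene_id = g[ok],
        quadrant = "enhancer_hypo_up", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      quadrant = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a sample sheet matching the generated matrices
#'
#' @param config From [sim_config()].
#' @return Sample sheet data frame with all assays available.
#' @export
simulate_sample_sheet <- function(config) {
  stopifnot(inherits(config, "methx_sim_config"))
  with_substream(config$seed, "sheet", {
    ids <- c(sprintf("T%02d", seq_len(config$n_tumor)),
             sprintf("N%d", seq_len(config$n_normal)))
    grp <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
    sample_sheet(data.frame(
      case_id = ids, group = grp,
      sex = sample(c("F", "M"), length(ids), replace = TRUE),
      age = round(stats::runif(length(ids), 40, 85)),
      survival_months = ifelse(grp == "tumor",
                               round(stats::runif(length(ids), 0, 18)), NA),
      has_expression = TRUE, has_methylation = TRUE,
      stringsAsFactors = FALSE))
  })
}

#' Run the full synthetic study generator
#'
#' Generates the manifest, beta matrix, count matrix and sample sheet under a
#' single base seed, and optionally writes the four input files plus a
#' `truth.tsv` ground-truth table to a directory.
#'
#' @param config From [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return List with `manifest`, `beta`, `counts`, `sheet` and `truth` (a list
#'   of `probes`, `genes`, `pairs` data frames).
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  manifest <- simulate_manifest(config)
  meth <- simulate_methylation(config, manifest)
  expr <- simulate_counts(config, manifest, meth$truth)
  sheet <- simulate_sample_sheet(config)
  truth <- list(probes = meth$truth, genes = expr$gene_truth, pairs = expr$pairs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(manifest, file.path(dir, "manifest.csv"), seed = config$seed)
    write_beta_matrix(meth$beta, file.path(dir, "beta.tsv"), seed = config$seed)
    write_count_matrix(expr$counts, file.path(dir, "counts.tsv"), seed = config$seed)
    write_sample_sheet(sheet, file.path(dir, "samples.csv"), seed = config$seed)
    tr <- merge(truth$probes,
                data.frame(probe_id = manifest$probe_id,
                           gene_symbol = manifest$gene_symbol,
                           stringsAsFactors = FALSE),
                by = "probe_id", sort = TRUE)
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth$pairs, file.path(dir, "truth_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, beta = meth$beta, counts = expr$counts,
       sheet = sheet, truth = truth, config = config)
}
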