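# Readers, writers and validators for the on-disk formats: beta-value TSV,
# count TSV, probe annotation CSV, sample sheet CSV and GMT gene sets.
# All writers emit a leading "#" comment line carrying the tool version and,
# when given, the simulation seed; all readers skip such lines.

ISLAND_LEVELS <- c("island", "shore", "shelf", "open_sea")
GENIC_LEVELS  <- c("promoter", "body", "intergenic")

format_header_comment <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("methx"))
  if (is.null(seed)) sprintf("# methx %s", v) else sprintf("# methx %s seed=%s", v, seed)
}

read_table_skip_comments <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", na.strings = c("NA", ""))
}

#' Construct a validated beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation beta values in
#' \[0, 1\] with unique probe ids as row names and unique sample ids as column
#' names. Missing values (`NA`) are permitted on input; downstream callers drop
#' probes with missingness among retained samples.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @return The validated matrix (invisibly classed as a plain matrix).
#' @export
beta_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_mx("beta matrix requires probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop_mx("duplicate probe ids: %s",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_mx("duplicate sample ids: %s",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop_mx("beta value out of [0,1] at probe '%s', sample '%s': %g",
            rownames(values)[i[1]], colnames(values)[i[2]], values[i[1], i[2]])
  }
  values
}

#' Read a beta-value matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds probe ids. Values must parse as decimal fractions in
#' \[0, 1\]; out-of-range cells raise an error naming the probe and sample.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (probes x samples), validated by [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- read_table_skip_comments(path, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  beta_matrix(m)
}

#' Write a beta-value matrix to TSV
#'
#' @param beta Matrix from [beta_matrix()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_beta_matrix <- function(beta, path, seed = NULL) {
  beta <- beta_matrix(beta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header_comment(seed), con)
  writeLines(paste(c("probe_id", colnames(beta)), collapse = "\t"), con)
  body <- cbind(rownames(beta),
                apply(beta, 2, function(x) formatC(x, digits = 8, format = "g")))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Construct a validated count matrix
#'
#' Gene-level read counts: non-negative integers, unique gene row names and
#' sample column names.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @return Validated integer-valued matrix.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_mx("count matrix requires gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop_mx("duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    stop_mx("duplicate sample ids")
  if (anyNA(counts)) stop_mx("count matrix contains missing values")
  if (any(counts < 0)) {
    i <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop_mx("negative count at gene '%s', sample '%s'",
            rownames(counts)[i[1]], colnames(counts)[i[2]])
  }
  if (any(counts != round(counts))) {
    i <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop_mx("non-integer count at gene '%s', sample '%s': %g",
            rownames(counts)[i[1]], colnames(counts)[i[2]], counts[i[1], i[2]])
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a gene-level count matrix from TSV
#'
#' @param path Path to a TSV with genes in rows (first column gene ids) and
#'   samples in columns. Counts must be non-negative integers.
#' @return Validated matrix via [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- read_table_skip_comments(path, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  count_matrix(m)
}

#' Write a count matrix to TSV
#' @param counts Matrix from [count_matrix()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_count_matrix <- function(counts, path, seed = NULL) {
  counts <- count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header_comment(seed), con)
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  body <- cbind(rownames(counts),
                apply(counts, 2, function(x) format(x, scientific = FALSE, trim = TRUE)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# Normalize manifest island-relation vocabulary (Illumina-style strings such as
# "N_Shore"/"S_Shelf" collapse to shore/shelf; empty means open sea).
normalize_island_relation <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  lx[is.na(x) | lx == ""] <- "open_sea"
  lx[lx %in% c("island", "cpg island")] <- "island"
  lx[lx %in% c("n_shore", "s_shore", "shore")] <- "shore"
  lx[lx %in% c("n_shelf", "s_shelf", "shelf")] <- "shelf"
  lx[lx %in% c("opensea", "open_sea", "open sea")] <- "open_sea"
  bad <- !lx %in% ISLAND_LEVELS
  if (any(bad))
    stop_mx("unknown island relation value(s): %s",
            paste(unique(x[bad]), collapse = ", "))
  lx
}

# Normalize genic-relation vocabulary. Promoter = TSS1500/TSS200/5'UTR/1stExon,
# body = Body/ExonBnd (manifest dialect); empty means intergenic.
normalize_genic_relation <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  lx[is.na(x) | lx == ""] <- "intergenic"
  lx[lx %in% c("tss1500", "tss200", "5'utr", "5utr", "1stexon", "promoter")] <- "promoter"
  lx[lx %in% c("body", "exonbnd", "3'utr", "3utr", "gene_body")] <- "body"
  bad <- !lx %in% GENIC_LEVELS
  if (any(bad))
    stop_mx("unknown genic relation value(s): %s",
            paste(unique(x[bad]), collapse = ", "))
  lx
}

#' Construct a validated probe annotation table
#'
#' @param df Data frame with columns `probe_id`, `chromosome`, `position`,
#'   `island_relation`, `genic_relation`, `gene_symbol`, `enhancer_flag`,
#'   `cross_reactive_flag`, `maf_over_5pct_flag`.
#' @return Validated data frame with normalized enumerations.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "chromosome", "position", "island_relation",
           "genic_relation", "gene_symbol", "enhancer_flag",
           "cross_reactive_flag", "maf_over_5pct_flag")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_mx("probe annotation missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id)) stop_mx("duplicate probe ids in annotation")
  df$position <- as.integer(df$position)
  df$island_relation <- normalize_island_relation(df$island_relation)
  df$genic_relation <- normalize_genic_relation(df$genic_relation)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$gene_symbol[!is.na(df$gene_symbol) & df$gene_symbol == ""] <- NA_character_
  genic <- df$genic_relation != "intergenic"
  if (any(genic & is.na(df$gene_symbol)))
    stop_mx("genic probes without a gene symbol: %s",
            paste(utils::head(df$probe_id[genic & is.na(df$gene_symbol)], 5), collapse = ", "))
  df$gene_symbol[!genic] <- NA_character_
  for (fl in c("enhancer_flag", "cross_reactive_flag", "maf_over_5pct_flag")) {
    if (is.character(df[[fl]])) df[[fl]] <- parse_yes_no(df[[fl]], fl)
    df[[fl]] <- as.logical(df[[fl]])
    if (anyNA(df[[fl]])) stop_mx("missing values in flag column '%s'", fl)
  }
  rownames(df) <- NULL
  df[, req]
}

#' Read a probe annotation manifest from CSV
#'
#' Accepts the manifest's semantics rather than its exact dialect: island
#' relations such as `N_Shore`/`S_Shelf` collapse to `shore`/`shelf`, empty
#' relations mean `open_sea`; genic labels `TSS1500`, `TSS200`, `5'UTR` and
#' `1stExon` map to `promoter`, `Body`/`ExonBnd` to `body`, empty to
#' `intergenic`. Unknown labels raise an error listing the offending value.
#'
#' @param path Path to a CSV with the columns documented in
#'   [probe_annotation()].
#' @return Validated annotation data frame.
#' @export
read_manifest <- function(path) {
  df <- read_table_skip_comments(path, sep = ",")
  probe_annotation(df)
}

#' Write a probe annotation manifest to CSV
#' @param annotation Data frame from [probe_annotation()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_manifest <- function(annotation, path, seed = NULL) {
  annotation <- probe_annotation(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header_comment(seed), con)
  out <- annotation
  out$gene_symbol[is.na(out$gene_symbol)] <- ""
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated sample sheet
#'
#' Per-sample metadata mirroring a small tumor/normal cohort table: case id,
#' group (tumor or normal), sex, age, survival in months (optional), and
#' availability flags for the expression and methylation assays.
#'
#' @param df Data frame with columns `case_id`, `group`, `sex`, `age`,
#'   `survival_months`, `has_expression`, `has_methylation`.
#' @return Validated data frame.
#' @export
sample_sheet <- function(df) {
  req <- c("case_id", "group", "sex", "age", "survival_months",
           "has_expression", "has_methylation")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_mx("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id)) stop_mx("duplicate case ids in sample sheet")
  grp <- tolower(trimws(as.character(df$group)))
  if (any(is.na(grp) | grp == ""))
    stop_mx("missing group for case(s): %s",
            paste(df$case_id[is.na(grp) | grp == ""], collapse = ", "))
  if (!all(grp %in% c("tumor", "normal")))
    stop_mx("group must be tumor or normal, got: %s",
            paste(unique(grp[!grp %in% c("tumor", "normal")]), collapse = ", "))
  df$group <- grp
  df$age <- as.numeric(df$age)
  df$survival_months <- suppressWarnings(as.numeric(df$survival_months))
  for (fl in c("has_expression", "has_methylation")) {
    if (!is.logical(df[[fl]])) df[[fl]] <- parse_yes_no(df[[fl]], fl)
  }
  rownames(df) <- NULL
  df[, req]
}

#' Read a sample sheet from CSV
#'
#' The CSV mirrors the cohort table of a small tumor/normal study: columns
#' `case_id`, `group`, `sex`, `age`, `survival_months`, and case-insensitive
#' Yes/No columns `has_expression` and `has_methylation`. A packaged fixture
#' with the 14-tumor/4-normal cohort ships as
#' `system.file("extdata", "table1.csv", package = "methx")`.
#'
#' @param path Path to the CSV.
#' @return Validated data frame via [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- read_table_skip_comments(path, sep = ",")
  sample_sheet(df)
}

#' Write a sample sheet to CSV
#' @param sheet Data frame from [sample_sheet()].
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_sample_sheet <- function(sheet, path, seed = NULL) {
  sheet <- sample_sheet(sheet)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header_comment(seed), con)
  out <- sheet
  out$has_expression <- ifelse(out$has_expression, "Yes", "No")
  out$has_methylation <- ifelse(out$has_methylation, "Yes", "No")
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select samples by assay availability
#'
#' Returns tumor case ids and normal ids that satisfy the requested
#' availability flags, in stable input order. On the packaged cohort fixture,
#' requiring both assays yields 7 tumors, expression only 11, methylation only
#' 10 (all with 4 normals).
#'
#' @param sheet Sample sheet from [read_sample_sheet()].
#' @param require_expression Require the expression assay.
#' @param require_methylation Require the methylation assay.
#' @return List with character vectors `tumors` and `normals`.
#' @export
select_samples <- function(sheet, require_expression = FALSE,
                           require_methylation = FALSE) {
  sheet <- sample_sheet(sheet)
  keep <- rep(TRUE, nrow(sheet))
  if (require_expression) keep <- keep & sheet$has_expression
  if (require_methylation) keep <- keep & sheet$has_methylation
  list(tumors = sheet$case_id[keep & sheet$group == "tumor"],
       normals = sheet$case_id[keep & sheet$group == "normal"])
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' members. The description is ignored. Duplicate set names and lines with
#' fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_mx("GMT line %d has %d field(s); need name, description, >=1 member",
              i, length(fields))
    name <- fields[1]
    if (name %in% names(sets)) stop_mx("duplicate gene-set name '%s' (line %d)", name, i)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) stop_mx("gene set '%s' has no members (line %d)", name, i)
    sets[[name]] <- members
  }
  sets
}

#' Write a GMT gene-set file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
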