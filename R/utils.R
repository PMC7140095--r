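# Internal helpers: seed substreams, validation, logging.

#' methx: methylation-expression integration for tumor/normal array studies
#'
#' Differential methylation on binned beta values with an exact 2x3 test,
#' negative-binomial differential expression, signature scores, integration
#' quadrants, enhancer-gene pairing, and a synthetic-data generator with
#' planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

# Derive a reproducible substream seed from a base seed and a stage name, so
# that adding a stage never perturbs the draws of earlier stages. Kept below
# 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647)
  for (k in codes) h <- (h * 31 + k) %% 2147483629
  as.integer(h %% 2147483647)
}

# Run expr with a local RNG state seeded from (seed, name).
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

mx_log <- function(fmt, ...) {
  message(sprintf(paste0("[methx] ", fmt), ...))
}

stop_mx <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Parse Yes/No (case-insensitive) into logical; anything else errors.
parse_yes_no <- function(x, field) {
  lx <- tolower(trimws(as.character(x)))
  bad <- !lx %in% c("yes", "no")
  if (any(bad)) {
    stop_mx("column '%s' must contain Yes/No, got: %s", field,
            paste(unique(x[bad]), collapse = ", "))
  }
  lx == "yes"
}
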