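# Shared fixtures built in code: tiny matrices, annotations and an
# independent brute-force oracle for the exact 2x3 test.

table1_path <- function() {
  system.file("extdata", "table1.csv", package = "methx")
}

tiny_beta <- function() {
  m <- matrix(c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), c("S1", "S2")))
  beta_matrix(m)
}

tiny_annotation <- function(probe_ids = c("cg1", "cg2", "cg3"),
                            chromosome = "chr1",
                            genic = "promoter",
                            island = "island",
                            gene = "GENE1",
                            enhancer = FALSE,
                            cross_reactive = FALSE,
                            maf = FALSE) {
  n <- length(probe_ids)
  probe_annotation(data.frame(
    probe_id = probe_ids,
    chromosome = rep_len(chromosome, n),
    position = seq(1000, by = 1000, length.out = n),
    island_relation = rep_len(island, n),
    genic_relation = rep_len(genic, n),
    gene_symbol = ifelse(rep_len(genic, n) == "intergenic", NA,
                         rep_len(gene, n)),
    enhancer_flag = rep_len(enhancer, n),
    cross_reactive_flag = rep_len(cross_reactive, n),
    maf_over_5pct_flag = rep_len(maf, n),
    stringsAsFactors = FALSE))
}

# a sheet with nt tumors (T01..) and nn normals (N1..), all assays available
tiny_sheet <- function(nt = 10, nn = 4) {
  ids <- c(sprintf("T%02d", seq_len(nt)), sprintf("N%d", seq_len(nn)))
  sample_sheet(data.frame(
    case_id = ids,
    group = rep(c("tumor", "normal"), c(nt, nn)),
    sex = "F", age = 60, survival_months = NA,
    has_expression = TRUE, has_methylation = TRUE,
    stringsAsFactors = FALSE))
}

# Brute-force two-sided exact p for a 2x3 table: nested loops over the free
# cells, probabilities as products of binomial coefficients (independent of
# the package's log-gamma enumeration).
oracle_fisher_2x3 <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); n <- sum(tab)
  p_of <- function(a, b, cc) {
    choose(cs[1], a) * choose(cs[2], b) * choose(cs[3], cc) / choose(n, r1)
  }
  p_obs <- p_of(tab[1, 1], tab[1, 2], tab[1, 3])
  total <- 0
  for (a in 0:min(r1, cs[1])) {
    for (b in 0:min(r1 - a, cs[2])) {
      cc <- r1 - a - b
      if (cc > cs[3]) next
      p <- p_of(a, b, cc)
      if (p <= p_obs * (1 + 1e-12)) total <- total + p
    }
  }
  min(total, 1)
}

# random 2x3 table with total at most n_max and both row sums >= 1
random_2x3 <- function(n_max = 20) {
  repeat {
    n <- sample(2:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(6, 0.05, 1)))
    tab <- matrix(cells, nrow = 2)
    if (all(rowSums(tab) >= 1)) return(tab)
  }
}

# Step-up BH oracle: direct application of the formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small-but-meaningful synthetic study for integration-level tests
small_config <- function(seed = 7, ...) {
  sim_config(n_probes = 400, n_genes = 400, seed = seed, ...)
}
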