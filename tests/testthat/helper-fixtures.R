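# Shared fixtures: everything is built in code at test time.

# Tiny deterministic dataset used by parsing and counting tests.
toy_dataset <- function() {
  genotype_dataset(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)),
                   phenotype = c(1L, 0L, 1L),
                   snp_names = c("N0", "N1"))
}

# Exact evaluation of the K2 product via integer factorials; valid for
# small cell counts, independent of the log-gamma implementation.
exact_k2_product <- function(counts) {
  counts <- as.matrix(counts)
  prod(apply(counts, 1L, function(row) {
    prod(factorial(row)) * factorial(ncol(counts) - 1) /
      factorial(sum(row) + ncol(counts) - 1)
  }))
}

random_small_table <- function(nrow, max_count = 12L) {
  repeat {
    m <- matrix(sample(0:max_count, nrow * 2L, replace = TRUE), nrow, 2L)
    if (sum(m) > 0 && all(rowSums(m) > 0)) return(m)
  }
}

# A case-control panel with one embedded epistatic pair; small enough
# for exhaustive checks.
embedded_panel <- function(seed, n_snps = 30L, n_cases = 400L,
                           n_controls = 400L, maf = 0.4, h2 = 0.4,
                           prevalence = 0.35, marginal = FALSE) {
  set.seed(seed)
  spec <- disease_model_spec(maf, h2, prevalence, marginal_effects = marginal)
  generate_dataset(spec, n_cases, n_controls, n_snps)
}

# Pure-noise panel: background genotypes, phenotype independent.
null_panel <- function(seed, n = 400L, n_snps = 40L) {
  set.seed(seed)
  mafs <- runif(n_snps, 0.05, 0.5)
  G <- matrix(rbinom(n * n_snps, 2L, rep(mafs, each = n)), n, n_snps)
  genotype_dataset(G, rep(c(0L, 1L), length.out = n))
}

all_pairs <- function(n) t(utils::combn(n, 2L))
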