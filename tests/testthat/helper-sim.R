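# Small, fast generator configurations and shared oracles for the suite.

tiny_config <- function(seed = 42L, ...) {
  args <- list(
    n_genes = 250L, n_catalog = 120L, scale_free_m = 2L,
    community_size = 40L, n_datasets = 3L,
    cases_per_dataset = 8L, controls_per_dataset = 6L,
    coverage_fraction = 1, n_terms = 12L, term_size = 15L, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(generation_config, args)
}

ref_table <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "mitonet"),
                    stringsAsFactors = FALSE)
}

# exhaustive hypergeometric upper-tail oracle: enumerate every possible
# draw of n from N, with the first K elements annotated
hyper_tail_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# hand step-up BH oracle
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# noiseless power-law degree distribution P(k) proportional to k^-alpha
powerlaw_distribution <- function(alpha, kmax = 50L) {
  k <- seq_len(kmax)
  p <- k^(-alpha)
  data.frame(k = k, p = p / sum(p))
}
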