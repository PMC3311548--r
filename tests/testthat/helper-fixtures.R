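# Shared helpers for building tiny in-code fixtures.

# A small arbitrary community used across tests.
toy_community <- function(k = 3) {
  mock_community(paste0("t", seq_len(k)),
                 copy_number = seq_len(k),
                 cell_fraction = rep(1, k))
}

# Random community under a fixed seed (property tests).
random_community <- function(k, seed) {
  set.seed(seed)
  mock_community(paste0("taxon", seq_len(k)),
                 copy_number = sample(1:10, k, replace = TRUE),
                 cell_fraction = runif(k, 0.1, 5))
}

# Count table with given columns (list of integer vectors) and taxa names.
make_counts <- function(cols, taxa = NULL, meta = NULL) {
  x <- do.call(cbind, cols)
  if (!is.null(taxa)) rownames(x) <- taxa
  count_table(x, meta)
}

# Independent brute-force oracle for the exact two-sided Wilcoxon rank-sum
# p-value: enumerate all C(n+m, n) assignments of the pooled ranks to x.
wilcoxon_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Closed-form beta-binomial log-pmf, the K = 2 oracle for the
# Dirichlet-multinomial likelihood.
betabinom_logpmf <- function(x, n, a, b) {
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# Multinomial log-likelihood of a counts matrix (columns = replicates).
multinom_loglik <- function(x, p) {
  sum(apply(x, 2, function(col) stats::dmultinom(col, prob = p, log = TRUE)))
}
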