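# Shared fixtures and independent oracles used across the suite.

# Two vectors with an exact sample Pearson correlation r, built by
# orthonormalizing two noise vectors and recombining them.
vectors_with_cor <- function(r, n = 50, seed = 1) {
  set.seed(seed)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- rnorm(n)
  z2 <- scale(resid(lm(z2 ~ z1)))[, 1]
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * z2)
}

# Direct triple-loop topological overlap, the independent oracle for tom().
tom_oracle <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  k <- colSums(A)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { W[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      W[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  W
}

# Random symmetric adjacency with entries in [0, 1].
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

# Pearson chi-square by hand, the oracle for the chi-square wrappers.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# A small planted cohort shared by slower tests (drawn once per test file).
small_cohort <- function(seed = 5) {
  generate_cohort(synth_config(), seed = seed)
}

# Expression vector realizing a given bins x groups contingency table under
# equal-width binning of the range.
expr_for_table <- function(counts) {
  n_bins <- nrow(counts)
  x <- g <- c()
  for (b in seq_len(n_bins)) {
    n_b <- sum(counts[b, ])
    if (n_b == 0) next
    x <- c(x, rep(b - 0.5, n_b))  # bin centers over range [0.5, n_bins - 0.5]
    g <- c(g, rep(colnames(counts), counts[b, ]))
  }
  # anchor min/max so equal-width bins of the range hit the bin centers
  list(x = x, groups = g)
}
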