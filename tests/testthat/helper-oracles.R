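# Independent oracles used across the suite.

# Benjamini-Hochberg step-up rule written directly from its definition:
# find the largest k with p_(k) <= k/m * alpha-free adjusted form
# p_adj_(i) = min over j >= i of m * p_(j) / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(m * ps[i:m] / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Build an n x k data matrix whose *sample* correlation matrix equals M
# exactly (columns centered, unit sample variance), so least-squares fits
# on it reproduce population regression algebra to machine precision.
make_exact_cor_data <- function(n, M, seed = 1) {
  set.seed(seed)
  k <- ncol(M)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  # whiten to exact identity sample covariance, then colour by chol(M)
  W <- Z %*% solve(chol(cov(Z)))
  X <- W %*% chol(M)
  colnames(X) <- colnames(M)
  X
}

# Sample skewness (moment estimator).
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Small helper: double-entered intraclass correlation of a simulated
# univariate cohort, by group.
sim_icc <- function(config, group) {
  intraclass_correlation(simulate_univariate_twins(config), group,
                         config$traits[1])$r
}
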