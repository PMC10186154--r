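# Shared helpers for the test suite: independent oracles and small
# utilities. Everything here is deliberately written without reference to
# the package internals it checks.

# Rank-based AUROC (equivalent to the Wilcoxon statistic).
auroc <- function(score, labels) {
  labels <- as.logical(labels)
  r <- rank(score)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Brute-force NB pmf via the term-by-term Gamma recurrence:
# P(0) = (r/(r+mu))^r, P(y) = P(y-1) * (y-1+r)/y * mu/(r+mu).
nb_pmf_brute <- function(y, mu, r) {
  p0 <- (r / (r + mu))^r
  if (y == 0) return(p0)
  p <- p0
  for (k in seq_len(y)) {
    p <- p * (k - 1 + r) / k * (mu / (r + mu))
  }
  p
}

# Element-by-element kernel evaluation (double loop over the formulas).
kernel_brute <- function(family, X, X2, l = 1, sf2 = 1, p = 1) {
  X <- as.matrix(X); X2 <- as.matrix(X2)
  K <- matrix(0, nrow(X), nrow(X2))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(X2))) {
      d <- sqrt(sum((X[i, ] - X2[j, ])^2))
      K[i, j] <- switch(family,
        rbf = sf2 * exp(-d^2 / (2 * l^2)),
        linear = sf2 * sum(X[i, ] * X2[j, ]),
        periodic = sf2 * exp(-2 * sin(pi * d / p)^2 / l^2),
        constant = sf2)
    }
  }
  K
}

# Closed-form Gaussian GP log marginal likelihood, written independently
# of the package (solve + determinant, no Cholesky reuse).
gauss_ml_oracle <- function(K, s2, y) {
  n <- length(y)
  S <- K + diag(s2, n)
  -0.5 * drop(t(y) %*% solve(S, y)) -
    0.5 * determinant(S, logarithm = TRUE)$modulus -
    0.5 * n * log(2 * pi)
}

# Quick control for fit-heavy tests (slightly looser stopping rule).
fast_ctl <- function(...) gp_control(factr = 1e8, maxit = 600, ...)
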