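#' Observation-model (likelihood) specification
#'
#' Specifies the count observation model placed on top of the latent GP
#' function `f`. For the count families the mean is linked through
#' \eqn{\mu(x) = e^{f(x)}} (log link); the Gaussian family instead models a
#' transformed count directly.
#'
#' * `"negative_binomial"` — \eqn{y \sim NB(\mu, r)} with dispersion
#'   \eqn{\alpha = 1/r}, so that \eqn{Var[y] = \mu + \alpha \mu^2}.
#' * `"zinb"` — zero-inflated NB: dropout probability
#'   \eqn{\psi(\mu) = \kappa / (\kappa + \mu)} (a Michaelis–Menten function
#'   of the mean, decreasing in \eqn{\mu}) adds mass at zero and the NB
#'   component is scaled by \eqn{1 - \psi}.
#' * `"poisson"` — \eqn{y \sim Pois(\mu)}; the \eqn{\alpha \to 0} limit of
#'   the NB.
#' * `"gaussian"` — \eqn{t(y) \sim N(f, \sigma^2)} where `t` is the chosen
#'   `transform` (`"log1p"`: \eqn{\log(y+1)}; `"anscombe"`:
#'   \eqn{2\sqrt{y + 3/8}}; `"none"`).
#'
#' @param family One of `"negative_binomial"`, `"zinb"`, `"poisson"`,
#'   `"gaussian"`.
#' @param dispersion NB/ZINB dispersion \eqn{\alpha \ge 0} (initial value;
#'   fitted by maximum likelihood in [fit_gp()]).
#' @param dropout_scale ZINB dropout scale \eqn{\kappa > 0} in mean-count
#'   units.
#' @param sigma2 Gaussian noise variance \eqn{\sigma^2 > 0}.
#' @param transform Transform applied to counts under the Gaussian family.
#' @return An object of class `"likelihood_spec"`.
#' @export
likelihood_spec <- function(family = c("negative_binomial", "zinb",
                                       "poisson", "gaussian"),
                            dispersion = 1, dropout_scale = 1,
                            sigma2 = 1,
                            transform = c("log1p", "anscombe", "none")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (!is.numeric(dispersion) || dispersion < 0 || !is.finite(dispersion)) {
    stop("'dispersion' must be a finite nonnegative number", call. = FALSE)
  }
  if (!is.numeric(dropout_scale) || dropout_scale <= 0) {
    stop("'dropout_scale' must be positive", call. = FALSE)
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be positive", call. = FALSE)
  }
  structure(
    list(family = family, dispersion = dispersion,
         dropout_scale = dropout_scale, sigma2 = sigma2,
         transform = transform),
    class = "likelihood_spec"
  )
}

#' @export
print.likelihood_spec <- function(x, ...) {
  cat("<likelihood_spec> family:", x$family)
  if (x$family %in% c("negative_binomial", "zinb")) {
    cat("  dispersion:", format(x$dispersion, digits = 4))
  }
  if (x$family == "zinb") {
    cat("  dropout_scale:", format(x$dropout_scale, digits = 4))
  }
  if (x$family == "gaussian") {
    cat("  sigma2:", format(x$sigma2, digits = 4),
        " transform:", x$transform)
  }
  cat("\n")
  invisible(x)
}

check_counts <- function(y, what = "y") {
  if (any(y < 0)) stop(what, " must be nonnegative", call. = FALSE)
  if (any(abs(y - round(y)) > 1e-8)) {
    stop(what, " must be integer-valued", call. = FALSE)
  }
  invisible(round(y))
}

#' Negative binomial log probability mass
#'
#' Log of \eqn{NB(y; \mu, r) = \frac{\Gamma(y+r)}{\Gamma(y+1)\Gamma(r)}
#' \left(\frac{r}{r+\mu}\right)^r \left(\frac{\mu}{r+\mu}\right)^y},
#' evaluated in log space via log-gamma so it stays finite for counts and
#' means up to 1e6 and beyond. `r` is the size (number of failures);
#' dispersion is \eqn{\alpha = 1/r}.
#'
#' @param y Nonnegative integer counts (vectorised).
#' @param mu Positive mean.
#' @param r Positive size parameter.
#' @return Log-probabilities, recycled to the common length.
#' @export
nb_log_pmf <- function(y, mu, r) {
  y <- check_counts(y)
  if (any(mu <= 0) || any(r <= 0)) {
    stop("'mu' and 'r' must be positive", call. = FALSE)
  }
  lgamma(y + r) - lgamma(y + 1) - lgamma(r) +
    r * (log(r) - log(r + mu)) + y * (log(mu) - log(r + mu))
}

#' Zero-inflated negative binomial log probability mass
#'
#' Mixture with dropout probability \eqn{\psi(\mu) = \kappa/(\kappa+\mu)}:
#' \eqn{P(y) = \psi \, 1\{y=0\} + (1-\psi)\, NB(y;\mu,r)}. As
#' \eqn{\kappa \to 0} the dropout vanishes and the NB is recovered.
#'
#' @inheritParams nb_log_pmf
#' @param kappa Positive dropout scale \eqn{\kappa}.
#' @export
zinb_log_pmf <- function(y, mu, r, kappa) {
  y <- check_counts(y)
  if (any(kappa <= 0)) stop("'kappa' must be positive", call. = FALSE)
  n <- max(length(y), length(mu), length(r), length(kappa))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  r <- rep_len(r, n); kappa <- rep_len(kappa, n)
  log_psi <- log(kappa) - log(kappa + mu)
  log_1mpsi <- log(mu) - log(kappa + mu)
  lnb <- nb_log_pmf(y, mu, r)
  out <- log_1mpsi + lnb
  z <- y == 0
  if (any(z)) {
    # log(psi + (1-psi) NB(0)) via logsumexp
    a <- log_psi[z]
    b <- log_1mpsi[z] + lnb[z]
    m <- pmax(a, b)
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

#' Count transforms for the Gaussian observation model
#'
#' `log1p` is \eqn{\log(y+1)}; `anscombe` is the Poisson-family
#' variance-stabilising map \eqn{2\sqrt{y + 3/8}}. Both are strictly
#' increasing, so gene rankings are preserved.
#'
#' @param y Nonnegative counts.
#' @param transform `"log1p"` or `"anscombe"`.
#' @export
transform_counts <- function(y, transform = c("log1p", "anscombe")) {
  transform <- match.arg(transform)
  if (any(y < 0)) stop("counts must be nonnegative", call. = FALSE)
  switch(transform,
         log1p = log1p(y),
         anscombe = 2 * sqrt(y + 3 / 8))
}

# --- Gauss-Hermite quadrature (Golub-Welsch) ---------------------------------
# Nodes/weights for integral over exp(-t^2); cached per order.
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(order) {
  if (order < 3) stop("quadrature order must be >= 3", call. = FALSE)
  key <- as.character(order)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  i <- seq_len(order - 1)
  J <- matrix(0, order, order)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  res <- list(nodes = nodes[ord], weights = weights[ord])
  .gh_cache[[key]] <- res
  res
}

# Log-density of the likelihood at latent value f (log-mean scale for count
# families), vectorised over f. 'off' is an additive offset on f (log scale
# normalisation factor).
lik_log_density <- function(lik, y, f) {
  switch(lik$family,
    negative_binomial = nb_log_pmf(y, exp(f), 1 / max(lik$dispersion, 1e-12)),
    poisson = stats::dpois(y, exp(f), log = TRUE),
    zinb = zinb_log_pmf(y, exp(f), 1 / max(lik$dispersion, 1e-12),
                        lik$dropout_scale),
    gaussian = stats::dnorm(y, f, sqrt(lik$sigma2), log = TRUE)
  )
}

#' Variational expectation of the log-density
#'
#' Computes \eqn{E_{q}[\log p(y \mid f)]} where
#' \eqn{q(f) = N(\mathrm{q\_mean}, \mathrm{q\_var})} and `f` is the latent
#' log-mean (identity-scale latent for the Gaussian family), using
#' fixed-order Gauss–Hermite quadrature. At `q_var = 0` this is the
#' log-density at \eqn{\mu = e^{\mathrm{q\_mean}}}. The Gaussian family is
#' evaluated in closed form.
#'
#' @param likelihood A [likelihood_spec()].
#' @param y Observed counts (or transformed values for Gaussian).
#' @param q_mean,q_var Mean and nonnegative variance of the Gaussian over
#'   the latent, recycled against `y`.
#' @param order Quadrature order (>= 3).
#' @return Vector of expected log-densities.
#' @export
variational_expectation <- function(likelihood, y, q_mean, q_var,
                                    order = 20) {
  stopifnot(inherits(likelihood, "likelihood_spec"))
  if (any(q_var < 0)) stop("'q_var' must be nonnegative", call. = FALSE)
  n <- max(length(y), length(q_mean), length(q_var))
  y <- rep_len(y, n); q_mean <- rep_len(q_mean, n)
  q_var <- rep_len(q_var, n)
  if (likelihood$family == "gaussian") {
    # E[log N(y | f, s2)] = log N(y | m, s2) - v / (2 s2)
    return(stats::dnorm(y, q_mean, sqrt(likelihood$sigma2), log = TRUE) -
             q_var / (2 * likelihood$sigma2))
  }
  gh <- gauss_hermite(order)
  w <- gh$weights / sqrt(pi)
  sd2 <- sqrt(2 * q_var)
  out <- numeric(n)
  for (j in seq_along(gh$nodes)) {
    out <- out + w[j] * lik_log_density(likelihood, y,
                                        q_mean + sd2 * gh$nodes[j])
  }
  out
}

# Expectations plus derivatives wrt q_mean and q_var, used by the inference
# engines. Returns list(e, dmu, dv). dv uses the identity
# dE/dv = E[g''(f)]/2 (stable as v -> 0). The quadrature is evaluated in
# one vectorised call over an n x order node matrix; deriv = FALSE skips
# the derivative accumulations (used by finite-difference hyper-parameter
# gradients).
lik_expectations <- function(lik, y, q_mean, q_var, order = 20,
                             deriv = TRUE) {
  n <- length(y)
  if (lik$family == "gaussian") {
    s2 <- lik$sigma2
    e <- stats::dnorm(y, q_mean, sqrt(s2), log = TRUE) - q_var / (2 * s2)
    if (!deriv) return(list(e = e))
    return(list(e = e, dmu = (y - q_mean) / s2, dv = rep(-0.5 / s2, n)))
  }
  gh <- gauss_hermite(order)
  w <- gh$weights / sqrt(pi)
  sd2 <- sqrt(2 * pmax(q_var, 0))
  fmat <- q_mean + outer(sd2, gh$nodes)        # n x order
  g <- lik_log_gradients(lik, rep.int(y, order), as.vector(fmat),
                         deriv = deriv)
  e <- drop(matrix(g$g0, n, order) %*% w)
  if (!deriv) return(list(e = e))
  g1m <- matrix(g$g1, n, order)
  dmu <- drop(g1m %*% w)
  # exact derivative of the quadrature wrt v (chain rule through the node
  # positions); fall back to the E[g'']/2 identity near v = 0
  dv <- drop(g1m %*% (w * gh$nodes)) / pmax(sd2, 1e-8)
  small <- q_var < 1e-8
  if (any(small)) {
    d2 <- drop(matrix(g$g2, n, order) %*% w)
    dv[small] <- d2[small] / 2
  }
  list(e = e, dmu = dmu, dv = dv)
}

# g0 = log p(y|f), g1 = d/df, g2 = d^2/df^2 (analytic for NB/Poisson,
# central differences for ZINB).
lik_log_gradients <- function(lik, y, f, deriv = TRUE) {
  if (lik$family == "negative_binomial") {
    r <- 1 / max(lik$dispersion, 1e-12)
    f <- pmin(f, 500)                    # cap latent consistently
    mu <- exp(f)
    lrm <- log(r + mu)
    g0 <- lgamma(y + r) - lgamma(y + 1) - lgamma(r) +
      r * (log(r) - lrm) + y * (f - lrm)
    if (!deriv) return(list(g0 = g0))
    frac <- mu / (r + mu)
    g1 <- y - (y + r) * frac
    g2 <- -(y + r) * r * frac / (r + mu)
    list(g0 = g0, g1 = g1, g2 = g2)
  } else if (lik$family == "poisson") {
    f <- pmin(f, 500)
    mu <- exp(f)
    g0 <- y * f - mu - lgamma(y + 1)
    if (!deriv) return(list(g0 = g0))
    list(g0 = g0, g1 = y - mu, g2 = -mu)
  } else if (lik$family == "zinb") {
    h <- 1e-4
    g0 <- lik_log_density(lik, y, f)
    if (!deriv) return(list(g0 = g0))
    gp <- lik_log_density(lik, y, f + h)
    gm <- lik_log_density(lik, y, f - h)
    list(g0 = g0, g1 = (gp - gm) / (2 * h), g2 = (gp - 2 * g0 + gm) / h^2)
  } else {
    stop("unsupported family in lik_log_gradients")
  }
}
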