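#' Posterior prediction from a GP fit
#'
#' Returns the approximate posterior of the latent function at new
#' locations. For count observation models the latent is the log-mean, so
#' `type = "response"` exponentiates (\eqn{E[e^f] = e^{m + v/2}}); for the
#' Gaussian family the latent lives on the transformed-count scale and
#' `"response"` adds back the training-data centring.
#'
#' @param object A converged [fit_gp()] object.
#' @param newdata Coordinates (vector or matrix); defaults to the training
#'   locations.
#' @param type `"latent"` or `"response"`.
#' @param full_cov Also return the full posterior covariance matrix?
#' @param ... Unused.
#' @return A list with `mean`, `var` and optionally `cov`.
#' @export
predict.gp_fit <- function(object, newdata = NULL,
                           type = c("latent", "response"),
                           full_cov = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(object$posterior)) {
    stop("fit has no posterior state (failed fit)", call. = FALSE)
  }
  Xs <- if (is.null(newdata)) object$X else as_coord_matrix(newdata)
  po <- object$posterior
  kern <- object$kernel
  Kss_diag <- kernel_diag(kern, Xs)
  jit <- object$control$jitter * max(kern$variance, 1e-12)

  if (po$engine == "exact_gauss") {
    K <- eval_kernel(kern, object$X)
    s2 <- object$likelihood$sigma2
    L <- t(chol(K + diag(s2 + jit, nrow(K))))
    Ks <- eval_kernel(kern, object$X, Xs)
    a <- backsolve(t(L), forwardsolve(L, object$t))
    mean <- drop(crossprod(Ks, a))
    V <- forwardsolve(L, Ks)
    var <- pmax(Kss_diag - colSums(V^2), 0)
    cov <- if (full_cov) eval_kernel(kern, Xs) - crossprod(V) else NULL
  } else if (po$engine == "titsias_gauss") {
    s2 <- object$likelihood$sigma2
    Z <- po$Z
    Kuu <- eval_kernel(kern, Z)
    Lk <- chol_jitter(Kuu, scale = kern$variance)
    Kuf <- eval_kernel(kern, Z, object$X)
    W <- forwardsolve(Lk, Kuf)
    B <- tcrossprod(W) / s2 + diag(nrow(W))
    Lb <- t(chol(B))
    Ks <- eval_kernel(kern, Z, Xs)
    As <- forwardsolve(Lk, Ks)                 # Lk^{-1} Kus
    c1 <- forwardsolve(Lb, W %*% object$t) / s2
    mean <- drop(crossprod(forwardsolve(Lb, As), c1))
    V2 <- forwardsolve(Lb, As)
    var <- pmax(Kss_diag - colSums(As^2) + colSums(V2^2), 0)
    cov <- if (full_cov) {
      eval_kernel(kern, Xs) - crossprod(As) + crossprod(V2)
    } else NULL
  } else if (po$engine == "oa_full") {
    Ks <- eval_kernel(kern, object$X, Xs)
    P <- backsolve(t(po$Lk), forwardsolve(po$Lk, Ks))   # Kj^{-1} Kxs
    mean <- drop(crossprod(Ks, backsolve(t(po$Lk),
                                         forwardsolve(po$Lk, po$mu))))
    rt <- sqrt(po$lambda)
    n <- nrow(po$Kj)
    B <- (rt * po$Kj) * rep(rt, each = n)
    diag(B) <- diag(B) + 1
    Lb <- t(chol(B))
    Wb <- forwardsolve(Lb, rt * po$Kj)
    S <- po$Kj - crossprod(Wb)
    SP <- S %*% P
    var <- pmax(Kss_diag - colSums(Ks * P) + colSums(P * SP), 1e-12)
    cov <- if (full_cov) {
      eval_kernel(kern, Xs) - crossprod(Ks, P) + crossprod(P, SP)
    } else NULL
  } else {  # svgp
    Z <- po$Z
    Ks <- eval_kernel(kern, Z, Xs)
    As <- t(forwardsolve(po$Lk, Ks))           # n* x M
    mean <- drop(As %*% po$m)
    Bc <- As %*% po$C
    var <- pmax(Kss_diag - rowSums(As^2) + rowSums(Bc^2), 1e-12)
    cov <- if (full_cov) {
      eval_kernel(kern, Xs) - tcrossprod(As) + tcrossprod(Bc)
    } else NULL
  }

  if (object$likelihood$family == "gaussian") {
    mean <- mean + object$center
  } else {
    mc <- object$mean_const
    if (!is.null(mc)) mean <- mean + mc
    if (type == "response") mean <- exp(mean + var / 2)
  }
  out <- list(mean = mean, var = var)
  if (full_cov) out$cov <- cov
  out
}

#' @export
fitted.gp_fit <- function(object, ...) {
  pr <- predict(object, object$X, type = "latent")
  if (object$likelihood$family == "gaussian") return(pr$mean)
  exp(object$offsets + pr$mean + pr$var / 2)
}

#' @export
residuals.gp_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  yy <- if (object$likelihood$family == "gaussian") object$t +
    object$center else object$y
  m <- fitted(object)
  r <- yy - m
  if (type == "response") return(r)
  v <- switch(object$likelihood$family,
    gaussian = rep(object$likelihood$sigma2, length(m)),
    poisson = m,
    negative_binomial = m + object$likelihood$dispersion * m^2,
    zinb = {
      psi <- object$likelihood$dropout_scale /
        (object$likelihood$dropout_scale + m)
      mu <- m
      (1 - psi) * (mu + object$likelihood$dispersion * mu^2) +
        psi * (1 - psi) * mu^2
    })
  r / sqrt(pmax(v, 1e-12))
}

#' Simulate replicate observations from a fitted GP
#'
#' Draws latent functions from the posterior at the training locations and
#' then draws counts (or transformed-scale Gaussians) from the observation
#' model, giving posterior-predictive replicates of the training data.
#'
#' @param object A converged `gp_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one replicate per column.
#' @export
simulate.gp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, object$X, type = "latent", full_cov = TRUE)
  n <- length(pr$mean)
  L <- t(chol(pr$cov + diag(1e-8 * max(diag(pr$cov), 1e-12), n)))
  lik <- object$likelihood
  out <- matrix(0, n, nsim)
  for (s in seq_len(nsim)) {
    f <- pr$mean + drop(L %*% stats::rnorm(n))
    out[, s] <- if (lik$family == "gaussian") {
      stats::rnorm(n, f, sqrt(lik$sigma2))
    } else {
      draw_counts(lik, exp(object$offsets + f))
    }
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

# Draw counts from the fitted observation model at mean mu.
draw_counts <- function(lik, mu) {
  n <- length(mu)
  switch(lik$family,
    poisson = stats::rpois(n, mu),
    negative_binomial = stats::rnbinom(n, mu = mu,
                                       size = 1 / max(lik$dispersion,
                                                      1e-12)),
    zinb = {
      y <- stats::rnbinom(n, mu = mu,
                          size = 1 / max(lik$dispersion, 1e-12))
      psi <- lik$dropout_scale / (lik$dropout_scale + mu)
      drop_mask <- stats::runif(n) < psi
      y[drop_mask] <- 0
      y
    },
    stop("no count draw for family ", lik$family))
}

#' @export
plot.gp_fit <- function(x, grid_size = 100, n_samples = 100, ...) {
  if (ncol(x$X) != 1L) {
    stop("plotting is implemented for 1-D inputs", call. = FALSE)
  }
  yy <- if (x$likelihood$family == "gaussian") x$t + x$center else x$y
  if (x$converged) {
    cr <- credible_region(x, grid_size = grid_size, n_samples = n_samples)
    ylim <- range(yy, cr$lower, cr$upper)
    plot(drop(x$X), yy, pch = 16, col = "grey30",
         xlab = "x", ylab = "y", ylim = ylim, ...)
    graphics::polygon(c(cr$x, rev(cr$x)), c(cr$lower, rev(cr$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(cr$x, cr$mean, col = "steelblue4", lwd = 2)
  } else {
    plot(drop(x$X), yy, pch = 16, col = "grey30", xlab = "x", ylab = "y",
         ...)
  }
  invisible(x)
}
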