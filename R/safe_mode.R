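#' Detect and repair poor GP fits by random restarts
#'
#' Local optima and occasional numerical failures (Cholesky or optimizer
#' errors) can leave a fit in a bad state. A local optimum is suspected
#' when the posterior predictive median lies strictly on one side of at
#' least 90% of the observations (the predictive is consistently above or
#' below the data). On detection the optimization is restarted from
#' hyper-parameters drawn log-uniformly within their bounds and the fit
#' with the highest bound is returned; the worst case returns the best fit
#' so far flagged as not converged.
#'
#' @param fit A [fit_gp()] result.
#' @param max_restarts Maximum number of restarts.
#' @param seed Optional integer seed for reproducible restart draws.
#' @param control Optional [gp_control()] for the restart fits (defaults
#'   to the original fit's control).
#' @return A `gp_fit`, with `n_restarts_used` recording the restarts
#'   taken (0 if the fit was already acceptable).
#' @export
safe_mode_refit <- function(fit, max_restarts = 5, seed = NULL,
                            control = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!needs_restart(fit)) return(fit)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  best <- fit
  ctrl <- if (is.null(control)) fit$control else control
  ctrl$safe_mode <- FALSE
  hb <- fit$hyper_bounds
  nm <- names(fit$hypers)
  used <- 0L
  for (i in seq_len(max_restarts)) {
    h <- stats::runif(length(nm), hb$lower, hb$upper)
    k2 <- fit$kernel; l2 <- fit$likelihood
    al <- apply_hypers(k2, l2, stats::setNames(h, nm))
    ctrl$init_lengthscale <- al$kernel$lengthscale
    cand <- fit_gp(fit$y, fit$X, kernel = al$kernel,
                   likelihood = al$likelihood,
                   sparse = fit$sparse,
                   M = if (fit$sparse) nrow(fit$inducing_points) else NULL,
                   scale_factors = if (any(fit$offsets != 0)) {
                     exp(fit$offsets)
                   } else NULL,
                   control = ctrl)
    used <- i
    if (is.finite(cand$log_ml) &&
        (!is.finite(best$log_ml) || cand$log_ml > best$log_ml)) {
      best <- cand
    }
    if (!needs_restart(best)) break
  }
  best$n_restarts_used <- used
  if (!is.finite(best$log_ml)) best$converged <- FALSE
  best
}

# TRUE when the fit failed numerically (factorization/optimizer error or
# non-convergence) or looks like a one-sided local optimum (predictive
# median above/below >= 90% of observations).
needs_restart <- function(fit, frac = 0.9) {
  if (fit$failed || !is.finite(fit$log_ml) || !fit$converged) return(TRUE)
  med <- tryCatch(predictive_median(fit), error = function(e) NULL)
  if (is.null(med)) return(TRUE)
  yy <- if (fit$likelihood$family == "gaussian") fit$t else fit$y
  above <- mean(med > yy)
  below <- mean(med < yy)
  max(above, below) >= frac
}

predictive_median <- function(fit) {
  lik <- fit$likelihood
  if (lik$family == "gaussian") {
    pr <- predict(fit, fit$X, type = "latent")
    return(pr$mean)
  }
  pr <- predict(fit, fit$X, type = "latent")
  mu <- exp(fit$offsets + pr$mean + pr$var / 2)
  switch(lik$family,
    poisson = stats::qpois(0.5, mu),
    negative_binomial = stats::qnbinom(0.5, mu = mu,
                                       size = 1 / max(lik$dispersion,
                                                      1e-12)),
    zinb = {
      med <- stats::qnbinom(0.5, mu = mu,
                            size = 1 / max(lik$dispersion, 1e-12))
      psi <- lik$dropout_scale / (lik$dropout_scale + mu)
      ifelse(psi >= 0.5, 0, med)
    })
}
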