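#' Posterior-predictive credible region
#'
#' Draws `n_samples` latent functions from the GP posterior on a
#' `grid_size` equally spaced grid, exponentiates each draw to obtain the
#' count-distribution mean, draws counts from the observation model, and
#' summarises the draws by their pointwise mean and 5th/95th percentiles.
#' The mean curve is smoothed with a cubic Savitzky-Golay filter and the
#' band edges with LOWESS.
#'
#' @param fit A converged 1-D [fit_gp()] object.
#' @param grid_size Number of equally spaced prediction points.
#' @param n_samples Number of posterior draws.
#' @param probs Lower/upper band percentiles.
#' @param span LOWESS span for the band edges; kept deliberately small so
#'   that smoothing does not shrink the band peaks.
#' @param seed Optional seed for the draws.
#' @return A data frame of class `"gp_credible"` with columns `x`, `mean`,
#'   `lower`, `upper`.
#' @export
credible_region <- function(fit, grid_size = 100, n_samples = 100,
                            probs = c(0.05, 0.95), span = 0.15,
                            seed = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!fit$converged) {
    stop("credible_region requires a converged fit", call. = FALSE)
  }
  if (ncol(fit$X) != 1L) {
    stop("credible_region is defined for 1-D inputs", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(min(fit$X), max(fit$X), length.out = grid_size)
  pr <- predict(fit, grid, type = "latent", full_cov = TRUE)
  L <- t(chol(pr$cov + diag(1e-8 * max(diag(pr$cov), 1e-12), grid_size)))
  lik <- fit$likelihood
  draws <- matrix(0, grid_size, n_samples)
  for (s in seq_len(n_samples)) {
    f <- pr$mean + drop(L %*% stats::rnorm(grid_size))
    draws[, s] <- if (lik$family == "gaussian") {
      stats::rnorm(grid_size, f, sqrt(lik$sigma2))
    } else {
      draw_counts(lik, exp(f))
    }
  }
  mean_curve <- rowMeans(draws)
  qs <- apply(draws, 1, stats::quantile, probs = probs)
  win <- min(11L, grid_size - (1 - grid_size %% 2))
  if (win %% 2 == 0) win <- win - 1
  smooth_mean <- if (win >= 5) {
    signal::sgolayfilt(mean_curve, p = 3, n = win)
  } else mean_curve
  lo <- stats::lowess(grid, qs[1, ], f = span)$y
  hi <- stats::lowess(grid, qs[2, ], f = span)$y
  out <- data.frame(x = grid, mean = smooth_mean,
                    lower = pmin(lo, hi), upper = pmax(lo, hi))
  class(out) <- c("gp_credible", "data.frame")
  attr(out, "draws") <- draws
  out
}
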