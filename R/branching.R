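#' Joint covariance for two GPs crossing at a branching point
#'
#' Builds the joint covariance of two functions `f` (trunk) and `g`
#' (branch) sharing a stationary kernel and constrained to cross at the
#' branching point `x_b`: the within-function blocks are `k(x, x')` and
#' the cross block is the rank-one form
#' \eqn{k(x, x_b) k(x', x_b)^\top / k(x_b, x_b)}, so that `f(x_b)` and
#' `g(x_b)` are perfectly correlated while the functions decouple far
#' from `x_b`.
#'
#' @param x_trunk Coordinates of points on `f`.
#' @param x_branch Coordinates of points on `g`.
#' @param x_b The branching point.
#' @param kernel A stationary [kernel_spec()].
#' @return A `(n_f + n_g)` square covariance matrix (trunk block first).
#' @export
branching_covariance <- function(x_trunk, x_branch, x_b, kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  Xf <- as_coord_matrix(x_trunk)
  Xg <- as_coord_matrix(x_branch)
  xb <- as_coord_matrix(x_b)
  kbb <- drop(eval_kernel(kernel, xb))
  if (kbb <= 0) {
    stop("degenerate branch point: k(x_b, x_b) = 0", call. = FALSE)
  }
  kff <- eval_kernel(kernel, Xf)
  kgg <- eval_kernel(kernel, Xg)
  kfb <- eval_kernel(kernel, Xf, xb)          # n_f x 1
  kgb <- eval_kernel(kernel, Xg, xb)          # n_g x 1
  kfg <- tcrossprod(kfb, kgb) / kbb
  rbind(cbind(kff, kfg), cbind(t(kfg), kgg))
}

# Optimize the structured variational bound at FIXED kernel matrix and
# likelihood (used per grid point of the branching posterior). Returns the
# bound and the optimal latent mean for warm starting.
elbo_fixed_K <- function(y, K, lik, off, control, mu_init = NULL) {
  n <- length(y)
  Lk <- chol_jitter(K, scale = mean(diag(K)), jitter0 = control$jitter,
                    jitter_max = control$jitter_max)
  Kj <- K + diag(attr(Lk, "jitter"), n)
  core <- function(a, lam, deriv = FALSE) {
    mu <- drop(Lk %*% a)
    rt <- sqrt(lam)
    B <- (rt * Kj) * rep(rt, each = n)
    diag(B) <- diag(B) + 1
    Lb <- tryCatch(t(chol(B)), error = function(e) NULL)
    if (is.null(Lb)) return(list(elbo = -Inf))
    Wb <- forwardsolve(Lb, rt * Kj)
    v <- pmax(diag(Kj) - colSums(Wb^2), 1e-12)
    kl <- 0.5 * ((n - sum(lam * v)) + sum(a^2) - n +
                   2 * sum(log(diag(Lb))))
    ee <- lik_expectations(lik, y, mu + off, v, order = control$order,
                           deriv = deriv)
    list(elbo = sum(ee$e) - kl, mu = mu, ee = ee, Wb = Wb)
  }
  neg_fn <- function(par) {
    el <- core(par[1:n], exp(par[(n + 1):(2 * n)]))$elbo
    if (!is.finite(el)) return(1e10)
    -el
  }
  neg_gr <- function(par) {
    a <- par[1:n]; lam <- exp(par[(n + 1):(2 * n)])
    el <- core(a, lam, deriv = TRUE)
    if (!is.finite(el$elbo)) return(rep(0, 2 * n))
    ga <- drop(crossprod(Lk, el$ee$dmu)) - a
    S <- Kj - crossprod(el$Wb)
    gtheta <- -drop(S^2 %*% (el$ee$dv + lam / 2)) * lam
    -c(ga, gtheta)
  }
  mu0 <- if (is.null(mu_init)) log(pmax(y, 0.5)) - off else mu_init
  a0 <- pmin(pmax(drop(forwardsolve(Lk, mu0)), -100), 100)
  lam0 <- pmin(pmax(-lik_log_gradients(lik, y, mu0 + off)$g2, 1e-2), 1e4)
  opt <- stats::optim(c(a0, log(lam0)), neg_fn, neg_gr,
                      method = "L-BFGS-B",
                      lower = c(rep(-200, n), rep(-15, n)),
                      upper = c(rep(200, n), rep(15, n)),
                      control = list(maxit = control$maxit,
                                     pgtol = control$pgtol,
                                     factr = control$factr))
  fin <- core(opt$par[1:n], exp(opt$par[(n + 1):(2 * n)]))
  list(elbo = fin$elbo, mu = fin$mu, converged = opt$convergence == 0L)
}

#' Posterior distribution over the branching time
#'
#' Evaluates the joint crossing-constrained model on a grid of candidate
#' branching points and normalizes the likelihoods into a posterior:
#' trunk observations always follow `f`; branch observations follow `f`
#' up to the candidate point and `g` after it. Kernel and likelihood
#' hyper-parameters are held fixed (fit them per lineage first, e.g. via
#' [fit_branching_hypers()]); for count likelihoods only the variational
#' distribution is re-optimized at each grid point, warm-started from its
#' neighbour.
#'
#' @param trunk_data,branch_data Lists with elements `x` (pseudotime) and
#'   `y` (counts, or values for the Gaussian family).
#' @param grid Candidate branching points (nonempty, increasing).
#' @param shared_hypers List with elements `kernel` ([kernel_spec()]) and
#'   `likelihood` ([likelihood_spec()]), already fitted.
#' @param control A [gp_control()].
#' @return An object of class `"branching_result"`: `grid`, `log_lik`,
#'   `posterior` (sums to 1), `map_branch_point`, `shared_hypers`.
#' @export
branching_posterior <- function(trunk_data, branch_data, grid,
                                shared_hypers,
                                control = gp_control()) {
  if (length(grid) == 0) stop("empty branching grid", call. = FALSE)
  kernel <- shared_hypers$kernel
  lik <- shared_hypers$likelihood
  stopifnot(inherits(kernel, "kernel_spec"),
            inherits(lik, "likelihood_spec"))
  xt <- as.numeric(trunk_data$x); yt <- trunk_data$y
  xb <- as.numeric(branch_data$x); yb <- branch_data$y
  gaussian <- lik$family == "gaussian"
  if (gaussian) {
    tt <- transform_counts(yt, lik$transform)
    tb <- transform_counts(yb, lik$transform)
    ctr <- mean(c(tt, tb))
    tt <- tt - ctr; tb <- tb - ctr
  } else {
    yt <- check_counts(yt); yb <- check_counts(yb)
  }
  y_all <- c(if (gaussian) tt else yt, if (gaussian) tb else yb)
  n <- length(y_all)
  off <- if (gaussian) rep(0, n) else {
    rep(mean(log(pmax(y_all, 0.5))), n)    # plug-in constant latent mean
  }
  ll <- numeric(length(grid))
  mu_warm <- NULL
  for (i in seq_along(grid)) {
    xbp <- grid[i]
    pre <- xb <= xbp
    # order: trunk points and pre-branch cells live on f, the rest on g
    x_f <- c(xt, xb[pre]); x_g <- xb[!pre]
    K <- branching_covariance(x_f, x_g, xbp, kernel)
    ord <- c(seq_along(xt), length(xt) + which(pre),
             length(xt) + which(!pre))
    yo <- y_all[ord]
    ll[i] <- if (gaussian) {
      tryCatch(gauss_log_ml_chol(K + diag(1e-6 * kernel$variance, n),
                                 lik$sigma2, yo),
               error = function(e) -Inf)
    } else {
      res <- tryCatch(elbo_fixed_K(yo, K, lik, off, control,
                                   mu_init = mu_warm[ord]),
                      error = function(e) list(elbo = -Inf))
      if (is.finite(res$elbo)) {
        mu_full <- numeric(n); mu_full[ord] <- res$mu
        mu_warm <- mu_full
      }
      res$elbo
    }
  }
  if (all(!is.finite(ll))) {
    stop("all branching-grid likelihoods are -Inf; cannot normalize",
         call. = FALSE)
  }
  mx <- max(ll[is.finite(ll)])
  w <- exp(ll - mx)
  w[!is.finite(ll)] <- 0
  post <- w / sum(w)
  structure(list(grid = grid, log_lik = ll, posterior = post,
                 map_branch_point = grid[which.max(post)],
                 shared_hypers = shared_hypers),
            class = "branching_result")
}

#' Fit shared hyper-parameters for the branching model
#'
#' Fits two separate GP regressions (one per lineage) with the requested
#' kernel and likelihood and combines the fitted hyper-parameters by
#' geometric mean; these are then held fixed while the branching-point
#' grid is scanned.
#'
#' @inheritParams branching_posterior
#' @param kernel,likelihood Starting specifications.
#' @param control A [gp_control()].
#' @return List with fitted `kernel`, `likelihood` and the two `gp_fit`
#'   objects.
#' @export
fit_branching_hypers <- function(trunk_data, branch_data,
                                 kernel = kernel_spec("rbf"),
                                 likelihood = likelihood_spec(
                                   "negative_binomial"),
                                 control = gp_control()) {
  # Branching trajectories are smooth by model assumption: the rank-one
  # crossing constraint carries no information once the lengthscale drops
  # below the cell spacing, so the per-lineage fits keep the lengthscale
  # above a tenth of the pseudotime range.
  control$lengthscale_rel[1] <- max(control$lengthscale_rel[1], 0.1)
  ft <- fit_gp(trunk_data$y, trunk_data$x, kernel = kernel,
               likelihood = likelihood, control = control)
  fb <- fit_gp(branch_data$y, branch_data$x, kernel = kernel,
               likelihood = likelihood, control = control)
  gm <- function(a, b) exp((log(a) + log(b)) / 2)
  kern <- kernel
  kern$lengthscale <- gm(ft$kernel$lengthscale, fb$kernel$lengthscale)
  # the shared amplitude must accommodate the more dynamic lineage
  kern$variance <- max(ft$kernel$variance, fb$kernel$variance)
  if (kernel$family == "periodic") {
    kern$period <- gm(ft$kernel$period, fb$kernel$period)
  }
  lik <- likelihood
  if (likelihood$family %in% c("negative_binomial", "zinb")) {
    lik$dispersion <- gm(max(ft$likelihood$dispersion, 1e-4),
                         max(fb$likelihood$dispersion, 1e-4))
  }
  if (likelihood$family == "zinb") {
    lik$dropout_scale <- gm(ft$likelihood$dropout_scale,
                            fb$likelihood$dropout_scale)
  }
  if (likelihood$family == "gaussian") {
    lik$sigma2 <- gm(ft$likelihood$sigma2, fb$likelihood$sigma2)
  }
  list(kernel = kern, likelihood = lik, fit_trunk = ft, fit_branch = fb)
}

#' Infer a gene's branching location from two lineages
#'
#' Convenience wrapper: splits cells by lineage label, fits shared
#' hyper-parameters per lineage, builds a uniform candidate grid
#' (spacing `delta`, default 1/50 of the pooled pseudotime range) and
#' computes the branching-time posterior.
#'
#' @param y Counts for one gene (all cells).
#' @param x Pseudotime per cell.
#' @param lineage Two-valued label per cell; the first level (or the
#'   `trunk` argument) is the trunk/baseline lineage.
#' @param trunk Label value to use as trunk (defaults to the first level).
#' @param kernel,likelihood Model specification.
#' @param delta Grid spacing.
#' @param control A [gp_control()].
#' @return A `"branching_result"` (see [branching_posterior()]).
#' @export
infer_branching <- function(y, x, lineage, trunk = NULL,
                            kernel = kernel_spec("rbf"),
                            likelihood = likelihood_spec(
                              "negative_binomial"),
                            delta = NULL, control = gp_control()) {
  lv <- unique(lineage)
  if (length(lv) != 2) stop("exactly two lineage labels required",
                            call. = FALSE)
  if (is.null(trunk)) trunk <- lv[1]
  it <- lineage == trunk
  td <- list(x = x[it], y = y[it])
  bd <- list(x = x[!it], y = y[!it])
  sh <- fit_branching_hypers(td, bd, kernel = kernel,
                             likelihood = likelihood, control = control)
  rng <- range(x)
  if (is.null(delta)) delta <- diff(rng) / 50
  grid <- seq(rng[1], rng[2], by = delta)
  res <- branching_posterior(td, bd, grid,
                             shared_hypers = sh[c("kernel", "likelihood")],
                             control = control)
  res$trunk_label <- trunk
  res
}

#' @export
print.branching_result <- function(x, ...) {
  cat("<branching_result> grid of", length(x$grid), "points on [",
      format(min(x$grid), digits = 4), ",",
      format(max(x$grid), digits = 4), "]\n")
  cat("  MAP branching point:", format(x$map_branch_point, digits = 5),
      "\n")
  invisible(x)
}

#' @export
plot.branching_result <- function(x, ...) {
  plot(x$grid, x$posterior, type = "h", lwd = 2,
       xlab = "branching point", ylab = "posterior probability", ...)
  graphics::abline(v = x$map_branch_point, col = "red3", lty = 2)
  invisible(x)
}
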