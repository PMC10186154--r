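test_that("Gaussian-likelihood marginal likelihood matches the closed form", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    x <- sort(runif(n))
    y <- rpois(n, exp(1 + sin(5 * x)))
    fit <- fit_gp(y, x, likelihood = likelihood_spec("gaussian"),
                  control = fast_ctl())
    # oracle at the fitted hyper-parameters, written independently
    t <- log1p(y); t <- t - mean(t)
    K <- eval_kernel(fit$kernel, x)
    expect_equal(fit$log_ml,
                 as.numeric(gauss_ml_oracle(K, fit$likelihood$sigma2, t)),
                 tolerance = 1e-6)
  }
})

test_that("sparse inference lower-bounds full inference", {
  set.seed(62)
  x <- sort(runif(60))
  y <- rpois(60, exp(2 + sin(6 * x)))
  # Gaussian: Titsias bound vs exact marginal likelihood
  ff <- fit_gp(y, x, likelihood = likelihood_spec("gaussian"),
               control = fast_ctl())
  fs <- fit_gp(y, x, likelihood = likelihood_spec("gaussian"),
               sparse = TRUE, M = 10, control = fast_ctl())
  expect_lte(fs$log_ml, ff$log_ml + 1e-6)
  # NB: both sides are separately optimized bounds, so allow optimizer
  # slop comparable to the LLR nestedness tolerance
  fnf <- fit_gp(y, x, control = fast_ctl())
  fns <- fit_gp(y, x, sparse = TRUE, M = 10, control = fast_ctl())
  expect_lte(fns$log_ml, fnf$log_ml + 0.05)
})

test_that("constant data yields a flat latent and a null likelihood ratio", {
  x <- seq(0, 1, length.out = 12)
  y <- rep(7, 12)
  fit <- fit_gp(y, x, control = fast_ctl())
  pr <- predict(fit, x)
  expect_equal(unname(pr$mean), rep(log(7), 12), tolerance = 0.15)
  fc <- fit_gp(y, x, kernel = kernel_spec("constant"),
               control = fast_ctl())
  expect_lt(abs(fit$log_ml - fc$log_ml), 0.05)
})

test_that("the lengthscale of a simulated NB-GP is recovered", {
  set.seed(63)
  l_true <- 0.3
  ls <- replicate(10, {
    n <- 100
    x <- sort(runif(n))
    K <- eval_kernel(kernel_spec("rbf", lengthscale = l_true,
                                 variance = 1), x)
    f <- 2 + drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
    y <- rnbinom(n, mu = exp(f), size = 10)
    fit <- fit_gp(y, x, control = fast_ctl())
    fit$kernel$lengthscale
  })
  expect_gte(median(ls), 0.15)
  expect_lte(median(ls), 0.6)
})

test_that("inducing-point selection is principled", {
  set.seed(64)
  x <- matrix(runif(10), ncol = 1)
  # M = N returns the inputs unchanged
  expect_equal(select_inducing_points(x, 10), x)
  expect_equal(select_inducing_points(x, 10, method = "kmeans"), x)
  # stationary kernel: all diagonals tie, lowest index wins
  z1 <- select_inducing_points(x, 1, kernel = kernel_spec("rbf"))
  expect_equal(drop(z1), x[1, 1])
  # greedy M = 2 matches exhaustive search over all pairs
  x5 <- matrix(c(0, 0.11, 0.43, 0.72, 0.95), ncol = 1)
  kern <- kernel_spec("rbf", lengthscale = 0.3)
  K <- eval_kernel(kern, x5)
  combos <- combn(5, 2)
  dets <- apply(combos, 2, function(idx) det(K[idx, idx]))
  best <- sort(combos[, which.max(dets)])
  z2 <- select_inducing_points(x5, 2, kernel = kern)
  expect_equal(sort(drop(z2)), drop(x5[best, ]))
  # kmeans returns M centres
  z3 <- select_inducing_points(matrix(runif(40), ncol = 2), 5,
                               method = "kmeans")
  expect_equal(dim(z3), c(5L, 2L))
  expect_error(select_inducing_points(x, 11), "M")
})

test_that("BIC penalizes hyper-parameters and selects the generative kernel", {
  expect_equal(bic(0, N = exp(1), d = 1), 1)
  expect_gt(bic(-10, N = 20, d = 3), bic(-10, N = 20, d = 2))
  set.seed(65)
  wins <- replicate(10, {
    x <- seq(0, 1, length.out = 30)
    f <- 2 + 1.2 * sin(2 * pi * x / 0.5)
    y <- rnbinom(30, mu = exp(f), size = 20)
    fp <- fit_gp(y, x, kernel = kernel_spec("periodic", period = 0.4),
                 control = fast_ctl())
    fl <- fit_gp(y, x, kernel = kernel_spec("linear"),
                 control = fast_ctl())
    bic(fp) < bic(fl)
  })
  expect_gte(mean(wins), 0.8)
})

test_that("safe mode detects failed or poor fits and restarts recover", {
  set.seed(66)
  x <- seq(0, 1, length.out = 16)
  y <- rnbinom(16, mu = exp(2 + sin(8 * x)), size = 5)
  good <- fit_gp(y, x, control = fast_ctl())
  expect_identical(safe_mode_refit(good)$n_restarts_used, 0L)
  # an under-optimized fit (tiny iteration budget) is flagged and the
  # restarts strictly improve the bound
  poor <- fit_gp(y, x, control = gp_control(maxit = 2))
  expect_false(poor$converged)
  fixed <- safe_mode_refit(poor, max_restarts = 3, seed = 1,
                           control = fast_ctl())
  expect_gt(fixed$n_restarts_used, 0)
  expect_gt(fixed$log_ml, poor$log_ml)
  expect_true(is.finite(fixed$log_ml))
})

test_that("stationary fits are invariant to coordinate translation and mean scaling", {
  set.seed(67)
  x <- seq(0, 1, length.out = 18)
  y <- rnbinom(18, mu = exp(2 + sin(5 * x)), size = 8)
  f1 <- fit_gp(y, x, control = fast_ctl())
  f2 <- fit_gp(y, x + 57.3, control = fast_ctl())
  expect_equal(f1$log_ml, f2$log_ml, tolerance = 1e-5)
  # supplying scale factors shifts the latent but not the test statistic
  c1 <- fit_gp(y, x, kernel = kernel_spec("constant"),
               control = fast_ctl())
  f3 <- fit_gp(y, x, scale_factors = rep(10, 18), control = fast_ctl())
  c3 <- fit_gp(y, x, kernel = kernel_spec("constant"),
               scale_factors = rep(10, 18), control = fast_ctl())
  expect_equal(f1$log_ml - c1$log_ml, f3$log_ml - c3$log_ml,
               tolerance = 0.1)
})

test_that("credible regions reflect the observation model", {
  set.seed(68)
  x <- rep(seq(0, 1, length.out = 11), each = 2)
  f <- 3 + 1.2 * sin(4 * x + 1)
  y <- rnbinom(22, mu = exp(f), size = 0.8)
  fnb <- fit_gp(y, x, control = fast_ctl())
  fpo <- fit_gp(y, x, likelihood = likelihood_spec("poisson"),
                control = fast_ctl())
  cr_nb <- credible_region(fnb, grid_size = 50, n_samples = 200, seed = 1)
  cr_po <- credible_region(fpo, grid_size = 50, n_samples = 200, seed = 1)
  # over-dispersion widens the predictive band on average
  expect_gt(mean(cr_nb$upper - cr_nb$lower),
            mean(cr_po$upper - cr_po$lower))
  # a non-converged fit is refused
  bad <- fit_gp(y, x, control = gp_control(maxit = 1))
  expect_error(credible_region(bad), "converged")
})

test_that("posterior-predictive bands achieve near-nominal coverage", {
  set.seed(69)
  grid <- seq(0, 1, length.out = 11)
  x <- rep(grid, each = 2)
  covered <- 0; total <- 0
  for (g in 1:25) {
    dr <- countgp:::draw_sine(grid, c(0.5, 2.5), c(2, 4))
    alpha <- runif(1, 0.1, 0.5)
    mu <- exp(dr$f[rep(seq_along(grid), each = 2)])
    y <- rnbinom(22, mu = mu, size = 1 / alpha)
    y_hold <- rnbinom(22, mu = mu, size = 1 / alpha)
    fit <- fit_gp(y, x, control = fast_ctl())
    if (!fit$converged) next
    cr <- credible_region(fit, grid_size = 60, n_samples = 150)
    lo <- approx(cr$x, cr$lower, xout = x)$y
    hi <- approx(cr$x, cr$upper, xout = x)$y
    covered <- covered + sum(y_hold >= lo & y_hold <= hi)
    total <- total + length(y_hold)
  }
  expect_gte(covered / total, 0.85)
  expect_lte(covered / total, 0.97)
})

test_that("gp_fit methods expose the fitted model coherently", {
  set.seed(70)
  x <- seq(0, 1, length.out = 14)
  y <- rnbinom(14, mu = exp(2 + sin(6 * x)), size = 5)
  fit <- fit_gp(y, x, control = fast_ctl())
  expect_named(coef(fit),
               c("lengthscale", "variance", "dispersion"))
  expect_equal(as.numeric(logLik(fit)), fit$log_ml)
  expect_equal(BIC(fit), bic(fit))
  expect_output(print(fit), "gp_fit")
  expect_output(print(summary(fit)), "BIC")
  # the logged bound trace only records improvements: non-decreasing
  expect_gt(length(fit$elbo_trace), 0)
  expect_true(all(diff(fit$elbo_trace) >= -1e-4))
  r <- residuals(fit)
  expect_length(r, 14)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(14L, 3L))
  expect_true(all(sims >= 0))
  pr <- predict(fit, c(0.25, 0.5), type = "response")
  expect_length(pr$mean, 2)
  expect_true(all(pr$mean > 0))
})
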