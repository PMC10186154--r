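test_that("branching covariance implements the crossing constraint", {
  kern <- kernel_spec("rbf", lengthscale = 0.3, variance = 1.7)
  xb <- 0.5
  # f(x_b) and g(x_b) are perfectly correlated
  K <- branching_covariance(xb, xb, xb, kern)
  expect_equal(K[1, 2], kern$variance)
  expect_equal(K[1, 1], K[1, 2])
  # a branch point far outside the data decouples the functions
  Kfar <- branching_covariance(c(0.1, 0.2), c(0.15, 0.3), 50, kern)
  expect_lt(max(abs(Kfar[1:2, 3:4])), 1e-12)
  # brute-force elementwise assembly on a 4 + 3 instance
  xf <- c(0.05, 0.3, 0.55, 0.9); xg <- c(0.2, 0.6, 0.85)
  Kb <- branching_covariance(xf, xg, xb, kern)
  k <- function(a, b) 1.7 * exp(-(a - b)^2 / (2 * 0.3^2))
  ref <- matrix(0, 7, 7)
  pts <- c(xf, xg)
  for (i in 1:7) for (j in 1:7) {
    same <- (i <= 4) == (j <= 4)
    ref[i, j] <- if (same) k(pts[i], pts[j]) else {
      k(pts[i], xb) * k(pts[j], xb) / k(xb, xb)
    }
  }
  expect_equal(Kb, ref, tolerance = 1e-12)
  # degenerate branch point
  lin <- kernel_spec("linear")
  expect_error(branching_covariance(0.2, 0.4, 0, lin), "degenerate")
})

test_that("the branching posterior normalizes and handles degenerate grids", {
  set.seed(101)
  sim <- simulate_branching(n_cells = 30, x_b_true = 0.5,
                            effect_size = 3, seed = 5)
  it <- sim$lineage == "trunk"
  td <- list(x = sim$x[it], y = sim$y[it])
  bd <- list(x = sim$x[!it], y = sim$y[!it])
  sh <- list(kernel = kernel_spec("rbf", lengthscale = 0.4,
                                  variance = 0.6),
             likelihood = likelihood_spec("negative_binomial",
                                          dispersion = 0.3))
  # single grid point: posterior mass 1 there
  b1 <- branching_posterior(td, bd, grid = 0.5, shared_hypers = sh,
                            control = fast_ctl())
  expect_equal(b1$posterior, 1)
  expect_equal(b1$map_branch_point, 0.5)
  # full grid: normalized posterior, MAP on the grid
  br <- branching_posterior(td, bd, grid = seq(0.05, 0.95, by = 0.05),
                            shared_hypers = sh, control = fast_ctl())
  expect_equal(sum(br$posterior), 1, tolerance = 1e-9)
  expect_true(br$map_branch_point %in% br$grid)
  expect_error(branching_posterior(td, bd, numeric(0), sh), "empty")
})

test_that("indistinguishable lineages give no early branching signal", {
  set.seed(102)
  x <- sort(runif(24))
  y <- rnbinom(24, mu = exp(2.5 + 0.5 * sin(3 * x)), size = 5)
  td <- list(x = x, y = y)
  bd <- list(x = x, y = y)      # branch identical to trunk
  sh <- list(kernel = kernel_spec("rbf", lengthscale = 0.4,
                                  variance = 0.5),
             likelihood = likelihood_spec("negative_binomial",
                                          dispersion = 0.25))
  br <- branching_posterior(td, bd, grid = seq(0.05, 0.95, by = 0.09),
                            shared_hypers = sh, control = fast_ctl())
  # no concentration of mass in the early region
  expect_lte(sum(br$posterior[br$grid < 0.25]), 0.5)
})

test_that("a strong branch point is localized near the truth", {
  errs <- sapply(1:5, function(s) {
    sim <- simulate_branching(n_cells = 50, x_b_true = 0.5,
                              effect_size = 4, dispersion = 0.2,
                              seed = 130 + s)
    br <- infer_branching(sim$y, sim$x, sim$lineage, trunk = "trunk",
                          delta = 0.05, control = fast_ctl())
    abs(br$map_branch_point - 0.5)
  })
  expect_lte(median(errs), 0.1)
})

test_that("NB and Gaussian agree on clean high-count branching data", {
  sim <- simulate_branching(n_cells = 60, x_b_true = 0.5,
                            effect_size = 4, dispersion = 0.05,
                            base_log_mean = 4, seed = 21)
  delta <- 0.1
  br_nb <- infer_branching(sim$y, sim$x, sim$lineage, trunk = "trunk",
                           delta = delta, control = fast_ctl())
  br_ga <- infer_branching(sim$y, sim$x, sim$lineage, trunk = "trunk",
                           likelihood = likelihood_spec("gaussian"),
                           delta = delta, control = fast_ctl())
  expect_lte(abs(br_nb$map_branch_point - br_ga$map_branch_point),
             delta + 1e-9)
})

test_that("NB credible bands cover zeros that Gaussian bands miss", {
  set.seed(103)
  x <- sort(runif(40))
  mu <- exp(1.5 + 1.2 * sin(4 * x))
  y <- rnbinom(40, mu = mu, size = 1 / 2.5)   # heavy zero inflation
  y[sample(40, 10)] <- 0
  f_nb <- fit_gp(y, x, control = fast_ctl())
  f_ga <- fit_gp(y, x, likelihood = likelihood_spec("gaussian"),
                 control = fast_ctl())
  cr_nb <- credible_region(f_nb, grid_size = 60, n_samples = 200,
                           seed = 2)
  cr_ga <- credible_region(f_ga, grid_size = 60, n_samples = 200,
                           seed = 2)
  zeros <- x[y == 0]
  lo_nb <- approx(cr_nb$x, cr_nb$lower, xout = zeros)$y
  # the Gaussian band lives on the log1p scale; zero maps to 0
  lo_ga <- approx(cr_ga$x, cr_ga$lower, xout = zeros)$y
  cov_nb <- mean(lo_nb <= 0)
  cov_ga <- mean(lo_ga <= 0)
  expect_gte(cov_nb, cov_ga)
  expect_gt(cov_nb, 0.5)
})
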