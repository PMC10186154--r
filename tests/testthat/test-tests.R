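test_that("chi-squared p-values use the corrected 2*LLR statistic", {
  expect_equal(chi2_pvalues(0, df = 1), 1)
  expect_equal(chi2_pvalues(3.841 / 2, df = 1), 0.05, tolerance = 1e-3)
  # negative ratios are clamped before the transform
  expect_equal(chi2_pvalues(-5, df = 1), 1)
  expect_true(is.na(chi2_pvalues(NA, df = 1)))
  expect_error(chi2_pvalues(1, df = 0), "df")
})

test_that("Storey q-values are monotone, bounded and consistent with BH", {
  expect_identical(qvalues(numeric(0)), numeric(0))
  expect_equal(as.numeric(qvalues(rep(1, 20))), rep(1, 20))
  set.seed(81)
  p <- runif(500)
  q <- qvalues(p)
  pi0 <- attr(q, "pi0")
  # null p-values: pi0 estimated near 1
  expect_gte(pi0, 0.8)
  expect_lte(pi0, 1.0)
  # q monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1 + 1e-12))
  # the Storey estimate is a pi0-scaled BH adjustment
  expect_equal(as.numeric(q), pi0 * p.adjust(p, "BH"), tolerance = 1e-10)
  # NA p-values (non-converged genes) propagate without contaminating
  p2 <- c(p, NA, NA)
  q2 <- qvalues(p2)
  expect_true(all(is.na(q2[501:502])))
  expect_equal(as.numeric(q2[1:500]), as.numeric(q), tolerance = 1e-10)
})

test_that("one-sample statistics separate dynamic from constant genes", {
  set.seed(82)
  grid <- seq(0, 1, length.out = 11)
  x <- rep(grid, each = 2)
  # constant genes give small ratios, strong sine genes large ones
  n_rep <- 20
  llr_null <- numeric(n_rep); llr_sig <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    y0 <- rnbinom(22, mu = 20, size = 1 / 0.05)
    f <- 2 + 1.8 * sin(6 * x + 1)
    y1 <- rnbinom(22, mu = exp(f), size = 1 / 0.05)
    ds <- counts_dataset(rbind(null_gene = y0, sine_gene = y1), x)
    tt <- one_sample_test(ds, control = fast_ctl())
    llr_null[i] <- tt$llr[1]; llr_sig[i] <- tt$llr[2]
  }
  expect_gte(mean(llr_null < 1, na.rm = TRUE), 0.9)
  expect_gte(mean(llr_sig > 5, na.rm = TRUE), 0.9)
  # nestedness: negative ratios only within optimizer tolerance
  expect_lte(mean(c(llr_null, llr_sig) < -0.01, na.rm = TRUE), 0.05)
})

test_that("a gene with identical counts everywhere has a null ratio", {
  x <- rep(seq(0, 1, length.out = 11), each = 2)
  ds <- counts_dataset(matrix(9, 1, 22), x)
  tt <- one_sample_test(ds, control = fast_ctl())
  expect_lt(abs(tt$llr[1]), 0.01)
  expect_equal(tt$p_value[1], 1, tolerance = 0.01)
})

test_that("two-sample test ignores identical conditions and flags diverging ones", {
  set.seed(83)
  x <- seq(0, 1, length.out = 12)
  yA <- rnbinom(12, mu = 10, size = 10)
  # B an exact copy of A: duplicated data can only favour the shared
  # model (llr <= 0), so the gene is not flagged
  ds_same <- counts_dataset(matrix(c(yA, yA), 1), c(x, x),
                            labels = rep(c("A", "B"), each = 12))
  t_same <- two_sample_test(ds_same, control = fast_ctl())
  expect_lt(t_same$llr[1], 0.1)
  expect_equal(t_same$p_value[1], 1, tolerance = 0.05)
  # B an independent replicate of the same process: llr near zero
  yB <- rnbinom(12, mu = 10, size = 10)
  ds_rep <- counts_dataset(matrix(c(yA, yB), 1), c(x, x),
                           labels = rep(c("A", "B"), each = 12))
  t_rep <- two_sample_test(ds_rep, control = fast_ctl())
  expect_lt(abs(t_rep$llr[1]), 2)
  # A constant, B sine-modulated around the same mean
  yB <- rnbinom(12, mu = exp(log(10) + 1.5 * sin(7 * x)), size = 10)
  ds_diff <- counts_dataset(matrix(c(yA, yB), 1), c(x, x),
                            labels = rep(c("A", "B"), each = 12))
  t_diff <- two_sample_test(ds_diff, control = fast_ctl())
  one_A <- one_sample_test(counts_dataset(matrix(yA, 1), x),
                           control = fast_ctl())
  expect_gt(t_diff$llr[1], 0)
  expect_gt(t_diff$llr[1], one_A$llr[1])
  # input validation
  expect_error(two_sample_test(counts_dataset(matrix(yA, 1), x)),
               "labels")
  ds3 <- counts_dataset(matrix(c(yA, yA), 1), c(x, x),
                        labels = rep(c("A", "B", "C"), length.out = 24))
  expect_error(two_sample_test(ds3), "two condition labels")
})

test_that("the NB likelihood flags over-dispersed divergence that a Gaussian misses", {
  set.seed(84)
  x <- seq(0, 1, length.out = 12)
  nb_flags <- 0; gauss_flags <- 0
  n_rep <- 8
  for (i in seq_len(n_rep)) {
    muA <- rep(15, 12)
    muB <- exp(log(15) + 1.6 * (x - 0.5))
    yA <- rnbinom(12, mu = muA, size = 1 / 1.5)
    yB <- rnbinom(12, mu = muB, size = 1 / 1.5)
    ds <- counts_dataset(matrix(c(yA, yB), 1), c(x, x),
                         labels = rep(c("A", "B"), each = 12))
    t_nb <- two_sample_test(ds, control = fast_ctl())
    t_ga <- two_sample_test(ds, likelihood = likelihood_spec("gaussian"),
                            control = fast_ctl())
    nb_flags <- nb_flags + (chi2_pvalues(t_nb$llr[1], df = 3) < 0.05)
    gauss_flags <- gauss_flags + (chi2_pvalues(t_ga$llr[1], df = 3) <
                                    0.05)
  }
  expect_gte(nb_flags, gauss_flags)
})

test_that("permutation p-value estimator respects its bounds", {
  pp <- countgp:::perm_pvalues
  # observed below every null statistic
  expect_equal(pp(0.1, c(1, 2, 3)), 1)
  # observed above all K pooled null values
  expect_equal(pp(10, c(1, 2, 3)), 1 / 4)
  expect_true(is.na(pp(NA, 1:3)))
})

test_that("the pipeline is deterministic under a fixed master seed", {
  run <- function() {
    sim <- simulate_timecourse(simulation_design(n_genes = 3, seed = 9))
    one_sample_test(sim$dataset, control = fast_ctl())
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1$llr, t2$llr)
  expect_identical(t1$q_value, t2$q_value)
})
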