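test_that("coverage filtering drops genes first, then locations, once each", {
  # gene D totals 2 (dropped); location l3 then totals 9 (dropped)
  counts <- rbind(A = c(5, 6, 4),
                  B = c(3, 8, 2),
                  C = c(7, 2, 3),
                  D = c(1, 1, 0))
  coords <- cbind(x = 1:3, y = c(1, 2, 1))
  ds <- filter_spatial(counts, coords)
  expect_equal(dim(ds$counts), c(3L, 2L))
  expect_equal(rownames(ds$counts), c("A", "B", "C"))
  # zero thresholds are the identity
  ds0 <- filter_spatial(counts, coords, 0, 0)
  expect_equal(ds0$counts, counts_dataset(counts, coords)$counts)
  # everything filtered is an explicit error
  expect_error(filter_spatial(counts, coords, min_gene_total = 100),
               "all genes")
})

test_that("filtering agrees with an independent two-pass oracle and is idempotent", {
  set.seed(91)
  counts <- matrix(rpois(30 * 40, 0.45), 30, 40)
  coords <- cbind(runif(40), runif(40))
  ds <- filter_spatial(counts, coords, 3, 5)
  # oracle: explicit row filter then column filter
  keep_g <- which(apply(counts, 1, sum) >= 3)
  keep_s <- which(apply(counts[keep_g, , drop = FALSE], 2, sum) >= 5)
  expect_equal(unname(ds$counts), unname(counts[keep_g, keep_s]))
  expect_equal(unname(ds$coords), unname(coords[keep_s, ]))
  ds2 <- filter_spatial(ds, min_gene_total = 3, min_location_total = 5)
  expect_identical(ds$counts, ds2$counts)
})

test_that("scale-factor regression recovers proportional structure", {
  # exactly proportional counts: beta equals the constant of proportion
  T_i <- c(20, 35, 50, 80, 120, 60, 45, 95)
  y <- 2 * T_i
  nf <- fit_scale_factors(y, T_i)
  expect_equal(nf$beta, 2, tolerance = 1e-3)
  expect_equal(nf$scale_factors, 2 * T_i, tolerance = 1e-2)
  # constant totals give identical factors (a scalar latent offset)
  nf2 <- fit_scale_factors(c(4, 6, 5, 3, 7), rep(100, 5))
  expect_equal(length(unique(round(nf2$scale_factors, 9))), 1L)
  # undefined slope for an all-zero gene
  expect_warning(out <- fit_scale_factors(rep(0, 5), T_i[1:5]),
                 "all-zero")
  expect_null(out)
})

test_that("the NB regression slope is recovered from noisy draws", {
  set.seed(92)
  rel_err <- replicate(10, {
    T_i <- rpois(100, 800) + 1
    y <- rnbinom(100, mu = 0.02 * T_i, size = 2)
    fit_scale_factors(y, T_i)$beta / 0.02 - 1
  })
  expect_lt(abs(median(rel_err)), 0.15)
})

test_that("a gene's spatial statistic is the same alone or in a batch", {
  set.seed(93)
  sp <- simulate_spatial(n_genes = 4, n_locations = 30,
                         pattern_fraction = 0.5, seed = 7)
  batch <- sv_pipeline(sp$dataset, normalize = FALSE,
                       min_location_total = 0, control = fast_ctl())
  solo_ds <- counts_dataset(sp$dataset$counts[2, , drop = FALSE],
                            sp$dataset$coords)
  solo <- sv_pipeline(solo_ds, normalize = FALSE, min_location_total = 0,
                      min_gene_total = 0, control = fast_ctl())
  expect_equal(solo$llr[1], batch$llr[2], tolerance = 1e-8)
})

test_that("size confounding inflates SV calls unless normalization absorbs it", {
  set.seed(94)
  sp <- simulate_spatial(n_genes = 40, n_locations = 36,
                         pattern_fraction = 0, dispersion = 0.3,
                         confound = 1.2, seed = 11)
  raw <- sv_pipeline(sp$dataset, normalize = FALSE,
                     min_location_total = 0, control = fast_ctl())
  norm <- sv_pipeline(sp$dataset, normalize = TRUE,
                      min_location_total = 0, control = fast_ctl())
  rate_raw <- mean(raw$call, na.rm = TRUE)
  rate_norm <- mean(norm$call, na.rm = TRUE)
  expect_gt(rate_raw, 0.5)            # almost everything looks spatial
  expect_lte(rate_norm, 0.15)         # normalization restores calibration
  # the beta column is present for every retained gene
  expect_true(all(is.finite(norm$beta)))
})
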