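test_that("delimited counts round-trip bit-identically", {
  td <- withr::local_tempdir()
  counts <- matrix(rpois(12, 5), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ds <- counts_dataset(counts, seq(0, 1, length.out = 4))
  p <- file.path(td, "counts.tsv")
  write_counts(ds, p)
  ds2 <- read_counts(p, coords = file.path(td, "counts_coords.tsv"))
  expect_identical(ds2$counts, ds$counts)
  expect_equal(unname(ds2$coords), unname(ds$coords),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("matrix-market triplets load identically to the dense file", {
  td <- withr::local_tempdir()
  counts <- matrix(rpois(40, 1.5), 8, 5,
                   dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  ds <- counts_dataset(counts, cbind(runif(5), runif(5)))
  write_counts(ds, file.path(td, "m.tsv"))
  write_counts(ds, file.path(td, "m.mtx"), format = "matrix_market")
  d1 <- read_counts(file.path(td, "m.tsv"),
                    coords = file.path(td, "m_coords.tsv"))
  d2 <- read_counts(file.path(td, "m.mtx"),
                    coords = file.path(td, "m_coords.tsv"))
  expect_equal(d1$counts, d2$counts)
})

test_that("invalid counts and unmatched samples are named in errors", {
  td <- withr::local_tempdir()
  writeLines(c("gene\ts1\ts2", "g1\t3\t-2", "g2\t1\t0"),
             file.path(td, "bad.tsv"))
  writeLines(c("id\tx", "s1\t0.1", "s2\t0.2"),
             file.path(td, "coords.tsv"))
  expect_error(read_counts(file.path(td, "bad.tsv"),
                           coords = file.path(td, "coords.tsv")),
               "g1.*s2")
  writeLines(c("gene\ts1\tsX", "g1\t3\t2", "g2\t1\t0"),
             file.path(td, "ok.tsv"))
  expect_error(read_counts(file.path(td, "ok.tsv"),
                           coords = file.path(td, "coords.tsv")),
               "sX")
})

test_that("the spatial x_y header dialect is parsed", {
  td <- withr::local_tempdir()
  writeLines(c("gene\t1.5_2.25\t3_4.5", "g1\t3\t2", "g2\t1\t0"),
             file.path(td, "sp.tsv"))
  ds <- read_counts(file.path(td, "sp.tsv"), coords = "header")
  expect_equal(unname(ds$coords),
               cbind(c(1.5, 3), c(2.25, 4.5)))
})

test_that("run_pipeline produces an auditable, reproducible results directory", {
  td <- withr::local_tempdir()
  simdir <- file.path(td, "sim")
  run_pipeline(list(subcommand = "simulate", n_genes = 6, seed = 5,
                    out = simdir))
  expect_true(file.exists(file.path(simdir, "counts.tsv")))
  expect_true(file.exists(file.path(simdir, "truth.tsv")))
  outdir <- file.path(td, "run1")
  cfg <- list(subcommand = "one_sample",
              counts = file.path(simdir, "counts.tsv"),
              coords = file.path(simdir, "counts_coords.tsv"),
              seed = 5, out = outdir)
  run_pipeline(cfg)
  res <- read.delim(file.path(outdir, "results.tsv"))
  expect_equal(nrow(res), 6)
  expect_true(all(c("gene", "llr", "p_value", "q_value", "call") %in%
                    names(res)))
  meta <- jsonlite::read_json(file.path(outdir, "config.json"))
  expect_true(!is.null(meta$package_version))
  expect_equal(meta$seed, 5)
  expect_true(nchar(meta$config_hash) == 32)
  lg <- jsonlite::read_json(file.path(outdir, "log.json"))
  expect_equal(lg$genes_attempted, 6)
  # identical config + seed => byte-identical results
  outdir2 <- file.path(td, "run2")
  cfg$out <- outdir2
  run_pipeline(cfg)
  expect_identical(readLines(file.path(outdir, "results.tsv")),
                   readLines(file.path(outdir2, "results.tsv")))
})

test_that("the spatial subcommand emits the normalization slope", {
  td <- withr::local_tempdir()
  sp <- simulate_spatial(n_genes = 5, n_locations = 25, confound = 1,
                         seed = 3)
  write_counts(sp$dataset, file.path(td, "sp.tsv"))
  outdir <- file.path(td, "out")
  run_pipeline(list(subcommand = "spatial",
                    counts = file.path(td, "sp.tsv"),
                    coords = file.path(td, "sp_coords.tsv"),
                    seed = 2, out = outdir))
  res <- read.delim(file.path(outdir, "results.tsv"))
  expect_true("beta" %in% names(res))
  expect_true(all(is.finite(res$beta)))
})
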