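#' Filter low-coverage genes and spatial locations
#'
#' Drops genes whose total count is below `min_gene_total`, then locations
#' whose total count (over the remaining genes) is below
#' `min_location_total`. Each filter is applied once, genes first; the
#' operation is idempotent on its own output.
#'
#' @param dataset A [counts_dataset()], or a counts matrix together with
#'   `coords`.
#' @param coords Coordinates when `dataset` is a bare matrix.
#' @param min_gene_total Minimum total count per gene (default 3).
#' @param min_location_total Minimum total count per retained location
#'   (default 10).
#' @return A filtered [counts_dataset()].
#' @export
filter_spatial <- function(dataset, coords = NULL, min_gene_total = 3,
                           min_location_total = 10) {
  if (!inherits(dataset, "counts_dataset")) {
    dataset <- counts_dataset(dataset, coords)
  }
  keep_g <- rowSums(dataset$counts) >= min_gene_total
  if (!any(keep_g)) stop("all genes removed by the gene filter",
                         call. = FALSE)
  cts <- dataset$counts[keep_g, , drop = FALSE]
  keep_s <- colSums(cts) >= min_location_total
  if (!any(keep_s)) stop("all locations removed by the location filter",
                         call. = FALSE)
  subset_dataset(dataset, genes = which(keep_g), samples = which(keep_s))
}

#' Location scale factors by zero-intercept NB regression
#'
#' Learns location-specific normalization factors for spatial counts:
#' for one gene, fits \eqn{y_i \sim NB(\beta T_i, r)} by maximum
#' likelihood, where \eqn{T_i} is the total count at location `i`, the
#' regression has an identity link and zero intercept, and
#' \eqn{\beta > 0} is enforced by a log parameterization. The scale
#' factors are \eqn{k_i = \beta T_i}.
#'
#' @param gene_counts Counts of one gene across locations.
#' @param location_totals Positive per-location total counts \eqn{T_i}.
#' @return A list of class `"spatial_normalization"` with `beta`, `r`,
#'   `scale_factors` and the achieved log-likelihood; `NULL` (with a
#'   warning) for an all-zero gene, whose slope is undefined.
#' @export
fit_scale_factors <- function(gene_counts, location_totals) {
  gene_counts <- check_counts(gene_counts, "gene_counts")
  if (any(location_totals <= 0)) {
    stop("location totals must be positive", call. = FALSE)
  }
  if (all(gene_counts == 0)) {
    warning("all-zero gene: slope undefined, skipping")
    return(NULL)
  }
  beta0 <- sum(gene_counts) / sum(location_totals)
  nll <- function(p) {
    beta <- exp(p[1]); r <- exp(p[2])
    -sum(nb_log_pmf(gene_counts, beta * location_totals, r))
  }
  o <- stats::optim(c(log(beta0), 0), nll, method = "L-BFGS-B",
                    lower = c(log(beta0) - 15, log(1e-4)),
                    upper = c(log(beta0) + 15, log(1e6)))
  beta <- exp(o$par[1]); r <- exp(o$par[2])
  structure(list(beta = beta, r = r,
                 scale_factors = beta * location_totals,
                 logLik = -o$value, converged = o$convergence == 0L),
            class = "spatial_normalization")
}

#' @export
print.spatial_normalization <- function(x, ...) {
  cat("<spatial_normalization> beta =", format(x$beta, digits = 5),
      " r =", format(x$r, digits = 5), "\n")
  invisible(x)
}

#' Spatially-variable-gene pipeline
#'
#' Runs the full spatial workflow: coverage filtering, per-gene
#' NB-regression scale factors (absorbing total-count confounding), a
#' one-sample test with a 2-D isotropic RBF kernel and NB likelihood, and
#' chi-squared (or permutation) p-values with Storey q-values at the
#' given FDR level. The spatial lengthscale is initialized at half the
#' median pairwise distance between locations.
#'
#' @param dataset A [counts_dataset()] with 2-D coordinates (raw counts;
#'   filtering happens inside).
#' @param likelihood Observation model (NB by default).
#' @param normalize Apply NB-regression scale factors?
#' @param fdr_method `"chi2"` or `"perm"`.
#' @param B Permutation rounds when `fdr_method = "perm"`.
#' @param min_gene_total,min_location_total Filter thresholds.
#' @param fdr_level FDR threshold.
#' @param sparse,M Sparse-inference options.
#' @param control A [gp_control()].
#' @param seed Seed for the permutation variant.
#' @param verbose Progress output?
#' @return A `"gp_test_table"` with an extra `beta` column (the fitted
#'   normalization slope; `NA` when `normalize = FALSE`).
#' @export
sv_pipeline <- function(dataset,
                        likelihood = likelihood_spec("negative_binomial"),
                        normalize = TRUE,
                        fdr_method = c("chi2", "perm"), B = 100,
                        min_gene_total = 3, min_location_total = 10,
                        fdr_level = 0.05, sparse = FALSE, M = NULL,
                        control = gp_control(), seed = NULL,
                        verbose = FALSE) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(dataset, "counts_dataset"))
  if (ncol(dataset$coords) != 2) {
    stop("sv_pipeline requires 2-D coordinates", call. = FALSE)
  }
  ds <- filter_spatial(dataset, min_gene_total = min_gene_total,
                       min_location_total = min_location_total)
  totals <- colSums(ds$counts)
  G <- nrow(ds$counts)
  betas <- rep(NA_real_, G)

  # spatial lengthscale initialization: half the median pairwise distance
  D <- stats::dist(ds$coords)
  control$init_lengthscale <- stats::median(D) / 2

  run_one <- function(d) {
    if (fdr_method == "chi2") {
      one_sample_test(d, kernel = kernel_spec("rbf"),
                      likelihood = likelihood, sparse = sparse, M = M,
                      fdr_level = fdr_level, control = control,
                      verbose = verbose)
    } else {
      permutation_test(d, kernel = kernel_spec("rbf"),
                       likelihood = likelihood, B = B, sparse = sparse,
                       M = M, fdr_level = fdr_level, seed = seed,
                       control = control, verbose = verbose)
    }
  }

  if (normalize) {
    sf <- matrix(1, G, ncol(ds$counts))
    for (g in seq_len(G)) {
      nf <- tryCatch(fit_scale_factors(ds$counts[g, ], totals),
                     warning = function(w) NULL,
                     error = function(e) NULL)
      if (!is.null(nf)) {
        betas[g] <- nf$beta
        sf[g, ] <- nf$scale_factors
      }
    }
    ds <- counts_dataset(ds$counts, ds$coords, scale_factors = sf)
  }
  tab <- as.data.frame(run_one(ds))
  tab$beta <- betas
  attr(tab, "fdr_level") <- fdr_level
  attr(tab, "n_not_converged") <- sum(!tab$converged)
  attr(tab, "n_genes_filtered") <- nrow(dataset$counts) - G
  attr(tab, "n_locations_filtered") <-
    ncol(dataset$counts) - ncol(ds$counts)
  class(tab) <- c("gp_test_table", "data.frame")
  tab
}
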