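#' Chi-squared p-values from log-likelihood ratios
#'
#' Converts per-gene log-likelihood ratios into upper-tail chi-squared
#' p-values using the corrected statistic `2 * LLR` (twice the natural-log
#' likelihood ratio). Negative ratios (optimizer noise under nested models)
#' are clamped to zero first.
#'
#' @param llr Log-likelihood ratios (alternative minus null, natural log).
#' @param df Chi-squared degrees of freedom (difference in optimized
#'   hyper-parameter count between alternative and null).
#' @return p-values in `[0, 1]`; `NA` ratios give `NA`.
#' @export
chi2_pvalues <- function(llr, df = 1) {
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  stats::pchisq(2 * pmax(llr, 0), df = df, lower.tail = FALSE)
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance measures with the null
#' proportion \eqn{\hat\pi_0} estimated on a lambda grid and extrapolated
#' with a smoothing spline (the "smoother" method). q-values are monotone
#' in p and capped at 1. `NA` p-values (non-converged genes) propagate as
#' `NA` and do not enter the estimate.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda Grid of tuning values for the \eqn{\hat\pi_0} estimate.
#' @return q-values aligned with `p`; the estimate `pi0` is attached as an
#'   attribute.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  pi0 <- if (m < 50) {
    1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                    error = function(e) NULL)
    est <- if (is.null(fit)) min(pi0_l) else {
      stats::predict(fit, x = max(lambda))$y
    }
    min(max(est, 1e-3), 1)
  }
  o <- order(pv, decreasing = TRUE)
  qs <- numeric(m)
  running <- 1
  rank_desc <- m:1
  for (i in seq_len(m)) {
    idx <- o[i]
    running <- min(running, pi0 * m * pv[idx] / rank_desc[i])
    qs[idx] <- running
  }
  q[ok] <- qs
  attr(q, "pi0") <- pi0
  q
}

# Shared per-gene fitting for the one-sample statistic: dynamic vs
# constant-kernel null under the same likelihood family.
fit_gene_one_sample <- function(y, coords, kernel, likelihood,
                                sparse, M, inducing_method,
                                scale_factors, control) {
  dyn <- fit_gp(y, coords, kernel = kernel, likelihood = likelihood,
                sparse = sparse, M = M, inducing_method = inducing_method,
                scale_factors = scale_factors, control = control)
  nul <- fit_gp(y, coords,
                kernel = kernel_spec("constant",
                                     variance = kernel$variance),
                likelihood = likelihood,
                sparse = FALSE, scale_factors = scale_factors,
                control = control)
  list(dyn = dyn, nul = nul,
       llr = dyn$log_ml - nul$log_ml,
       df = dyn$n_hypers - nul$n_hypers,
       converged = dyn$converged && nul$converged)
}

finish_test_table <- function(tab, df, fdr_level) {
  tab$p_value <- ifelse(is.na(tab$llr), NA_real_,
                        chi2_pvalues(tab$llr, df = df))
  q <- qvalues(tab$p_value)
  tab$q_value <- as.numeric(q)
  tab$call <- !is.na(tab$q_value) & tab$q_value <= fdr_level
  attr(tab, "pi0") <- attr(q, "pi0")
  attr(tab, "df") <- df
  attr(tab, "fdr_level") <- fdr_level
  attr(tab, "n_not_converged") <- sum(!tab$converged)
  class(tab) <- c("gp_test_table", "data.frame")
  tab
}

#' One-sample differential-expression / spatial-variability test
#'
#' For every gene, fits a dynamic GP (the requested kernel) and a
#' constant-latent null under the same observation model and forms the
#' log-likelihood ratio `llr = L_dyn - L_const`. The models are nested:
#' the constant model is the infinite-lengthscale limit of the dynamic
#' one. p-values are upper-tail chi-squared on `2 * llr` and FDR control
#' uses Storey q-values. Genes whose fits do not converge get `NA`
#' statistics and are excluded from the FDR computation (their count is
#' recorded in the `n_not_converged` attribute).
#'
#' @param dataset A [counts_dataset()] (single condition).
#' @param kernel,likelihood Model specification ([kernel_spec()],
#'   [likelihood_spec()]).
#' @param sparse,M,inducing_method Sparse-inference options, see
#'   [fit_gp()].
#' @param fdr_level FDR threshold for the `call` column.
#' @param df Chi-squared degrees of freedom; defaults to the difference in
#'   optimized hyper-parameter count between the two models.
#' @param control A [gp_control()].
#' @param verbose Print a progress line every 25 genes?
#' @return A data frame of class `"gp_test_table"` with one row per gene:
#'   `gene`, `llr`, `p_value`, `q_value`, `call`, `alpha_hat`,
#'   `lengthscale_hat`, `converged`.
#' @export
one_sample_test <- function(dataset,
                            kernel = kernel_spec("rbf"),
                            likelihood = likelihood_spec(
                              "negative_binomial"),
                            sparse = FALSE, M = NULL,
                            inducing_method = "mdpp",
                            fdr_level = 0.05, df = NULL,
                            control = gp_control(), verbose = FALSE) {
  stopifnot(inherits(dataset, "counts_dataset"))
  G <- nrow(dataset$counts)
  rows <- vector("list", G)
  df_used <- df
  for (g in seq_len(G)) {
    fr <- fit_gene_one_sample(dataset$counts[g, ], dataset$coords,
                              kernel, likelihood, sparse, M,
                              inducing_method, sf_row(dataset, g),
                              control)
    if (is.null(df_used)) df_used <- fr$df
    rows[[g]] <- data.frame(
      gene = rownames(dataset$counts)[g],
      llr = if (fr$converged) fr$llr else NA_real_,
      alpha_hat = if (fr$dyn$likelihood$family %in%
                        c("negative_binomial", "zinb")) {
        fr$dyn$likelihood$dispersion
      } else NA_real_,
      lengthscale_hat = fr$dyn$kernel$lengthscale,
      converged = fr$converged,
      stringsAsFactors = FALSE)
    if (verbose && g %% 25 == 0) {
      message("fitted ", g, "/", G, " genes")
    }
  }
  tab <- do.call(rbind, rows)
  finish_test_table(tab, df = df_used, fdr_level = fdr_level)
}

#' Two-sample differential-expression test
#'
#' Tests whether two conditions follow different trajectories. Three GPs
#' are fitted per gene: one to each condition and a shared GP treating
#' both conditions as replicates on common coordinates; the statistic is
#' `llr = (L_A + L_B) - L_shared`.
#'
#' @param dataset A [counts_dataset()] whose `labels` take exactly two
#'   values, with overlapping coordinate ranges.
#' @inheritParams one_sample_test
#' @return A `"gp_test_table"` with additional columns `llr_a`, `llr_b`
#'   holding the per-condition marginal likelihoods.
#' @export
two_sample_test <- function(dataset,
                            kernel = kernel_spec("rbf"),
                            likelihood = likelihood_spec(
                              "negative_binomial"),
                            sparse = FALSE, M = NULL,
                            inducing_method = "mdpp",
                            fdr_level = 0.05, df = NULL,
                            control = gp_control(), verbose = FALSE) {
  stopifnot(inherits(dataset, "counts_dataset"))
  if (is.null(dataset$labels)) {
    stop("two_sample_test needs per-sample labels", call. = FALSE)
  }
  lv <- unique(dataset$labels)
  if (length(lv) != 2) {
    stop("exactly two condition labels are required, got ",
         length(lv), call. = FALSE)
  }
  ia <- which(dataset$labels == lv[1])
  ib <- which(dataset$labels == lv[2])
  if (length(ia) == 0 || length(ib) == 0) {
    stop("one condition is empty", call. = FALSE)
  }
  ra <- range(dataset$coords[ia, 1]); rb <- range(dataset$coords[ib, 1])
  if (ra[2] < rb[1] || rb[2] < ra[1]) {
    warning("condition coordinate ranges do not overlap")
  }
  G <- nrow(dataset$counts)
  rows <- vector("list", G)
  df_used <- df
  for (g in seq_len(G)) {
    y <- dataset$counts[g, ]
    sfg <- sf_row(dataset, g)
    fa <- fit_gp(y[ia], dataset$coords[ia, , drop = FALSE],
                 kernel = kernel, likelihood = likelihood,
                 sparse = sparse, M = M,
                 inducing_method = inducing_method,
                 scale_factors = sfg[ia],
                 control = control)
    fb <- fit_gp(y[ib], dataset$coords[ib, , drop = FALSE],
                 kernel = kernel, likelihood = likelihood,
                 sparse = sparse, M = M,
                 inducing_method = inducing_method,
                 scale_factors = sfg[ib],
                 control = control)
    fs <- fit_gp(y, dataset$coords, kernel = kernel,
                 likelihood = likelihood, sparse = sparse, M = M,
                 inducing_method = inducing_method,
                 scale_factors = sfg,
                 control = control)
    conv <- fa$converged && fb$converged && fs$converged
    if (is.null(df_used)) df_used <- fa$n_hypers
    rows[[g]] <- data.frame(
      gene = rownames(dataset$counts)[g],
      llr = if (conv) fa$log_ml + fb$log_ml - fs$log_ml else NA_real_,
      llr_a = fa$log_ml, llr_b = fb$log_ml,
      alpha_hat = if (fs$likelihood$family %in%
                        c("negative_binomial", "zinb")) {
        fs$likelihood$dispersion
      } else NA_real_,
      lengthscale_hat = fs$kernel$lengthscale,
      converged = conv,
      stringsAsFactors = FALSE)
    if (verbose && g %% 25 == 0) message("fitted ", g, "/", G, " genes")
  }
  tab <- do.call(rbind, rows)
  finish_test_table(tab, df = df_used, fdr_level = fdr_level)
}

# Add-one permutation p-values: observed statistics against a pool of null
# statistics. Exposed internally for direct testing of the estimator.
perm_pvalues <- function(observed, nulls) {
  vapply(observed, function(o) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(nulls >= o)) / (1 + length(nulls))
  }, numeric(1))
}

#' Permutation test for spatial/temporal variability
#'
#' Estimates p-values under a permuted null: in each of `B` rounds the
#' coordinates are randomly rearranged (the same permutation applied to
#' every gene) and the one-sample statistic recomputed. The constant-model
#' likelihood is permutation invariant, so only the dynamic fit is redone.
#' Null statistics are pooled across genes by default (per-gene nulls via
#' `pool = FALSE`) and p-values use the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + #null)`.
#'
#' @inheritParams one_sample_test
#' @param B Number of permutation rounds (>= 1).
#' @param pool Pool null statistics across genes?
#' @param seed Optional seed for the permutations.
#' @return A `"gp_test_table"`; the matrix of null statistics is attached
#'   as attribute `"null_llr"` (B columns).
#' @export
permutation_test <- function(dataset,
                             kernel = kernel_spec("rbf"),
                             likelihood = likelihood_spec(
                               "negative_binomial"),
                             B = 100, pool = TRUE,
                             sparse = FALSE, M = NULL,
                             inducing_method = "mdpp",
                             fdr_level = 0.05, seed = NULL,
                             control = gp_control(), verbose = FALSE) {
  stopifnot(inherits(dataset, "counts_dataset"))
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  G <- nrow(dataset$counts)
  if (pool && B * G < 20 / fdr_level) {
    warning("B = ", B, " gives coarse p-value resolution at FDR level ",
            fdr_level)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- one_sample_test(dataset, kernel = kernel,
                         likelihood = likelihood, sparse = sparse,
                         M = M, inducing_method = inducing_method,
                         fdr_level = fdr_level, control = control,
                         verbose = verbose)
  # constant-model likelihoods, reused across permutations
  null_const <- numeric(G)
  for (g in seq_len(G)) {
    fn <- fit_gp(dataset$counts[g, ], dataset$coords,
                 kernel = kernel_spec("constant",
                                      variance = kernel$variance),
                 likelihood = likelihood,
                 scale_factors = sf_row(dataset, g),
                 control = control)
    null_const[g] <- fn$log_ml
  }
  n <- ncol(dataset$counts)
  null_llr <- matrix(NA_real_, G, B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    Xp <- dataset$coords[perm, , drop = FALSE]
    for (g in seq_len(G)) {
      fd <- fit_gp(dataset$counts[g, ], Xp, kernel = kernel,
                   likelihood = likelihood, sparse = sparse, M = M,
                   inducing_method = inducing_method,
                   scale_factors = sf_row(dataset, g),
                   control = control)
      null_llr[g, b] <- if (fd$converged) {
        fd$log_ml - null_const[g]
      } else NA_real_
    }
    if (verbose) message("permutation round ", b, "/", B)
  }
  tab <- as.data.frame(obs)
  if (pool) {
    pool_stats <- pmax(null_llr[is.finite(null_llr)], 0)
    tab$p_value <- perm_pvalues(pmax(tab$llr, 0), pool_stats)
  } else {
    tab$p_value <- vapply(seq_len(G), function(g) {
      ns <- pmax(null_llr[g, is.finite(null_llr[g, ])], 0)
      if (length(ns) == 0 || is.na(tab$llr[g])) return(NA_real_)
      perm_pvalues(max(tab$llr[g], 0), ns)
    }, numeric(1))
  }
  q <- qvalues(tab$p_value)
  tab$q_value <- as.numeric(q)
  tab$call <- !is.na(tab$q_value) & tab$q_value <= fdr_level
  attr(tab, "pi0") <- attr(q, "pi0")
  attr(tab, "fdr_level") <- fdr_level
  attr(tab, "B") <- B
  attr(tab, "null_llr") <- null_llr
  attr(tab, "n_not_converged") <- sum(!tab$converged)
  class(tab) <- c("gp_test_table", "data.frame")
  tab
}

#' @export
print.gp_test_table <- function(x, ...) {
  cat("<gp_test_table> ", nrow(x), " genes, ",
      sum(x$call, na.rm = TRUE), " called at FDR ",
      attr(x, "fdr_level"), sep = "")
  nc <- attr(x, "n_not_converged")
  if (!is.null(nc) && nc > 0) cat(" (", nc, " not converged)", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
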