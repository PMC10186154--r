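# Run expr with a temporary RNG state seeded at `seed` (NULL = leave the
# current stream alone), restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Design of a synthetic time-course counts experiment
#'
#' Captures the generative design for [simulate_timecourse()]: `n_genes`
#' genes measured at `timepoints` with `replicates` replicate draws per
#' time, a fraction of genes carrying a genuine temporal signal, two
#' expression regimes (low/high, via the `c` range of the latent mean)
#' and two dispersion regimes (`alpha_low ~ U[0.01, 0.1]`,
#' `alpha_high ~ U[1, 3]`). Dynamic latent functions are sines
#' \eqn{f(x) = a \sin(x b + d) + c} with `b ~ U[pi/4, 2*pi]`,
#' `d ~ U[0, 2*pi]`, or natural cubic splines through two interior
#' control points; non-dynamic genes are constant at the median of a
#' dynamic function evaluated on the grid. Counts are drawn from
#' \eqn{NB(e^{f(x)}, \alpha)}.
#'
#' @param n_genes Number of genes.
#' @param fraction_dynamic Fraction of genes with a time-varying latent.
#' @param timepoints Coordinate grid.
#' @param replicates Replicate draws per timepoint.
#' @param expression_level `"low"` or `"high"` (sets the `c` range).
#' @param dispersion_level `"low"` or `"high"` (sets the `alpha` range).
#' @param function_family `"sine"`, `"spline"` or `"mix"` (half each).
#' @param a_range,c_range_low,c_range_high Latent amplitude/offset ranges
#'   (natural-log scale).
#' @param seed Integer seed.
#' @return A list of class `"simulation_design"`.
#' @export
simulation_design <- function(n_genes = 600, fraction_dynamic = 0.5,
                              timepoints = seq(0, 1, length.out = 11),
                              replicates = 2,
                              expression_level = c("high", "low"),
                              dispersion_level = c("high", "low"),
                              function_family = c("sine", "spline",
                                                  "mix"),
                              a_range = c(0.5, 2.5),
                              c_range_low = c(0.5, 2),
                              c_range_high = c(3, 6),
                              seed = 1L) {
  expression_level <- match.arg(expression_level)
  dispersion_level <- match.arg(dispersion_level)
  function_family <- match.arg(function_family)
  if (fraction_dynamic < 0 || fraction_dynamic > 1) {
    stop("'fraction_dynamic' must be in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_design")
}

# Draw one latent sine function on the grid; returns f values + params.
draw_sine <- function(grid, a_range, c_range) {
  a <- stats::runif(1, a_range[1], a_range[2])
  b <- stats::runif(1, pi / 4, 2 * pi)
  d <- stats::runif(1, 0, 2 * pi)
  cc <- stats::runif(1, c_range[1], c_range[2])
  list(f = a * sin(grid * b + d) + cc,
       params = c(a = a, b = b, c = cc, d = d))
}

# Natural cubic spline through two interior control points (plus drawn
# endpoint values), giving a C^2 latent on [0, 1].
draw_spline <- function(grid, a_range, c_range) {
  a <- stats::runif(1, a_range[1], a_range[2])
  cc <- stats::runif(1, c_range[1], c_range[2])
  cx <- sort(stats::runif(2, 0.1, 0.9))
  xs <- c(min(grid), cx, max(grid))
  ys <- cc + a * stats::runif(4, -1, 1)
  f <- stats::spline(xs, ys, method = "natural", xout = grid)$y
  list(f = f, params = c(a = a, c = cc, x1 = cx[1], x2 = cx[2]))
}

#' Simulate a time-course counts dataset
#'
#' Generates counts according to a [simulation_design()]: dynamic genes
#' get a sine or spline latent log-mean, non-dynamic genes sit at the
#' median of a dynamic function, and counts are NB draws with the
#' regime's dispersion. Truth labels are returned alongside.
#'
#' @param design A [simulation_design()].
#' @return List of class `"gp_simulation"` with elements `dataset`
#'   (a [counts_dataset()], genes x (timepoints x replicates)), `truth`
#'   (data frame: `gene`, `dynamic`, `family`, `alpha`, `f_median`) and
#'   `design`.
#' @export
simulate_timecourse <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    grid <- design$timepoints
    x <- rep(grid, each = design$replicates)
    n <- length(x)
    G <- design$n_genes
    n_dyn <- round(design$fraction_dynamic * G)
    c_range <- if (design$expression_level == "high") {
      design$c_range_high
    } else design$c_range_low
    a_rng <- if (design$dispersion_level == "high") c(1, 3) else {
      c(0.01, 0.1)
    }
    fams <- if (design$function_family == "mix") {
      rep_len(c("sine", "spline"), n_dyn)
    } else rep(design$function_family, n_dyn)

    fmat <- matrix(0, G, length(grid))
    truth <- data.frame(gene = paste0("gene_", seq_len(G)),
                        dynamic = FALSE, family = "constant",
                        alpha = stats::runif(G, a_rng[1], a_rng[2]),
                        a = NA_real_, b = NA_real_, c = NA_real_,
                        d = NA_real_,
                        f_median = NA_real_, stringsAsFactors = FALSE)
    for (g in seq_len(n_dyn)) {
      dr <- if (fams[g] == "sine") {
        draw_sine(grid, design$a_range, c_range)
      } else {
        draw_spline(grid, design$a_range, c_range)
      }
      fmat[g, ] <- dr$f
      for (pn in intersect(names(dr$params), c("a", "b", "c", "d"))) {
        truth[[pn]][g] <- dr$params[[pn]]
      }
      # degenerate draws (flat latent) are reclassified as constant
      truth$dynamic[g] <- stats::sd(dr$f) > 1e-8
      truth$family[g] <- if (truth$dynamic[g]) fams[g] else "constant"
    }
    if (n_dyn < G) {
      # constants sit at the medians of the dynamic functions, cycling
      # through them when there are more constant than dynamic genes
      src <- if (n_dyn > 0) rep_len(seq_len(n_dyn), G - n_dyn) else {
        integer(0)
      }
      for (i in seq_len(G - n_dyn)) {
        med <- if (n_dyn > 0) stats::median(fmat[src[i], ]) else {
          mean(c_range)
        }
        fmat[n_dyn + i, ] <- med
      }
    }
    truth$f_median <- apply(fmat, 1, stats::median)
    counts <- matrix(0L, G, n)
    rep_idx <- rep(seq_along(grid), each = design$replicates)
    for (g in seq_len(G)) {
      mu <- exp(fmat[g, rep_idx])
      counts[g, ] <- stats::rnbinom(n, mu = mu, size = 1 / truth$alpha[g])
    }
    rownames(counts) <- truth$gene
    colnames(counts) <- paste0("s", seq_len(n))
    structure(list(dataset = counts_dataset(counts, x),
                   truth = truth, latent = fmat, design = design),
              class = "gp_simulation")
  })
}

#' Simulate spatial counts with patterned and flat genes
#'
#' Places locations on a jittered square grid; patterned genes get a
#' smooth 2-D latent surface (a Gaussian bump with random centre and
#' width), flat genes a constant latent, and counts are NB draws.
#' Optionally a shared smooth location-size factor multiplies every
#' gene's mean (total-count confounding), exercising the NB-regression
#' scale normalization downstream.
#'
#' @param n_genes Number of genes.
#' @param n_locations Number of spatial locations (>= 25).
#' @param pattern_fraction Fraction of genes with a spatial pattern.
#' @param dispersion NB dispersion `alpha` (scalar).
#' @param base_log_mean Latent constant (natural log of the flat mean).
#' @param amplitude Bump height on the log scale.
#' @param confound Strength of the shared location-size factor on the log
#'   scale (0 disables confounding).
#' @param seed Integer seed.
#' @return A `"gp_simulation"` list: `dataset`, `truth` (`gene`,
#'   `pattern`), `size_factor` (per location) and the call parameters.
#' @export
simulate_spatial <- function(n_genes = 100, n_locations = 64,
                             pattern_fraction = 0.5, dispersion = 0.5,
                             base_log_mean = 2, amplitude = 1.5,
                             confound = 0, seed = 1L) {
  if (n_locations < 25) stop("need at least 25 locations", call. = FALSE)
  with_seed(seed, {
    side <- ceiling(sqrt(n_locations))
    gx <- as.vector(outer(seq_len(side), rep(1, side)))[1:n_locations]
    gy <- as.vector(outer(rep(1, side), seq_len(side)))[1:n_locations]
    coords <- cbind(x = gx + stats::runif(n_locations, -0.3, 0.3),
                    y = gy + stats::runif(n_locations, -0.3, 0.3))
    n_pat <- round(pattern_fraction * n_genes)
    bump <- function() {
      ctr <- c(stats::runif(1, 1, side), stats::runif(1, 1, side))
      w <- stats::runif(1, 0.15, 0.35) * side
      exp(-((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2) /
            (2 * w^2))
    }
    size_factor <- if (confound > 0) {
      b <- bump()
      exp(confound * (b - mean(b)) / max(stats::sd(b), 1e-9))
    } else rep(1, n_locations)
    counts <- matrix(0L, n_genes, n_locations)
    pattern <- c(rep(TRUE, n_pat), rep(FALSE, n_genes - n_pat))
    for (g in seq_len(n_genes)) {
      f <- if (pattern[g]) {
        base_log_mean + amplitude * (bump() - 0.5)
      } else rep(base_log_mean, n_locations)
      mu <- size_factor * exp(f)
      counts[g, ] <- stats::rnbinom(n_locations, mu = mu,
                                    size = 1 / dispersion)
    }
    rownames(counts) <- paste0("gene_", seq_len(n_genes))
    colnames(counts) <- paste0("loc_", seq_len(n_locations))
    structure(list(dataset = counts_dataset(counts, coords),
                   truth = data.frame(gene = rownames(counts),
                                      pattern = pattern),
                   size_factor = size_factor,
                   params = list(n_genes = n_genes,
                                 n_locations = n_locations,
                                 pattern_fraction = pattern_fraction,
                                 dispersion = dispersion,
                                 confound = confound, seed = seed)),
              class = "gp_simulation")
  })
}

#' Simulate a branching two-lineage dataset
#'
#' Two lineages share a smooth trunk latent before `x_b_true` and
#' diverge after it: the branch latent picks up a linear ramp reaching
#' `effect_size` at pseudotime 1, so the functions cross at the branch
#' point and divergence starts there rather than drifting in later.
#' Counts are NB draws along pseudotime.
#'
#' @param n_cells Total cells (split evenly between lineages).
#' @param x_b_true True branching point in `(0, 1]`.
#' @param effect_size Log-scale divergence at pseudotime 1.
#' @param dispersion NB dispersion.
#' @param base_log_mean,amplitude Trunk latent parameters
#'   (`f = base + amplitude * sin(2 x + 1)`).
#' @param seed Integer seed.
#' @return A list of class `"gp_simulation"`: `x` (pseudotime), `y`
#'   (counts), `lineage` (`"trunk"` / `"branch"`), `truth`.
#' @export
simulate_branching <- function(n_cells = 60, x_b_true = 0.5,
                               effect_size = 3, dispersion = 0.3,
                               base_log_mean = 2.5, amplitude = 0.8,
                               seed = 1L) {
  if (x_b_true <= 0 || x_b_true > 1) {
    stop("'x_b_true' must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_t <- ceiling(n_cells / 2)
    n_b <- n_cells - n_t
    xt <- sort(stats::runif(n_t))
    xb <- sort(stats::runif(n_b))
    f <- function(x) base_log_mean + amplitude * sin(2 * x + 1)
    g <- function(x) {
      f(x) + effect_size * pmax(x - x_b_true, 0) / max(1 - x_b_true,
                                                       1e-12)
    }
    yt <- stats::rnbinom(n_t, mu = exp(f(xt)), size = 1 / dispersion)
    yb <- stats::rnbinom(n_b, mu = exp(g(xb)), size = 1 / dispersion)
    structure(list(x = c(xt, xb), y = c(yt, yb),
                   lineage = rep(c("trunk", "branch"), c(n_t, n_b)),
                   truth = list(x_b_true = x_b_true,
                                effect_size = effect_size,
                                dispersion = dispersion),
                   params = list(n_cells = n_cells, seed = seed)),
              class = "gp_simulation")
  })
}
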