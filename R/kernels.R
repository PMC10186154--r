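#' Kernel (covariance function) specification
#'
#' Constructs a covariance-function specification used as the GP prior over
#' the latent log-mean. Four stationary-or-simpler families are supported:
#'
#' * `"rbf"` — squared-exponential,
#'   \eqn{k(x,x') = \sigma_f^2 \exp(-\|x-x'\|^2 / (2 l^2))};
#'   isotropic Euclidean distance is used in any input dimension.
#' * `"linear"` — \eqn{k(x,x') = \sigma_f^2 \, x x'^\top}.
#' * `"periodic"` —
#'   \eqn{k(x,x') = \sigma_f^2 \exp(-2 \sin^2(\pi |x-x'| / p) / l^2)}.
#' * `"constant"` — \eqn{k(x,x') = \sigma_f^2} everywhere. This is the null
#'   model covariance (a GP with infinite lengthscale); it is kept as an
#'   explicit family for numerical stability.
#'
#' @param family One of `"rbf"`, `"linear"`, `"periodic"`, `"constant"`.
#' @param lengthscale Positive lengthscale `l`, in input units (rbf,
#'   periodic).
#' @param variance Amplitude \eqn{\sigma_f^2 \ge 0} (all families).
#' @param period Positive period `p`, in input units (periodic only).
#' @return An object of class `"kernel_spec"`.
#' @examples
#' ks <- kernel_spec("rbf", lengthscale = 0.3, variance = 2)
#' eval_kernel(ks, c(0, 0.3))
#' @export
kernel_spec <- function(family = c("rbf", "linear", "periodic", "constant"),
                        lengthscale = 1, variance = 1, period = 1) {
  family <- match.arg(family)
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0) {
    stop("'lengthscale' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance < 0) {
    stop("'variance' must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L ||
      !is.finite(period) || period <= 0) {
    stop("'period' must be a single positive number", call. = FALSE)
  }
  structure(
    list(family = family, lengthscale = lengthscale,
         variance = variance, period = period),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> family:", x$family,
      " variance:", format(x$variance, digits = 4), sep = "")
  if (x$family %in% c("rbf", "periodic")) {
    cat("  lengthscale:", format(x$lengthscale, digits = 4))
  }
  if (x$family == "periodic") cat("  period:", format(x$period, digits = 4))
  cat("\n")
  invisible(x)
}

# Coerce coordinates to an n x d matrix (1-D vectors become n x 1).
as_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("coordinates must be finite", call. = FALSE)
  x
}

# Squared Euclidean cross-distances between rows of X (n x d) and X2 (m x d).
sq_dist <- function(X, X2) {
  n2x <- rowSums(X^2)
  n2y <- rowSums(X2^2)
  d2 <- outer(n2x, n2y, "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  d2
}

#' Evaluate a kernel as a covariance matrix
#'
#' Evaluates the covariance function at all pairs of locations, returning an
#' `|X| x |X2|` matrix. Locations may be 1-D (numeric vector or one-column
#' matrix) or 2-D (two-column matrix); `X` and `X2` must share the same
#' dimensionality.
#'
#' @param spec A [kernel_spec()].
#' @param X,X2 Coordinate sets; `X2` defaults to `X`.
#' @return Covariance matrix of dimension `nrow(X) x nrow(X2)`.
#' @export
eval_kernel <- function(spec, X, X2 = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as_coord_matrix(X)
  X2 <- as_coord_matrix(X2)
  if (ncol(X) != ncol(X2)) {
    stop("dimension mismatch: X has ", ncol(X), " column(s), X2 has ",
         ncol(X2), call. = FALSE)
  }
  sf2 <- spec$variance
  K <- switch(spec$family,
    rbf = sf2 * exp(-sq_dist(X, X2) / (2 * spec$lengthscale^2)),
    linear = sf2 * tcrossprod(X, X2),
    periodic = {
      if (ncol(X) != 1L) {
        stop("periodic kernel is defined on 1-D inputs only", call. = FALSE)
      }
      d <- abs(outer(drop(X), drop(X2), "-"))
      sf2 * exp(-2 * sin(pi * d / spec$period)^2 / spec$lengthscale^2)
    },
    constant = matrix(sf2, nrow(X), nrow(X2))
  )
  unname(K)
}

# Cholesky with escalating relative jitter (1e-6 * amplitude scale, x10 up
# to 1e-2). Returns the lower-triangular factor; errors only after the
# escalation ladder is exhausted.
chol_jitter <- function(K, scale = NULL, jitter0 = 1e-6, jitter_max = 1e-2) {
  n <- nrow(K)
  if (is.null(scale)) scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- jitter0
  repeat {
    L <- tryCatch(t(chol(K + diag(jit * scale, n))), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- jit * scale
      return(L)
    }
    jit <- max(jit * 10, 1e-10)
    if (jit > jitter_max * 1.0001) {
      stop("Cholesky factorization failed after jitter escalation",
           call. = FALSE)
    }
  }
}
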