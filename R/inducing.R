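#' Select inducing-point locations
#'
#' Chooses `M` locations summarising the data coordinates for sparse
#' variational inference. `"mdpp"` greedily maximises the determinant of
#' the kernel submatrix (greedy MAP of an M-determinantal point process,
#' via pivoted Cholesky on the kernel matrix), stopping early if the
#' determinant increment falls below `eps`; ties are broken by lowest
#' index. `"kmeans"` returns cluster centres. `M = N` returns the input
#' locations unchanged for either method.
#'
#' @param coords Coordinates (vector or matrix, one row per sample).
#' @param M Number of inducing points, `1 <= M <= N`.
#' @param method `"mdpp"` or `"kmeans"`.
#' @param kernel Kernel used for the determinantal criterion.
#' @param eps Determinant-increment stopping tolerance.
#' @return A matrix of `M` (or fewer, if the increment tolerance triggers)
#'   coordinate rows.
#' @export
select_inducing_points <- function(coords, M,
                                   method = c("mdpp", "kmeans"),
                                   kernel = kernel_spec("rbf"),
                                   eps = 1e-12) {
  method <- match.arg(method)
  X <- as_coord_matrix(coords)
  n <- nrow(X)
  if (M < 1 || M > n) stop("'M' must satisfy 1 <= M <= N", call. = FALSE)
  if (M == n) return(X)
  if (method == "kmeans") {
    km <- stats::kmeans(X, centers = M, nstart = 3, iter.max = 100)
    return(unname(as.matrix(km$centers)))
  }
  K <- eval_kernel(kernel, X)
  d <- diag(K)
  chosen <- integer(0)
  Cc <- matrix(0, n, 0)
  for (step in seq_len(M)) {
    j <- which.max(d)               # ties -> lowest index
    if (d[j] < eps * max(kernel$variance, 1e-300)) break
    cnew <- if (ncol(Cc) == 0) K[, j] else K[, j] - Cc %*% Cc[j, ]
    cnew <- drop(cnew) / sqrt(d[j])
    Cc <- cbind(Cc, cnew)
    chosen <- c(chosen, j)
    d <- pmax(d - cnew^2, 0)
    d[chosen] <- -Inf
  }
  X[chosen, , drop = FALSE]
}
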