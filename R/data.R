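#' Counts dataset with per-sample coordinates
#'
#' Bundles a genes-by-samples matrix of nonnegative integer counts with the
#' per-sample covariate needed for GP regression: a 1-D time/pseudotime
#' coordinate or 2-D spatial coordinates, optional condition/lineage
#' labels, and optional positive per-sample scale factors.
#'
#' @param counts Matrix (genes in rows, samples in columns) of nonnegative
#'   integers; row names identify genes.
#' @param coords Numeric vector (1-D) or 2-column matrix/data frame (2-D),
#'   one entry/row per sample.
#' @param labels Optional per-sample condition or lineage labels.
#' @param scale_factors Optional positive per-sample multipliers `k_i` on
#'   the count mean: either one vector shared by all genes or a
#'   genes-by-samples matrix (per-gene normalization).
#' @return An object of class `"counts_dataset"`.
#' @export
counts_dataset <- function(counts, coords, labels = NULL,
                           scale_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  }
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be nonnegative integers; first offender: gene '",
         rownames(counts)[bad[1, 1]], "', sample ",
         if (!is.null(colnames(counts))) {
           paste0("'", colnames(counts)[bad[1, 2]], "'")
         } else bad[1, 2],
         call. = FALSE)
  }
  storage.mode(counts) <- "double"
  X <- as_coord_matrix(if (is.data.frame(coords)) as.matrix(coords) else
    coords)
  if (nrow(X) != ncol(counts)) {
    stop("coords must have one row per sample (", ncol(counts), ")",
         call. = FALSE)
  }
  if (!ncol(X) %in% c(1L, 2L)) {
    stop("coords must be 1-D or 2-D", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != ncol(counts)) {
    stop("labels must match the sample count", call. = FALSE)
  }
  if (!is.null(scale_factors)) {
    ok_dim <- if (is.matrix(scale_factors)) {
      all(dim(scale_factors) == dim(counts))
    } else length(scale_factors) == ncol(counts)
    if (!ok_dim || any(scale_factors <= 0) ||
        any(!is.finite(scale_factors))) {
      stop("scale_factors must be positive and match the sample count",
           call. = FALSE)
    }
  }
  structure(list(counts = counts, coords = X, labels = labels,
                 scale_factors = scale_factors),
            class = "counts_dataset")
}

#' @export
print.counts_dataset <- function(x, ...) {
  cat("<counts_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples, ", ncol(x$coords), "-D coordinates", sep = "")
  if (!is.null(x$labels)) {
    cat(", labels: ", paste(unique(x$labels), collapse = "/"), sep = "")
  }
  if (!is.null(x$scale_factors)) cat(", scale factors present")
  cat("\n")
  invisible(x)
}

#' @export
dim.counts_dataset <- function(x) dim(x$counts)

# Subset a dataset by gene and/or sample index.
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(ds$counts))
  if (is.null(samples)) samples <- seq_len(ncol(ds$counts))
  sf <- ds$scale_factors
  if (!is.null(sf)) {
    sf <- if (is.matrix(sf)) sf[genes, samples, drop = FALSE] else {
      sf[samples]
    }
  }
  counts_dataset(ds$counts[genes, samples, drop = FALSE],
                 ds$coords[samples, , drop = FALSE],
                 labels = ds$labels[samples],
                 scale_factors = sf)
}

# Per-gene scale-factor row (or the shared vector, or NULL).
sf_row <- function(ds, g) {
  sf <- ds$scale_factors
  if (is.null(sf)) return(NULL)
  if (is.matrix(sf)) sf[g, ] else sf
}
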