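#' Read a counts matrix with its coordinate table
#'
#' Reads a genes-by-samples counts matrix from delimited text or a
#' matrix-market triplet file and attaches per-sample coordinates.
#' Coordinates come either from a separate delimited table (first column
#' sample id, then `x` and optionally `y`), matched to the counts by
#' sample id, or — for the spatial-transcriptomics export dialect — from
#' column headers of the form `"12.5_3.2"` (`coords = "header"`).
#'
#' Counts are validated to be nonnegative integers; violations and
#' unmatched sample ids are hard errors naming the offenders.
#'
#' @param path Counts file. For `format = "matrix_market"` the row/column
#'   names are read from `<stem>_genes.txt` / `<stem>_samples.txt` next
#'   to the `.mtx` file when present.
#' @param coords Path of the coordinate table, or `"header"`.
#' @param format `"auto"` (by extension), `"delimited"` or
#'   `"matrix_market"`.
#' @param sep Field separator for delimited input.
#' @return A [counts_dataset()].
#' @export
read_counts <- function(path, coords = NULL,
                        format = c("auto", "delimited", "matrix_market"),
                        sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "matrix_market" else "delimited"
  }
  if (format == "matrix_market") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    gf <- paste0(stem, "_genes.txt")
    sf <- paste0(stem, "_samples.txt")
    rownames(m) <- if (file.exists(gf)) readLines(gf) else {
      paste0("gene_", seq_len(nrow(m)))
    }
    colnames(m) <- if (file.exists(sf)) readLines(sf) else {
      paste0("s", seq_len(ncol(m)))
    }
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  if (!is.numeric(m)) stop("counts are not numeric", call. = FALSE)
  bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative counts, e.g. gene '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]],
         "' (", nrow(bad), " offending entries)", call. = FALSE)
  }

  if (is.null(coords)) {
    stop("a coordinate table (or coords = \"header\") is required",
         call. = FALSE)
  }
  if (identical(coords, "header")) {
    parts <- strsplit(colnames(m), "_", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("column headers are not in the 'x_y' coordinate dialect",
           call. = FALSE)
    }
    X <- do.call(rbind, lapply(parts, as.numeric))
    if (any(!is.finite(X))) {
      stop("could not parse coordinates from headers", call. = FALSE)
    }
    colnames(X) <- c("x", "y")
  } else {
    ct <- utils::read.table(coords, header = TRUE, sep = sep,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(ct[[1]])
    missing_ids <- setdiff(colnames(m), ids)
    if (length(missing_ids) > 0) {
      stop("samples absent from the coordinate table: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) ", ...", call. = FALSE)
    }
    ct <- ct[match(colnames(m), ids), , drop = FALSE]
    num_cols <- intersect(c("x", "y"), colnames(ct))
    if (length(num_cols) == 0) {
      num_cols <- colnames(ct)[vapply(ct, is.numeric, logical(1))]
    }
    X <- as.matrix(ct[, num_cols, drop = FALSE])
  }
  labels <- NULL
  if (!identical(coords, "header") && "label" %in% colnames(ct)) {
    labels <- as.character(ct$label)
  }
  counts_dataset(m, X, labels = labels)
}

#' Write a counts dataset to disk
#'
#' Writes the counts as delimited text or matrix-market triplets (with
#' `<stem>_genes.txt` / `<stem>_samples.txt` sidecars) plus a coordinate
#' table `<stem>_coords.tsv`.
#'
#' @param dataset A [counts_dataset()].
#' @param path Output counts path (`.tsv` or `.mtx`).
#' @param format `"delimited"` or `"matrix_market"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(dataset, path,
                         format = c("delimited", "matrix_market")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "counts_dataset"))
  if (format == "matrix_market") {
    Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(dataset$counts), paste0(stem, "_genes.txt"))
    writeLines(colnames(dataset$counts), paste0(stem, "_samples.txt"))
    coord_path <- paste0(stem, "_coords.tsv")
  } else {
    utils::write.table(dataset$counts, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    coord_path <- paste0(sub("\\.[a-z]+$", "", path), "_coords.tsv")
  }
  cd <- data.frame(id = colnames(dataset$counts), dataset$coords)
  colnames(cd) <- c("id", c("x", "y")[seq_len(ncol(dataset$coords))])
  if (!is.null(dataset$labels)) cd$label <- dataset$labels
  utils::write.table(cd, coord_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
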