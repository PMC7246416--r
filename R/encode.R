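#' Fit quantile bin edges for one-hot encoding
#'
#' Learns, per feature, interior cut points at the empirical quantiles
#' `j/n_bins` of the training rows. Duplicate edges (heavy ties, constant
#' features) are collapsed, so a constant feature ends up with a single bin.
#' Quantile rather than equal-width edges keep the one-hot columns roughly
#' balanced, which is what gives the factorization machine usable support
#' per latent row. Fit on training rows only, then encode train and test
#' with the same `bin_spec`.
#'
#' @param features Numeric matrix (rows x features) or data frame of
#'   training feature rows.
#' @param n_bins Target bins per feature (default 10).
#' @return A `bin_spec`: list with `edges` (list of increasing interior edge
#'   vectors, possibly empty), `feature_names`, `n_bins_per_feature`,
#'   `field_offsets` (0-based column offset of each feature's field) and
#'   `n_cols`.
#' @export
#' @examples
#' bs <- fit_bins(matrix(runif(200), 50, 4), n_bins = 5)
#' bs$n_cols
fit_bins <- function(features, n_bins = 10) {
  x <- as.matrix(features)
  if (nrow(x) < 1L || n_bins < 1L) stop("need rows >= 1 and n_bins >= 1", call. = FALSE)
  nas <- which(colSums(is.na(x)) > 0)
  if (length(nas) > 0L) {
    stop(sprintf("feature %d contains NaN/NA values", nas[1]), call. = FALSE)
  }
  edges <- lapply(seq_len(ncol(x)), function(j) {
    if (n_bins == 1L) return(numeric(0))
    q <- stats::quantile(x[, j], probs = seq_len(n_bins - 1) / n_bins,
                         names = FALSE, type = 7)
    unique(q[is.finite(q)])
  })
  # collapse degenerate (constant-feature) edge lists to zero edges
  edges <- lapply(seq_along(edges), function(j) {
    e <- edges[[j]]
    if (length(e) > 0 && min(x[, j]) == max(x[, j])) numeric(0) else e
  })
  n_per <- vapply(edges, length, integer(1)) + 1L
  structure(list(
    edges = edges,
    feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
    n_bins_per_feature = n_per,
    field_offsets = c(0L, cumsum(n_per))[seq_len(ncol(x))],
    n_cols = sum(n_per)
  ), class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("<bin_spec> %d features -> %d one-hot columns (bins per feature: %s)\n",
              length(x$edges), x$n_cols,
              paste(range(x$n_bins_per_feature), collapse = "-")))
  invisible(x)
}

#' One-hot encode features against fitted bins
#'
#' Each value activates exactly one column of its feature's field: the bin
#' whose half-open interval `[edge_{j-1}, edge_j)` contains it. A value equal
#' to an interior edge therefore lands in the higher bin; values below the
#' first edge go to the first bin and values at or above the last edge clip
#' to the last bin, so out-of-range test values never error. The result is
#' the sparse design matrix the factorization machine consumes: exactly one
#' 1 per feature per row, everything else 0.
#'
#' @param features Numeric matrix (rows x features) with the same feature
#'   count/order as used in [fit_bins()].
#' @param bins A `bin_spec` from [fit_bins()].
#' @return A `sparse_design`: list with `active` (rows x features integer
#'   matrix of active 1-based column indices), `n_rows`, `n_cols`,
#'   `field_offsets`, `feature_names`.
#' @export
one_hot_encode <- function(features, bins) {
  stopifnot(inherits(bins, "bin_spec"))
  x <- as.matrix(features)
  if (ncol(x) != length(bins$edges)) {
    stop(sprintf("feature count mismatch: got %d, bin_spec has %d",
                 ncol(x), length(bins$edges)), call. = FALSE)
  }
  active <- matrix(0L, nrow = nrow(x), ncol = ncol(x))
  for (j in seq_len(ncol(x))) {
    e <- bins$edges[[j]]
    # bin index: 1 + number of edges <= value, clipped to the field size
    b <- findInterval(x[, j], e, left.open = FALSE) + 1L
    b <- pmin(b, bins$n_bins_per_feature[j])
    active[, j] <- bins$field_offsets[j] + b
  }
  structure(list(
    active = active, n_rows = nrow(x), n_cols = bins$n_cols,
    field_offsets = bins$field_offsets, feature_names = bins$feature_names
  ), class = "sparse_design")
}

#' @export
print.sparse_design <- function(x, ...) {
  cat(sprintf("<sparse_design> %d rows x %d columns, %d active per row (density %.3f)\n",
              x$n_rows, x$n_cols, ncol(x$active), ncol(x$active) / x$n_cols))
  invisible(x)
}

#' Convert a sparse design to a Matrix::sparseMatrix
#'
#' @param design A `sparse_design`.
#' @return A `dgCMatrix` of 0/1 values.
#' @export
as_sparse_matrix <- function(design) {
  stopifnot(inherits(design, "sparse_design"))
  Matrix::sparseMatrix(
    i = rep(seq_len(design$n_rows), times = ncol(design$active)),
    j = as.vector(design$active),
    x = 1,
    dims = c(design$n_rows, design$n_cols)
  )
}

#' Serialize / restore a bin_spec as JSON
#'
#' Makes train-time binning reproducible byte-for-byte at test/deploy time.
#'
#' @param bins A `bin_spec`.
#' @param path File path to write to / read from.
#' @return `write_bin_spec()` returns `path` invisibly; `read_bin_spec()`
#'   returns the restored `bin_spec`.
#' @export
write_bin_spec <- function(bins, path) {
  stopifnot(inherits(bins, "bin_spec"))
  jsonlite::write_json(
    list(edges = bins$edges, feature_names = bins$feature_names),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_bin_spec
#' @export
read_bin_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  edges <- lapply(raw$edges, function(e) as.numeric(unlist(e)))
  n_per <- vapply(edges, length, integer(1)) + 1L
  structure(list(
    edges = edges,
    feature_names = as.character(unlist(raw$feature_names)),
    n_bins_per_feature = n_per,
    field_offsets = c(0L, cumsum(n_per))[seq_along(edges)],
    n_cols = sum(n_per)
  ), class = "bin_spec")
}
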