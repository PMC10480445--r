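#' Cells-by-features count container
#'
#' A `FeatureMatrix` wraps a sparse cells x features matrix together with its
#' cell and feature names and a tag saying whether the features are genes or
#' peaks.  Raw matrices hold non-negative integer counts; normalized matrices
#' (e.g. after [tfidf_transform()]) carry `normalized = TRUE` and may hold
#' reals.
#'
#' @param values matrix-like, cells in rows, features in columns.  Coerced to
#'   a sparse `dgCMatrix`.
#' @param cell_ids character vector, one unique id per row.  Defaults to the
#'   rownames of `values`.
#' @param feature_ids character vector, one unique id per column.  Defaults to
#'   the colnames of `values`.
#' @param kind `"gene"` or `"peak"`.
#' @param normalized logical; `FALSE` for raw counts (enforced integer-valued
#'   and non-negative).
#' @return An object of class `FeatureMatrix`: a list with elements `values`
#'   (dgCMatrix with dimnames), `kind` and `normalized`.
#' @examples
#' m <- FeatureMatrix(matrix(0:5, nrow = 2,
#'                    dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' dim(m)
#' @export
FeatureMatrix <- function(values, cell_ids = rownames(values),
                          feature_ids = colnames(values),
                          kind = c("gene", "peak"), normalized = FALSE) {
  kind <- match.arg(kind)
  values <- methods::as(methods::as(methods::as(
    Matrix::Matrix(values, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (is.null(cell_ids) || is.null(feature_ids))
    stop("cell and feature ids are required (set dimnames or pass them)")
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values))
    stop(sprintf("%d cell ids for %d matrix rows", length(cell_ids),
                 nrow(values)))
  if (length(feature_ids) != ncol(values))
    stop(sprintf("%d feature ids for %d matrix columns", length(feature_ids),
                 ncol(values)))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3],
               collapse = ", "))
  x <- values@x
  if (length(x) && min(x) < 0) stop("matrix contains negative values")
  if (!normalized && length(x) && any(x != round(x)))
    stop("raw count matrix contains non-integer values")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "FeatureMatrix")
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

#' @export
dimnames.FeatureMatrix <- function(x) dimnames(x$values)

#' Cell ids of a FeatureMatrix
#' @param x a `FeatureMatrix`.
#' @return character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x$values)

#' Feature ids of a FeatureMatrix
#' @param x a `FeatureMatrix`.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(x) colnames(x$values)

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d cells x %d %ss (%s)\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Subset a FeatureMatrix
#'
#' @param x a `FeatureMatrix`.
#' @param i cell selector (names, indices or logical).
#' @param j feature selector.
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @return the subset `FeatureMatrix`.
#' @export
`[.FeatureMatrix` <- function(x, i, j, ..., drop = FALSE) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  FeatureMatrix(v, kind = x$kind, normalized = x$normalized)
}
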