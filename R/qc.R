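#' Hormone-based doublet calling
#'
#' An islet STAMP (bead-cell capture) is called a doublet when it is "high"
#' for two or more hormone genes.  For each hormone the positive population
#' is the set of cells with a nonzero count; a cell is high when its count
#' exceeds `frac` times the median count of that positive population.
#'
#' @param rna raw-count [FeatureMatrix()] of kind gene.
#' @param hormone_genes hormone gene names; all must be present in the
#'   matrix.  Defaults to the four main islet hormones.
#' @param frac fraction of the positive-population median that defines
#'   "highly expressed" (default 0.10).
#' @param positive `"nonzero"` (default) defines the positive population as
#'   cells with nonzero counts; `"typed"` restricts it to cells of the types
#'   in `cell_types` expected to express the hormone (sensitivity option;
#'   requires `cell_types` and `type_hormone`).
#' @param cell_types,type_hormone optional named vectors used only with
#'   `positive = "typed"`: cell -> type and type -> hormone.
#' @return data.frame with cell_id, high_hormones (comma-joined), n_high and
#'   is_doublet.
#' @export
hormone_doublet_filter <- function(rna, hormone_genes = c("INS", "GCG",
                                                          "SST", "PPY"),
                                   frac = 0.10,
                                   positive = c("nonzero", "typed"),
                                   cell_types = NULL, type_hormone = NULL) {
  positive <- match.arg(positive)
  missing_h <- setdiff(hormone_genes, feature_ids(rna))
  if (length(missing_h))
    stop("hormone gene(s) absent from matrix: ",
         paste(missing_h, collapse = ", "))
  counts <- as.matrix(rna$values[, hormone_genes, drop = FALSE])
  high <- matrix(FALSE, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  for (h in hormone_genes) {
    x <- counts[, h]
    pos <- if (positive == "nonzero") x > 0 else {
      types_h <- names(type_hormone)[type_hormone == h]
      cell_types[rownames(counts)] %in% types_h & x > 0
    }
    if (!any(pos)) {
      warning("no positive cells for hormone ", h,
              "; it contributes no high calls")
      next
    }
    high[, h] <- x > frac * stats::median(x[pos])
  }
  n_high <- rowSums(high)
  data.frame(
    cell_id = rownames(counts),
    high_hormones = apply(high, 1, function(z)
      paste(hormone_genes[z], collapse = ",")),
    n_high = n_high,
    is_doublet = n_high >= 2,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Post-clustering hormone consistency filter
#'
#' After cell typing, flags endocrine cells carrying more than `max_off`
#' transcripts of a hormone that their assigned type is not expected to
#' express (strictly greater than, so a count equal to `max_off` passes).
#' Cells without a type, or whose type has no hormone mapping, pass and are
#' treated as non-endocrine.
#'
#' @param rna raw-count [FeatureMatrix()].
#' @param cell_types named character vector mapping cell id -> type.
#' @param type_hormone named character vector mapping type -> its expected
#'   hormone gene (e.g. `c(beta = "INS", alpha = "GCG")`).
#' @param max_off transcript threshold for an off-type hormone (default 15).
#' @return character vector of flagged cell ids.
#' @export
hormone_consistency_filter <- function(rna, cell_types, type_hormone,
                                       max_off = 15) {
  hormones <- unique(unname(type_hormone))
  missing_h <- setdiff(hormones, feature_ids(rna))
  if (length(missing_h))
    stop("hormone gene(s) absent from matrix: ",
         paste(missing_h, collapse = ", "))
  cells <- intersect(cell_ids(rna), names(cell_types))
  counts <- as.matrix(rna$values[cells, hormones, drop = FALSE])
  types <- cell_types[cells]
  endocrine <- types %in% names(type_hormone)
  if (any(!endocrine))
    message(sum(!endocrine), " cell(s) of unmapped type treated as ",
            "non-endocrine (pass)")
  expected <- type_hormone[types]           # NA for non-endocrine
  off <- counts > max_off
  for (h in hormones) off[expected == h | is.na(expected), h] <- FALSE
  flagged <- cells[endocrine & rowSums(off) > 0]
  flagged
}

#' snATAC cell-level QC on fraction of reads in peaks
#'
#' A nucleus passes when its fraction of reads falling in peaks exceeds
#' `min_frac` and its total read count exceeds `min_reads`; both thresholds
#' are strict.
#'
#' @param reads_in_peaks,total_reads non-negative integer vectors (named by
#'   cell id, or use `cell_id`).
#' @param cell_id optional cell ids; defaults to names of `total_reads`.
#' @param min_frac fraction-in-peaks threshold (default 0.15, strict).
#' @param min_reads total-read threshold (default 1500, strict).
#' @return data.frame with cell_id, reads_in_peaks, total_reads,
#'   frac_in_peaks, passes.
#' @export
atac_cell_qc <- function(reads_in_peaks, total_reads,
                         cell_id = names(total_reads), min_frac = 0.15,
                         min_reads = 1500) {
  if (length(reads_in_peaks) != length(total_reads))
    stop("reads_in_peaks and total_reads differ in length")
  if (any(reads_in_peaks < 0) || any(total_reads < 0))
    stop("read counts must be non-negative")
  if (any(reads_in_peaks > total_reads))
    stop("reads_in_peaks exceeds total_reads for ",
         sum(reads_in_peaks > total_reads), " cell(s)")
  if (is.null(cell_id)) cell_id <- paste0("cell", seq_along(total_reads))
  frac <- ifelse(total_reads > 0, reads_in_peaks / total_reads, 0)
  data.frame(cell_id = cell_id, reads_in_peaks = reads_in_peaks,
             total_reads = total_reads, frac_in_peaks = frac,
             passes = frac > min_frac & total_reads > min_reads,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted-KNN unambiguity score for cross-modality doublet filtering
#'
#' For every query cell, its `k` nearest reference cells in the co-embedding
#' are grouped by reference cell type; the unambiguity score is the ratio of
#' the mean distance to the second-nearest type over the mean distance to
#' the nearest type (>= 1; larger means less ambiguous).  Cells whose
#' neighbours are all one type get score `Inf`.  A cell passes when its
#' score is at least `cutoff`; ambiguous cells (low score) are the potential
#' doublets.
#'
#' @param embedding numeric matrix of coordinates with rownames, containing
#'   both reference and query cells (e.g. the L2-normalized CCA space), or an
#'   object returned by the embedding functions.
#' @param labeled_reference named character vector: reference cell -> type
#'   (at least two types).
#' @param query_cells character vector of query cell ids.
#' @param k neighbours to use (default 20).
#' @param cutoff score cutoff (default 10).
#' @return data.frame with cell_id, nearest_type, second_type, score,
#'   passes.
#' @export
knn_unambiguity_filter <- function(embedding, labeled_reference, query_cells,
                                   k = 20, cutoff = 10) {
  coords <- embedding_coords(embedding)
  ref <- names(labeled_reference)
  if (length(unique(labeled_reference)) < 2)
    stop("reference must contain at least 2 cell types")
  if (!all(ref %in% rownames(coords)))
    stop("reference cell(s) absent from embedding")
  if (!all(query_cells %in% rownames(coords)))
    stop("query cell(s) absent from embedding")
  if (k > length(ref))
    stop(sprintf("k = %d exceeds reference size %d", k, length(ref)))
  rx <- coords[ref, , drop = FALSE]
  qx <- coords[query_cells, , drop = FALSE]
  # squared Euclidean distances query x reference
  d2 <- outer(rowSums(qx^2), rowSums(rx^2), `+`) - 2 * tcrossprod(qx, rx)
  d2[d2 < 0] <- 0
  out <- lapply(seq_along(query_cells), function(i) {
    d <- sqrt(d2[i, ])
    self <- which(ref == query_cells[i])
    if (length(self)) d <- d[-self]
    types <- labeled_reference[if (length(self)) ref[-self] else ref]
    nn <- order(d)[seq_len(min(k, length(d)))]
    md <- tapply(d[nn], types[nn], mean)
    md <- md[order(md, names(md))]   # ties broken by type name order
    if (length(md) == 1L)
      data.frame(cell_id = query_cells[i], nearest_type = names(md)[1],
                 second_type = NA_character_, score = Inf,
                 stringsAsFactors = FALSE)
    else
      data.frame(cell_id = query_cells[i], nearest_type = names(md)[1],
                 second_type = names(md)[2],
                 score = if (md[[1]] == 0) Inf else md[[2]] / md[[1]],
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$passes <- out$score >= cutoff
  out
}
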