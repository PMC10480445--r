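#' Read a cells-by-features count matrix
#'
#' Reads either a MatrixMarket coordinate file (1-based indices, converted to
#' R indexing exactly once here) or a dense TSV, together with line-per-entry
#' name files for cells (rows) and features (columns).
#'
#' @param path_matrix path to the `.mtx` (MatrixMarket coordinate) or dense
#'   TSV file.  Files ending in `.mtx` are treated as MatrixMarket.
#' @param path_cells path to a headerless text file, one cell id per line.
#' @param path_features path to a headerless text file, one feature id per
#'   line.
#' @param kind `"gene"` or `"peak"`.
#' @return a [FeatureMatrix()].
#' @export
read_feature_matrix <- function(path_matrix, path_cells, path_features,
                                kind = c("gene", "peak")) {
  kind <- match.arg(kind)
  cells <- readLines(path_cells)
  feats <- readLines(path_features)
  if (grepl("\\.mtx$", path_matrix)) {
    m <- Matrix::readMM(path_matrix)
  } else {
    m <- as.matrix(utils::read.table(path_matrix, sep = "\t", header = FALSE))
  }
  if (nrow(m) != length(cells))
    stop(sprintf("matrix has %d rows but cells file has %d names", nrow(m),
                 length(cells)))
  if (ncol(m) != length(feats))
    stop(sprintf("matrix has %d columns but features file has %d names",
                 ncol(m), length(feats)))
  FeatureMatrix(m, cell_ids = cells, feature_ids = feats, kind = kind)
}

#' Write a FeatureMatrix as MatrixMarket + name files
#'
#' @param x a [FeatureMatrix()].
#' @param path_matrix,path_cells,path_features output paths; see
#'   [read_feature_matrix()].
#' @return invisibly, `x`.
#' @export
write_feature_matrix <- function(x, path_matrix, path_cells, path_features) {
  Matrix::writeMM(x$values, path_matrix)
  writeLines(cell_ids(x), path_cells)
  writeLines(feature_ids(x), path_features)
  invisible(x)
}

#' Read cell metadata
#'
#' Expects a TSV with header and columns `cell_id`, `donor_id`, `phenotype`
#' and optionally `cell_type`.  Phenotype labels are accepted
#' case-insensitively from healthy / T2D / disease and normalized to
#' healthy / disease.
#'
#' @param path TSV path.
#' @return a data.frame with columns cell_id, donor_id, phenotype (factor
#'   levels healthy, disease) and cell_type (NA when absent).
#' @export
read_cells <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("cell_id", "donor_id", "phenotype")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cell table missing columns: ",
                         paste(miss, collapse = ", "))
  d$phenotype <- normalize_phenotype(d$phenotype)
  if (anyDuplicated(d$cell_id)) stop("duplicate cell_id in cell table")
  if (is.null(d$cell_type)) d$cell_type <- NA_character_
  d[, c("cell_id", "donor_id", "phenotype", "cell_type")]
}

normalize_phenotype <- function(x) {
  lx <- tolower(as.character(x))
  out <- ifelse(lx == "healthy", "healthy",
         ifelse(lx %in% c("t2d", "disease"), "disease", NA_character_))
  if (anyNA(out))
    stop("unknown phenotype label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (accepted: healthy, T2D, disease)")
  factor(out, levels = c("healthy", "disease"))
}

#' Write a cell metadata table
#' @param cells data.frame as returned by [read_cells()].
#' @param path output TSV path.
#' @return invisibly, `cells`.
#' @export
write_cells <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cells)
}

#' Read genomic intervals from BED
#'
#' BED coordinates are 0-based half-open and are kept that way internally.
#'
#' @param path BED file (>= 3 columns; column 4, when present, supplies ids).
#' @return data.frame with columns chrom, start, end, id.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d$id <- if (ncol(d) >= 4) as.character(d[[4]]) else
    paste0("iv", seq_len(nrow(d)))
  validate_intervals(d[, c("chrom", "start", "end", "id")])
}

validate_intervals <- function(d) {
  if (any(d$start >= d$end))
    stop("interval with start >= end at row(s) ",
         paste(utils::head(which(d$start >= d$end), 3), collapse = ", "))
  if (anyDuplicated(d$id)) stop("duplicate interval ids")
  d
}

#' Write intervals as BED4
#' @param intervals data.frame with chrom, start, end, id.
#' @param path output path.
#' @return invisibly, `intervals`.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(intervals)
}

#' Read chromatin loops from BEDPE
#'
#' Columns 1-6 are the two anchors (0-based half-open); column 7, when
#' present, is a loop id; any remaining numeric columns are per-condition
#' strengths (named from the header when the file has one, otherwise
#' `strength1`, `strength2`, ...).
#'
#' @param path BEDPE path.
#' @param top_k optional; keep only the `top_k` loops with the largest
#'   maximum strength across conditions (rank filter applied at ingestion).
#' @return data.frame with chrom_a, start_a, end_a, chrom_b, start_b, end_b,
#'   loop_id and one column per strength condition.
#' @export
read_bedpe <- function(path, top_k = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^#|^chrom", first)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         comment.char = "", stringsAsFactors = FALSE)
  if (has_header) names(d)[1] <- sub("^#", "", names(d)[1])
  names(d)[1:6] <- c("chrom_a", "start_a", "end_a",
                     "chrom_b", "start_b", "end_b")
  ncol7_id <- ncol(d) >= 7 && !is.numeric(d[[7]])
  d$loop_id <- if (ncol7_id) as.character(d[[7]]) else
    paste0("loop", seq_len(nrow(d)))
  strength_cols <- setdiff(seq_len(ncol(d)), c(1:6, if (ncol7_id) 7L))
  strength_cols <- strength_cols[vapply(d[strength_cols], is.numeric,
                                        logical(1))]
  strengths <- d[strength_cols]
  if (!length(strengths)) stop("BEDPE has no numeric strength column")
  if (!has_header || any(grepl("^V[0-9]+$", names(strengths))))
    names(strengths) <- paste0("strength", seq_along(strengths))
  if (any(d$start_a >= d$end_a | d$start_b >= d$end_b))
    stop("loop anchor with start >= end")
  if (any(d$chrom_a != d$chrom_b))
    stop("trans-chromosomal loop(s) not supported")
  if (any(as.matrix(strengths) < 0)) stop("negative loop strength")
  out <- cbind(d[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                     "end_b", "loop_id")], strengths)
  if (!is.null(top_k) && top_k < nrow(out)) {
    score <- do.call(pmax, strengths)
    out <- out[order(-score)[seq_len(top_k)], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write loops as BEDPE
#' @param loops data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @return invisibly, `loops`.
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(loops)
}

#' Read motif occurrences from a FIMO-style TSV
#'
#' Expects a header with columns `motif_id`, `sequence_name` (the peak id),
#' `start`, `stop`, `score`, `p-value` (or `p_value`).  Hits with p-value
#' above `p_max` are dropped at ingestion; 1e-6 is the conventional cutoff
#' for counting a motif as present in a peak.
#'
#' @param path FIMO TSV path.
#' @param p_max retain hits with `p_value <= p_max`.
#' @return data.frame with motif_id, peak_id, start, stop, score, p_value.
#' @export
read_fimo <- function(path, p_max = 1e-6) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
  pcol <- intersect(c("p-value", "p_value"), names(d))
  if (!length(pcol)) stop("FIMO table lacks a p-value column")
  out <- data.frame(motif_id = as.character(d$motif_id),
                    peak_id = as.character(d$sequence_name),
                    start = d$start, stop = d$stop,
                    score = if (is.null(d$score)) NA_real_ else d$score,
                    p_value = d[[pcol[1]]], stringsAsFactors = FALSE)
  if (any(out$p_value <= 0 | out$p_value > 1))
    stop("FIMO p-values must lie in (0, 1]")
  out[out$p_value <= p_max, , drop = FALSE]
}

#' Write a motif hit table in FIMO layout
#' @param hits data.frame as returned by [read_fimo()].
#' @param path output path.
#' @return invisibly, `hits`.
#' @export
write_fimo <- function(hits, path) {
  d <- data.frame(motif_id = hits$motif_id, sequence_name = hits$peak_id,
                  start = hits$start, stop = hits$stop, strand = "+",
                  score = hits$score, check.names = FALSE)
  d[["p-value"]] <- hits$p_value
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}

#' Read gene sets from GMT
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1])
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  out <- unlist(sets, recursive = FALSE)
  if (any(!lengths(out))) stop("empty gene set in GMT")
  out
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), character(1)), path)
  invisible(sets)
}

#' Read a gene TSS table
#'
#' TSV with header and columns `gene`, `chrom`, `tss` (0-based position) and
#' `strand`.  When several rows share a gene, the 5'-most TSS on the gene's
#' strand is kept.
#'
#' @param path TSV path.
#' @return data.frame with one row per gene.
#' @export
read_tss <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("TSS table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (anyDuplicated(d$gene)) {
    key <- ifelse(d$strand == "+", d$tss, -d$tss)
    d <- d[order(d$gene, key), ]
    d <- d[!duplicated(d$gene), ]
  }
  rownames(d) <- NULL
  d[, need]
}

#' Write a gene TSS table
#' @param tss data.frame with gene, chrom, tss, strand.
#' @param path output path.
#' @return invisibly, `tss`.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tss)
}
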