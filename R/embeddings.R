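#' Embedding container
#'
#' @param coordinates cells x components numeric matrix with cell rownames.
#' @param kind one of `"pca"`, `"lsi"`, `"cca"`.
#' @param component_variance optional per-component variance (singular value
#'   based).
#' @return object of class `Embedding`.
#' @export
Embedding <- function(coordinates, kind = c("pca", "lsi", "cca"),
                      component_variance = NULL) {
  kind <- match.arg(kind)
  coordinates <- as.matrix(coordinates)
  if (is.null(rownames(coordinates))) stop("embedding needs cell rownames")
  if (anyNA(coordinates)) stop("embedding contains missing values")
  if (is.null(colnames(coordinates)))
    colnames(coordinates) <- paste0(toupper(kind), seq_len(ncol(coordinates)))
  structure(list(coordinates = coordinates, kind = kind,
                 n_components = ncol(coordinates),
                 component_variance = component_variance),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding (%s): %d cells x %d components\n", x$kind,
              nrow(x$coordinates), x$n_components))
  invisible(x)
}

embedding_coords <- function(x) {
  if (inherits(x, "Embedding")) x$coordinates else as.matrix(x)
}

#' Depth-normalize, log-transform and scale an RNA count matrix
#'
#' Counts per 10k -> log1p -> per-gene z-score (genes with zero variance map
#' to 0).  This is the normalization feeding [pca_embed()].
#'
#' @param rna raw-count [FeatureMatrix()].
#' @param genes optional gene subset.
#' @param scale_features z-score genes (default TRUE).
#' @return dense cells x genes numeric matrix.
#' @export
normalize_rna <- function(rna, genes = NULL, scale_features = TRUE) {
  m <- rna$values
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  depth <- Matrix::rowSums(rna$values)
  if (any(depth == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(cell_ids(rna)[depth == 0], 3), collapse = ", "))
  x <- log1p(as.matrix(m) / depth * 1e4)
  if (scale_features) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sd, `/`)
  }
  x
}

#' Select informative genes by normalized dispersion
#'
#' Genes are ranked by dispersion (variance/mean of depth-normalized counts)
#' z-scored within 20 equal-frequency mean bins, so highly dispersed genes
#' are picked across the whole expression range.
#'
#' @param rna raw-count [FeatureMatrix()].
#' @param n number of genes to return (default 500).
#' @param n_bins mean bins for dispersion standardization.
#' @return character vector of gene names, ranked.
#' @export
select_informative_genes <- function(rna, n = 500, n_bins = 20) {
  if (n > ncol(rna$values)) {
    warning("n exceeds the gene count; returning all genes")
    n <- ncol(rna$values)
  }
  depth <- Matrix::rowSums(rna$values)
  depth[depth == 0] <- 1
  x <- as.matrix(rna$values) / depth * 1e4
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- min(n_bins, max(1L, ncol(x) %/% 5L))  # keep bins populated
  grp <- as.integer(cut(rank(mu, ties.method = "first"),
                        breaks = n_bins, labels = FALSE))
  z <- disp
  for (g in unique(grp)) {
    i <- grp == g
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  feature_ids(rna)[order(-z, feature_ids(rna))][seq_len(n)]
}

#' PCA embedding of normalized RNA data
#'
#' Truncated SVD of the normalized (CP10k, log1p, z-scored) matrix restricted
#' to the selected genes.  Component signs are fixed by making the
#' largest-magnitude gene loading positive.
#'
#' @param rna raw-count [FeatureMatrix()].
#' @param genes genes to use (e.g. from [select_informative_genes()]);
#'   default all.
#' @param n_components components to keep (default 10).
#' @return an [Embedding()] of kind `"pca"`.
#' @export
pca_embed <- function(rna, genes = NULL, n_components = 10) {
  x <- normalize_rna(rna, genes)
  if (nrow(x) < n_components)
    stop("fewer cells than requested components")
  s <- truncated_svd(x, n_components)
  scores <- s$u %*% diag(s$d, length(s$d))
  fx <- fix_signs(scores, s$v)
  rownames(fx$scores) <- rownames(x)
  Embedding(fx$scores, "pca",
            component_variance = s$d^2 / max(1, nrow(x) - 1))
}

#' TF-IDF normalization of a peak count matrix
#'
#' `entry[c, p] = (count[c, p] / total_c) * log(1 + N / (1 + df_p))` where
#' `N` is the number of cells and `df_p` the number of cells in which peak
#' `p` is open.  The term frequency is depth-invariant; the IDF up-weights
#' rarely open peaks.
#'
#' @param atac raw-count [FeatureMatrix()] of kind peak.
#' @return normalized [FeatureMatrix()].
#' @export
tfidf_transform <- function(atac) {
  m <- atac$values
  depth <- Matrix::rowSums(m)
  if (any(depth == 0))
    stop("cell(s) with zero peak counts (remove in QC first): ",
         paste(utils::head(cell_ids(atac)[depth == 0], 3), collapse = ", "))
  tf <- m / depth
  df <- Matrix::colSums(m > 0)
  idf <- log(1 + nrow(m) / (1 + df))
  out <- tf %*% Matrix::Diagonal(x = idf)
  dimnames(out) <- dimnames(m)
  FeatureMatrix(out, kind = "peak", normalized = TRUE)
}

#' LSI embedding of a TF-IDF matrix
#'
#' Truncated SVD of the TF-IDF matrix (latent semantic indexing).  Component
#' 1 is retained; its correlation with cell depth is reported in the result
#' so users can drop it if it tracks sequencing depth.
#'
#' @param tfidf normalized [FeatureMatrix()] from [tfidf_transform()].
#' @param dims components (default 50; reduced with a warning if above the
#'   matrix rank).
#' @return an [Embedding()] of kind `"lsi"` with extra element
#'   `depth_correlation`.
#' @export
lsi_embed <- function(tfidf, dims = 50) {
  x <- as.matrix(tfidf$values)
  maxdim <- min(dim(x))
  if (dims > maxdim) {
    warning(sprintf("dims = %d exceeds matrix rank bound %d; reduced", dims,
                    maxdim))
    dims <- maxdim
  }
  s <- truncated_svd(x, dims)
  scores <- s$u %*% diag(s$d, length(s$d))
  fx <- fix_signs(scores, s$v)
  rownames(fx$scores) <- rownames(x)
  emb <- Embedding(fx$scores, "lsi",
                   component_variance = s$d^2 / max(1, nrow(x) - 1))
  emb$depth_correlation <- as.numeric(
    stats::cor(rowSums(x), fx$scores[, 1]))
  emb
}

#' Diagonal CCA co-embedding of RNA and ATAC gene-score matrices
#'
#' Both matrices are restricted to shared features and feature-standardized
#' within modality; the SVD of the cross-product between the two cell sets
#' gives the canonical coordinates (RNA cells from the left singular
#' vectors, ATAC cells from the right).  Every output row is L2-normalized.
#'
#' @param rna raw-count gene [FeatureMatrix()].
#' @param atac_genescore gene-score [FeatureMatrix()] for the ATAC cells
#'   (see [atac_gene_scores()]).
#' @param n_cc canonical components (default 20).
#' @return an [Embedding()] of kind `"cca"` covering both cell sets, with a
#'   `modality` element naming each row's source.
#' @export
cca_coembed <- function(rna, atac_genescore, n_cc = 20) {
  shared <- intersect(feature_ids(rna), feature_ids(atac_genescore))
  if (length(shared) < n_cc)
    stop(sprintf("only %d shared features for %d canonical components",
                 length(shared), n_cc))
  std <- function(fm) {
    x <- as.matrix(fm$values[, shared, drop = FALSE])
    x <- log1p(x)
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(x, 2, mu), 2, sd, `/`)
  }
  x <- std(rna)
  y <- std(atac_genescore)
  cc <- truncated_svd(tcrossprod(x, y), n_cc)
  coords <- rbind(cc$u, cc$v)
  rownames(coords) <- c(rownames(x), rownames(y))
  # L2 row normalization
  nrm <- sqrt(rowSums(coords^2))
  nrm[nrm == 0] <- 1
  coords <- coords / nrm
  emb <- Embedding(coords, "cca")
  emb$modality <- stats::setNames(rep(c("rna", "atac"),
                                      c(nrow(x), nrow(y))),
                                  rownames(coords))
  emb
}

#' Gene scores for ATAC cells
#'
#' Sums peak counts over peaks overlapping the gene body plus `upstream`
#' bases upstream of the TSS, producing the gene-level matrix consumed by
#' [cca_coembed()].
#'
#' @param atac raw peak-count [FeatureMatrix()].
#' @param peaks peak intervals (chrom, start, end, id) matching the matrix
#'   feature ids.
#' @param gene_ranges gene-body intervals (chrom, start, end, id, strand).
#' @param upstream bases added upstream of the TSS (default 2000).
#' @return gene [FeatureMatrix()] for the ATAC cells.
#' @export
atac_gene_scores <- function(atac, peaks, gene_ranges, upstream = 2000) {
  g <- gene_ranges
  ext_start <- ifelse(g$strand == "-", g$start, pmax(0, g$start - upstream))
  ext_end <- ifelse(g$strand == "-", g$end + upstream, g$end)
  pk <- peaks[match(feature_ids(atac), peaks$id), ]
  score <- matrix(0, nrow(atac$values), nrow(g),
                  dimnames = list(cell_ids(atac), g$id))
  for (i in seq_len(nrow(g))) {
    hit <- pk$chrom == g$chrom[i] & pk$start < ext_end[i] &
      ext_start[i] < pk$end
    if (any(hit))
      score[, i] <- Matrix::rowSums(atac$values[, hit, drop = FALSE])
  }
  FeatureMatrix(score, kind = "gene")
}

#' SVM label transfer on a co-embedding
#'
#' Trains a radial-kernel SVM (cost 10) on a stratified half of the labeled
#' reference cells, reports accuracy on the held-out half, and predicts
#' types for the query cells.
#'
#' @param embedding an [Embedding()] or coordinate matrix containing
#'   reference and query cells.
#' @param labels named character vector: reference cell -> type (>= 2
#'   classes, each with >= 2 cells).
#' @param query character vector of query cell ids.
#' @param train_fraction fraction of labeled cells used for training
#'   (default 0.5).
#' @param cost SVM cost parameter (default 10).
#' @param seed RNG seed for the stratified split.
#' @return list with `predicted_type` (named character vector over `query`),
#'   `validation_accuracy`, `train_fraction` and the fitted `model`.
#' @export
svm_label_transfer <- function(embedding, labels, query,
                               train_fraction = 0.5, cost = 10, seed = 1L) {
  coords <- embedding_coords(embedding)
  ref <- names(labels)
  if (!all(ref %in% rownames(coords)))
    stop("labeled cell(s) absent from embedding")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 2))
    stop("class(es) with a single member: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         "; merge or drop them")
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(ref), labels), function(i) {
      n_tr <- max(1L, round(length(i) * train_fraction))
      sample(i, n_tr)
    }), use.names = FALSE)
  })
  train <- ref[train_idx]
  heldout <- setdiff(ref, train)
  y <- factor(labels)
  fit <- e1071::svm(x = coords[train, , drop = FALSE],
                    y = y[match(train, ref)], kernel = "radial", cost = cost)
  acc <- if (length(heldout)) {
    pred_h <- stats::predict(fit, coords[heldout, , drop = FALSE])
    mean(as.character(pred_h) == labels[heldout])
  } else NA_real_
  pred_q <- stats::predict(fit, coords[query, , drop = FALSE])
  list(predicted_type = stats::setNames(as.character(pred_q), query),
       validation_accuracy = acc, train_fraction = train_fraction,
       model = fit)
}

#' Write an embedding as TSV
#' @param embedding an [Embedding()].
#' @param path output path.
#' @return invisibly, the embedding.
#' @export
write_embedding <- function(embedding, path) {
  d <- data.frame(cell_id = rownames(embedding$coordinates),
                  embedding$coordinates, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(embedding)
}
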