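# interval arithmetic on 0-based half-open coordinates ---------------------

# distance from intervals [start, end) to points; 0 when the point is inside
point_interval_distance <- function(start, end, point) {
  pmax(start - point, point - end, 0)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Pseudo-bulk RPKM by cell type
#'
#' Aggregates single-cell counts within each cell type and normalizes by
#' feature length (kb) and per-type depth (millions):
#' `RPKM[f, t] = 1e9 * counts[f, t] / (length_f * total_counts_t)`.
#'
#' @param matrix a raw-count [FeatureMatrix()].
#' @param cell_types named character vector, cell -> type, covering every
#'   cell of the matrix.
#' @param feature_lengths named numeric vector of feature lengths in bp; for
#'   peaks this is `end - start`.  If NULL, a counts-per-million fallback is
#'   used (all lengths 1000) with a warning.
#' @return list of class `PseudoBulk` with `rpkm` (features x types),
#'   `cell_type_sizes`, `feature_lengths`.
#' @export
pseudobulk_rpkm <- function(matrix, cell_types, feature_lengths = NULL) {
  cells <- cell_ids(matrix)
  if (!all(cells %in% names(cell_types)))
    stop("untyped cell(s): ",
         paste(utils::head(setdiff(cells, names(cell_types)), 3),
               collapse = ", "))
  feats <- feature_ids(matrix)
  if (is.null(feature_lengths)) {
    warning("no feature lengths supplied; using counts-per-million ",
            "(length 1000 for every feature)")
    feature_lengths <- stats::setNames(rep(1000, length(feats)), feats)
  }
  if (!all(feats %in% names(feature_lengths)))
    stop("missing length for feature(s): ",
         paste(utils::head(setdiff(feats, names(feature_lengths)), 3),
               collapse = ", "))
  len <- feature_lengths[feats]
  if (any(len <= 0)) stop("zero or negative feature length")
  type <- factor(cell_types[cells])
  agg <- t(rowsum(as.matrix(matrix$values), type))  # features x types
  totals <- colSums(agg)
  if (any(totals == 0))
    stop("cell type(s) with zero total counts: ",
         paste(colnames(agg)[totals == 0], collapse = ", "))
  rpkm <- 1e9 * sweep(sweep(agg, 1, len, `/`), 2, totals, `/`)
  structure(list(rpkm = rpkm,
                 cell_type_sizes = table(type),
                 feature_lengths = len),
            class = "PseudoBulk")
}

#' Classify peak cell-type specificity
#'
#' For each peak, the ratio of the maximum RPKM over endocrine types to the
#' maximum over non-endocrine types (with a pseudocount) classifies the peak
#' as endocrine-specific (ratio > 2), non-endocrine-specific (ratio < 0.5)
#' or common.
#'
#' @param pb a [pseudobulk_rpkm()] result over peaks.
#' @param endocrine_types,non_endocrine_types column names of the two type
#'   groups.
#' @param eps pseudocount RPKM guarding zero denominators (default 0.01).
#' @return data.frame with peak, ratio, class.
#' @export
classify_peak_specificity <- function(pb, endocrine_types,
                                      non_endocrine_types, eps = 0.01) {
  stopifnot(length(endocrine_types) > 0, length(non_endocrine_types) > 0)
  r <- pb$rpkm
  miss <- setdiff(c(endocrine_types, non_endocrine_types), colnames(r))
  if (length(miss)) stop("unknown cell type(s): ",
                         paste(miss, collapse = ", "))
  emax <- apply(r[, endocrine_types, drop = FALSE], 1, max)
  nmax <- apply(r[, non_endocrine_types, drop = FALSE], 1, max)
  ratio <- (emax + eps) / (nmax + eps)
  data.frame(peak = rownames(r), ratio = ratio,
             class = ifelse(ratio > 2, "endocrine",
                     ifelse(ratio < 0.5, "non_endocrine", "common")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' K-means clustering of peak specificity profiles
#'
#' Rows are normalized to maximum 1 before clustering; cluster labels are
#' renamed by the cell type at which the cluster mean peaks, so the naming
#' is stable across runs.
#'
#' @param rpkm features x types matrix (one specificity class).
#' @param k number of clusters.
#' @param seed RNG seed for the k-means initialization.
#' @param nstart restarts (default 10).
#' @return named integer vector of cluster labels (1..k).
#' @export
kmeans_peak_clusters <- function(rpkm, k, seed = 1L, nstart = 10) {
  x <- rpkm / pmax(apply(rpkm, 1, max), .Machine$double.eps)
  if (k == 1)
    return(stats::setNames(rep(1L, nrow(x)), rownames(x)))
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart))
  peak_type <- apply(km$centers, 1, which.max)
  ord <- order(peak_type, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  stats::setNames(relabel[km$cluster], rownames(x))
}

# upper-tail exact binomial: P(X >= observed), X ~ Binomial(n, p)
binomial_upper_tail <- function(observed, n, p) {
  stats::pbinom(observed - 1L, size = n, prob = p, lower.tail = FALSE)
}

#' Motif enrichment in a peak group by binomial test
#'
#' Background frequency per motif is the fraction of background peaks
#' carrying at least one hit; the foreground hit count is referred to the
#' upper tail of the corresponding binomial.
#'
#' @param hits motif hit table (see [read_fimo()]; hits are assumed
#'   pre-filtered at the ingestion p-value cutoff).
#' @param foreground character vector of peak ids (subset of background).
#' @param background character vector of peak ids.
#' @param q_method method for [qvalues()].
#' @return data.frame with term (motif), observed, group_size,
#'   background_freq, p, q.
#' @export
motif_enrichment <- function(hits, foreground, background,
                             q_method = "storey") {
  if (!length(foreground)) stop("empty foreground peak set")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  motifs <- unique(hits$motif_id)
  hits <- hits[hits$peak_id %in% background, , drop = FALSE]
  res <- lapply(motifs, function(m) {
    mp <- unique(hits$peak_id[hits$motif_id == m])
    bg_freq <- length(mp) / length(background)
    if (bg_freq == 0) {
      warning("motif ", m, " absent from the background; skipped")
      return(NULL)
    }
    obs <- sum(foreground %in% mp)
    data.frame(term = m, observed = obs, group_size = length(foreground),
               background_freq = bg_freq,
               p = binomial_upper_tail(obs, length(foreground), bg_freq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$q <- qvalues(out$p, method = q_method)
  out[order(out$q, out$p), , drop = FALSE]
}

#' Gene-set enrichment by iterative binomial test
#'
#' For each annotated set, the fraction of the universe belonging to the set
#' is the background frequency and the overlap of the query genes with the
#' set is referred to the binomial upper tail; results are ranked by
#' q-value.
#'
#' @param genes query gene names (must lie in the universe).
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe background gene names.
#' @param q_method method for [qvalues()].
#' @return data.frame with term, observed, group_size, background_freq, p,
#'   q, ranked by q.
#' @export
geneset_enrichment <- function(genes, sets, universe, q_method = "storey") {
  if (!all(genes %in% universe))
    stop("query genes must be a subset of the universe")
  res <- lapply(names(sets), function(nm) {
    inset <- intersect(sets[[nm]], universe)
    bg_freq <- length(inset) / length(universe)
    if (bg_freq == 0) return(NULL)
    obs <- sum(genes %in% inset)
    data.frame(term = nm, observed = obs, group_size = length(genes),
               background_freq = bg_freq,
               p = binomial_upper_tail(obs, length(genes), bg_freq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$q <- qvalues(out$p, method = q_method)
  out[order(out$q, out$p), , drop = FALSE]
}

# peak-TSS distances for all same-chromosome pairs within max_dist
peak_tss_pairs <- function(peaks, tss, max_dist) {
  res <- lapply(unique(peaks$chrom), function(ch) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    ts <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(pk) || !nrow(ts)) return(NULL)
    grid <- expand.grid(pi_ = seq_len(nrow(pk)), ti_ = seq_len(nrow(ts)))
    d <- point_interval_distance(pk$start[grid$pi_], pk$end[grid$pi_],
                                 ts$tss[grid$ti_])
    keep <- d <= max_dist
    data.frame(peak = pk$id[grid$pi_[keep]], gene = ts$gene[grid$ti_[keep]],
               distance = d[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(peak = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  out
}

#' Proximity-based peak-gene links
#'
#' Links every (peak, gene) pair whose gap between the peak interval and the
#' gene TSS is at most `max_dist` bases (0 when the TSS falls inside the
#' peak; the cutoff is inclusive).
#'
#' @param peaks intervals data.frame (chrom, start, end, id).
#' @param tss TSS table (gene, chrom, tss, strand).
#' @param max_dist inclusive distance cutoff (default 10000).
#' @return data.frame with peak, gene, mode = "proximal", distance.
#' @export
link_proximal <- function(peaks, tss, max_dist = 10000) {
  out <- peak_tss_pairs(peaks, tss, max_dist)
  if (nrow(out)) out$mode <- "proximal"
  else out$mode <- character(0)
  out[, c("peak", "gene", "mode", "distance")]
}

#' Nearest-gene assignment for peaks
#'
#' Each peak is assigned the gene with the smallest TSS distance; ties are
#' broken toward the lexicographically smaller gene name.
#'
#' @param peaks intervals data.frame.
#' @param tss TSS table.
#' @return data.frame with peak, gene, mode = "nearest", distance (one row
#'   per peak with a same-chromosome gene).
#' @export
link_nearest <- function(peaks, tss) {
  pairs <- peak_tss_pairs(peaks, tss, Inf)
  pairs <- pairs[order(pairs$peak, pairs$distance, pairs$gene), ]
  out <- pairs[!duplicated(pairs$peak), , drop = FALSE]
  out$mode <- "nearest"
  rownames(out) <- NULL
  out[, c("peak", "gene", "mode", "distance")]
}

#' Correlation-based peak-gene links across cell types
#'
#' Candidate pairs are peaks and TSS within `window` bases; the Pearson
#' correlation of their pseudo-bulk RPKM profiles across cell types links
#' pairs with `r > r_min` (strict).  Pairs involving a zero-variance profile
#' are skipped.
#'
#' @param pb_peaks,pb_genes [pseudobulk_rpkm()] results (or plain
#'   feature x type matrices) over the same cell types (>= 3).
#' @param peaks,tss coordinates for the candidate window.
#' @param window candidate distance (default 1e6).
#' @param r_min correlation threshold (default 0.7, strict).
#' @return data.frame with peak, gene, mode = "correlation", distance, r.
#' @export
link_by_correlation <- function(pb_peaks, pb_genes, peaks, tss,
                                window = 1e6, r_min = 0.7) {
  pm <- if (inherits(pb_peaks, "PseudoBulk")) pb_peaks$rpkm else
    as.matrix(pb_peaks)
  gm <- if (inherits(pb_genes, "PseudoBulk")) pb_genes$rpkm else
    as.matrix(pb_genes)
  shared <- intersect(colnames(pm), colnames(gm))
  if (length(shared) < 3)
    stop("need at least 3 shared cell types for correlation linking")
  pm <- pm[, shared, drop = FALSE]
  gm <- gm[, shared, drop = FALSE]
  cand <- peak_tss_pairs(peaks, tss, window)
  cand <- cand[cand$peak %in% rownames(pm) & cand$gene %in% rownames(gm), ]
  if (!nrow(cand))
    return(data.frame(peak = character(), gene = character(),
                      mode = character(), distance = numeric(),
                      r = numeric(), stringsAsFactors = FALSE))
  pv <- pm[cand$peak, , drop = FALSE]
  gv <- gm[cand$gene, , drop = FALSE]
  sdp <- apply(pv, 1, stats::sd)
  sdg <- apply(gv, 1, stats::sd)
  ok <- sdp > 0 & sdg > 0
  if (any(!ok))
    message(sum(!ok), " candidate pair(s) skipped (zero-variance profile)")
  r <- rep(NA_real_, nrow(cand))
  r[ok] <- colSums(scale(t(pv[ok, , drop = FALSE])) *
                     scale(t(gv[ok, , drop = FALSE]))) / (length(shared) - 1)
  keep <- ok & r > r_min
  out <- cand[keep, , drop = FALSE]
  out$mode <- "correlation"
  out$r <- r[keep]
  rownames(out) <- NULL
  out[, c("peak", "gene", "mode", "distance", "r")]
}

#' Loop-supported peak-gene links
#'
#' Links (peak, gene) when the peak overlaps one loop anchor and the gene's
#' TSS lies in the other anchor (either orientation).  The reported distance
#' is |TSS - peak midpoint|.
#'
#' @param peaks intervals data.frame.
#' @param tss TSS table.
#' @param loops loop set (see [read_bedpe()]).
#' @return data.frame with peak, gene, mode = "loop", distance, loop_id.
#' @export
link_by_loops <- function(peaks, tss, loops) {
  empty <- data.frame(peak = character(), gene = character(),
                      mode = character(), distance = numeric(),
                      loop_id = character(), stringsAsFactors = FALSE)
  if (!nrow(loops)) return(empty)
  one_side <- function(as_, ae_, bs_, be_, chrom, loop_id) {
    res <- lapply(seq_along(as_), function(i) {
      pk <- peaks[peaks$chrom == chrom[i] &
                    intervals_overlap(peaks$start, peaks$end, as_[i], ae_[i]),
                  , drop = FALSE]
      ts <- tss[tss$chrom == chrom[i] & tss$tss >= bs_[i] &
                  tss$tss < be_[i], , drop = FALSE]
      if (!nrow(pk) || !nrow(ts)) return(NULL)
      grid <- expand.grid(p = seq_len(nrow(pk)), g = seq_len(nrow(ts)))
      data.frame(peak = pk$id[grid$p], gene = ts$gene[grid$g],
                 mode = "loop",
                 distance = abs(ts$tss[grid$g] -
                                  (pk$start[grid$p] + pk$end[grid$p]) / 2),
                 loop_id = loop_id[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(
    one_side(loops$start_a, loops$end_a, loops$start_b, loops$end_b,
             loops$chrom_a, loops$loop_id),
    one_side(loops$start_b, loops$end_b, loops$start_a, loops$end_a,
             loops$chrom_a, loops$loop_id))
  if (is.null(out)) return(empty)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Reconstruct the trajectory gene-peak circuit
#'
#' Attaches trajectory peaks to trajectory genes through proximal (promoter,
#' <= 10 kb) or loop-supported links; correlation-only links do not count as
#' explaining a gene.  A gene with at least one attached trajectory peak is
#' "explained".
#'
#' @param gene_calls list with `up`/`down` character vectors (from
#'   [call_trajectory_genes()]).
#' @param peak_calls list with `gain`/`loss` character vectors (from
#'   [call_trajectory_peaks()]).
#' @param links data.frame of links (rbind of [link_proximal()] and
#'   [link_by_loops()] output; correlation rows are ignored).
#' @param gene_categories,peak_categories optional named vectors (feature ->
#'   four-way category from [classify_heterogeneity()]) carried into the
#'   edge table.
#' @return data.frame of circuit edges: gene, peak, mode, gene_direction,
#'   peak_direction, gene_category, peak_category.
#' @export
circuit_table <- function(gene_calls, peak_calls, links,
                          gene_categories = NULL, peak_categories = NULL) {
  traj_genes <- c(gene_calls$up, gene_calls$down)
  traj_peaks <- c(peak_calls$gain, peak_calls$loss)
  e <- links[links$mode %in% c("proximal", "loop") &
               links$gene %in% traj_genes & links$peak %in% traj_peaks,
             c("peak", "gene", "mode"), drop = FALSE]
  if (!nrow(e))
    return(data.frame(gene = character(), peak = character(),
                      mode = character(), gene_direction = character(),
                      peak_direction = character(),
                      gene_category = character(),
                      peak_category = character(), stringsAsFactors = FALSE))
  e$gene_direction <- ifelse(e$gene %in% gene_calls$up, "up", "down")
  e$peak_direction <- ifelse(e$peak %in% peak_calls$gain, "gain", "loss")
  e$gene_category <- if (is.null(gene_categories)) NA_character_ else
    unname(gene_categories[e$gene])
  e$peak_category <- if (is.null(peak_categories)) NA_character_ else
    unname(peak_categories[e$peak])
  e <- unique(e[, c("gene", "peak", "mode", "gene_direction",
                    "peak_direction", "gene_category", "peak_category")])
  rownames(e) <- NULL
  e
}

#' Category enrichment between linked genes and peaks
#'
#' For every (gene category, peak category) pair, builds the 2x2 table of
#' genes in/outside the gene category versus linked/not linked to at least
#' one peak of the peak category, and applies a two-sided Fisher's exact
#' test.
#'
#' @param gene_categories named vector, gene -> category (the gene
#'   universe).
#' @param peak_categories named vector, peak -> category.
#' @param edges circuit edge table from [circuit_table()].
#' @param q_method method for [qvalues()].
#' @return data.frame with gene_category, peak_category, n_genes_linked,
#'   odds_ratio, p, q.
#' @export
category_enrichment <- function(gene_categories, peak_categories, edges,
                                q_method = "bh") {
  genes <- names(gene_categories)
  gcats <- sort(unique(unname(gene_categories)))
  pcats <- sort(unique(unname(peak_categories)))
  res <- list()
  for (gc_ in gcats) for (pc_ in pcats) {
    linked_peaks <- names(peak_categories)[peak_categories == pc_]
    linked_genes <- unique(edges$gene[edges$peak %in% linked_peaks])
    in_cat <- gene_categories == gc_
    is_linked <- genes %in% linked_genes
    tab <- table(factor(in_cat, c(TRUE, FALSE)),
                 factor(is_linked, c(TRUE, FALSE)))
    if (sum(in_cat) == 0 || length(linked_peaks) == 0) {
      warning("empty category pair (", gc_, ", ", pc_, ") skipped")
      next
    }
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    res[[paste(gc_, pc_, sep = "|")]] <-
      data.frame(gene_category = gc_, peak_category = pc_,
                 n_genes_linked = sum(in_cat & is_linked),
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$q <- qvalues(out$p, method = q_method)
  rownames(out) <- NULL
  out
}

#' Predict targets of a transcription factor from trajectory peaks
#'
#' Selects trajectory peaks carrying at least one hit of `tf_motif`,
#' collects their nearest genes and loop-connected genes, and intersects
#' with the trajectory gene set.
#'
#' @param tf_motif motif id.
#' @param hits motif hit table (pre-filtered at the ingestion cutoff).
#' @param peak_calls list with `gain`/`loss` peak sets.
#' @param links link table containing `nearest` and/or `loop` mode rows.
#' @param gene_calls list with `up`/`down` gene sets.
#' @return data.frame with gene, peak, mode (evidence rows; a gene reachable
#'   through several peaks/modes appears once per evidence row).
#' @export
predict_tf_targets <- function(tf_motif, hits, peak_calls, links,
                               gene_calls) {
  traj_peaks <- c(peak_calls$gain, peak_calls$loss)
  traj_genes <- c(gene_calls$up, gene_calls$down)
  motif_peaks <- unique(hits$peak_id[hits$motif_id == tf_motif])
  sel <- intersect(traj_peaks, motif_peaks)
  ev <- links[links$peak %in% sel & links$mode %in% c("nearest", "loop") &
                links$gene %in% traj_genes,
              c("gene", "peak", "mode"), drop = FALSE]
  ev <- unique(ev)
  ev <- ev[order(ev$gene, ev$peak, ev$mode), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
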