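#' Per-donor trend tests along the global trajectory
#'
#' Iterates over donors: each donor's cells are re-binned into `n_bins`
#' equal-width intervals over that donor's own pseudo-index range, and every
#' feature's per-bin means are regressed on the bin values exactly as in
#' [feature_trend_test()].  Donors yielding fewer than `min_bins` non-empty
#' bins are excluded (and reported), never silently NaN'd.
#'
#' @param matrix a [FeatureMatrix()] over the model's cells.
#' @param model a `TrajectoryModel` from [fit_trajectory()].
#' @param cells data.frame with cell_id and donor_id.
#' @param n_bins bins per donor (default 20).
#' @param min_bins minimum non-empty bins for a donor to be included
#'   (default 5).
#' @param scale per-bin statistic, as in [feature_trend_test()].
#' @return data.frame with feature, donor, slope_k, p_k, n_cells,
#'   n_bins_used; excluded donors are listed in the `excluded_donors`
#'   attribute.
#' @export
per_donor_trends <- function(matrix, model, cells, n_bins = 20, min_bins = 5,
                             scale = c("raw_mean", "zscore")) {
  scale <- match.arg(scale)
  idx <- model$pseudo_index
  donors <- split(cells$cell_id, cells$donor_id)
  excluded <- character(0)
  res <- lapply(names(donors), function(d) {
    dc <- intersect(donors[[d]], names(idx))
    di <- idx[dc]
    if (length(unique(di)) < 3) {
      warning("donor ", d, " excluded: fewer than 3 distinct index values")
      excluded <<- c(excluded, d)
      return(NULL)
    }
    bins <- suppressWarnings(bin_by_index(di, n_bins))
    used <- sum(bins$cells_per_bin > 0)
    if (used < max(3, min_bins)) {
      warning("donor ", d, " excluded: only ", used, " non-empty bins")
      excluded <<- c(excluded, d)
      return(NULL)
    }
    values <- if (inherits(matrix, "FeatureMatrix")) matrix$values else matrix
    tr <- feature_trend_test(values[dc, , drop = FALSE], bins, scale = scale)
    data.frame(feature = tr$feature, donor = d, slope_k = tr$slope,
               p_k = pmax(tr$p, .Machine$double.xmin), n_cells = length(dc),
               n_bins_used = used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "excluded_donors") <- excluded
  out
}

#' Combine p-values across donors by Fisher's method
#'
#' `statistic = -2 * sum(log p_k)` is referred to the upper tail of a
#' chi-squared distribution with `2k` degrees of freedom, `k` the number of
#' donors entering the combination.
#'
#' @param p_list numeric vector of per-donor p-values in (0, 1\]; zeros are
#'   clamped to the smallest representable positive value with a warning.
#' @return list with `statistic`, `n_donors`, `df`, `p_combined`.
#' @export
fisher_combine <- function(p_list) {
  if (!length(p_list)) stop("empty p-value list")
  if (any(is.na(p_list) | p_list < 0 | p_list > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_list == 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    p_list[p_list == 0] <- .Machine$double.xmin
  }
  k <- length(p_list)
  stat <- -2 * sum(log(p_list))
  list(statistic = stat, n_donors = k, df = 2L * k,
       p_combined = stats::pchisq(stat, df = 2 * k, lower.tail = FALSE))
}

#' Classify trajectory features into intra-/inter-donor heterogeneity
#'
#' Features already called by the global trajectory test are classified by
#' combining their per-donor trend p-values with Fisher's method: q-values
#' are computed over the globally-called feature set, features with combined
#' q below `q_cut` are intra-donor heterogeneous (reproducible within-donor
#' trend), the rest inter-donor; the direction comes from the global call.
#' The heterogeneity score is `-log10(q_combined)`, so the default cut
#' corresponds to a score strictly above 2.
#'
#' @param global_results a [feature_trend_test()] result for the global
#'   trajectory.
#' @param donor_trends a [per_donor_trends()] result.
#' @param global_q_cut q-value cut defining the globally-called set
#'   (default 0.05).
#' @param q_cut Fisher q-value cut for the intra call (strict; default
#'   0.01).
#' @param sign_consistent if TRUE, additionally require the median per-donor
#'   slope sign to match the global direction for an intra call.
#' @param q_universe compute the combined-p q-values within the
#'   globally-called set (`"called"`, default) or over all features
#'   (`"all"`).
#' @param q_method method for [qvalues()].  Defaults to `"bh"` here: the
#'   called set is small and signal-enriched by construction, so Storey's
#'   pi0 estimate (which assumes a large, mostly-null p-value population)
#'   is unstable and can collapse every q below the cut.
#' @return data.frame with feature, direction, statistic, df, n_donors,
#'   p_combined, q_combined, score, category (intra_up / intra_down /
#'   inter_up / inter_down).
#' @export
classify_heterogeneity <- function(global_results, donor_trends,
                                   global_q_cut = 0.05, q_cut = 0.01,
                                   sign_consistent = FALSE,
                                   q_universe = c("called", "all"),
                                   q_method = "bh") {
  q_universe <- match.arg(q_universe)
  called <- global_results[global_results$q < global_q_cut, ]
  unknown <- setdiff(unique(donor_trends$feature), global_results$feature)
  if (length(unknown))
    warning(length(unknown), " feature(s) in donor trends absent from the ",
            "global results; ignored")
  universe <- if (q_universe == "called") called$feature else
    global_results$feature
  empty <- data.frame(feature = character(), direction = character(),
                      statistic = numeric(), df = integer(),
                      n_donors = integer(), p_combined = numeric(),
                      q_combined = numeric(), score = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  if (!length(universe) || !nrow(called)) return(empty)
  dt <- donor_trends[donor_trends$feature %in% universe, ]
  if (!nrow(dt)) return(empty)
  combos <- lapply(split(dt, dt$feature), function(d) {
    fc <- fisher_combine(d$p_k)
    data.frame(feature = d$feature[1], statistic = fc$statistic,
               df = fc$df, n_donors = fc$n_donors,
               p_combined = fc$p_combined,
               median_slope = stats::median(d$slope_k),
               stringsAsFactors = FALSE)
  })
  combos <- do.call(rbind, combos)
  combos$q_combined <- qvalues(combos$p_combined, method = q_method)
  out <- combos[combos$feature %in% called$feature, , drop = FALSE]
  out$direction <- called$direction[match(out$feature, called$feature)]
  out$score <- -log10(out$q_combined)
  intra <- out$q_combined < q_cut
  if (sign_consistent)
    intra <- intra & (sign(out$median_slope) ==
                        ifelse(out$direction == "up", 1, -1))
  out$category <- paste0(ifelse(intra, "intra_", "inter_"), out$direction)
  rownames(out) <- NULL
  out[, c("feature", "direction", "statistic", "df", "n_donors",
          "p_combined", "q_combined", "score", "category")]
}
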