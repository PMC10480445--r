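#' Fit a disease trajectory by logistic regression on embedding components
#'
#' The trajectory model regresses the binary phenotype on the selected
#' embedding components (PC1-10 for RNA, LSI1-10 for ATAC by default) with a
#' small ridge penalty for stability under separation.  The per-cell pseudo
#' index is the model score: it ranks cells from healthy-like (low) to
#' disease-like (high).
#'
#' By default the pseudo-index is the linear predictor `intercept + x' beta`.
#' `index_type = "probability"` gives the logistic-transformed score instead
#' (the ranking is identical); note that when the two phenotype classes are
#' nearly separable in the embedding the probability saturates at 0/1 and
#' equal-width binning of it degenerates, so the linear scale is the working
#' default.
#'
#' @param embedding an [Embedding()] or coordinate matrix with cell
#'   rownames.
#' @param phenotype per-cell labels, named by cell or aligned with the
#'   embedding rows; factor/character with levels healthy/disease, or 0/1.
#' @param components component indices used in the fit (default 1:10,
#'   truncated to the available components).
#' @param ridge ridge penalty lambda on the slope coefficients (the
#'   intercept is unpenalized).  The default `"auto"` sets lambda to ten
#'   times the largest eigenvalue of the centered component cross-product,
#'   i.e. shrinkage strong relative to the embedding spectrum: the fitted
#'   direction then approaches the phenotype-centroid axis, which preserves
#'   within-donor severity variation instead of collapsing onto the
#'   maximally donor-discriminating (and within-donor noise-dominated)
#'   direction that a nearly unpenalized fit finds on separable cohorts.
#'   Any non-negative number (e.g. `1e-4` for a minimal
#'   stabilize-the-separation penalty) can be given instead.
#' @param index_type `"linear"` (default) or `"probability"`.
#' @return object of class `TrajectoryModel`: list with `coefficients`,
#'   `intercept`, `components_used`, `pseudo_index` (named), `fitted_prob`
#'   (named, in \[0, 1\]) and `phenotype`.
#' @export
fit_trajectory <- function(embedding, phenotype, components = 1:10,
                           ridge = "auto",
                           index_type = c("linear", "probability")) {
  index_type <- match.arg(index_type)
  coords <- embedding_coords(embedding)
  components <- components[components <= ncol(coords)]
  x <- coords[, components, drop = FALSE]
  if (!is.null(names(phenotype))) phenotype <- phenotype[rownames(coords)]
  y <- phenotype_to_binary(phenotype)
  if (length(unique(y)) < 2)
    stop("both phenotype classes must be present")
  if (identical(ridge, "auto")) {
    xc <- sweep(x, 2, colMeans(x))
    ridge <- 10 * max(eigen(crossprod(xc), symmetric = TRUE,
                            only.values = TRUE)$values)
  }
  beta <- ridge_logistic(x, y, ridge)
  eta <- drop(beta[1] + x %*% beta[-1])
  prob <- stats::plogis(eta)
  idx <- if (index_type == "linear") eta else prob
  names(idx) <- names(prob) <- rownames(coords)
  structure(list(coefficients = stats::setNames(beta[-1], colnames(x)),
                 intercept = beta[1], components_used = components,
                 pseudo_index = idx, fitted_prob = prob,
                 index_type = index_type,
                 phenotype = stats::setNames(y, rownames(coords))),
            class = "TrajectoryModel")
}

phenotype_to_binary <- function(phenotype) {
  if (is.numeric(phenotype)) {
    if (!all(phenotype %in% c(0, 1))) stop("numeric phenotype must be 0/1")
    return(as.integer(phenotype))
  }
  ph <- tolower(as.character(phenotype))
  if (!all(ph %in% c("healthy", "disease", "t2d")))
    stop("phenotype labels must be healthy/disease/T2D or 0/1")
  as.integer(ph != "healthy")
}

# ridge-penalized logistic regression by IRLS; intercept unpenalized
ridge_logistic <- function(x, y, lambda, max_iter = 100, tol = 1e-10) {
  xm <- cbind(1, x)
  p <- ncol(xm)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(xm * w)
    new_beta <- solve(xtw %*% xm + pen, xtw %*% z)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- drop(new_beta)
      break
    }
    beta <- drop(new_beta)
  }
  beta
}

#' @export
print.TrajectoryModel <- function(x, ...) {
  cat(sprintf("TrajectoryModel: %d cells, components %s\n",
              length(x$pseudo_index),
              paste(range(x$components_used), collapse = "-")))
  invisible(x)
}

#' Donor-level permutation test of trajectory-phenotype association
#'
#' Phenotype is a donor-level variable, so the evidence that a fitted
#' trajectory is disease-associated must be judged with donors (not cells)
#' as the exchangeable unit.  Because the trajectory direction is estimated
#' from the labeled cells themselves, any in-sample test of index-phenotype
#' separation is circular; this test therefore refits the trajectory under
#' every (or many) reassignment of phenotype labels to whole donors and
#' compares the observed donor-level separation (Welch t on per-donor mean
#' pseudo-index) against the permutation distribution.  Downstream feature
#' calling should be gated on this test: per-feature trends along a
#' trajectory without established phenotype association are not
#' interpretable as disease trends.
#'
#' @param embedding the embedding the trajectory is fitted on.
#' @param cells data.frame with cell_id, donor_id, phenotype.
#' @param components,ridge passed to [fit_trajectory()].
#' @param n_perm Monte-Carlo permutations when the exact assignment count
#'   exceeds `exact_limit` (default 999).
#' @param exact_limit enumerate all donor-label assignments when their
#'   number is at most this (default 1000).
#' @param seed RNG seed for Monte-Carlo sampling.
#' @return list with `p_value`, `statistic` (observed |t|), `n_perm`,
#'   `exact` flag and `donor_means`.
#' @export
trajectory_phenotype_test <- function(embedding, cells, components = 1:10,
                                      ridge = "auto", n_perm = 999,
                                      exact_limit = 1000, seed = 1L) {
  donors <- unique(cells$donor_id)
  ph_d <- phenotype_to_binary(
    cells$phenotype[match(donors, cells$donor_id)])
  n_dis <- sum(ph_d)
  if (n_dis == 0 || n_dis == length(donors))
    stop("both phenotype classes required at donor level")
  sep_stat <- function(y_donor) {
    y <- y_donor[match(cells$donor_id, donors)]
    names(y) <- cells$cell_id
    m <- fit_trajectory(embedding, y, components = components,
                        ridge = ridge)
    dm <- tapply(m$pseudo_index[cells$cell_id], cells$donor_id, mean)
    yd <- y_donor[match(names(dm), donors)]
    abs(stats::t.test(dm[yd == 1], dm[yd == 0])$statistic)
  }
  obs <- sep_stat(ph_d)
  n_assign <- choose(length(donors), n_dis)
  if (n_assign <= exact_limit) {
    combs <- utils::combn(length(donors), n_dis)
    stats_perm <- apply(combs, 2, function(i) {
      y <- integer(length(donors)); y[i] <- 1L
      sep_stat(y)
    })
    p <- mean(stats_perm >= obs - 1e-12)
    exact <- TRUE
    n_used <- ncol(combs)
  } else {
    stats_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      y <- integer(length(donors))
      y[sample(length(donors), n_dis)] <- 1L
      sep_stat(y)
    }, numeric(1)))
    p <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
    exact <- FALSE
    n_used <- n_perm
  }
  idx <- fit_trajectory(embedding,
                        stats::setNames(ph_d[match(cells$donor_id, donors)],
                                        cells$cell_id),
                        components = components, ridge = ridge)$pseudo_index
  list(p_value = p, statistic = unname(obs), n_perm = n_used, exact = exact,
       donor_means = tapply(idx[cells$cell_id], cells$donor_id, mean))
}

#' Depth-normalize a count matrix to counts per 10k
#'
#' @param fm raw-count [FeatureMatrix()].
#' @return normalized [FeatureMatrix()] (counts / cell total * 1e4).
#'
#' The per-bin trend statistic computed on this matrix is insensitive to
#' correlation between the pseudo-index and per-cell sequencing depth, which
#' confounds raw-count bin means; note however that on strongly
#' disease-shifted cohorts the per-cell total itself tracks severity, so the
#' normalized statistic acquires a compositional trend in otherwise flat
#' features.  The default pipeline keeps raw-count means and relies on
#' [trajectory_phenotype_test()] to reject trajectories without donor-level
#' phenotype support.
#' @export
depth_normalize <- function(fm) {
  depth <- Matrix::rowSums(fm$values)
  depth[depth == 0] <- 1
  out <- fm$values / depth * 1e4
  FeatureMatrix(out, kind = fm$kind, normalized = TRUE)
}

#' Bin cells by pseudo-index into equal-width intervals
#'
#' @param pseudo_index named numeric vector (e.g. from [fit_trajectory()]).
#' @param n_bins number of equal-width bins over the observed range
#'   (default 20).  Bins are half-open on the right except the last, which
#'   includes the maximum; a value exactly on an interior edge falls in the
#'   right-hand bin.
#' @return object of class `BinnedProfile`: list with `n_bins`, `edges`,
#'   `bin_of_cell` (named integer), `bin_value` (bin centers),
#'   `cells_per_bin`.
#' @export
bin_by_index <- function(pseudo_index, n_bins = 20) {
  rng <- range(pseudo_index)
  if (diff(rng) == 0)
    stop("constant pseudo-index: degenerate trajectory")
  if (length(unique(pseudo_index)) < n_bins)
    warning("fewer distinct index values than bins")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  w <- diff(rng) / n_bins
  bin <- pmin(floor((pseudo_index - rng[1]) / w) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(n_bins = as.integer(n_bins), edges = edges,
                 bin_of_cell = stats::setNames(as.integer(bin),
                                               names(pseudo_index)),
                 bin_value = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                 cells_per_bin = counts),
            class = "BinnedProfile")
}

#' @export
print.BinnedProfile <- function(x, ...) {
  cat(sprintf("BinnedProfile: %d bins over [%.3g, %.3g], %d empty\n",
              x$n_bins, min(x$edges), max(x$edges),
              sum(x$cells_per_bin == 0)))
  invisible(x)
}

# per-bin feature means over non-empty bins; returns list(profile B x F, x)
bin_profile <- function(values, bins) {
  m <- as.matrix(values)
  bin <- bins$bin_of_cell
  if (!is.null(names(bin)) && !is.null(rownames(m)))
    bin <- bin[rownames(m)]
  keep <- which(bins$cells_per_bin > 0)
  sums <- rowsum(m, group = factor(bin, levels = keep))
  prof <- sums / bins$cells_per_bin[keep]
  list(profile = prof, x = bins$bin_value[keep])
}

#' Per-feature trend test along the binned trajectory
#'
#' For every feature, cells are averaged within trajectory bins and the
#' per-bin means are regressed on the bin index values by ordinary least
#' squares; the two-sided p-value comes from the slope t-statistic and
#' q-values are computed over all features in the call.  With
#' `scale = "zscore"` each feature's bin profile is z-scored and the bin
#' values rescaled to \[0, 1\], making slopes scale-free (the convention
#' under which the ATAC gain/loss threshold of +/-0.5 is applied).
#'
#' @param matrix a [FeatureMatrix()] (or plain matrix, cells x features)
#'   over the same cells as the binning.
#' @param bins a [bin_by_index()] result.
#' @param scale `"raw_mean"` (RNA convention: average transcript counts) or
#'   `"zscore"` (ATAC convention).
#' @param x_values regress against the bin-center index values (default) or
#'   the bin rank.
#' @param weights `"cells"` (default) weights every bin by its cell count,
#'   the correct variance model for means of unequal sample sizes (sparsely
#'   populated tail bins otherwise dominate the fit through high-leverage,
#'   high-variance points); `"equal"` gives plain unweighted least squares,
#'   which coincides with the weighted fit when bins are equally populated.
#' @param q_cut threshold used to fill the `significant` column (default
#'   0.05).
#' @param q_method multiple-testing method for [qvalues()].
#' @return data.frame with feature, slope, p, q, direction, significant.
#' @export
feature_trend_test <- function(matrix, bins, scale = c("raw_mean", "zscore"),
                               x_values = c("bin_value", "rank"),
                               weights = c("cells", "equal"),
                               q_cut = 0.05, q_method = "storey") {
  scale <- match.arg(scale)
  x_values <- match.arg(x_values)
  weights <- match.arg(weights)
  values <- if (inherits(matrix, "FeatureMatrix")) matrix$values else matrix
  bp <- bin_profile(values, bins)
  if (nrow(bp$profile) < 3)
    stop("fewer than 3 non-empty bins: trend regression is not identifiable")
  y <- bp$profile
  x <- if (x_values == "rank") seq_len(nrow(y)) else bp$x
  w <- if (weights == "cells")
    bins$cells_per_bin[bins$cells_per_bin > 0] else rep(1, nrow(y))
  if (scale == "zscore") {
    mu <- colMeans(y)
    sd <- apply(y, 2, stats::sd)
    zero_var <- sd == 0
    sd[zero_var] <- 1
    y <- sweep(sweep(y, 2, mu), 2, sd, `/`)
    x <- (x - min(x)) / (max(x) - min(x))
  }
  fit <- ols_slope_test(x, y, w)
  out <- data.frame(feature = colnames(y), slope = fit$slope, p = fit$p,
                    q = qvalues(fit$p, method = q_method),
                    direction = ifelse(fit$slope >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$q < q_cut
  out
}

# vectorized (weighted) least-squares slope of each column of y on x with a
# two-sided t-test; zero-variance columns get slope 0, p 1
ols_slope_test <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  sw <- sum(w)
  xc <- x - sum(w * x) / sw
  sxx <- sum(w * xc^2)
  yc <- sweep(y, 2, colSums(w * y) / sw)
  slope <- drop(crossprod(yc, w * xc)) / sxx
  wss <- colSums(w * yc^2)
  rss <- wss - slope^2 * sxx
  rss[rss < 0] <- 0
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  t <- ifelse(se > 0, slope / se, 0)
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- wss == 0
  slope[zero_var] <- 0
  p[zero_var] <- 1
  # exact linear fit (rss == 0) with nonzero slope: p underflows to 0; keep
  p[!zero_var & se == 0 & slope != 0] <- 0
  list(slope = slope, p = p)
}

#' Call trajectory genes from trend results
#'
#' @param results a [feature_trend_test()] result.
#' @param q_cut q-value threshold (strict; default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
call_trajectory_genes <- function(results, q_cut = 0.05) {
  sig <- results$q < q_cut
  list(up = results$feature[sig & results$slope > 0],
       down = results$feature[sig & results$slope < 0])
}

#' Call gain/loss trajectory peaks from trend results
#'
#' Expects results computed with `scale = "zscore"` so the slope threshold
#' is scale-free.
#'
#' @param results a [feature_trend_test()] result.
#' @param q_cut q-value threshold (strict; default 0.01).
#' @param slope_cut absolute standardized-slope threshold (strict; default
#'   0.5).
#' @return list with character vectors `gain` and `loss`.
#' @export
call_trajectory_peaks <- function(results, q_cut = 0.01, slope_cut = 0.5) {
  sig <- results$q < q_cut
  list(gain = results$feature[sig & results$slope > slope_cut],
       loss = results$feature[sig & results$slope < -slope_cut])
}

#' Trend test for motif deviation z-scores along the trajectory
#'
#' Applies the binned OLS machinery to a cells x motifs deviation matrix
#' (chromVAR-style z-scores supplied externally).
#'
#' @param motif_z numeric cells x motifs matrix with cell rownames.
#' @param bins a [bin_by_index()] result.
#' @param ... passed to [feature_trend_test()].
#' @return data.frame as from [feature_trend_test()].
#' @export
motif_trend_test <- function(motif_z, bins, ...) {
  feature_trend_test(as.matrix(motif_z), bins, scale = "raw_mean", ...)
}

#' Serialize a trajectory model to JSON
#' @param model a `TrajectoryModel`.
#' @param path output path.
#' @param bins optional [bin_by_index()] result to embed (edges).
#' @return invisibly, the path.
#' @export
write_trajectory_model <- function(model, path, bins = NULL) {
  obj <- list(coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              components_used = model$components_used,
              pseudo_index = as.list(model$pseudo_index))
  if (!is.null(bins)) obj$bin_edges <- bins$edges
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory model from JSON
#' @param path path written by [write_trajectory_model()].
#' @return a `TrajectoryModel` (without phenotype).
#' @export
read_trajectory_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 intercept = obj$intercept,
                 components_used = obj$components_used,
                 pseudo_index = unlist(obj$pseudo_index),
                 phenotype = NULL, bin_edges = obj$bin_edges),
            class = "TrajectoryModel")
}
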