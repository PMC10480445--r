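#' Configuration for a synthetic multi-donor cohort
#'
#' Defines the generative model behind [generate_cohort()]: a binary-phenotype
#' cohort in which each donor carries a latent severity shift and each cell a
#' within-donor latent severity, and three feature classes load on them:
#'
#' * intra-donor heterogeneous features respond to the full per-cell severity
#'   `s_c = b_d + u_c` (disease-associated and variable within donors),
#' * inter-donor heterogeneous features respond to the donor component `b_d`
#'   only (shifted between donors, flat within a donor),
#' * null features respond to nothing.
#'
#' @param n_donors_healthy,n_donors_disease donors per phenotype.
#' @param cells_per_donor cells sampled from every donor.
#' @param n_genes,n_peaks feature counts for the RNA and ATAC matrices.
#' @param n_intra_features,n_inter_features planted feature counts per class;
#'   the classes are planted at the same feature indices in both modalities.
#' @param disease_shift mean donor-severity shift of the disease phenotype
#'   (delta; default 2).
#' @param donor_sd sd of donor severity around its phenotype mean (sigma_b).
#' @param cell_sd sd of the within-donor cell latent (sigma_u).
#' @param effect_size log-scale (RNA) / logit-scale (ATAC) slope magnitude of
#'   planted features (gamma); signs alternate up/down within each class.
#' @param dispersion negative-binomial shape parameter theta for RNA counts.
#' @param libsize_sd log-normal sd of per-cell library size.
#' @param mean_libsize geometric-mean library size (expected UMIs per cell).
#' @param dropout probability that an RNA count is zeroed post-hoc
#'   (zero-inflation; default 0).
#' @param seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_donors_healthy = 4, n_donors_disease = 4,
                          cells_per_donor = 400, n_genes = 2000,
                          n_peaks = 2000, n_intra_features = 150,
                          n_inter_features = 150, disease_shift = 2.0,
                          donor_sd = 0.5, cell_sd = 1.0, effect_size = 0.5,
                          dispersion = 5, libsize_sd = 0.3,
                          mean_libsize = 5000, dropout = 0, seed = 1L) {
  cfg <- list(
    n_donors_healthy = check_count(n_donors_healthy, "n_donors_healthy"),
    n_donors_disease = check_count(n_donors_disease, "n_donors_disease"),
    cells_per_donor = check_count(cells_per_donor, "cells_per_donor"),
    n_genes = check_count(n_genes, "n_genes"),
    n_peaks = check_count(n_peaks, "n_peaks"),
    n_intra_features = check_count(n_intra_features, "n_intra_features",
                                   min = 0L),
    n_inter_features = check_count(n_inter_features, "n_inter_features",
                                   min = 0L),
    disease_shift = check_real(disease_shift, "disease_shift"),
    donor_sd = check_real(donor_sd, "donor_sd", lower = 0,
                          strict_lower = TRUE),
    cell_sd = check_real(cell_sd, "cell_sd", lower = 0, strict_lower = TRUE),
    effect_size = check_real(effect_size, "effect_size"),
    dispersion = check_real(dispersion, "dispersion", lower = 0,
                            strict_lower = TRUE),
    libsize_sd = check_real(libsize_sd, "libsize_sd", lower = 0),
    mean_libsize = check_real(mean_libsize, "mean_libsize", lower = 1),
    dropout = check_real(dropout, "dropout", lower = 0, upper = 1,
                         strict_upper = TRUE),
    seed = check_count(seed, "seed", min = 0L))
  n_planted <- cfg$n_intra_features + cfg$n_inter_features
  if (n_planted > cfg$n_genes)
    stop("field 'n_intra_features + n_inter_features' exceeds n_genes",
         call. = FALSE)
  if (n_planted > cfg$n_peaks)
    stop("field 'n_intra_features + n_inter_features' exceeds n_peaks",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

plant_classes <- function(n_features, n_intra, n_inter, prefix) {
  cls <- rep("null", n_features)
  cls[seq_len(n_intra)] <- "intra"
  if (n_inter > 0) cls[n_intra + seq_len(n_inter)] <- "inter"
  dir <- rep(NA_character_, n_features)
  planted <- which(cls != "null")
  dir[planted] <- rep_len(c("up", "down"), length(planted))
  data.frame(feature = sprintf("%s%04d", prefix, seq_len(n_features)),
             class = cls, direction = dir, stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic scRNA + snATAC cohort
#'
#' Draws donor severities `b_d ~ N(delta * 1[disease], sigma_b^2)`, cell
#' latents `u_c ~ N(0, sigma_u^2)` and per-cell severities `s_c = b_d + u_c`.
#' Gene log-means are `alpha_g + gamma_g * x` with `x = s_c` (intra class),
#' `x = b_d` (inter class) or `x = 0` (null); RNA counts are negative
#' binomial with per-cell log-normal library sizes and optional dropout.
#' ATAC entries are `Binomial(2, plogis(a_p + c_p * x))` under the same class
#' scheme, mimicking near-binary diploid accessibility.
#'
#' @param config a [cohort_config()].
#' @return list with elements `rna` and `atac` ([FeatureMatrix()]s), `cells`
#'   (data.frame: cell_id, donor_id, phenotype) and `truth` (list with
#'   `cells` incl. per-cell `s`, `b`, `u`; `donors`; `rna_features`;
#'   `atac_features`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    nh <- config$n_donors_healthy; nd <- config$n_donors_disease
    donors <- data.frame(
      donor_id = c(sprintf("H%02d", seq_len(nh)),
                   sprintf("D%02d", seq_len(nd))),
      phenotype = factor(rep(c("healthy", "disease"), c(nh, nd)),
                         levels = c("healthy", "disease")),
      stringsAsFactors = FALSE)
    donors$b <- stats::rnorm(nh + nd,
                             mean = config$disease_shift *
                               (donors$phenotype == "disease"),
                             sd = config$donor_sd)
    n_cells <- (nh + nd) * config$cells_per_donor
    donor_of_cell <- rep(seq_len(nh + nd), each = config$cells_per_donor)
    cells <- data.frame(
      cell_id = sprintf("%s_c%04d", donors$donor_id[donor_of_cell],
                        sequence(rep(config$cells_per_donor, nh + nd))),
      donor_id = donors$donor_id[donor_of_cell],
      phenotype = donors$phenotype[donor_of_cell],
      stringsAsFactors = FALSE)
    u <- stats::rnorm(n_cells, 0, config$cell_sd)
    b <- donors$b[donor_of_cell]
    s <- b + u

    rna_feat <- plant_classes(config$n_genes, config$n_intra_features,
                              config$n_inter_features, "g")
    atac_feat <- plant_classes(config$n_peaks, config$n_intra_features,
                               config$n_inter_features, "p")

    gamma_of <- function(feat) {
      g <- numeric(nrow(feat))
      g[!is.na(feat$direction) & feat$direction == "up"] <- config$effect_size
      g[!is.na(feat$direction) & feat$direction == "down"] <-
        -config$effect_size
      g
    }
    covariate_of <- function(feat) {
      # n_cells x n_features covariate: s (intra), b (inter), 0 (null)
      x <- matrix(0, n_cells, nrow(feat))
      x[, feat$class == "intra"] <- s
      x[, feat$class == "inter"] <- b
      x
    }

    # RNA: NB counts around library-size-scaled relative abundances
    alpha <- stats::rnorm(config$n_genes, 0, 1)
    gamma_g <- gamma_of(rna_feat)
    mu <- sweep(covariate_of(rna_feat), 2, gamma_g, `*`)
    mu <- sweep(mu, 2, alpha, `+`)
    emu <- exp(mu)
    # population-constant normalizer: feature classes stay literal (a null
    # gene is independent of severity given the library size); a per-cell
    # normalizer would couple every gene to the planted ones through the
    # sum constraint
    z <- mean(rowSums(emu))
    libsize <- exp(stats::rnorm(n_cells, log(config$mean_libsize),
                                config$libsize_sd))
    means <- emu / z * libsize
    counts <- matrix(stats::rnbinom(length(means), mu = as.vector(means),
                                    size = config$dispersion),
                     n_cells, config$n_genes)
    if (config$dropout > 0) {
      keep <- stats::rbinom(length(counts), 1L, 1 - config$dropout)
      counts <- counts * keep
    }
    rna <- FeatureMatrix(counts, cell_ids = cells$cell_id,
                         feature_ids = rna_feat$feature, kind = "gene")

    # ATAC: diploid-like Binomial(2, sigmoid) accessibility
    a0 <- stats::rnorm(config$n_peaks, -1, 0.5)
    gamma_p <- gamma_of(atac_feat)
    eta <- sweep(covariate_of(atac_feat), 2, gamma_p, `*`)
    eta <- sweep(eta, 2, a0, `+`)
    acount <- matrix(stats::rbinom(length(eta), 2L,
                                   stats::plogis(as.vector(eta))),
                     n_cells, config$n_peaks)
    atac <- FeatureMatrix(acount, cell_ids = cells$cell_id,
                          feature_ids = atac_feat$feature, kind = "peak")

    list(rna = rna, atac = atac, cells = cells,
         truth = list(cells = cbind(cells, s = s, b = b, u = u),
                      donors = donors, rna_features = rna_feat,
                      atac_features = atac_feat))
  })
}

#' Generate a toy regulome with planted peak-gene relationships
#'
#' Lays out `n_genes` genes on one toy chromosome at fixed spacing, places
#' promoter-proximal peaks (within 10 kb of exactly one TSS) and distal peaks
#' (15-25 kb downstream, nearest gene unambiguous), plants loops connecting
#' the first `n_loops` distal peaks to their genes' TSS via 5-kb anchors,
#' plants a TF motif in a labeled subset of peaks, and builds cell-type RPKM
#' profiles in which exactly the planted pairs are correlated.  All planted
#' relationships are returned as truth so the downstream linkers can be
#' checked for exact recovery.
#'
#' @param n_genes,n_peaks,n_loops element counts; `n_loops` must not exceed
#'   the number of distal peaks, and distal peaks are limited to two per gene
#'   (`n_peaks * (1 - promoter_frac) <= 2 * n_genes`).
#' @param seed integer RNG seed.
#' @param promoter_frac fraction of peaks placed within 10 kb of a TSS.
#' @param n_cell_types number of pseudo-bulk cell types for the correlation
#'   profiles.
#' @return list with `tss`, `genes` (gene-body intervals), `peaks`, `loops`,
#'   `motif_hits`, `profiles` (list `gene_rpkm`, `peak_rpkm`) and `truth`
#'   (data.frames `proximal`, `loop`, `correlated`, `nearest`, and character
#'   vector `motif_peaks`).
#' @export
generate_toy_regulome <- function(n_genes, n_peaks, n_loops, seed = 1L,
                                  promoter_frac = 0.5, n_cell_types = 7L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_peaks <- check_count(n_peaks, "n_peaks")
  n_loops <- check_count(n_loops, "n_loops", min = 0L)
  spacing <- 50000L
  width <- 400L
  with_seed(seed, {
    tss_pos <- 20000L + spacing * (seq_len(n_genes) - 1L)
    genes <- sprintf("gene%03d", seq_len(n_genes))
    tss <- data.frame(gene = genes, chrom = "chrT", tss = tss_pos,
                      strand = "+", stringsAsFactors = FALSE)
    gene_body <- data.frame(chrom = "chrT", start = tss_pos,
                            end = tss_pos + 8000L, id = genes,
                            strand = "+", stringsAsFactors = FALSE)

    n_prom <- round(n_peaks * promoter_frac)
    n_dist <- n_peaks - n_prom
    if (n_dist > 2L * n_genes)
      stop("too many distal peaks: at most 2 per gene are supported")
    if (n_loops > n_dist) stop("n_loops exceeds the number of distal peaks")

    peak_id <- sprintf("peak%03d", seq_len(n_peaks))
    is_prom <- seq_len(n_peaks) <= n_prom
    gene_of_peak <- integer(n_peaks)
    gene_of_peak[is_prom] <- rep_len(seq_len(n_genes), n_prom)
    gene_of_peak[!is_prom] <- rep_len(seq_len(n_genes), n_dist)
    slot <- integer(n_peaks)  # distal slot (0 or 1) per gene
    if (n_dist > 0)
      slot[!is_prom] <- (seq_len(n_dist) - 1L) %/% n_genes
    off <- integer(n_peaks)
    off[is_prom] <- sample(-9500:9100, n_prom, replace = TRUE)
    # distal: one peak per 5-kb slot, fully inside the slot's loop anchor
    off[!is_prom] <- 15000L + 5000L * slot[!is_prom] +
      sample(100:4400, n_dist, replace = TRUE)
    start <- tss_pos[gene_of_peak] + off
    peaks <- data.frame(chrom = "chrT", start = start, end = start + width,
                        id = peak_id, stringsAsFactors = FALSE)

    truth_prox <- data.frame(peak = peak_id[is_prom],
                             gene = genes[gene_of_peak[is_prom]],
                             stringsAsFactors = FALSE)
    truth_nearest <- data.frame(peak = peak_id, gene = genes[gene_of_peak],
                                stringsAsFactors = FALSE)

    # loops: 5-kb anchors over the first n_loops distal peaks and their TSS
    dist_idx <- which(!is_prom)[seq_len(n_loops)]
    if (n_loops > 0) {
      amid <- (peaks$start[dist_idx] + peaks$end[dist_idx]) %/% 2L
      a_start <- (amid %/% 5000L) * 5000L
      b_start <- (tss_pos[gene_of_peak[dist_idx]] %/% 5000L) * 5000L
      loops <- data.frame(chrom_a = "chrT", start_a = a_start,
                          end_a = a_start + 5000L, chrom_b = "chrT",
                          start_b = b_start, end_b = b_start + 5000L,
                          loop_id = sprintf("loop%03d", seq_len(n_loops)),
                          strength = stats::runif(n_loops, 1, 100),
                          stringsAsFactors = FALSE)
      truth_loop <- data.frame(peak = peak_id[dist_idx],
                               gene = genes[gene_of_peak[dist_idx]],
                               loop_id = loops$loop_id,
                               stringsAsFactors = FALSE)
    } else {
      loops <- data.frame(chrom_a = character(), start_a = integer(),
                          end_a = integer(), chrom_b = character(),
                          start_b = integer(), end_b = integer(),
                          loop_id = character(), strength = numeric(),
                          stringsAsFactors = FALSE)
      truth_loop <- data.frame(peak = character(), gene = character(),
                               loop_id = character(), stringsAsFactors = FALSE)
    }

    # motif hits: plant MOTIF_A in every third peak (strong p), decoy
    # MOTIF_B hits below and above the ingestion threshold
    motif_peaks <- peak_id[seq(1L, n_peaks, by = 3L)]
    hits <- data.frame(motif_id = "MOTIF_A", peak_id = motif_peaks,
                       start = 10L, stop = 10L + 12L, score = 15,
                       p_value = 1e-8, stringsAsFactors = FALSE)
    decoy_strong <- peak_id[seq(2L, n_peaks, by = 5L)]
    decoy_weak <- peak_id[seq(3L, n_peaks, by = 4L)]
    hits <- rbind(hits,
                  data.frame(motif_id = "MOTIF_B", peak_id = decoy_strong,
                             start = 50L, stop = 62L, score = 12,
                             p_value = 5e-7, stringsAsFactors = FALSE),
                  data.frame(motif_id = "MOTIF_B", peak_id = decoy_weak,
                             start = 80L, stop = 92L, score = 6,
                             p_value = 1e-5, stringsAsFactors = FALSE))

    # correlation profiles: planted pairs share their gene's profile; other
    # peaks are resampled until no unplanted in-window pair crosses r = 0.65
    gene_rpkm <- matrix(exp(stats::rnorm(n_genes * n_cell_types, 2, 1)),
                        n_genes, n_cell_types,
                        dimnames = list(genes,
                                        paste0("type", seq_len(n_cell_types))))
    # keep gene profiles mutually uncorrelated (< 0.65) so a planted peak
    # (copy of its gene's profile) cannot also cross r = 0.7 with a second
    # gene inside the linking window
    for (iter in seq_len(200)) {
      gc_ <- stats::cor(t(gene_rpkm))
      diag(gc_) <- 0
      bad <- which(apply(gc_, 1, max) > 0.65)
      if (!length(bad)) break
      gene_rpkm[bad, ] <- exp(stats::rnorm(length(bad) * n_cell_types, 2, 1))
    }
    corr_idx <- unique(c(which(is_prom), dist_idx))
    truth_corr <- data.frame(peak = peak_id[corr_idx],
                             gene = genes[gene_of_peak[corr_idx]],
                             stringsAsFactors = FALSE)
    peak_rpkm <- matrix(exp(stats::rnorm(n_peaks * n_cell_types, 2, 1)),
                        n_peaks, n_cell_types,
                        dimnames = list(peak_id, colnames(gene_rpkm)))
    peak_rpkm[corr_idx, ] <- gene_rpkm[gene_of_peak[corr_idx], ]
    free_idx <- setdiff(seq_len(n_peaks), corr_idx)
    pmid <- (peaks$start + peaks$end) / 2
    for (iter in seq_len(200)) {
      bad <- free_idx[vapply(free_idx, function(i) {
        near <- which(abs(tss_pos - pmid[i]) <= 1e6)
        any(stats::cor(peak_rpkm[i, ], t(gene_rpkm[near, , drop = FALSE])) >
              0.65)
      }, logical(1))]
      if (!length(bad)) break
      peak_rpkm[bad, ] <- exp(stats::rnorm(length(bad) * n_cell_types, 2, 1))
    }

    list(tss = tss, genes = gene_body, peaks = peaks, loops = loops,
         motif_hits = hits,
         profiles = list(gene_rpkm = gene_rpkm, peak_rpkm = peak_rpkm),
         truth = list(proximal = truth_prox, loop = truth_loop,
                      correlated = truth_corr, nearest = truth_nearest,
                      motif_peaks = motif_peaks))
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats the readers consume: MTX + name files per modality
#' and a cell metadata TSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_feature_matrix(cohort$rna, p("rna.mtx"), p("rna_cells.txt"),
                       p("rna_features.txt"))
  write_feature_matrix(cohort$atac, p("atac.mtx"), p("atac_cells.txt"),
                       p("atac_features.txt"))
  write_cells(cohort$cells, p("cells.tsv"))
  invisible(c(p("rna.mtx"), p("atac.mtx"), p("cells.tsv")))
}
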