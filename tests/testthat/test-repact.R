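test_that("pseudo-index is monotone in a perfectly separating component", {
  withr::with_seed(2, {
    x <- cbind(c(rnorm(30, -4), rnorm(30, 4)), matrix(rnorm(60 * 4), 60, 4))
  })
  rownames(x) <- paste0("c", 1:60)
  y <- setNames(rep(c(0, 1), each = 30), rownames(x))
  m1 <- fit_trajectory(x, y, components = 1)
  expect_equal(abs(cor(m1$pseudo_index, x[, 1], method = "spearman")), 1)
  m <- fit_trajectory(x, y, components = 1:5)
  expect_gt(abs(cor(m$pseudo_index, x[, 1], method = "spearman")), 0.99)
  expect_true(all(m$fitted_prob >= 0 & m$fitted_prob <= 1))
  expect_error(fit_trajectory(x, setNames(rep(1, 60), rownames(x))),
               "both phenotype classes")
})

test_that("pseudo-index ranking is invariant to affine component rescaling", {
  withr::with_seed(14, {
    x <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(paste0("c", 1:80), NULL))
    y <- setNames(rbinom(80, 1, 0.5), rownames(x))
  })
  m1 <- fit_trajectory(x, y, components = 1:4, ridge = 1e-4)
  x2 <- sweep(sweep(x, 2, c(2, 0.5, 3, 10), `*`), 2, c(1, -2, 0, 5), `+`)
  m2 <- fit_trajectory(x2, y, components = 1:4, ridge = 1e-4)
  expect_equal(cor(m1$pseudo_index, m2$pseudo_index, method = "spearman"), 1,
               tolerance = 1e-6)
})

test_that("pseudo-index AUC against independent labels is near chance", {
  aucs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      x <- matrix(rnorm(4000 * 10), 4000, 10,
                  dimnames = list(paste0("c", 1:4000), NULL))
      y <- setNames(rbinom(4000, 1, 0.5), rownames(x))
    })
    m <- fit_trajectory(x, y)
    auc_of(m$pseudo_index, y[names(m$pseudo_index)])
  }, numeric(1))
  expect_true(all(aucs > 0.45 & aucs < 0.55))
})

test_that("disease cells score higher than healthy cells on default cohorts", {
  co <- small_cohort()
  pca <- pca_embed(co$rna, select_informative_genes(co$rna, 100))
  ph <- setNames(as.character(co$cells$phenotype), co$cells$cell_id)
  m <- fit_trajectory(pca, ph)
  expect_gt(mean(m$pseudo_index[ph == "disease"]),
            mean(m$pseudo_index[ph == "healthy"]))
})

test_that("equal-width binning matches brute-force interval assignment", {
  idx <- setNames(seq(0, 1, length.out = 21), paste0("c", 1:21))
  b <- bin_by_index(idx, 20)
  expect_equal(b$edges, seq(0, 1, by = 0.05))
  idx2 <- setNames(c(0, 0.1, 0.2, 0.3, 0.4, 0.5), paste0("c", 1:6))
  b2 <- suppressWarnings(bin_by_index(idx2, 3))
  # brute force: width 1/6 over [0, 0.5]; right-half-open bins
  brute <- pmin(floor((idx2 - 0) / (0.5 / 3)) + 1, 3)
  expect_equal(b2$bin_of_cell, setNames(as.integer(brute), names(idx2)))
  # interior edge value goes right
  b3 <- suppressWarnings(bin_by_index(c(a = 0, b = 0.5, c = 1), 2))
  expect_equal(unname(b3$bin_of_cell["b"]), 2L)
  expect_error(bin_by_index(rep(1, 5)), "constant")
})

test_that("trend test handles constant and exactly linear features", {
  idx <- setNames(seq(0, 1, length.out = 200), paste0("c", 1:200))
  bins <- bin_by_index(idx, 20)
  m <- cbind(flat = rep(5, 200), lin = 3 * idx + 1)
  rownames(m) <- names(idx)
  res <- feature_trend_test(m, bins)
  expect_equal(res$slope[res$feature == "flat"], 0)
  expect_equal(res$p[res$feature == "flat"], 1)
  # bin means of an exactly linear feature regress to the generating slope
  # (up to the bin-center vs within-bin-mean offset) with a vanishing p
  expect_equal(res$slope[res$feature == "lin"], 3, tolerance = 1e-2)
  expect_lt(res$p[res$feature == "lin"], 1e-10)
})

test_that("trend slopes and p-values match an independent lm oracle", {
  withr::with_seed(6, {
    idx <- setNames(c(rnorm(150), rnorm(50, 2)), paste0("c", 1:200))
    m <- matrix(rpois(200 * 25, 6), 200, 25,
                dimnames = list(names(idx), paste0("g", 1:25)))
  })
  bins <- bin_by_index(idx, 20)
  res <- feature_trend_test(m, bins)
  keep <- bins$cells_per_bin > 0
  w <- bins$cells_per_bin[keep]
  x <- bins$bin_value[keep]
  for (g in c("g1", "g7", "g25")) {
    prof <- tapply(m[, g], bins$bin_of_cell, mean)
    fit <- summary(lm(prof ~ x, weights = w))
    expect_equal(res$slope[res$feature == g], unname(coef(fit)[2, 1]),
                 tolerance = 1e-10)
    expect_equal(res$p[res$feature == g], unname(coef(fit)[2, 4]),
                 tolerance = 1e-10)
  }
})

test_that("reversing phenotype labels negates every slope exactly", {
  co <- small_cohort()
  pca <- pca_embed(co$rna, select_informative_genes(co$rna, 100))
  ph <- setNames(as.integer(co$cells$phenotype == "disease"),
                 co$cells$cell_id)
  m1 <- fit_trajectory(pca, ph)
  m2 <- fit_trajectory(pca, setNames(1L - ph, names(ph)))
  r1 <- feature_trend_test(co$rna, bin_by_index(m1$pseudo_index))
  r2 <- feature_trend_test(co$rna, bin_by_index(m2$pseudo_index))
  expect_equal(r1$slope, -r2$slope, tolerance = 1e-8)
  # gain/loss peak sets swap under label reversal
  a1 <- feature_trend_test(co$atac, bin_by_index(m1$pseudo_index),
                           scale = "zscore", q_cut = 0.01)
  a2 <- feature_trend_test(co$atac, bin_by_index(m2$pseudo_index),
                           scale = "zscore", q_cut = 0.01)
  c1 <- call_trajectory_peaks(a1)
  c2 <- call_trajectory_peaks(a2)
  expect_setequal(c1$gain, c2$loss)
  expect_setequal(c1$loss, c2$gain)
})

test_that("gene and peak calls use strict thresholds", {
  res <- data.frame(feature = c("a", "b", "c"), slope = c(1, -1, 2),
                    p = c(0.001, 0.001, 0.04), q = c(0.05, 0.01, 0.049))
  g <- call_trajectory_genes(res, q_cut = 0.05)
  expect_false("a" %in% c(g$up, g$down))  # q exactly at the cut
  expect_equal(g$up, "c")
  expect_equal(g$down, "b")
  pres <- data.frame(feature = c("p1", "p2", "p3"),
                     slope = c(0.5, 0.51, -0.6),
                     p = 1e-6, q = c(1e-5, 1e-5, 1e-5))
  pk <- call_trajectory_peaks(pres)
  expect_false("p1" %in% pk$gain)  # slope exactly at the cut
  expect_equal(pk$gain, "p2")
  expect_equal(pk$loss, "p3")
})

test_that("motif trend test recovers a noise-free linear deviation", {
  idx <- setNames(seq(-2, 2, length.out = 300), paste0("c", 1:300))
  bins <- bin_by_index(idx, 20)
  # deviation exactly linear in the bin value, so the recovered slope is the
  # generating coefficient
  z <- cbind(m_flat = rep(0.3, 300),
             m_lin = -1.7 * bins$bin_value[bins$bin_of_cell])
  rownames(z) <- names(idx)
  res <- motif_trend_test(z, bins)
  expect_equal(res$slope[res$feature == "m_flat"], 0)
  expect_equal(res$slope[res$feature == "m_lin"], -1.7, tolerance = 1e-6)
  # permuting cells within bins leaves results unchanged
  perm <- unlist(lapply(split(seq_along(idx), bins$bin_of_cell), sample))
  res2 <- motif_trend_test(z[perm, ], bins)
  expect_equal(res2$slope, res$slope, tolerance = 1e-12)
})

test_that("q-values reduce to BH at pi0 = 1 and behave at the edges", {
  expect_equal(qvalues(0.037), 0.037)   # single p
  expect_equal(qvalues(rep(1, 10)), rep(1, 10))
  withr::with_seed(3, p <- runif(200))
  expect_equal(qvalues(p, method = "bh"), p.adjust(p, "BH"),
               tolerance = 1e-12)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))  # pi0 <= 1
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("trajectory model JSON round-trips", {
  d <- withr::local_tempdir()
  withr::with_seed(4, {
    x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(paste0("c", 1:40),
                                                      NULL))
    y <- setNames(rep(c(0, 1), 20), rownames(x))
  })
  m <- fit_trajectory(x, y, components = 1:3)
  bins <- bin_by_index(m$pseudo_index, 5)
  write_trajectory_model(m, file.path(d, "m.json"), bins)
  back <- read_trajectory_model(file.path(d, "m.json"))
  expect_equal(back$pseudo_index, m$pseudo_index, tolerance = 1e-12)
  expect_equal(unname(back$coefficients), unname(m$coefficients),
               tolerance = 1e-12)
  expect_equal(back$bin_edges, bins$edges, tolerance = 1e-12)
})

test_that("donor-permutation gate passes signal cohorts and is calibrated", {
  co <- generate_cohort(cohort_config(
    n_donors_healthy = 4, n_donors_disease = 4, cells_per_donor = 80,
    n_genes = 300, n_peaks = 80, n_intra_features = 30,
    n_inter_features = 30, seed = 17L))
  pca <- pca_embed(co$rna, select_informative_genes(co$rna, 100))
  g <- trajectory_phenotype_test(pca, co$cells)
  expect_true(g$exact)
  # observed labeling (and its complement) are the most extreme of the 70
  expect_equal(g$p_value, 2 / 70, tolerance = 1e-12)
  # scrambling donor phenotypes removes the donor-level association
  cells2 <- co$cells
  donors <- unique(cells2$donor_id)
  relab <- setNames(rep(c("healthy", "disease"), 4), donors)
  cells2$phenotype <- factor(relab[cells2$donor_id],
                             levels = c("healthy", "disease"))
  g2 <- trajectory_phenotype_test(pca, cells2)
  expect_gt(g2$p_value, 0.05)
})
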