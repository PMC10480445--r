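# shared fixtures: everything is generated in code at test time

# small cohort used by several unit tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(
        n_donors_healthy = 3, n_donors_disease = 3, cells_per_donor = 120,
        n_genes = 300, n_peaks = 300, n_intra_features = 30,
        n_inter_features = 30, seed = 11L))
    cache
  }
})

# tiny labeled embedding: two well-separated Gaussian clusters
two_cluster_embedding <- function(n_per = 40, d = 5, sep = 10, seed = 3) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * d), n_per, d)
    b <- matrix(rnorm(n_per * d), n_per, d)
    b[, 1] <- b[, 1] + sep
    coords <- rbind(a, b)
    rownames(coords) <- paste0("c", seq_len(2 * n_per))
    list(coords = coords,
         labels = setNames(rep(c("A", "B"), each = n_per),
                           rownames(coords)))
  })
}

# in-sample AUC of a score against binary labels
auc_of <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

expect_same_links <- function(links, truth_df, cols = c("peak", "gene")) {
  got <- links[do.call(order, links[cols]), cols, drop = FALSE]
  want <- truth_df[do.call(order, truth_df[cols]), cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
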