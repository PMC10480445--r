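toy <- generate_toy_regulome(n_genes = 8, n_peaks = 20, n_loops = 5,
                             seed = 33)

test_that("pseudo-bulk RPKM follows the definition and its invariances", {
  m <- matrix(c(10, 0, 5, 3), 2, 2,
              dimnames = list(c("c1", "c2"), c("pk1", "pk2")))
  # force a clean arithmetic case: one cell type with 1 kb peak, pk1 takes
  # 10 of the type's reads; scale totals to 1e6 via a filler peak
  big <- cbind(m, filler = c(1e6 - 15, 0))  # c1 totals exactly 1e6
  pb <- pseudobulk_rpkm(FeatureMatrix(big, kind = "peak"),
                        c(c1 = "A", c2 = "B"),
                        c(pk1 = 1000, pk2 = 1000, filler = 1000))
  expect_equal(unname(pb$rpkm["pk1", "A"]), 1e9 * 10 / (1000 * 1e6))
  # doubling every count of a type leaves its column unchanged
  big2 <- big; big2["c2", ] <- big2["c2", ] * 2
  pb2 <- pseudobulk_rpkm(FeatureMatrix(big2, kind = "peak"),
                         c(c1 = "A", c2 = "B"),
                         c(pk1 = 1000, pk2 = 1000, filler = 1000))
  expect_equal(pb2$rpkm[, "B"], pb$rpkm[, "B"])
  # feature absent from a type has RPKM zero
  expect_equal(unname(pb$rpkm["pk1", "B"]), 0)
  expect_error(pseudobulk_rpkm(FeatureMatrix(big, kind = "peak"),
                               c(c1 = "A", c2 = "B"),
                               c(pk1 = 0, pk2 = 1000, filler = 1000)),
               "length")
})

test_that("peak specificity ratio classifies with strict 2 / 0.5 cuts", {
  rpkm <- rbind(pk_endo = c(10, 2, 4, 1), pk_comm = c(4, 1, 4, 2),
                pk_non = c(1, 0.5, 10, 8), pk_zero = c(1, 0.2, 0, 0))
  colnames(rpkm) <- c("beta", "alpha", "acinar", "duct")
  pb <- structure(list(rpkm = rpkm), class = "PseudoBulk")
  cls <- classify_peak_specificity(pb, c("beta", "alpha"),
                                   c("acinar", "duct"))
  expect_equal(cls$class,
               c("endocrine", "common", "non_endocrine", "endocrine"))
  # arithmetic: (10 + 0.01) / (4 + 0.01) = 2.497...
  expect_equal(cls$ratio[1], 10.01 / 4.01, tolerance = 1e-12)
  # partition: disjoint and exhaustive
  expect_true(all(cls$class %in% c("endocrine", "non_endocrine", "common")))
  equal_pb <- structure(list(rpkm = rbind(pk = c(3, 1, 3, 1))[,
    , drop = FALSE]), class = "PseudoBulk")
  colnames(equal_pb$rpkm) <- colnames(rpkm)
  expect_equal(classify_peak_specificity(equal_pb, c("beta", "alpha"),
                                         c("acinar", "duct"))$class, "common")
})

test_that("k-means recovers duplicated prototypes and is seed-stable", {
  proto <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  x <- proto[rep(1:3, each = 6), ] + 0.01 * matrix(sin(1:54), 18, 3)
  rownames(x) <- paste0("pk", 1:18)
  colnames(x) <- c("t1", "t2", "t3")
  cl <- kmeans_peak_clusters(x, k = 3, seed = 2)
  expect_equal(length(unique(cl)), 3L)
  expect_true(all(tapply(cl, rep(1:3, each = 6), function(v)
    length(unique(v))) == 1))
  expect_identical(cl, kmeans_peak_clusters(x, k = 3, seed = 2))
  expect_equal(unique(kmeans_peak_clusters(x, k = 1, seed = 2)), 1L)
})

test_that("motif enrichment equals the exact binomial summation", {
  background <- paste0("pk", 1:1000)
  foreground <- paste0("pk", 1:20)
  hit_peaks <- paste0("pk", c(1:8, 101:192))   # 8/20 fg, 100/1000 bg
  hits <- data.frame(motif_id = "M1", peak_id = hit_peaks, start = 1,
                     stop = 10, score = 10, p_value = 1e-8)
  res <- motif_enrichment(hits, foreground, background)
  # oracle: direct summation of the binomial upper tail
  oracle <- sum(choose(20, 8:20) * 0.1^(8:20) * 0.9^(20 - (8:20)))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$observed, 8L)
  expect_equal(res$background_freq, 0.1)
})

test_that("motif enrichment edge cases behave", {
  background <- paste0("pk", 1:100)
  hits <- data.frame(motif_id = "M1", peak_id = paste0("pk", 1:50),
                     start = 1, stop = 5, score = 1, p_value = 1e-8)
  # foreground frequency equal to background -> p >= 0.5
  res <- motif_enrichment(hits, paste0("pk", seq(1, 100, 2)), background)
  expect_gte(res$p, 0.5)
  ghost <- data.frame(motif_id = "M2", peak_id = "nowhere", start = 1,
                      stop = 5, score = 1, p_value = 1e-8)
  expect_warning(r2 <- motif_enrichment(rbind(hits, ghost),
                                        paste0("pk", 1:10), background),
                 "absent from the background")
  expect_equal(r2$term, "M1")
  expect_error(motif_enrichment(hits, character(0), background), "empty")
})

test_that("gene-set enrichment matches arithmetic and ranks by q", {
  universe <- paste0("g", 1:100)
  sets <- list(ALL = paste0("g", 1:10), NONE = paste0("g", 90:99))
  genes <- paste0("g", 1:10)
  res <- geneset_enrichment(genes, sets, universe)
  expect_equal(res$p[res$term == "ALL"], 0.1^10, tolerance = 1e-12)
  expect_equal(res$term[1], "ALL")  # ranked by q
  expect_equal(res$observed[res$term == "NONE"], 0L)
  expect_error(geneset_enrichment("not_in_universe", sets, universe),
               "subset")
})

test_that("random query genes are rarely enriched anywhere", {
  universe <- paste0("g", 1:500)
  withr::with_seed(41, {
    sets <- lapply(1:50, function(i) sample(universe, 25))
    names(sets) <- paste0("S", 1:50)
    hits <- vapply(1:10, function(s) {
      genes <- sample(universe, 20)
      min(geneset_enrichment(genes, sets, universe, q_method = "bh")$q)
    }, numeric(1))
  })
  expect_gte(sum(hits >= 0.05), 9)
})

test_that("proximity linking matches interval arithmetic and the boundary", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 1000),
                      end = c(1500, 5000), id = c("pkA", "pkB"))
  tss <- data.frame(gene = c("gIn", "gEdge", "gFar"), chrom = "chr1",
                    tss = c(1200, 15000, 16000), strand = "+")
  links <- link_proximal(peaks, tss)
  # containment -> distance 0; 10 kb gap is linked inclusively
  expect_equal(links$distance[links$peak == "pkA" & links$gene == "gIn"], 0)
  expect_true(any(links$peak == "pkB" & links$gene == "gEdge" &
                    links$distance == 10000))
  expect_false(any(links$gene == "gFar"))
})

test_that("toy-regulome proximal, nearest and loop links equal planted truth", {
  expect_same_links(link_proximal(toy$peaks, toy$tss), toy$truth$proximal)
  expect_same_links(link_nearest(toy$peaks, toy$tss), toy$truth$nearest)
  got_loops <- link_by_loops(toy$peaks, toy$tss, toy$loops)
  expect_same_links(got_loops, toy$truth$loop)
  expect_setequal(got_loops$loop_id, toy$truth$loop$loop_id)
})

test_that("loop linking is symmetric in anchor order and empty-safe", {
  swapped <- toy$loops
  names(swapped)[1:6] <- c("chrom_b", "start_b", "end_b", "chrom_a",
                           "start_a", "end_a")
  swapped <- swapped[, names(toy$loops)]
  a <- link_by_loops(toy$peaks, toy$tss, toy$loops)
  b <- link_by_loops(toy$peaks, toy$tss, swapped)
  expect_same_links(b, a)
  expect_equal(nrow(link_by_loops(toy$peaks, toy$tss, toy$loops[0, ])), 0L)
})

test_that("correlation linking recovers exactly the planted profile pairs", {
  links <- link_by_correlation(toy$profiles$peak_rpkm,
                               toy$profiles$gene_rpkm, toy$peaks, toy$tss)
  expect_same_links(links, toy$truth$correlated)
  expect_true(all(links$r > 0.7))
  # hand-computed Pearson on one planted pair
  pr <- toy$truth$correlated[1, ]
  x <- toy$profiles$peak_rpkm[pr$peak, ]
  y <- toy$profiles$gene_rpkm[pr$gene, ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(links$r[links$peak == pr$peak & links$gene == pr$gene],
               r_hand, tolerance = 1e-12)
})

test_that("far peaks yield no correlation candidates", {
  peaks <- data.frame(chrom = "chr1", start = 5e6, end = 5e6 + 400,
                      id = "pkFar")
  pm <- matrix(1:7, 1, 7, dimnames = list("pkFar", paste0("type", 1:7)))
  gm <- toy$profiles$gene_rpkm
  links <- link_by_correlation(pm, gm, peaks, toy$tss)
  expect_equal(nrow(links), 0L)
})

test_that("circuits attach trajectory peaks through proximal/loop modes only", {
  gene_calls <- list(up = c("gene001", "gene002"), down = "gene003")
  prox <- toy$truth$proximal
  # trajectory peaks: only those at gene001/gene002 promoters, so gene003
  # is reachable solely through the correlation-mode row below
  peak_calls <- list(gain = prox$peak[prox$gene %in% c("gene001", "gene002")],
                     loss = character(0))
  links <- rbind(link_proximal(toy$peaks, toy$tss)[
    , c("peak", "gene", "mode")],
    data.frame(peak = peak_calls$gain[1], gene = "gene003",
               mode = "correlation"))
  edges <- circuit_table(gene_calls, peak_calls, links)
  expect_true(all(edges$mode == "proximal"))
  expect_false("gene003" %in% edges$gene)   # correlation does not explain
  expect_setequal(unique(edges$gene), c("gene001", "gene002"))
})

test_that("every gene with a planted promoter trajectory peak is explained", {
  gene_calls <- list(up = unique(toy$truth$proximal$gene),
                     down = character(0))
  peak_calls <- list(gain = toy$truth$proximal$peak, loss = character(0))
  links <- link_proximal(toy$peaks, toy$tss)
  edges <- circuit_table(gene_calls, peak_calls, links)
  expect_setequal(unique(edges$gene), unique(toy$truth$proximal$gene))
  expect_equal(nrow(edges), nrow(toy$truth$proximal))
})

test_that("category enrichment matches a hypergeometric summation oracle", {
  # gene universe of 20: 10 in category X; linked set chosen so the 2x2
  # table is [[8, 2], [1, 9]]
  gene_categories <- setNames(rep(c("X", "Y"), each = 10), paste0("g", 1:20))
  peak_categories <- setNames("P", "pk1")
  edges <- data.frame(gene = paste0("g", c(1:8, 11)), peak = "pk1",
                      mode = "proximal")
  res <- category_enrichment(gene_categories, peak_categories, edges)
  # oracle: two-sided Fisher p by direct summation over the hypergeometric
  # 9 linked genes drawn from 10 category-X and 10 category-Y genes
  probs <- dhyper(0:9, 10, 10, 9)
  oracle <- sum(probs[probs <= dhyper(8, 10, 10, 9) * (1 + 1e-7)])
  expect_equal(res$p[res$gene_category == "X"], oracle, tolerance = 1e-12)
  expect_gt(res$odds_ratio[res$gene_category == "X"], 1)
  # balanced table gives OR 1, p 1
  edges2 <- data.frame(gene = paste0("g", c(1:5, 11:15)), peak = "pk1",
                       mode = "proximal")
  res2 <- category_enrichment(gene_categories, peak_categories, edges2)
  expect_equal(res2$p, c(1, 1))
})

test_that("TF target prediction returns exactly the planted reachable genes", {
  # trajectory peaks: motif-bearing peaks; trajectory genes: their genes
  motif_pk <- toy$truth$motif_peaks
  nearest <- link_nearest(toy$peaks, toy$tss)
  loops <- link_by_loops(toy$peaks, toy$tss, toy$loops)
  links <- rbind(nearest[, c("peak", "gene", "mode")],
                 loops[, c("peak", "gene", "mode")])
  targets_truth <- sort(unique(
    nearest$gene[nearest$peak %in% motif_pk]))
  res <- predict_tf_targets("MOTIF_A",
                            toy$motif_hits[toy$motif_hits$p_value <= 1e-6, ],
                            list(gain = motif_pk, loss = character(0)),
                            links,
                            list(up = targets_truth, down = character(0)))
  expect_setequal(unique(res$gene), targets_truth)
  expect_true(all(res$gene %in% targets_truth))  # always within trajectory
  # no hits in trajectory peaks -> empty
  none <- predict_tf_targets("MOTIF_A", toy$motif_hits[0, ],
                             list(gain = motif_pk, loss = character(0)),
                             links,
                             list(up = targets_truth, down = character(0)))
  expect_equal(nrow(none), 0L)
})

test_that("a gene reachable by nearest and loop evidence is deduplicated", {
  lp <- toy$truth$loop[1, ]
  links <- rbind(
    data.frame(peak = lp$peak, gene = lp$gene, mode = "nearest"),
    data.frame(peak = lp$peak, gene = lp$gene, mode = "loop"),
    data.frame(peak = lp$peak, gene = lp$gene, mode = "loop"))
  res <- predict_tf_targets(
    "MOTIF_A",
    data.frame(motif_id = "MOTIF_A", peak_id = lp$peak, start = 1, stop = 5,
               score = 1, p_value = 1e-9),
    list(gain = lp$peak, loss = character(0)), links,
    list(up = lp$gene, down = character(0)))
  expect_equal(nrow(res), 2L)   # one row per evidence mode, no duplicates
  expect_setequal(res$mode, c("nearest", "loop"))
})
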