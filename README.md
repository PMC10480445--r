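# repactools

Disease-trajectory regression and intra- vs inter-donor heterogeneity
decomposition for single-cell multiomics.

Case/control single-cell studies of complex disease — the motivating case
is type 2 diabetes in pancreatic islet β-cells — rarely find discrete
disease-specific subpopulations; instead, cells shift continuously along a
latent severity axis that is partly visible even within single donors.
`repactools` implements the RePACT approach to exploit that structure,
for both scRNA-seq and snATAC-seq, together with the surrounding analysis
stack: cell-level QC filters, embeddings and cross-modality label
transfer, peak–gene linking through chromatin loops, and a seeded
synthetic-cohort generator used to validate every stage offline.

## The method

For a cohort of donors with binary phenotype (healthy / disease):

1. **Trajectory.**  Embed cells (PCA of 500 informative genes for RNA;
   TF-IDF + LSI, 50 components, for ATAC) and fit a ridge-penalized
   logistic regression of the phenotype on components 1–10.  Each cell's
   **pseudo-index** β′x ranks it from healthy-like to disease-like.
   A donor-label permutation test establishes that the trajectory is
   phenotype-associated before any feature is called.
2. **Trajectory features.**  Group cells into 20 equal-width bins of
   pseudo-index; regress each feature's per-bin mean on the bin value
   (bins weighted by cell count); convert two-sided slope p-values to
   q-values.  Genes with q < 0.05 are trajectory genes; peaks with
   q < 0.01 and standardized |slope| > 0.5 gain or lose accessibility.
3. **Heterogeneity decomposition.**  Re-bin each donor's cells over its
   own index range, rerun the trend test per donor, and combine the
   per-donor p-values with Fisher's method
   (−2 Σ log pₖ ~ χ²(2k)).  Trajectory features with combined q < 0.01
   are **intra-donor heterogeneous** (the trend reproduces inside
   donors); the rest are **inter-donor**.  The heterogeneity score is
   −log₁₀(q), with the intra call at score > 2.

The regulome module then links trajectory peaks to genes (promoter
proximity ≤ 10 kb, loop anchors, or pseudo-bulk correlation r > 0.7
within 1 Mb), reconstructs gene–peak circuits, tests category enrichment
(two-sided Fisher's exact), scores motif and gene-set enrichment by exact
binomial tests, and predicts TF target genes from motif-bearing
trajectory peaks.

## Worked example

Everything below runs offline on a synthetic cohort with planted truth:

```r
library(repactools)

co <- generate_cohort(cohort_config(
  n_donors_healthy = 4, n_donors_disease = 4, cells_per_donor = 200,
  n_genes = 1000, n_intra_features = 80, n_inter_features = 80, seed = 42))

genes <- select_informative_genes(co$rna, 500)
pca   <- pca_embed(co$rna, genes)

gate  <- trajectory_phenotype_test(pca, co$cells)
sprintf("donor-level association p = %.3f", gate$p_value)
#> "donor-level association p = 0.029"

model <- fit_trajectory(pca, setNames(as.character(co$cells$phenotype),
                                      co$cells$cell_id))
bins  <- bin_by_index(model$pseudo_index)
res   <- feature_trend_test(co$rna, bins)
calls <- call_trajectory_genes(res)
sprintf("trajectory genes: %d up, %d down", length(calls$up),
        length(calls$down))
#> "trajectory genes: 80 up, 91 down"

dt  <- per_donor_trends(co$rna, model, co$cells)
het <- classify_heterogeneity(res, dt)
table(het$category)
#> inter_down   inter_up intra_down   intra_up
#>         51         40         40         40

head(het[order(-het$score), c("feature", "category", "score")], 3)
#>    feature   category    score
#> 28   g0028 intra_down 42.25557
#> 60   g0060 intra_down 42.25557
#> 55   g0055   intra_up 38.61410
```

The gate p-value of 0.029 is the smallest achievable with 4 + 4 donors
(the observed labeling and its complement are the most extreme of the 70
donor-label assignments), so the trajectory is phenotype-associated.  The
cohort planted 80 intra and 80 inter features; the decomposition recovers
the 80 intra features exactly (40 up + 40 down at score > 2) and assigns
the planted inter features — plus a handful of leaked nulls — to the
inter categories.  A matched ATAC run is identical in shape:
`tfidf_transform()` → `lsi_embed()` → `fit_trajectory()` →
`feature_trend_test(..., scale = "zscore")` → `call_trajectory_peaks()`.

A thin command-line wrapper over the same functions lives at
`inst/cli/repact-suite`:

```sh
Rscript inst/cli/repact-suite simulate embed repact-rna intra-donor \
        --outdir out/ --seed 3
```

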