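---
title: "Disease-trajectory regression and the intra-donor heterogeneity decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-trajectory regression and the intra-donor heterogeneity decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repactools)
```

# The model

`repactools` implements RePACT (Regressing Principal components for the
Assembly of Continuous Trajectory) for case/control single-cell cohorts.
The working assumption is that disease does not create a discrete cell
subpopulation but shifts cells continuously along a latent severity axis,
and that this axis is partly visible *within* every donor.  The method has
three stages:

1. **Trajectory fit.**  Cells are embedded in a low-dimensional space —
   PCA of the 500 most informative genes for scRNA-seq (`pca_embed()`),
   TF-IDF followed by LSI (truncated SVD, 50 components) for snATAC-seq
   (`tfidf_transform()`, `lsi_embed()`) — and the binary phenotype is
   regressed on the first ten components by ridge-penalized logistic
   regression (`fit_trajectory()`).  The per-cell *pseudo-index* is the
   model score; it ranks cells from healthy-like to disease-like.
2. **Binned trend tests.**  Cells are grouped into 20 equal-width bins of
   pseudo-index (`bin_by_index()`); for every feature the per-bin mean is
   regressed on the bin index value and the two-sided slope p-value is
   adjusted to q-values over all features (`feature_trend_test()`,
   `qvalues()`).  Genes with q < 0.05 are trajectory genes
   (`call_trajectory_genes()`); peaks with q < 0.01 and a standardized
   slope beyond ±0.5 are gain/loss peaks (`call_trajectory_peaks()`).
3. **Heterogeneity decomposition.**  For each donor separately, that
   donor's cells are re-binned over their own index range and the same
   trend test is run (`per_donor_trends()`).  Per-donor p-values are
   combined by Fisher's method, `-2 * sum(log p_k) ~ chi-squared(2k)`
   (`fisher_combine()`), and q-values of the combined p within the
   globally-called set split trajectory features into *intra-donor*
   heterogeneous (q < 0.01: the trend reproduces inside donors) versus
   *inter-donor* (`classify_heterogeneity()`); the heterogeneity score is
   `-log10(q)`, so the intra call corresponds to a score strictly above 2.

Downstream, the regulome module links trajectory peaks to genes by
promoter proximity (≤ 10 kb), chromatin loops (peak in one ~5-kb anchor,
TSS in the other) and cross-cell-type pseudo-bulk correlation (Pearson
r > 0.7 within 1 Mb), reconstructs gene–peak circuits, tests four-way
category enrichment by two-sided Fisher's exact tests, and predicts TF
targets from motif-bearing trajectory peaks.

# Design choices and their reasons

Several points are under-determined by the procedure sketched above; the
package resolves them as follows.

**The pseudo-index is the linear predictor, not the fitted probability.**
Both give the same cell ranking, but once the two phenotype classes are
nearly separable in the embedding — which happens whenever donor-level
signatures are strong — the fitted probability saturates at 0 and 1.
Equal-width bins of a saturated index collapse: most cells land in the two
extreme bins and the middle bins starve, destroying the power of the trend
regression.  On the linear scale the index stays continuous and all bins
are populated.  `index_type = "probability"` restores the bounded variant.

**Ridge strength defaults to `"auto"` (strong shrinkage).**  A nearly
unpenalized logistic fit on separable data converges to the direction with
the *least within-class variance*.  That is precisely the direction
dominated by features that differ between donors but are flat within them
— so the within-donor component of such an index is noise, and the
intra-donor decomposition degenerates (features without any within-donor
signal inherit a circular within-donor correlation with the index).
Strong shrinkage (`lambda` = 10 × the largest eigenvalue of the centered
component cross-product) pulls the direction toward the phenotype-centroid
axis, which weights within-donor severity variation properly.  Any
numeric `ridge` is accepted; `1e-4` reproduces a minimal
stability-only penalty.

**Bins are weighted by their cell count in the trend regression.**  The
regression's observations are bin means, whose sampling variance is
`sigma^2 / n_b`.  With thousands of cells per bin (the regime the 20-bin
design was built for) weighting is immaterial; at a few hundred cells per
donor the sparse tail bins otherwise carry both the highest leverage and
the highest variance, which makes the unweighted test anti-conservative —
about 22% of per-donor null p-values fall below 0.05, and Fisher's method
amplifies that into wholesale false intra calls.  `weights = "equal"`
restores the unweighted fit; the two coincide for equally filled bins.

**Feature calling is gated on a donor-level permutation test.**
Phenotype is a property of donors, not cells, and the trajectory direction
is estimated from the labeled cells themselves, so any cell-level test of
index–phenotype separation is circular.  `trajectory_phenotype_test()`
refits the trajectory under every reassignment of phenotype labels to
whole donors (exhaustive up to 1000 assignments, Monte-Carlo beyond) and
compares the observed donor-level separation (Welch t on per-donor mean
index) against that permutation distribution.  On cohorts without true
signal the test is calibrated and blocks downstream calling; on genuinely
disease-associated cohorts the observed labeling is the most extreme
assignment and the gate passes (p = 2/70 for a 4 + 4 cohort).  Note the
resolution limit: with fewer than 4 + 4 donors the smallest achievable
two-sided p exceeds 0.05.

**Multiple testing.**  Global feature calls use Storey q-values with a
smoothed pi0 estimate over a lambda grid (`qvalues()`), which reduces to
Benjamini–Hochberg when pi0 is forced to 1 (always the case for fewer
than 20 p-values).  The combined-p adjustment inside
`classify_heterogeneity()` defaults to BH instead: the globally-called set
is small and signal-enriched by construction, so a pi0 estimated from its
p-value tail is unstable and can collapse every q below the intra cut.
The adjustment universe is the called set (`q_universe = "called"`), i.e.
the population actually being classified; `"all"` is available.

**Other conventions.**  The RNA per-bin statistic is the mean raw
transcript count; `depth_normalize()` provides a counts-per-10k variant
for data whose index correlates with sequencing depth (on strongly
shifted cohorts the per-cell total itself tracks severity, so the
normalized statistic is not a free lunch — see its help page).  The ATAC
per-bin profile is z-scored per peak and regressed on bin values rescaled
to [0, 1], which makes the ±0.5 slope threshold scale-free.  Bin
assignment is half-open to the right, with the maximum in the last bin.
Zero-variance features get slope 0 and p 1 rather than NaN.  Per-donor
p-values enter Fisher's combination exactly as produced by the two-sided
test; `sign_consistent = TRUE` additionally requires the median per-donor
slope sign to match the global direction.  Donors contributing fewer than
5 non-empty bins are excluded from the combination (df shrinks to 2 × the
included donors).  The unambiguity score of the KNN doublet filter is
oriented as second-nearest-type over nearest-type mean distance (≥ 1,
larger = cleaner), so the cutoff of 10 keeps high-score cells.  The
"positive population" behind the hormone-doublet threshold is the set of
cells with nonzero counts for that hormone (a typed-population strategy is
available).  The snATAC gene-score matrix feeding the CCA co-embedding
sums peak counts over the gene body plus 2 kb upstream; this construction
is a stand-in convention and is flagged as such.  TF-IDF uses term
frequency by cell-depth division and `idf = log(1 + N/(1 + df))`.  LSI
component 1 is retained, and its correlation with cell depth is reported
(`depth_correlation`) so users can drop it.

# The synthetic cohort generator

`generate_cohort()` emulates the structure the decomposition is designed
to detect: donors carry a latent severity `b_d ~ N(delta * disease,
sigma_b^2)` (default shift 2.0, donor sd 0.5), cells add a within-donor
latent `u_c ~ N(0, 1)`, and features come in three classes — *intra*
features load on the full per-cell severity `s_c = b_d + u_c`, *inter*
features on `b_d` only, *null* features on nothing — with log-scale
effect 0.5 alternating in sign.  RNA counts are negative binomial (shape
5) around library-size-scaled means (log-normal libraries, geometric mean
5000, sd 0.3) with optional dropout; the normalizer of the relative
abundances is a population constant so that a null feature is genuinely
independent of severity given the library size.  ATAC entries are
`Binomial(2, plogis(a_p + c_p x))` — near-binary, diploid-like.  The
default cohort (4 + 4 donors × 400 cells, 2000 genes, 150 intra + 150
inter) mirrors a realistic islet study in donor count and matches the
planted-feature scale at which the validation suite runs.

What the generator does *not* emulate: batch effects, doublets, ambient
contamination, cell-type mixtures, realistic gene–gene correlation, or
chromatin biology; passing on synthetic cohorts therefore demonstrates
the statistical machinery, not robustness to those artifacts.
`generate_toy_regulome()` builds a single toy chromosome with genes at
50-kb spacing, promoter peaks within 10 kb of exactly one TSS, distal
peaks with unambiguous nearest genes, loops through 5-kb anchors, planted
motif hits and cell-type profiles in which exactly the planted peak–gene
pairs correlate — so every linker can be checked for exact recovery.

# Problem sizes and runtime

The validation suite runs 10 null cohorts and 3 signal cohorts at the
8-donor × 400-cell × 2000-feature scale (about a minute in total), the
trend-test oracle on 2000 features, and the combination/enrichment
oracles on 500–1000 random instances; `scripts/acceptance.R` recomputes
all of it from scratch under a caller-supplied seed.

# Known limitations

* Only binary phenotypes are supported (no continuous-trait regression).
* The permutation gate needs ≥ 4 donors per group to resolve p < 0.05.
* Features used to build the embedding are circularly associated with the
  index; under a global null this inflates their trend calls, which is
  why calling is gated rather than left to per-feature q-values alone.
* Raw-count bin means conflate severity with sequencing depth if the two
  correlate; inspect `depth_correlation` and consider
  `depth_normalize()`.
* chromVAR-style motif deviations and FIMO scans are consumed, never
  computed.
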