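---
title: "Methods: discovery, validation and copy-number characterization of tumor expression subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery, validation and copy-number characterization of tumor expression subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

subtypeforge implements an integrated workflow for molecular subtyping of
bulk tumor cohorts: unsupervised discovery of expression subtypes, a
statistical check that the discovered clusters are not artifacts of
high-dimensional noise, a portable nearest-centroid classifier for
transferring subtypes to external cohorts, and a permutation framework for
linking subtypes to recurrent DNA copy-number aberrations, genomic
instability, clinical covariates and survival. This vignette documents the
models, the tunable parameters, and the design decisions taken where the
underlying methods leave choices open.

## Synthetic cohorts and what they stand for

All tests and the reproduction script run on synthetic cohorts with known
ground truth, generated by `simulate_subtyped_expression()`,
`simulate_copy_number_cohort()` and `simulate_clinical_outcomes()` from a
single `sim_config()`.

The expression model is deliberately minimal: gene-wise independent
Gaussian noise (`noise_sd`, log2 units) with a constant mean shift
(`effect_size`) added to each informative gene in exactly one subtype.
This is precisely the structure that correlation-based clustering assumes,
so recovery results on these cohorts measure the machinery, not model
mismatch. The defaults emulate a cohort of 138 samples by 15597 genes with
four subtypes, 50 informative genes per subtype, an effect of 2 noise SDs
— the regime in which consensus clustering should recover planted labels
essentially perfectly, which the test suite verifies (adjusted Rand index
at least 0.9).

The copy-number model places equally spaced markers on a configurable
multi-chromosome genome and adds rectangular gain/loss events (amplitude
in log2 units) to a random `carrier_fraction` of the samples in the
affected subtypes, over independent Gaussian marker noise. The clinical
model draws categorical covariates from subtype-conditional probability
tables and recurrence-free survival from per-subtype exponential hazards
with independent censoring: with probability `censoring_rate` a subject is
censored uniformly before its event time, so a rate of 1 yields a cohort
with no events.

What the generators do **not** emulate: gene-gene correlation, batch and
platform effects, probe-level artifacts, heavy-tailed noise, segmental
marker spacing, purity/ploidy distortion, and non-exponential hazards.
Passing tests therefore demonstrate correctness of the algorithms under
their stated assumptions, not robustness to every pathology of real
arrays. One shared seed expands into independent child seeds per
generator, so adding a downstream generator call never perturbs earlier
draws.

## Preprocessing

Expression values are gene median centered (`median_center_genes()`,
idempotent, exact row medians of 0) and restricted to the most variable
genes by unscaled median absolute deviation (`gene_mad()`,
`select_top_variable_genes()`, default 2500 genes). The MAD deliberately
omits the 1.4826 Gaussian consistency factor: only the ranking matters for
selection and rescaling is rank-invariant. Ties at the selection boundary
are broken by lexicographic gene id so results are platform-independent.
Because the MAD is translation invariant, it is irrelevant whether
variability is computed before or after centering.

## Consensus clustering and model selection

`consensus_cluster()` draws `n_resamples` (default 1000) subsamples of
`item_fraction` (default 0.8) of the samples without replacement,
hierarchically clusters each subsample with distance 1 − Pearson
correlation, and cuts at every k in `k_range`. Only samples are resampled;
all genes participate in every draw. The consensus entry for a sample pair
is its co-clustering count divided by its co-draw count; a pair never
co-drawn is an error instructing more resamples rather than a silent NA.
Average linkage is used both within resamples and for the final clustering
of 1 − consensus, the default of the consensus approach this follows;
both are configurable. Samples with zero variance have no defined
correlation and are rejected by name.

Model selection (`select_k()`) reports the area under the consensus CDF
per k and its relative change (delta-area). The recommended k is the last
k before the delta-area first drops below the threshold (default 0.05):
once adding a (k+1)-th cluster no longer improves co-clustering stability,
k was sufficient. The threshold codifies what is usually a visual
judgement; it is a package default, not an estimated quantity. Because
unstructured data can also produce small delta-areas, the recommendation
carries a stability flag: if the proportion of ambiguous consensus entries
(between 0.1 and 0.9; PAC) at the recommended k exceeds 0.4, the
recommendation is flagged unstable — single-Gaussian data reliably trip
this flag in the test suite. A tracking count reports how many samples
change cluster between consecutive k after greedily matching each
k-cluster to its dominant (k+1)-cluster.

## Cluster significance

`sigclust_pvalue()` asks whether a two-group split could have arisen from
a single Gaussian. The statistic is the cluster index: the within-cluster
sum of squares about the two cluster means over the total sum of squares
about the grand mean, summed over genes (rotation and translation
invariant; defined as 0 for degenerate zero-variance data). The null is a
d-dimensional Gaussian whose covariance eigenvalues are the sample
covariance eigenvalues hard-thresholded from below at a background noise
variance estimated as the squared MAD of all matrix entries (Gaussian
consistency constant applied). Each of `n_sim` (default 1000) simulated
datasets of the observed dimensions is reduced to its minimal cluster
index over 2-means with 10 seeded restarts, and the add-one estimator
p = (1 + #{null CI ≤ observed CI}) / (1 + n_sim) is reported, so p is
never 0 and never below 1/(1+n_sim). `sigclust_all_pairs()` runs every
unordered subtype pair with independent child seeds and Bonferroni-adjusts
over the K(K−1)/2 tests (6 tests for four subtypes).

A property worth stating plainly: this test is **conservative**. The
hard-thresholded plug-in spectrum stochastically dominates the data's
realized spectrum — the leading empirical eigenvalues are inflated
relative to their population values, and the sub-threshold tail is raised
to the noise floor — so simulated null data are at least as "clusterable"
as the observed sample and null cluster indices sit below the observed one
more often than chance. Under a pure single-Gaussian null the p-values
therefore pile up toward 1 and the rejection rate at any α falls below
nominal, across every dimension regime we examined. The package's property
tests assert exactly this one-sided validity (never anti-conservative);
genuinely separated groups still saturate the statistic at the minimal
attainable p. Users should read large p-values as "no evidence against one
Gaussian", not as a calibrated error rate.

## Core samples and the balanced centroid classifier

Consensus clustering labels every sample, including ambiguous ones.
`silhouette_core_samples()` computes silhouette widths under 1 − Pearson
distance on the variable-gene matrix and retains samples with strictly
positive width as the training core. The metric choice mirrors the
clustering metric; classes of size one have no intra-class distance and
are rejected by name.

`train_nearest_centroid_classifier()` scores every gene for every class
with a moderated class-versus-overall statistic
t. = (class mean − overall mean) / (pooled within-class SD + s0), with
s0 fixed at the median pooled SD. Each gene is assigned to the class
maximizing |t|, which makes the per-class lists disjoint by construction,
and each class keeps its top `genes_per_class` genes. When a grid is
supplied (default {50, 100, 150, 210, 300}), seeded stratified
cross-validation (default 5-fold) picks the gene count minimizing
misclassification; 210 genes per class on four classes yields the
840-gene configuration used throughout the examples. Centroids are
per-class per-gene **medians** over core samples. Prediction
(`predict_subtypes()`) assigns the class with minimal 1 − Pearson
distance between the sample and the centroid over the classifier genes,
matching the metric used everywhere else in the workflow rather than a
discriminant rule; missing genes are dropped pairwise with a hard floor of
50% coverage, and ties break by class order.

Two transfer modes serve different external data:

* `harmonize_external()` z-scores each classifier gene in the external
  cohort and rescales to the stored training mean/SD; the harmonized
  matrix reproduces those moments to numerical precision (asserted at
  1e-9), after which ordinary prediction applies. Zero-variance external
  genes cannot be rescaled and are dropped with a warning.
* `standardize_and_predict()` median-centers and unit-scales both the
  centroids and the external data per gene before assignment, for
  sequencing-style data whose per-gene location and scale are not
  comparable to arrays; labels are invariant to per-gene affine changes in
  the external cohort.

`cross_study_validate()` restricts two labelled cohorts to shared genes
(floor 100), median-centers each separately, and reports 1 − Pearson
distances between all cross-study centroid pairs; concordant subtypes
appear as row minima on the diagonal.

## Copy-number analysis

Marker-level log2 profiles are imputed from the genomically nearest
non-missing marker on the same chromosome (equidistant ties resolve to the
upstream marker), then smoothed and median centered per sample:
single-marker outliers deviating from a running median (window 5) by more
than 3 MAD-based residual scales are shrunk to the running median, and
each profile is centered to median 0. Window and threshold are codified
defaults for "smoothing and outlier removal"; both are arguments.

Recurrent aberrations are tested with a cyclic-shift permutation test
(`cyclic_shift_peak_test()`): the observed statistic is the maximum (gains)
or minimum (losses) over markers of the cross-sample sum; each null
replicate rotates every sample's genome-wide vector by an independent
uniform offset, preserving serial autocorrelation while destroying
cross-sample locus alignment. The add-one estimator over `n_perm`
(default 250) shifts gives p ≥ 1/(1+n_perm), and the inclusive comparison
makes an all-zero cohort return exactly p = 1. Peaks are localized with a
bootstrap (`peak_confidence_interval()`, default 500 resamples, level
0.95): samples are resampled with replacement, the peak is re-found within
the observed peak's chromosome (restricting to the chromosome avoids
cross-chromosome quantile artifacts), and the CI spans the α/2 and
1 − α/2 quantiles of the bootstrap peak positions, always containing the
observed peak. `peel_and_repeat()` removes each detected peak's signal —
in every carrier sample, the contiguous run around the peak that stays
above (below) the centered background is reset to the sample's chromosome
median — and re-tests, exposing up to `n_peaks` independent events, each
reported with the p-value of its own round.

Segmentation (`segment_profiles()`) is a plumbing component: recursive
binary splitting at the breakpoint maximizing the two-sample t statistic.
Because that statistic is a maximum over all candidate positions, the
acceptance rule uses the Bonferroni-adjusted p-value
(p × number of candidates < α, default α = 0.01, minimum segment 3
markers); with the naive per-split p-value the segmenter over-segments
noise badly, which the breakpoint-recovery tests demonstrate. Segments
partition every chromosome.

Gene-level copy number is the mean of segmented values at markers inside
the gene plus one nearest flanking marker per side ("immediately
adjacent" is interpreted as one flank, configurable to none); genes more
than 1 Mb from any marker are an error. Calls use the conventional
±0.35 log2 threshold with strict inequalities (a value of exactly 0.35 is
neutral), applied to segments of median-centered profiles — the same
representation used for peak detection. The chromosomal instability index
is the median over chromosome arms of the arm-wise median absolute
segmented value: a per-sample genome disruption score that is 0 for a flat
genome and scales linearly with amplitude. Subtype association of a
detected region (`region_subtype_association()`) averages each sample's
centered values over the region's markers and applies the Kruskal-Wallis
rank test, with an optional Bonferroni adjustment over the number of
regions examined.

## Association statistics

* **Fisher tests.** `fisher_exact_rxc()` computes the exact two-sided
  p-value by the network algorithm under the "probability ≤ observed"
  convention; tables beyond the enumeration budget raise an error naming
  `fisher_monte_carlo()`, which samples margin-fixed tables and applies
  the add-one estimator (default 100,000 tables, seeded, Monte-Carlo
  standard error reported).
* **Kruskal-Wallis.** Tie-corrected H against chi-squared with
  (groups − 1) df; invariant to monotone transformations; all-identical
  data return H = 0, p = 1 rather than NaN.
* **SAM-style differential expression.** `sam_two_class()` uses
  d = (mean₁ − mean₂)/(pooled SE + s0) with s0 = median pooled SE, and
  a label-permutation null. Calling follows the canonical
  order-statistic band: the ordered observed d are compared with their
  expected order statistics under the permutations, the cut points are
  the first statistics whose deviation reaches ±delta, and the smallest
  delta whose **median FDR** (median over permutations of the null count
  beyond the cuts, divided by the number called) stays at or below the
  threshold defines the called set. A simplified symmetric-|d| cutoff was
  considered and rejected: the top observed |d| exceeds the median
  permutation maximum half the time, so pure-null data would call one
  gene in half of all runs, while the band rule leaves null data with a
  median of zero calls. No π0 correction is applied (π0 ≈ 1 in the
  designed use, one subtype against the rest, is not guaranteed, so
  reported FDRs are mildly conservative). The delta search uses a grid of
  at most 300 quantiles of the observed deviations.
* **Survival.** `km_logrank()` wraps product-limit estimation and the
  log-rank test; cohorts with zero events are an explicit "no events"
  error. Missing categorical covariates are excluded per test
  (`subtype_contingency()`), never imputed, which is why published
  category counts need not sum to the cohort size.

## Determinism and problem sizes

Every stochastic component takes an explicit seed; workflow functions
expand one master seed into named child seeds per stage, so adding a stage
never changes another stage's draws, and a config plus seed reproduces a
run bit-for-bit (the manifest is asserted identical across repeated runs
in the tests). The test suite exercises the stochastic components at
sizes chosen to make their operating characteristics measurable in
minutes: cluster-significance calibration at 50 genes × 30 samples with
200 simulations over 200 replicates; cyclic-shift type-I on 400-marker,
40-sample noise cohorts over 200 replicates and power on 1000-marker,
60-sample cohorts with a 50-marker, 40%-carrier, 0.6-amplitude gain over
50 replicates; bootstrap CI coverage over 50 replicate cohorts; SAM power
at 5000 genes × 60 samples. The reproduction script runs the full
workflow at the emulated study scale (15597 × 138 expression, 1000-marker
× 107 copy-number).

## Known limitations

The cluster-significance test is conservative (see above). The consensus
delta-area threshold and PAC flag are heuristics; for borderline cohorts
the CDF curves should be inspected directly (`autoplot()` on a
`consensus_result`). The plumbing segmenter is adequate for the
rectangular events the generator plants but is not a replacement for a
production circular-binary-segmentation implementation on real array
data. Gene-gene correlation, batch effects and purity are outside the
synthetic model, so real-data performance of the classifier and the CIN
index should be validated per cohort.
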