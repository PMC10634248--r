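---
title: "Immune activation profiling and neurocognitive biomarker screening: methods"
author: "immunoprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune activation profiling and neurocognitive biomarker screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoprof)
```

## The analysis problem

Treated people living with HIV (PLWH) retain a substantial risk of
neurocognitive impairment (NCI), graded by the Frascati research criteria
into asymptomatic impairment (ANI) and mild neurocognitive disorder (MND).
Chronic immune activation is a suspected driver, so cohorts of PLWH are
phenotyped with broad panels of activation markers: percentages and
absolute counts of activated (HLA-DR+, CD38+), exhausted (PD-1+),
senescent (CD57+, CD28-, CD27-), naive and memory CD4+ and CD8+ T cells,
NK-cell subsets, and soluble markers of monocyte activation (sCD163),
inflammation (sTNFRI) and endothelial activation (tPA, sEPCR).

`immunoprof` implements the two complementary analysis arms used in this
setting:

* a **supervised arm** — marker-level quality control, univariate
  screening against NCI status, a linear discriminant (LDA) classifier
  evaluated by repeated stratified 2-fold cross-validation, and a genetic
  algorithm (GA) searching for parsimonious marker subsets; and
* an **unsupervised arm** — double hierarchical clustering of patients
  (Euclidean distance on z-scored markers) and of markers
  (1 − |correlation|), both under Ward linkage, yielding *immune
  activation profiles* whose enrichment for NCI is then tested with
  Fisher's exact test and odds ratios.

Because patient-level data from such cohorts are generally not
distributable, the package carries a calibrated synthetic-cohort
generator as a first-class, tested module.  All statements below about
what the pipeline recovers are statements about these synthetic cohorts;
the package computes nothing about any real cohort unless you load one.

## The marker registry

`build_registry()` fixes a canonical 59-marker panel: twelve T-cell
phenotypes × {percent, count} × {CD4, CD8} (48), three NK phenotypes ×
{percent, count} (6), four soluble markers, and the lymphocyte count.
The published panel is described by category rather than itemised, so
this composition is a reconstruction consistent with every marker named
in the source analyses; it is deliberately frozen (59 entries, stable
order) so that downstream code can rely on it.  Two auxiliary summary
measures that cohort files typically carry — the percentage of CD8+
T cells and the total CD4 count (`aux_markers()`) — travel alongside the
registry without being part of it.

## The synthetic-cohort generator

`generate_profile_cohort()` draws, by default, 240 patients in six
planted immune-activation profiles of 40 patients each.  Marker vectors
are lineage-blocked equicorrelated Gaussians: markers of one lineage
share a latent factor with correlation `within_block_rho` (default 0.1,
weak positive dependence among related subsets), lineages are
independent.  Values are censored at physiologic bounds (percentages to
[0, 100], counts and concentrations at 0); censoring rather than
rejection sampling keeps the planted correlation structure intact.

Each profile is defined by mean/SD overrides on a coherent set of
markers of one biological axis:

1. globally **low activated/senescent T cells** (e.g. %CD57+ T4 cells
   2.2 ± 1.9 versus a baseline of 8.8 ± 8.1),
2. **high CD38 activation** (%CD38+ T8 57.3 ± 13.3),
3. **poor CD4 reconstitution** (CD4 count 576 ± 250 cells/µL, naive
   depletion, PD-1 elevation),
4. **monocyte/inflammation activation** (sCD163 974 ± 466 pg/mL, sTNFRI
   elevated),
5. **endothelial activation** (tPA 16.4 ± 9.8 ng/mL, sEPCR elevated,
   mild immunosenescence),
6. **high HLA-DR activation** (%HLA-DR+ T4 44.9 ± 13.7).

Published group moments are used verbatim wherever available.  A profile
characterised by a single published marker contrast would not be a
recoverable multivariate cluster, so each profile also co-shifts related
unpublished markers of its axis, with within-profile SDs at roughly
60–80% of baseline: a profile is a coherent biological state, internally
more homogeneous on its own axis than the cohort at large.  These
auxiliary shifts were fixed once, by simulation at the default design
(240 patients, 31 clustered markers), such that the six planted clusters
are separable — the structure the generator exists to plant — and are
part of the frozen defaults.  NCI status is Bernoulli per profile with
default probabilities (0.60, 0.20, 0.53, 0.20, 0.20, 0.20): profiles 1
and 3 are NCI-enriched, matching the qualitative published pattern (the
exact per-profile counts are not published).

Realism features: 2% sporadic missingness (MCAR) plus two markers with
15% concentrated missingness (these should, and do, fall to the
missingness filter); and two near-duplicate marker pairs — CD38hi
percentages generated as r ≥ 0.95 noisy copies of the corresponding
CD38+ percentages within each T lineage (a realistic source of
collinearity), which the deduplication stage should, and does, collapse.

`generate_nci_substudy()` draws the 65-patient case–control design (40
NCI−, 25 NCI+, the positives split 16 ANI / 9 MND) in which exactly six
markers discriminate the groups, using the published group-conditional
means and SDs (e.g. %HLA-DR+ T4: 19.0 ± 8.4 in NCI+ versus 27.5 ± 13.5
in NCI−).  All other markers are drawn from the shared baseline.  This
cohort is drawn complete (no missingness) so that classifier evaluation
is well defined without a preprocessing step.

`generate_wmh_annotations()` adds correlated ordinal Fazekas scores (0–3,
periventricular and deep) by thresholding a shared latent Gaussian at
cut-points matching the published marginals (12/54/25/9% and 9/59/16/16%),
with latent correlation 0.9 (published rank correlation r = 0.891).  The
latent severity is negatively coupled to the patient's %HLA-DR+ T4 cells;
the default coupling 0.55 was derived analytically so that the mean
difference between the dichotomised Fazekas groups (0–1 versus 2–3)
reproduces the published ~0.9 SD contrast (29.2 ± 14.6 vs 18.5 ± 8.7%).

**What the generator does not emulate**: heavy-tailed or skewed marker
distributions (it is a censored Gaussian model; real cytometry
percentages near 0 are strongly skewed), missingness that depends on
marker values (MNAR), batch effects, demographic confounding, and
longitudinal structure.  Tests passing on these cohorts therefore
validate the *pipeline machinery* — not distributional robustness on
real data, where the Mann-Whitney branches and rank statistics matter
more than they do here.

## Quality control

Three stages, in a fixed order (`preprocess_cohort()`):

1. `drop_high_missing()` removes markers missing in **strictly more
   than** 10% of patients (a literal reading of "more than"; exactly 10%
   survives).
2. `impute_knn2()` replaces each missing cell by the mean of that
   marker's values in the two nearest patients.  Distance is Euclidean
   over the markers observed in both patients, each marker standardised
   by its observed mean/SD (the panel mixes %, cells/µL and pg/mL —
   unstandardised Euclidean distance would be dominated by the
   largest-scale marker), and normalised by the square root of the
   overlap size so that distances are comparable across different
   overlaps.  Neighbours must have the target marker observed.
   Imputed values are therefore always inside the observed range of the
   marker.  Neighbouring over *patients* (not markers) is a design
   choice; the alternative reading exists but gives a mean of two other
   markers' values, which has no meaning across units.
3. `dedup_correlated()` computes pairwise Pearson correlations and,
   within each connected component of the graph on pairs with |r| > 0.95,
   keeps the single marker with the largest absolute pooled-variance
   Student t statistic between the NCI groups.  Operating on connected
   components (rather than pair by pair) makes the result independent of
   marker order; exactly one marker survives per component.

## Screening

`screen_markers()` runs a Kruskal–Wallis test per marker across the
outcome groups and adjusts the raw p-values with Benjamini–Hochberg
across all markers that survived quality control (that is the tested
family).  The default grouping is the three observed outcome levels
(none/ANI/MND); a two-level NCI dichotomy is available
(`grouping = "two"`, equivalent to Mann–Whitney), and is the more
powerful choice when ANI and MND are not expected to differ.  A marker is
selected when its adjusted p ≤ α (default 0.05).

`kruskal_wallis()` uses the tie-corrected H with the chi-square reference
distribution, except at very small samples (N ≤ 8), where the chi-square
approximation misstates tail probabilities by up to ~0.05 and the exact
permutation distribution of H is enumerated instead.

`two_group_compare()` operationalises "Student t or Mann–Whitney as
appropriate": Shapiro–Wilk in each group at α = 0.05; pooled-variance t
if neither group rejects normality, otherwise Mann–Whitney with normal
approximation and continuity/tie correction.

A caution the synthetic substudy makes concrete: at the published effect
sizes (standardised group differences of 0.5–0.85 at n = 40 vs 25) the
BH-adjusted p-values of the six discriminating markers sit at the 0.05
boundary — as the published adjusted p-values (0.039–0.049) themselves
do.  Which of the six clear the threshold in a given draw is unstable,
even though their p-value *ranking* ahead of the noise markers is highly
stable.  Marker selection at this sample size should be read as a
ranking, not a verdict.

## Classification

`fit_lda()` is classic two-class Gaussian LDA: discriminant direction
w = S⁻¹(µ₁ − µ₀) with S the pooled within-class covariance,
ridge-stabilised by adding `ridge · trace(S)/p` (default ridge 1e-6) to
the diagonal — GA subsets can push p towards n, where S degenerates.
Class priors are empirical by default (the cohort is imbalanced, 40/25);
the decision threshold is wᵀ(µ₀+µ₁)/2 − log(π₁/π₀), with exact boundary
ties assigned to class 0 (controls) for determinism.

`cv_evaluate()` implements the evaluation protocol used throughout: a
stratified random 2-fold partition per repeat (30 repeats by default),
each fold predicted by a model fitted on the other, so every patient is
predicted exactly once per repeat.  Accuracy is pooled over the repeat's
predictions (unbiased with unequal fold sizes), sensitivity/specificity
are the correct fractions among NCI+ / NCI−, and all rates are averaged
over repeats.  The same protocol serves as the GA's fitness evaluator
and its final re-evaluator, which keeps search and reporting consistent.

## Genetic-algorithm marker selection

`run_ga()` is a binary-chromosome GA (one bit per marker): tournament
selection (size 3), uniform crossover (probability 0.8), per-bit mutation
(probability 1/p), elitism 1, population 100, 50 generations, with empty
chromosomes repaired by switching on one random bit.  Fitness is
cross-validated accuracy minus a parsimony penalty of 0.005 per marker,
so that among equally accurate subsets the smaller always wins.  During
the search the CV is shortened to 5 repeats with folds fixed per run —
fitness is then a deterministic, memoisable function of the subset;
`select_solutions()` pools the de-duplicated final generations of 4
independent runs and re-evaluates every pooled subset with the full
30 × 2-fold protocol on a seed stream independent of the search, ranking
by re-evaluated accuracy (ties: smaller subset, then lexicographic ids).
The hyperparameters are standard textbook values — none are published
for this protocol — and all are configurable; on panels small enough to
enumerate (≤ 12 markers) the GA's top solution is required by test to be
within 0.03 of the exhaustive-search optimum under identical CV seeds.
No nested CV is performed: the re-evaluated accuracies of
searched-over subsets retain selection optimism, a deliberate limitation
of the protocol being reproduced.

## Double hierarchical clustering

Patients are clustered on Euclidean distance over z-scored markers;
markers on 1 − |Pearson r| (sign-blind: markers moving together in
either direction are close); both trees use Ward's minimum-variance
linkage (`hclust` method `ward.D2`, the Lance–Williams recurrence on
squared dissimilarities — applied to the correlation distance as a
pragmatic convention, since 1 − |r| is not Euclidean).  By default only
percentage and soluble-concentration markers enter the patient
clustering: percentages are more stable over time than absolute counts,
and counts would double-weight the same biology.

Diagnostics:

* `hopkins_stat()` — clusterability; H = Σu/(Σu + Σw) comparing
  nearest-neighbour distances of uniform probes (u) in the data's
  bounding box against those of sampled real points (w); ≈ 0.5 under
  spatial randomness, → 1 for clusterable data.  Sample fraction 0.1.
* `choose_k()` — mean silhouette width and the Tibshirani gap statistic
  over k = 2..10, the gap with B = 50 uniform bounding-box references
  (not PCA-rotated — simpler, and adequate for z-scored input) and
  squared-Euclidean within-cluster dispersion.  The gap rule is the
  standard one: the smallest k with Gap(k) ≥ Gap(k+1) − s(k+1).  When
  silhouette and gap disagree the **gap choice wins** (silhouette tends
  to favour the coarsest split of this data; both values are always
  reported).  On default synthetic cohorts the selected k is 6 in ~95%
  of seeds.

`assign_profiles()` renumbers the cut's clusters by decreasing size
(profile 1 = largest), making labels comparable across runs;
`heatmap_export()` writes the dendrogram-ordered heat map (via
`pheatmap`) plus the ordered matrix as TSV so runs can be diffed
exactly.

## Enrichment

`nci_enrichment()` builds the 2×2 table (profile set vs rest × NCI±) and
reports Fisher's two-sided exact p (probability-mass criterion) with the
sample odds ratio and Woolf's logit confidence interval.  The
Haldane–Anscombe +0.5 correction is applied only when a zero cell exists
— this reproduces the qualitative behaviour of a large finite OR with a
CI crossing 1 when the rest-group has no events.  Profile
characterisation (`profile_vs_rest_markers()`) reuses the two-group
comparison per marker and ranks by p; comparisons against external
reference moments (`compare_to_reference()`) use Welch's t from summary
statistics, the only form the available information (mean/SD/n) permits.

## Numerical and reproducibility choices

* Every stochastic stage takes an integer seed; a master seed is
  expanded into per-stage sub-seeds via a seeded draw, so whole runs are
  bit-reproducible and stages are independently re-runnable.  RNG state
  is always restored afterwards.
* Degenerate inputs have defined behaviour rather than accidents:
  all-identical values in Kruskal–Wallis give H = 0, p = 1; constant
  markers are dropped (with a warning) before z-scoring; singleton
  clusters contribute silhouette 0; empty GA chromosomes are repaired;
  LDA boundary ties go to class 0.
* Problem sizes used by the test-suite simulations — 10–25 seeds for
  cluster-number and recovery checks, 200 replicates for FDR and
  odds-ratio calibration, n = 4000 for the Bayes-rate limit of the CV
  estimator, panels of 8 markers for exhaustive-versus-GA comparisons —
  were chosen as the smallest designs at which the checked quantities
  are stable enough to assert.

## Known limitations

* The censored-Gaussian generator understates the skewness of real
  cytometry data; the automatic t/Mann–Whitney switch is consequently
  exercised mostly on its t branch in synthetic tests.
* GA re-evaluated accuracies are optimistic (no nested CV), as in the
  protocol being reproduced.
* The 1 − |r| marker tree is a visualisation aid; Ward on a
  non-Euclidean dissimilarity has no variance interpretation.
* Registry composition beyond the named markers is a plausible
  reconstruction, not a published itemisation.
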