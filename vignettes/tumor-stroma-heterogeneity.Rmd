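---
title: "Methods: radiogenomic analysis of cellular tumor-stroma heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiogenomic analysis of cellular tumor-stroma heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tshradiomics)
```

## The scientific problem

Solid tumors and the surrounding stroma exchange cells and signals, and the
*difference* in cellular composition between the two compartments carries
prognostic information that neither compartment shows alone. This package
implements a three-stage analysis of that contrast in breast cancer:

1. **Genomic arm.** Ten cell populations (eight immune: CD3+ T cells, CD8+
   T cells, cytotoxic lymphocytes, NK cells, B lineage, monocytic lineage,
   myeloid dendritic cells, neutrophils; two stromal: endothelial cells,
   fibroblasts) are scored from bulk expression of paired tumor and stroma
   samples by marker-gene-set averaging. The tumor-stroma heterogeneity
   (TSH) statistic for a population is the relative abundance difference
   `(A_tumor - A_stroma) / A_stroma`. Patients are stratified into good/poor
   survival groups by thresholding TSH, and the groups are compared with
   Kaplan-Meier/log-rank, multivariate Cox, and cell-population correlation
   networks.
2. **Imaging arm.** DCE-MRI series (one precontrast volume `S0`, three to
   six postcontrast volumes) are resampled to 0.8 x 0.8 x 2 mm, the tumor is
   segmented by seeded spatial fuzzy c-means, a 20 mm (25-pixel) peritumoral
   stroma band is constructed, and 572 radiomic features are extracted from
   tumor and band across the `S0` / `S_I` / `S_L` phases.
3. **Radiogenomic link.** A random-forest classifier maps imaging features
   to the genomically defined TSH group; features are pruned for
   collinearity (`|r| > 0.8`) and selected by a genetic algorithm under
   cross-validated AUC. The classifier's poor-class probability is the
   *imaging TSH score*; thresholding it at 0.5 yields prognostic groups
   validated by log-rank, adjusted Cox, and likelihood-ratio tests.

The cohort data behind the original study are not redistributable, so the
package ships first-class synthetic generators with known ground truth.
Every quantitative claim made by the test suite and the acceptance script is
computed from those generators at run time.

## Abundance scoring and the TSH statistic

The estimator is deliberately simple (marker-set averaging in the style of
MCP-counter): the score of population $c$ in sample $s$ is

$$ A_{c,s} = \frac{1}{|M_c|} \sum_{g \in M_c} \log_2\!\big(x_{g,s} + 1\big), $$

where $M_c$ is the marker set. Decisions worth noting:

* **Pseudo-count.** The transform is `log2(x + 1)`: bulk matrices contain
  zeros and the raw log is undefined there. The `+1` convention keeps the
  zero-noise synthetic round trip exact because the generator emits linear
  values `2^y - 1` for planted log2 level `y`.
* **Gene filter.** Genes that are zero or missing in at least 80% of
  samples are removed before scoring (`filter_genes`, threshold
  configurable). Remaining sporadic missing values are excluded from the
  marker mean rather than imputed, consistent with the filter's tolerance of
  sparse missingness.
* **Markers are an input.** The curated marker lists of the published
  estimator are licensed material and are not shipped; `read_gmt` accepts
  any disjoint 10-set collection and the synthetic generator provides one.
  The algorithmic contract — the mean-log2 score — is what this package
  implements and tests.
* **TSH edge case.** The ratio is undefined when `A_stroma` is (numerically)
  zero; `tsh_score` raises an error naming the offending entries rather than
  emitting infinities. Ties at the stratification threshold go to the
  *poor* group, a deterministic rule chosen once and documented here. The
  published operating threshold 0.3512 ships as
  `tsh_threshold_default()`; it is a cohort-derived constant, treated as
  user input because its derivation (an optimal cut-point search on cohort
  data) is outside this package's scope.

## Survival statistics

Standard machinery is delegated to the `survival` package: `survfit`
(product-limit curves), `survdiff` (two-group log-rank), `coxph` with
**Breslow** tie handling (ties are rare in continuous follow-up; Breslow is
the simplest standard), and `p.adjust(method = "BH")`. Follow-up is
administratively censored at 10 years (`censor_at`). The Wilcoxon
signed-rank test discards zero differences before ranking (the conventional
treatment; an all-zero comparison returns p = 1 with a warning) and uses the
exact null for n <= 25 untied differences, otherwise the normal
approximation with continuity correction.

The likelihood-ratio test compares nested Cox models by `2 *
(logL_full - logL_null)` against a chi-square with the parameter-count
difference as degrees of freedom; identical models return p = 1 by
definition.

## Cell-population networks

Within each (survival group, region) stratum, populations are nodes and an
edge joins pairs whose abundance correlates across patients with Pearson
r **strictly greater than 0.5** — signed, not absolute, because the network
definition used in the field draws positive co-abundance links. The
topology panel has nine parameters; conventions follow the Cytoscape
NetworkAnalyzer, the tool practitioners use for this panel:

* node number counts only nodes carrying at least one edge (matching
  edge-list import, and why node counts can differ between groups despite a
  fixed 10 populations);
* density `2E / (n(n-1))` and mean degree `2E / n` over those nodes — the
  ninth parameter is mean degree (Cytoscape's "avg. number of neighbors"),
  an assumption recorded here since the published list names eight;
* clustering coefficient averages local clustering over nodes of degree
  >= 2;
* centralization is Freeman's `n/(n-2) * (max_deg/(n-1) - density)`;
  heterogeneity is `sd(deg)/mean(deg)` with population variance;
* diameter and characteristic path length are computed on the largest
  connected component. Ties between equal-sized components are resolved
  deterministically: most internal edges first, then the component holding
  the alphabetically first node. Degenerate (empty) networks report zeros.

Because node counting ignores isolated vertices, adding an edge that
recruits a previously isolated node can *lower* density; the monotonicity
property "adding an edge never decreases density" therefore holds — and is
tested — for edges added within the already-connected node set.

## Image preprocessing

* **Resampling** to 0.8 x 0.8 x 2 mm: trilinear for intensities,
  nearest-neighbour for masks. The resampler is written in-package (none of
  the installed NIfTI packages resample); voxel `i` sits at world coordinate
  `(i-1) * spacing`, so resampling at the native spacing is the identity.
* **Phases.** `S_I = post[ceil(k/2)] - S0` and `S_L = post[k] - S0`. The
  "intermediate" index is not specified for k in 3..6 anywhere upstream;
  `ceil(k/2)` is the documented, configurable choice.
* **Normalization** divides each acquired volume by its mean over the
  parenchymal region, defined by default as breast minus tumor minus stroma
  band (the upstream description does not define "parenchyma"; an explicit
  mask input overrides the default). Subtraction phases are re-derived from
  the normalized volumes.
* **Segmentation** is two-class fuzzy c-means (fuzzifier m = 2) on the
  intensities inside the breast mask, with a spatial regularizer: each
  membership update is followed by `u <- u * h^w` (renormalized), where `h`
  is the 3x3 in-plane neighbourhood average of the membership and `w` is
  `spatial_weight` (default 1; `w = 0` is plain FCM). The cited spatial-FCM
  family has several variants; this membership-averaging form is declared
  as the implemented one, not inferred as the original authors' exact code.
  Cluster centers are initialized deterministically, with the tumor-class
  center seeded from the intensity at the user-supplied seed voxel — a pure
  quantile initialization can collapse onto the background mode when the
  tumor occupies a small fraction of the breast. The FCM objective is
  recorded per iteration; for plain FCM it is provably non-increasing and
  the suite asserts that. The segmentation runs on `S_I` by default
  (strongest tumor contrast; configurable) and returns the 6-connected
  component of the thresholded (> 0.5) tumor membership containing the
  seed.
* **Stroma band**: per-slice 2D Euclidean dilation of the tumor by 25
  pixels (20 mm at 0.8 mm), minus the tumor, clipped to the breast. The
  dilation is 2D because the band width is defined in in-plane units and
  3D dilation would be anisotropic at 2 mm slices. Implemented with
  `EBImage::distmap`.
* Breast masks (skin/chest-wall exclusion) are accepted as input; automatic
  breast segmentation is out of scope.

## The 572-feature radiomic engine

Per (region, phase): 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM +
14 GLDM + 5 NGTDM = 93 features; over {tumor, stroma} x {S0, S_I, S_L}
that is 558, plus 14 shape features computed once from the tumor mask
(shape depends only on the mask, so the hosting sequence is moot): **572**.
Names follow `<region>_<phase>_<family>_<feature>` /
`tumor_shape_<feature>` in a fixed order (schema version 1).

Numerical conventions, chosen once and configurable where sensible:

* **Discretization**: equal-width binning into a fixed 32 bins. Fixed bin
  *count* (rather than fixed width) keeps normalized features comparable
  across subtraction phases whose dynamic ranges differ. A constant ROI is
  assigned a single level, flagged degenerate, and its texture features take
  their analytic limits (e.g. IDMN = 1, contrast = 0, correlation = 1);
  `extract_all` surfaces the flag so such ROIs can be excluded from
  modelling.
* **Texture geometry**: 3D, distance 1, the 13 unique directions of the
  26-neighborhood; co-occurrence matrices are symmetrized and averaged over
  directions before feature computation, run-length matrices are averaged
  over directions; zones use 26-connected components; GLDM dependence size
  is 1 + the number of neighbours within `alpha` (default 0) gray levels;
  NGTDM neighbourhood means exclude the centre voxel.
* **Quantiles** use linear interpolation (R type 7). Skewness and kurtosis
  are population moment ratios (kurtosis non-excess); both are defined as 0
  for constant ROIs.
* **Shape**: surface area comes from a marching-tetrahedra triangulation of
  the lightly Gaussian-smoothed mask (sigma 0.7 voxel) — meshing the raw
  binary mask overestimates the area of smooth anatomy through voxelization
  faceting, and the smoothed mesh tracks an analytic sphere's area to ~2%.
  Mesh volume uses the exact inside-fraction decomposition of the binary
  midpoint mesh. Axis lengths derive from the principal components of the
  physical voxel coordinates (`4*sqrt(lambda)`), giving elongation
  `sqrt(l2/l1)` and flatness `sqrt(l3/l1)`.

Every texture family is verified against an independent brute-force
enumeration oracle (direct pair/run/zone/neighbourhood counting with
explicit loops) on dozens of random small grids; the suite enumerates all
32768 six-node graphs for the topology panel and all sign assignments for
the exact Wilcoxon null.

## Signature modelling

* **Pruning** removes collinear pairs greedily: while any pair exceeds
  `|r| > 0.8`, the pair with the largest `|r|` loses its member with the
  larger mean absolute correlation (ties: lexicographic, keep the earlier
  name). Absolute correlation is used although the upstream description
  writes `r > 0.8`: the anti-collinearity intent covers strong negative
  correlation equally.
* **GA**: binary-mask chromosomes, fitness = mean out-of-fold AUC of a
  random forest on the masked features (folds fixed per run), tournament
  selection (size 3), uniform crossover (rate 0.8), bit-flip mutation
  (rate 1/n features), elitism 1, fitness memoized per mask. The published
  search sizes — population 100, 100 generations, tenfold CV — are the
  `ga_config()` defaults; AUC (not accuracy) is the fitness because AUC is
  the reported model metric. The elite trajectory is non-decreasing by
  construction and asserted. Because the search fitness is a maximum over
  many candidate masks it is optimistically biased; `ga_select`
  re-estimates the selected subset's CV AUC on fresh folds after the search
  (`cv_auc`). Even that estimate retains *sample-level* selection bias on
  null data (the GA chooses the subset most spuriously label-correlated in
  the sample at hand), so the null-calibration checks score the selected
  model on independently generated data, where the expected AUC is exactly
  one half.
* **Scoring convention**: the imaging TSH score is the forest's probability
  of the *poor* class; scores above 0.5 predict poor survival. The
  published six-feature signature is available as `paper_signature()` — a
  preset for scoring, not an assertion about what the GA selects on
  synthetic data.
* **Tumor-only model**: greedy forward selection over the ten abundance
  scores by CV AUC, stopping when no candidate improves; sensitivity and
  specificity are reported at the Youden-optimal threshold of the
  out-of-fold scores (the published operating point is not stated to be
  Youden; this is the package's documented choice).
* **Prognostic validation** joins scores to survival records, censors at 10
  years, and reports the log-rank test, the Cox hazard ratio of the
  predicted-poor group adjusted for age, ER, PR, HER2 and tumor size, and
  the likelihood-ratio test against the clinical-covariates-only model.
* A single pipeline seed fans out deterministically to folds, GA and
  forests; identical seeds give bit-identical selected feature lists.

## What the synthetic generators emulate — and what they do not

`generate_expression_cohort` plants, per (cell type, region, group), a mean
log2 abundance; marker genes fluctuate around it with `noise_sd` (default
0.3 log2 units, a mid-range bulk-array noise level) plus a per-patient
latent factor shared across cell types whose group-specific SD (defaults
0.4 good / 0.1 poor) controls inter-cell-type correlation — the device that
lets the network analysis see denser good-group coupling, as observed in
cohort data. The default planted table gives the good group 2x tumor
enrichment and the poor group the reverse gradient. Background genes are
group-independent log-normal. Real cohorts add batch effects, correlated
marker noise within genes, and compositional constraints; none are
emulated, so passing tests demonstrate algorithmic correctness, not
cohort-level effect sizes.

`generate_phantom` builds an ellipsoidal tumor in an ellipsoidal breast
(default grid 48 x 48 x 14 at 0.8 x 0.8 x 2 mm — small enough that the full
feature engine runs in seconds, large enough for a ~13-voxel-diameter
tumor), a precontrast plus 3-6 postcontrast volumes with per-tissue
enhancement curves (tumor wash-in to 2.2x baseline vs mild parenchymal
uptake of 1.1x, giving the tumor twice the background contrast once
enhanced), a smoothed Gaussian random texture field per tissue (amplitude
10% of contrast, correlation length 1.5 voxels) so texture matrices are
non-degenerate, and 5% voxel noise. It does not model scanner physics,
bias fields, motion, or realistic breast anatomy.

`generate_survival` draws exponential event times under proportional
hazards (good-group baseline 0.08/year by default; configurable) and
censors non-informatively: censoring times are uniform on `(0, c_max)` with
`c_max` solved per hazard rate so the expected censored fraction equals
`censor_rate`. An earlier draft censored at a uniform fraction of the
event time itself; that makes censoring informative and subtly biases Cox
coverage, which is why the calibrated-uniform scheme is the one shipped.

## Problem sizes used by the suite

The test suite and acceptance script size their simulations to run on a
single CPU in minutes while keeping each check statistically meaningful:
cohorts of 100-200 patients for power/calibration checks (1000 null
replicates for the log-rank type-I rate; 100 replicates of n = 500 for Cox
coverage), 50 random grids for texture oracles, the full 2^15 six-node
graph enumeration for topology, 10 GA seeds at n = 200 with 20 noise
features for planted-feature recovery, and one default phantom per
segmentation/feature check.

## Known limitations

* Feature *values* are convention-dependent (binning, direction averaging,
  mesh construction), so only structural counts and oracle agreement — not
  specific feature values — are asserted; cross-package numeric identity
  with other radiomics engines is not a goal.
* The GA is a stochastic search; only planted-recovery rates and null
  calibration are guaranteed, not a unique selected subset.
* Whether the upstream analysis scored MCP-counter jointly or per region is
  unstated; `estimate_abundance` is region-agnostic and callers pass
  regions explicitly.
* No competing risks, time-varying covariates, or >2-group log-rank; no
  wavelet/filtered feature variants; no community detection or weighted
  path metrics in the network panel.
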