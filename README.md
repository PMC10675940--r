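# tshradiomics

Radiogenomic analysis of cellular **tumor-stroma heterogeneity (TSH)** in
breast cancer: a reusable, tested R implementation of the full pipeline
linking bulk-expression cell subpopulation scores, the TSH ratio statistic
and its survival stratification, cell-population correlation networks, a
peritumoral-band DCE-MRI radiomics engine (572 features), and a genetic
algorithm / random-forest signature model with prognostic validation.

## Who this is for

Researchers in cancer radiogenomics who want to (a) quantify the contrast
in cellular composition between a tumor and its surrounding stroma from
paired bulk expression, (b) extract a reproducible peritumoral radiomic
feature set from DCE-MRI, and (c) train and prognostically validate imaging
signatures of that contrast — all with synthetic generators that make every
step testable without access to the original cohorts.

## The statistic at the core

For a cell population with marker set $M_c$, the abundance score in sample
$s$ is the mean log2 expression of its markers,
$A_{c,s} = \tfrac{1}{|M_c|}\sum_{g \in M_c}\log_2(x_{g,s}+1)$.
The TSH biomarker compares compartments:

$$ \mathrm{TSH}_c \;=\; \frac{A_{\mathrm{tumor}} - A_{\mathrm{stroma}}}{A_{\mathrm{stroma}}} $$

TSH > 0 means tumor enrichment; patients with TSH above an operating
threshold (0.3512 for the cytotoxic-lymphocyte biomarker,
`tsh_threshold_default()`) form the good-survival group, evaluated by
Kaplan-Meier/log-rank and multivariate Cox (Breslow ties, 10-year
censoring). The imaging arm predicts the TSH group from 572 radiomic
features (18 first-order + 75 texture per region x phase over
{tumor, stroma} x {S0, S\_I, S\_L}, plus 14 tumor shape features), selected
by a GA under tenfold cross-validated AUC after `|r| > 0.8` collinearity
pruning, with a random forest whose poor-class probability is the *imaging
TSH score* (threshold 0.5).

## Worked example

Genomic arm on a synthetic cohort (120 patients, planted group structure):

```r
library(tshradiomics)

markers <- generate_markers(5, seed = 1)
cfg     <- cohort_config(n_patients = 120, n_genes = 300,
                         noise_sd = 0.3, seed = 1)
cohort  <- generate_expression_cohort(cfg, markers)

tumor  <- estimate_abundance(filter_genes(cohort$tumor),  markers, "tumor")
stroma <- estimate_abundance(filter_genes(cohort$stroma), markers, "stroma")
tt     <- tsh_table(tumor, stroma, cell_type = "Cytotoxic lymphocytes")
groups <- stratify(tt$tsh, threshold = tsh_threshold_default())
table(groups)
#> good poor
#>   60   60

surv <- censor_at(generate_survival(cohort$groups, cfg))
lr   <- logrank_test(surv, groups)
#> log-rank chi-square 19.01, p = 1.3e-05
```

The TSH-stratified groups separate survival exactly as planted (the
generator gives the poor group a 3x hazard). A multivariate Cox fit on the
continuous TSH value adjusted for age and tumor size:

```r
fit <- cox_fit(merge(surv, data.frame(patient = tt$patient, tsh = tt$tsh)),
               c("tsh", "age", "size"))
fit$table
#>   feature     beta    hr ci_low ci_high   wald        p
#> 1     tsh -0.67382 0.510  0.379   0.685 19.967 7.88e-06
#> 2     age -0.00475 0.995  0.978   1.013  0.271 6.03e-01
#> 3    size -0.01844 0.982  0.953   1.011  1.532 2.16e-01
```

Higher TSH (tumor-enriched cytotoxic lymphocytes) halves the hazard per
unit; the synthetic clinical covariates are null, as generated. Imaging
arm on a phantom:

```r
ph <- generate_phantom(phantom_config(seed = 1))
pr <- prep_patient(ph)          # resample, segment (spatial FCM), band, normalize
fv <- extract_all(pr$phases, pr$tumor_mask, pr$stroma_mask)
length(fv)
#> [1] 572
round(fv[c("tumor_shape_sphericity", "tumor_shape_flatness",
           "tumor_S0_glcm_idmn")], 4)
#> tumor_shape_sphericity   tumor_shape_flatness     tumor_S0_glcm_idmn
#>                 0.9924                 0.6824                 0.9837
```

The ellipsoidal phantom tumor is near-spherical (sphericity 0.99), flatter
than a ball (flatness 0.68 = least/major axis ratio), and its precontrast
texture is homogeneous (IDMN close to 1). `ga_select`, `train_classifier`
and `validate_prognosis` then link such feature tables to TSH groups and
survival; see the methods vignette
(`vignettes/tumor-stroma-heterogeneity.Rmd`) for the modelling chain and
every numerical convention.

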