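# Shared fixture builders: small cohorts and phantoms generated in code.

small_cohort <- function(n = 60, noise_sd = 0, seed = 11,
                         latent_sd = c(good = 0, poor = 0), ...) {
  markers <- generate_markers(4, seed = seed)
  cfg <- cohort_config(n_patients = n, n_genes = 120, noise_sd = noise_sd,
                       latent_sd = latent_sd, seed = seed, ...)
  cohort <- generate_expression_cohort(cfg, markers)
  list(markers = markers, config = cfg, cohort = cohort)
}

small_phantom <- function(seed = 7, ...) {
  generate_phantom(phantom_config(seed = seed, ...))
}

## dice coefficient between two logical masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
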