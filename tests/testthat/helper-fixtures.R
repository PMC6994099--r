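# Shared fixture builders. Everything is generated in code; no files.

# A noise spec with every stochastic platform term switched off.
silent_noise <- function(seed = 1L, ...) {
  platform_noise_spec(
    qpcr_ct_sd = 0, qpcr_sample_sd = 0, qpcr_pipette_slope = 0,
    plate_effect_sd = 0, outlier_rate = 0,
    dpcr_plate_sd = 0,
    array_probe_sd = 0, array_sample_sd = 0,
    batch_effect_loadings = numeric(0), array_gc_amplitude = 0,
    wes_batch_sd = 0, seed = seed, ...
  )
}

# A small cohort with no covariate effects and a fixed latent spread.
plain_cohort <- function(n = 50, seed = 1L, latent_sd = 0.3, ...) {
  generate_cohort(cohort_spec(
    n_individuals = n, beta_age = 0, beta_sex = 0, beta_wbc = 0,
    beta_duffy_on_wbc = 0, gamma_cvd = 0, center_effect_sd = 0,
    wbc_missing_rate = 0, latent_sd = latent_sd, seed = seed, ...
  ))
}

# Replicate table for hand-constructed qPCR plates: one row per replicate.
qpcr_rows <- function(sample_id, dct, plate_id = "P1",
                      pipetting_order = seq_along(dct), ct_rpph1 = 26) {
  tibble::tibble(
    sample_id = sample_id, plate_id = plate_id,
    pipetting_order = pipetting_order,
    ct_nd1 = ct_rpph1 - dct, ct_rpph1 = ct_rpph1
  )
}
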