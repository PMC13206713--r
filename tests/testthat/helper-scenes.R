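# Small scenes keep unit tests fast; geometry is still the real protocol
# (462-row B-scans, 8.6 mm scan length), only laterally downsampled.

small_scene <- function(..., n_ascans = 128, seed = 1) {
  scene_params(..., n_ascans = n_ascans, seed = seed)
}

clean_scene <- function(..., noise_sd = 0, n_shadow_columns = 0) {
  small_scene(..., noise_sd = noise_sd, n_shadow_columns = n_shadow_columns)
}

# A quick grid-level cohort with a given CVI effect profile.
quick_cohort <- function(profile = NULL, n = 6, eye_sd = 3, cell_sd = 6,
                         seed = 1) {
  generate_cohort(cohort_spec(
    n_per_group = n,
    effect_profile = if (is.null(profile)) list() else list(cvi = profile),
    between_eye_sd = eye_sd, cell_noise_sd = cell_sd, seed = seed))
}
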