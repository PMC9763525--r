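# Shared fixtures built in code.

# small, fast phantom: three spheres, modest grid
small_phantom_spec <- function(eta = 0, fwhm = 6.4, noise = 0, seed = 1) {
  phantom_spec(sphere_volumes = c(2.57, 5.57, 11.49),
               background_ratio = eta, psf_fwhm = fwhm,
               noise_scale = noise, seed = seed)
}

# noiseless deterministic cohort following the pure mono-exponential model
exact_cohort_spec <- function(seed = 1, n_patients = 4, ...) {
  cohort_spec(n_patients = n_patients, noise_cv = 0, half_life_cv = 0,
              tumours_per_patient = c(2, 4), seed = seed, ...)
}

# recovery surface sampled on the six-volume x five-ratio phantom grid
rc_surface_grid <- function(params, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(v_physical = c(0.52, 1.15, 2.57, 5.57, 11.49, 26.52),
                   eta = c(0, 0.2, 0.4, 0.6, 0.8))
  g$recovery <- rc_full(g$v_physical, g$eta, params)
  if (noise_cv > 0)
    g$recovery <- g$recovery * rlnorm(nrow(g), 0, noise_cv)
  g
}
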