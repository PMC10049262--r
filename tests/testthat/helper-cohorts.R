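# Small fast cohort configurations for unit tests: narrow m/z window so
# spectra stay short.

quick_config <- function(...) {
  defaults <- list(classes = c("A", "B"), n_patients_per_class = 4L,
                   spectra_per_patient = 5L,
                   mz_min = 600, mz_max = 800, grid_step = 0.1,
                   n_peaks = 12L, n_discriminative = 4L,
                   effect_log2fc = 1.5, peak_width_sigma = 0.35,
                   baseline_amplitude = 10, noise_cv = 0.15,
                   patient_cv = 0.2, noise_floor_sd = 0.02,
                   mass_jitter_sd = 0.1, seed = 1L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# deterministic noise-free configuration (all stochastic intensity and mass
# components off)
noisefree_config <- function(...) {
  quick_config(noise_cv = 0, patient_cv = 0, noise_floor_sd = 0,
               mass_jitter_sd = 0, baseline_amplitude = 0, ...)
}

quick_fm <- function(cfg, tolerance = 0.5, align = FALSE) {
  coh <- simulate_cohort(cfg)
  fm <- preprocess_cohort(coh$spectra, peaks = coh$truth$peak_mz,
                          reference_mz = if (align) coh$truth$peak_mz,
                          tolerance = tolerance)
  list(fm = fm, truth = coh$truth, spectra = coh$spectra)
}

# two well-separated Gaussian point clouds as a feature matrix
separable_fm <- function(n_per_class = 20, p = 4, delta = 5, seed = 1) {
  maldiclass:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p, -delta / 2), ncol = p),
               matrix(rnorm(n_per_class * p, delta / 2), ncol = p))
    feature_matrix(x, seq(700, by = 10, length.out = p),
                   patient_id = sprintf("p%02d", seq_len(2 * n_per_class)),
                   class_label = rep(c("neg", "pos"), each = n_per_class))
  })
}

# pure-noise feature matrix with balanced labels, one row per patient
null_fm <- function(n_per_class = 20, p = 10, seed = 1) {
  maldiclass:::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
    feature_matrix(x, seq(700, by = 10, length.out = p),
                   patient_id = sprintf("p%02d", seq_len(2 * n_per_class)),
                   class_label = rep(c("a", "b"), each = n_per_class))
  })
}
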