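#' Configuration for a synthetic MALDI imaging cohort
#'
#' Describes a patient-grouped cohort of tryptic-peptide profile spectra with
#' known discriminative peaks. Defaults emulate a three-genotype melanoma
#' profiling study: ~22 patients per genotype, 17 tumor-region spectra per
#' patient, acquisition range m/z 600-3200, and genotype effect sizes on the
#' log2 scale comparable to published peak discriminator tables (|log2 FC|
#' roughly 0.3-2.5, average peak intensities roughly 2-50 arbitrary units).
#'
#' The generator is hierarchical: each discriminative peak has class mean
#' intensities differing by exactly `2^|effect_log2fc|`; each patient draws a
#' per-peak expected intensity log-normally around the class mean
#' (coefficient of variation `patient_cv`); each spectrum draws per-peak apex
#' amplitudes log-normally around the patient mean (`noise_cv`). All
#' log-normal draws are mean-corrected, so arithmetic class means of apex
#' intensities equal the declared ground truth.
#'
#' @param classes Character vector of class labels (>= 2).
#' @param n_patients_per_class Patients simulated for each class.
#' @param spectra_per_patient Spectra per patient tumor region.
#' @param mz_min,mz_max Acquisition range in Da.
#' @param grid_step Sampling interval of the common m/z grid, Da.
#' @param n_peaks Number of peptide-like Gaussian peaks.
#' @param n_discriminative Number of peaks carrying a class effect
#'   (`<= n_peaks`). Effects cycle over the classes: each discriminative peak
#'   is elevated (or suppressed, if `effect_log2fc < 0`) in exactly one class.
#' @param effect_log2fc Signed log2 ratio between the affected class mean and
#'   the other class means at discriminative peaks.
#' @param peak_width_sigma Gaussian peak sigma, Da.
#' @param baseline_amplitude Amplitude of the smooth exponentially decaying
#'   chemical baseline at `mz_min` (0 disables the baseline).
#' @param baseline_tau Decay constant of the baseline, Da.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   spectrum-level intensity noise.
#' @param patient_cv Coefficient of variation of the patient-level random
#'   effect around the class mean.
#' @param noise_floor_sd Standard deviation of additive point-wise detector
#'   noise (intensities are clipped at zero).
#' @param mass_jitter_sd Standard deviation of the per-spectrum global mass
#'   shift, Da.
#' @param intensity_scale Global multiplier applied to all class mean
#'   intensities (useful for linearity checks).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(classes = c("BRAF_MUT", "NRAS_MUT", "WT"),
                          n_patients_per_class = 22L,
                          spectra_per_patient = 17L,
                          mz_min = 600, mz_max = 3200,
                          grid_step = 0.1,
                          n_peaks = 60L,
                          n_discriminative = 9L,
                          effect_log2fc = 1.0,
                          peak_width_sigma = 0.35,
                          baseline_amplitude = 15,
                          baseline_tau = 400,
                          noise_cv = 0.2,
                          patient_cv = 0.3,
                          noise_floor_sd = 0.05,
                          mass_jitter_sd = 0.15,
                          intensity_scale = 1,
                          seed = 1L) {
  if (length(classes) < 2 || anyDuplicated(classes))
    stop_field("classes", "need >= 2 distinct class labels")
  if (!is_count(n_patients_per_class))
    stop_field("n_patients_per_class", "must be a count >= 1")
  if (!is_count(spectra_per_patient))
    stop_field("spectra_per_patient", "must be a count >= 1")
  if (!is_number(mz_min) || !is_number(mz_max) || mz_min >= mz_max)
    stop_field("mz_min", "need mz_min < mz_max")
  if (!is_number(grid_step) || grid_step <= 0)
    stop_field("grid_step", "must be > 0")
  if (!is_count(n_peaks)) stop_field("n_peaks", "must be a count >= 1")
  if (!is_count(n_discriminative) || n_discriminative > n_peaks)
    stop_field("n_discriminative", "must be a count in [1, n_peaks]")
  if (!is_number(effect_log2fc)) stop_field("effect_log2fc", "must be a number")
  if (!is_number(peak_width_sigma) || peak_width_sigma <= 0)
    stop_field("peak_width_sigma", "must be > 0")
  if (!is_number(baseline_amplitude) || baseline_amplitude < 0)
    stop_field("baseline_amplitude", "must be >= 0")
  if (!is_number(baseline_tau) || baseline_tau <= 0)
    stop_field("baseline_tau", "must be > 0")
  if (!is_number(noise_cv) || noise_cv < 0)
    stop_field("noise_cv", "must be >= 0")
  if (!is_number(patient_cv) || patient_cv < 0)
    stop_field("patient_cv", "must be >= 0")
  if (!is_number(noise_floor_sd) || noise_floor_sd < 0)
    stop_field("noise_floor_sd", "must be >= 0")
  if (!is_number(mass_jitter_sd) || mass_jitter_sd < 0)
    stop_field("mass_jitter_sd", "must be >= 0")
  if (!is_number(intensity_scale) || intensity_scale <= 0)
    stop_field("intensity_scale", "must be > 0")
  if (!is_count(abs(seed) + 1)) stop_field("seed", "must be an integer")

  structure(list(
    classes = as.character(classes),
    n_patients_per_class = as.integer(n_patients_per_class),
    spectra_per_patient = as.integer(spectra_per_patient),
    mz_min = mz_min, mz_max = mz_max, grid_step = grid_step,
    n_peaks = as.integer(n_peaks),
    n_discriminative = as.integer(n_discriminative),
    effect_log2fc = effect_log2fc,
    peak_width_sigma = peak_width_sigma,
    baseline_amplitude = baseline_amplitude,
    baseline_tau = baseline_tau,
    noise_cv = noise_cv, patient_cv = patient_cv,
    noise_floor_sd = noise_floor_sd,
    mass_jitter_sd = mass_jitter_sd,
    intensity_scale = intensity_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a single profile spectrum
#'
#' @param mz Strictly increasing numeric vector of m/z values (Da).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param patient_id,class_label,region_id Metadata strings.
#' @return An object of class `maldi_spectrum`.
#' @export
maldi_spectrum <- function(mz, intensity, patient_id, class_label,
                           region_id = patient_id) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) && any(diff(mz) <= 0))
    stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  structure(list(
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    patient_id = as.character(patient_id),
    class_label = as.character(class_label),
    region_id = as.character(region_id),
    tic = NA_real_, applied_shift = 0,
    provenance = character(0)
  ), class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<maldi_spectrum> %d points, m/z %.1f-%.1f | patient %s (%s), region %s\n",
    length(x$mz), min(x$mz), max(x$mz), x$patient_id, x$class_label,
    x$region_id))
  if (length(x$provenance))
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Simulate a labeled, patient-grouped cohort of profile spectra
#'
#' Draws peak positions and base intensities once per cohort, then builds
#' each spectrum as the sum of Gaussian peaks, a smooth exponentially
#' decaying baseline and noise, with a per-spectrum global mass shift drawn
#' from `Normal(0, mass_jitter_sd)`. Peak centers are snapped to the sampling
#' grid so that in the noise-free limit sampled apex heights equal the
#' declared class means exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of class `maldi_cohort` with elements
#'   \describe{
#'     \item{spectra}{list of [maldi_spectrum()] objects
#'       (`classes x patients x spectra_per_patient` of them);}
#'     \item{truth}{a `cohort_truth` object: `peak_mz`, `discriminative_mz`,
#'       the `per_class_peak_means` table (peak x class) and the seed.}
#'   }
#' @examples
#' cfg <- cohort_config(classes = c("A", "B"), n_patients_per_class = 2,
#'                      spectra_per_patient = 3, mz_min = 600, mz_max = 700,
#'                      n_peaks = 5, n_discriminative = 2, seed = 7)
#' coh <- simulate_cohort(cfg)
#' length(coh$spectra)  # 2 * 2 * 3
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be created by cohort_config()", call. = FALSE)
  cf <- config
  with_seed(cf$seed, {
    grid <- seq(cf$mz_min, cf$mz_max, by = cf$grid_step)
    ngrid <- length(grid)

    # peak centers on the grid, away from the edges, minimum separation wide
    # enough that binning windows at the peak list never overlap
    margin <- max(10, 8 * cf$peak_width_sigma)
    min_sep <- max(8 * cf$peak_width_sigma, 2.5)
    ok <- grid >= cf$mz_min + margin & grid <= cf$mz_max - margin
    cand <- sort(sample(which(ok), min(50L * cf$n_peaks, sum(ok))))
    keep <- integer(0)
    last <- -Inf
    for (i in cand) {
      if (grid[i] - last >= min_sep) {
        keep <- c(keep, i)
        last <- grid[i]
      }
    }
    if (length(keep) < cf$n_peaks)
      stop("m/z range too narrow for the requested number of peaks",
           call. = FALSE)
    peak_idx <- sort(sample(keep, cf$n_peaks))
    peak_mz <- grid[peak_idx]

    # base intensities span roughly 2-50 a.u., as in published average
    # peptide peak intensities
    base <- cf$intensity_scale * rlnorm(cf$n_peaks, meanlog = log(8), sdlog = 0.6)
    n_cls <- length(cf$classes)
    means <- matrix(rep(base, n_cls), ncol = n_cls,
                    dimnames = list(sprintf("%.4f", peak_mz), cf$classes))
    disc <- sort(sample(cf$n_peaks, cf$n_discriminative))
    for (j in seq_along(disc)) {
      cls <- ((j - 1L) %% n_cls) + 1L
      means[disc[j], cls] <- means[disc[j], cls] * 2^cf$effect_log2fc
    }

    # Gaussian template shared by all peaks (constant sigma, centers on grid)
    half <- max(1L, ceiling(5 * cf$peak_width_sigma / cf$grid_step))
    tmpl <- exp(-((-half:half) * cf$grid_step)^2 / (2 * cf$peak_width_sigma^2))
    baseline <- if (cf$baseline_amplitude > 0) {
      cf$baseline_amplitude * exp(-(grid - cf$mz_min) / cf$baseline_tau)
    } else {
      numeric(ngrid)
    }

    spectra <- vector("list",
                      n_cls * cf$n_patients_per_class * cf$spectra_per_patient)
    s <- 0L
    for (ci in seq_len(n_cls)) {
      for (pi in seq_len(cf$n_patients_per_class)) {
        pid <- sprintf("%s_p%02d", cf$classes[ci], pi)
        pat_mean <- means[, ci] * lnorm_cv(cf$n_peaks, cf$patient_cv)
        for (si in seq_len(cf$spectra_per_patient)) {
          amp <- pat_mean * lnorm_cv(cf$n_peaks, cf$noise_cv)
          y <- baseline + numeric(ngrid)
          for (p in seq_len(cf$n_peaks)) {
            i0 <- peak_idx[p] - half
            i1 <- peak_idx[p] + half
            y[i0:i1] <- y[i0:i1] + amp[p] * tmpl
          }
          if (cf$noise_floor_sd > 0)
            y <- pmax(y + rnorm(ngrid, sd = cf$noise_floor_sd), 0)
          delta <- if (cf$mass_jitter_sd > 0) rnorm(1, sd = cf$mass_jitter_sd) else 0
          sp <- maldi_spectrum(grid + delta, y, patient_id = pid,
                               class_label = cf$classes[ci], region_id = pid)
          s <- s + 1L
          spectra[[s]] <- sp
        }
      }
    }

    truth <- structure(list(
      peak_mz = peak_mz,
      discriminative_mz = peak_mz[disc],
      per_class_peak_means = means,
      effect_log2fc = cf$effect_log2fc,
      seed = cf$seed
    ), class = "cohort_truth")

    structure(list(spectra = spectra, truth = truth, config = cf),
              class = "maldi_cohort")
  })
}

#' @export
print.maldi_cohort <- function(x, ...) {
  cls <- table(vapply(x$spectra, `[[`, "", "class_label"))
  cat(sprintf("<maldi_cohort> %d spectra, %d peaks (%d discriminative)\n",
              length(x$spectra), length(x$truth$peak_mz),
              length(x$truth$discriminative_mz)))
  print(cls)
  invisible(x)
}

#' Ground-truth discriminative peaks for one pairwise contrast
#'
#' Returns the m/z positions whose declared class mean intensities differ
#' between two classes, i.e. the features a perfect selector should recover
#' for that pairwise comparison.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param class_a,class_b Class labels present in the truth table.
#' @return Numeric vector of m/z positions (possibly empty).
#' @export
truth_features <- function(truth, class_a, class_b) {
  m <- truth$per_class_peak_means
  if (!all(c(class_a, class_b) %in% colnames(m)))
    stop("unknown class label", call. = FALSE)
  differ <- abs(log2(m[, class_a] / m[, class_b])) > 1e-12
  truth$peak_mz[differ]
}
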