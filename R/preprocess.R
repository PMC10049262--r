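#' Morphological TopHat baseline subtraction
#'
#' Subtracts the morphological opening of the intensity profile — an erosion
#' (running minimum) followed by a dilation (running maximum) with a flat
#' structuring element of `window_points` samples and replicate-edge padding.
#' The opening traces the broad baseline under the spectrum; subtracting it
#' removes any baseline wider than the window while preserving peaks narrower
#' than the window at full height. The result is non-negative everywhere and
#' the operation is idempotent.
#'
#' @param spectrum A [maldi_spectrum()].
#' @param window_points Odd structuring-element width in samples; default is
#'   the odd number of samples spanning about 10 Da at the spectrum's median
#'   grid spacing — wider than any tryptic peptide peak, narrower than
#'   chemical-baseline undulation.
#' @return The spectrum with baseline removed; `"tophat"` appended to its
#'   provenance.
#' @export
tophat_baseline <- function(spectrum, window_points = NULL) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  n <- length(spectrum$intensity)
  if (is.null(window_points)) {
    step <- stats::median(diff(spectrum$mz))
    window_points <- max(3L, as.integer(round(10 / step)))
    if (window_points %% 2L == 0L) window_points <- window_points + 1L
    window_points <- min(window_points, if (n %% 2L == 1L) n else n - 1L)
  }
  if (window_points %% 2L != 1L || window_points < 3L || window_points > n)
    stop("window_points must be odd, >= 3 and <= the spectrum length",
         call. = FALSE)
  opening <- morph_dilate(morph_erode(spectrum$intensity, window_points),
                          window_points)
  spectrum$intensity <- spectrum$intensity - opening
  spectrum$provenance <- c(spectrum$provenance, "tophat")
  spectrum
}

#' Total-ion-count normalization
#'
#' Rescales the intensity profile so that its sum equals `target`; the
#' original sum (the TIC) is recorded in the spectrum's `tic` field.
#'
#' @param spectrum A [maldi_spectrum()].
#' @param target Positive normalization target (default 1).
#' @return The normalized spectrum with `"tic_normalize"` appended to its
#'   provenance.
#' @export
tic_normalize <- function(spectrum, target = 1) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  if (!is_number(target) || target <= 0)
    stop("target must be a positive number", call. = FALSE)
  s <- sum(spectrum$intensity)
  if (s <= 0)
    stop(sprintf("cannot TIC-normalize all-zero spectrum (patient %s, region %s)",
                 spectrum$patient_id, spectrum$region_id), call. = FALSE)
  spectrum$tic <- s
  spectrum$intensity <- spectrum$intensity * (target / s)
  spectrum$provenance <- c(spectrum$provenance, "tic_normalize")
  spectrum
}

#' Estimate the global mass shift of a spectrum
#'
#' Cross-correlates the intensity profile with a comb of reference peak
#' positions over candidate shifts on the spectrum's native sampling grid and
#' returns the shift (Da) that maximizes the correlation. Subtracting the
#' returned shift from the m/z axis ([align_spectrum()]) moves the observed
#' peaks onto the reference positions.
#'
#' @param spectrum A [maldi_spectrum()].
#' @param reference_mz Reference peak positions (Da); at least one must lie
#'   inside the spectrum's m/z range.
#' @param max_shift Half-width of the shift search window, Da (default 1;
#'   residual shifts after external calibration are sub-Da).
#' @return The estimated shift in Da (a multiple of the grid step). Ties are
#'   broken toward the smallest absolute shift.
#' @export
estimate_mass_shift <- function(spectrum, reference_mz, max_shift = 1) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  mz <- spectrum$mz
  inside <- reference_mz >= mz[1] & reference_mz <= mz[length(mz)]
  if (!any(inside))
    stop("no reference peak lies inside the spectrum's m/z range",
         call. = FALSE)
  refs <- reference_mz[inside]
  step <- stats::median(diff(mz))
  K <- max(1L, as.integer(round(max_shift / step)))
  base <- findInterval(refs, mz)
  base <- pmax(pmin(base, length(mz)), 1L)
  # snap to nearest grid point
  up <- base < length(mz) & (mz[pmin(base + 1L, length(mz))] - refs) < (refs - mz[base])
  base[up] <- base[up] + 1L
  shifts <- -K:K
  score <- vapply(shifts, function(s) {
    idx <- base + s
    ok <- idx >= 1L & idx <= length(mz)
    sum(spectrum$intensity[idx[ok]])
  }, numeric(1))
  best <- which(score == max(score))
  best <- best[which.min(abs(shifts[best]))]
  shifts[best] * step
}

#' Apply a mass shift to a spectrum
#'
#' @param spectrum A [maldi_spectrum()].
#' @param shift Shift in Da, as returned by [estimate_mass_shift()]; the m/z
#'   axis becomes `mz - shift`.
#' @return The aligned spectrum, with the cumulative shift recorded in
#'   `applied_shift` and `"align"` appended to its provenance.
#' @export
align_spectrum <- function(spectrum, shift) {
  stopifnot(inherits(spectrum, "maldi_spectrum"), is_number(shift))
  spectrum$mz <- spectrum$mz - shift
  spectrum$applied_shift <- spectrum$applied_shift + shift
  spectrum$provenance <- c(spectrum$provenance, "align")
  spectrum
}

#' Bin spectra into a feature matrix
#'
#' Each feature value is the maximum intensity (the apex) observed inside the
#' half-open window `[feature_mz - tolerance, feature_mz + tolerance)`.
#' Features with zero signal in every spectrum are dropped. Row order
#' preserves the input order.
#'
#' @param spectra List of (processed) [maldi_spectrum()] objects.
#' @param peaks Optional explicit feature m/z list. Windows must not overlap.
#' @param bin_width Uniform bin width in Da, used when `peaks` is `NULL`;
#'   bins partition the common m/z range.
#' @param tolerance Half-width of each feature window in Da (defaults to
#'   `bin_width / 2` for uniform bins, and is required with explicit peaks).
#' @return A [feature_matrix()].
#' @export
bin_to_features <- function(spectra, peaks = NULL, bin_width = NULL,
                            tolerance = NULL) {
  stopifnot(length(spectra) >= 1)
  if (is.null(peaks)) {
    if (is.null(bin_width) || bin_width <= 0)
      stop("either `peaks` or a positive `bin_width` is required",
           call. = FALSE)
    lo <- min(vapply(spectra, function(s) s$mz[1], numeric(1)))
    hi <- max(vapply(spectra, function(s) s$mz[length(s$mz)], numeric(1)))
    peaks <- seq(lo + bin_width / 2, hi, by = bin_width)
    if (is.null(tolerance)) tolerance <- bin_width / 2
  }
  if (is.null(tolerance) || tolerance <= 0)
    stop("`tolerance` must be a positive half-width in Da", call. = FALSE)
  peaks <- as.numeric(peaks)
  if (is.unsorted(peaks, strictly = TRUE))
    stop("feature peak list must be strictly increasing", call. = FALSE)
  if (length(peaks) > 1 && any(peaks[-length(peaks)] + tolerance >
                               peaks[-1] - tolerance + 1e-12))
    stop("explicit peak windows overlap", call. = FALSE)

  los <- peaks - tolerance
  his <- peaks + tolerance
  vals <- t(vapply(spectra, function(sp) {
    i1 <- findInterval(los, sp$mz)            # last index with mz <= lo
    start <- ifelse(i1 >= 1 & sp$mz[pmax(i1, 1L)] == los, i1, i1 + 1L)
    i2 <- findInterval(his, sp$mz)            # last index with mz <= hi
    end <- ifelse(i2 >= 1 & sp$mz[pmax(i2, 1L)] == his, i2 - 1L, i2)
    vapply(seq_along(peaks), function(j) {
      if (start[j] > end[j]) 0 else max(sp$intensity[start[j]:end[j]])
    }, numeric(1))
  }, numeric(length(peaks))))
  if (length(peaks) == 1L) vals <- matrix(vals, ncol = 1L)

  keep <- colSums(vals > 0) > 0
  if (!any(keep))
    stop("all candidate features have zero signal in every spectrum",
         call. = FALSE)
  feature_matrix(vals[, keep, drop = FALSE], peaks[keep],
                 patient_id = vapply(spectra, `[[`, "", "patient_id"),
                 class_label = vapply(spectra, `[[`, "", "class_label"),
                 region_id = vapply(spectra, `[[`, "", "region_id"))
}

#' Subsample spectra per tumor region
#'
#' Uniformly samples up to `n` spectra without replacement from each region
#' (regions processed in order of first appearance); regions with fewer than
#' `n` spectra contribute all of them, with a warning.
#'
#' @param spectra List of [maldi_spectrum()] objects.
#' @param n Target number of spectra per region (default 17).
#' @param seed Integer seed; the subset is deterministic given the seed.
#' @return The selected spectra, in their original relative order.
#' @export
select_spectra_per_region <- function(spectra, n = 17, seed = 1L) {
  if (!is_count(n)) stop("`n` must be a count >= 1", call. = FALSE)
  regions <- vapply(spectra, `[[`, "", "region_id")
  keep <- logical(length(spectra))
  with_seed(seed, {
    for (r in unique(regions)) {
      idx <- which(regions == r)
      if (length(idx) <= n) {
        if (length(idx) < n)
          warning(sprintf("region '%s' has only %d spectra (requested %d)",
                          r, length(idx), n))
        keep[idx] <- TRUE
      } else {
        keep[sample(idx, n)] <- TRUE
      }
    }
  })
  spectra[keep]
}

#' Run the full preprocessing chain on a set of spectra
#'
#' Canonical order: optional per-region subsampling, TopHat baseline
#' subtraction, TIC normalization, optional mass-shift alignment against a
#' reference peak list, and apex binning into a feature matrix. Provenance is
#' recorded per spectrum so the order can be audited.
#'
#' @param spectra List of [maldi_spectrum()] objects.
#' @param window_points TopHat window ([tophat_baseline()]).
#' @param tic_target TIC normalization target.
#' @param reference_mz Optional reference peaks for alignment.
#' @param max_shift Alignment search half-width, Da.
#' @param peaks,bin_width,tolerance Binning parameters ([bin_to_features()]).
#' @param n_per_region Optional per-region spectrum count
#'   ([select_spectra_per_region()]).
#' @param seed Seed for the per-region subsampling.
#' @return A [feature_matrix()].
#' @export
preprocess_cohort <- function(spectra, window_points = NULL, tic_target = 1,
                              reference_mz = NULL, max_shift = 1,
                              peaks = NULL, bin_width = NULL, tolerance = 0.5,
                              n_per_region = NULL, seed = 1L) {
  if (!is.null(n_per_region))
    spectra <- select_spectra_per_region(spectra, n_per_region, seed)
  processed <- lapply(spectra, function(sp) {
    sp <- tophat_baseline(sp, window_points)
    sp <- tic_normalize(sp, tic_target)
    if (!is.null(reference_mz)) {
      shift <- estimate_mass_shift(sp, reference_mz, max_shift)
      sp <- align_spectrum(sp, shift)
    }
    sp
  })
  bin_to_features(processed, peaks = peaks, bin_width = bin_width,
                  tolerance = tolerance)
}
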