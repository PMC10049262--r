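make_sp <- function(intensity, mz = seq_along(intensity)) {
  maldi_spectrum(mz, intensity, "p1", "A")
}

test_that("TopHat removes flat and broad baselines, preserves narrow peaks", {
  # constant spectrum: fully removed
  out <- tophat_baseline(make_sp(rep(3, 20)), 5)
  expect_equal(out$intensity, rep(0, 20))
  # narrow peak and broad plateau, window 3 (hand-derivable case)
  out <- tophat_baseline(make_sp(c(0, 5, 0, 0, 4, 4, 4, 0)), 3)
  expect_equal(out$intensity, c(0, 5, 0, 0, 0, 0, 0, 0))
  expect_equal(out$provenance, "tophat")
  # invalid windows
  expect_error(tophat_baseline(make_sp(rep(1, 10)), 4), "odd")
  expect_error(tophat_baseline(make_sp(rep(1, 10)), 11), "odd|length")
})

test_that("TopHat matches the sliding-extrema oracle and never increases intensity", {
  set.seed(71)
  for (w in c(3, 5, 51)) {
    for (rep in 1:5) {
      n <- sample(w:1000, 1)
      x <- abs(rnorm(n, sd = 3)) + 5 * sin(seq(0, 3, length.out = n))^2
      got <- tophat_baseline(make_sp(x), w)$intensity
      expect_equal(got, tophat_oracle(x, w), tolerance = 1e-12)
      expect_true(all(got <= x + 1e-12))
      expect_true(all(got >= 0))
    }
  }
})

test_that("TopHat is idempotent", {
  set.seed(5)
  x <- abs(rnorm(300)) + seq(0, 4, length.out = 300)
  once <- tophat_baseline(make_sp(x), 21)
  twice <- tophat_baseline(once, 21)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)
})

test_that("TIC normalization scales to target and records the original sum", {
  sp <- tic_normalize(make_sp(c(2, 3, 5)), 1)
  expect_equal(sp$intensity, c(0.2, 0.3, 0.5))
  expect_equal(sp$tic, 10)
  # idempotence at target
  again <- tic_normalize(sp, 1)
  expect_equal(again$intensity, sp$intensity, tolerance = 1e-12)
  # other targets
  expect_equal(tic_normalize(make_sp(c(1, 1)), 100)$intensity, c(50, 50))
  # all-zero spectrum is an error naming the spectrum
  zero <- maldi_spectrum(1:3, c(0, 0, 0), "pat7", "A")
  expect_error(tic_normalize(zero), "pat7")
})

test_that("mass-shift estimation recovers planted shifts on the grid", {
  grid <- seq(600, 700, by = 0.1)
  refs <- c(620, 650, 680)
  y <- rep(0, length(grid))
  y[match(refs, grid)] <- c(5, 8, 3)
  sp0 <- maldi_spectrum(grid, y, "p", "A")
  expect_equal(estimate_mass_shift(sp0, refs), 0)
  # +0.5 Da planted shift recovered within one grid step
  sp_pos <- maldi_spectrum(grid + 0.5, y, "p", "A")
  expect_equal(estimate_mass_shift(sp_pos, refs), 0.5, tolerance = 0.1 + 1e-9)
  sp_neg <- maldi_spectrum(grid - 0.5, y, "p", "A")
  expect_equal(estimate_mass_shift(sp_neg, refs),
               -estimate_mass_shift(sp_pos, refs), tolerance = 1e-9)
  # alignment moves peaks back onto the references
  aligned <- align_spectrum(sp_pos, estimate_mass_shift(sp_pos, refs))
  expect_equal(aligned$mz[which.max(aligned$intensity)], 650,
               tolerance = 0.1 + 1e-9)
  expect_equal(aligned$applied_shift, 0.5, tolerance = 0.1 + 1e-9)
  # no reference inside the range
  expect_error(estimate_mass_shift(sp0, c(100, 200)), "no reference peak")
})

test_that("binning takes the window apex, drops dead features, preserves rows", {
  sp1 <- maldi_spectrum(seq(600, 610, 0.5), c(rep(0, 10), 7, rep(0, 10)),
                        "p1", "A")
  fm <- bin_to_features(list(sp1), peaks = 605, tolerance = 1)
  expect_equal(dim(fm), c(1L, 1L))
  expect_equal(unname(fm$values[1, 1]), 7)
  # two identical spectra -> two identical rows
  fm2 <- bin_to_features(list(sp1, sp1), peaks = 605, tolerance = 1)
  expect_equal(fm2$values[1, ], fm2$values[2, ])
  # dead feature windows are dropped
  fm3 <- bin_to_features(list(sp1), peaks = c(602, 605), tolerance = 1)
  expect_equal(fm3$feature_mz, 605)
  # overlapping explicit windows rejected
  expect_error(bin_to_features(list(sp1), peaks = c(604, 605), tolerance = 1),
               "overlap")
})

test_that("binning windows are half-open [lo, hi)", {
  sp <- maldi_spectrum(c(600, 601, 602, 603, 604), c(1, 2, 9, 4, 5), "p", "A")
  # window [601, 603): includes 601 and 602, excludes 603
  fm <- bin_to_features(list(sp), peaks = 602, tolerance = 1)
  expect_equal(unname(fm$values[1, 1]), 9)
  fm <- bin_to_features(list(sp), peaks = 603.5, tolerance = 0.5)  # [603, 604)
  expect_equal(unname(fm$values[1, 1]), 4)
})

test_that("noise-free binned cohort equals truth means after TIC scaling", {
  coh <- simulate_cohort(noisefree_config())
  fm <- preprocess_cohort(coh$spectra, peaks = coh$truth$peak_mz,
                          tolerance = 0.5)
  # all spectra of a class share one TIC; normalized apex = mean * target/tic
  processed <- lapply(coh$spectra, function(s) tic_normalize(tophat_baseline(s)))
  for (i in c(1, length(coh$spectra))) {
    cl <- fm$class_label[i]
    expected <- coh$truth$per_class_peak_means[, cl] / processed[[i]]$tic
    expect_equal(unname(fm$values[i, ]), unname(expected), tolerance = 1e-9)
  }
})

test_that("binning is permutation-equivariant in spectra order", {
  coh <- simulate_cohort(quick_config(n_patients_per_class = 2))
  perm <- rev(seq_along(coh$spectra))
  a <- bin_to_features(coh$spectra, peaks = coh$truth$peak_mz, tolerance = 0.5)
  b <- bin_to_features(coh$spectra[perm], peaks = coh$truth$peak_mz,
                       tolerance = 0.5)
  expect_equal(b$values, a$values[perm, ])
  expect_equal(b$patient_id, a$patient_id[perm])
})

test_that("per-region subsampling clips, warns and is seed-deterministic", {
  coh <- simulate_cohort(quick_config(n_patients_per_class = 2,
                                      spectra_per_patient = 40))
  sel <- select_spectra_per_region(coh$spectra, n = 17, seed = 3)
  regions <- vapply(sel, `[[`, "", "region_id")
  expect_true(all(table(regions) == 17))
  # fewer available than requested: all retained, with a warning
  small <- coh$spectra[1:10]
  expect_warning(all10 <- select_spectra_per_region(small, 17, seed = 3),
                 "only 10")
  expect_length(all10, 10)
  # determinism
  sel2 <- select_spectra_per_region(coh$spectra, n = 17, seed = 3)
  expect_identical(sel, sel2)
  expect_false(identical(sel,
                         select_spectra_per_region(coh$spectra, 17, seed = 4)))
})

test_that("the canonical processing order is recorded in provenance", {
  coh <- simulate_cohort(quick_config(n_patients_per_class = 2,
                                      spectra_per_patient = 3))
  sp <- coh$spectra[[1]]
  sp <- tophat_baseline(sp)
  sp <- tic_normalize(sp)
  sp <- align_spectrum(sp, estimate_mass_shift(sp, coh$truth$peak_mz))
  expect_equal(sp$provenance, c("tophat", "tic_normalize", "align"))
})
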