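test_that("both models separate well-separated point clouds at resubstitution", {
  fm <- separable_fm(n_per_class = 20, p = 3, delta = 5)
  for (kind in c("lda", "svm")) {
    fit <- fit_model(model_spec(kind), fm$values, fm$class_label)
    pred <- predict(fit, fm$values)
    expect_equal(mean(pred == fm$class_label), 1.0)
  }
  # single-class training is a fit error
  expect_error(fit_model(model_spec("lda"), fm$values[1:5, ],
                         rep("pos", 5)), "two classes")
})

test_that("LDA is well-defined with many more features than samples", {
  maldiclass:::with_seed(31, {
    x <- matrix(rnorm(20 * 100), nrow = 20)
    x[1:10, 1] <- x[1:10, 1] + 4
    y <- rep(c("a", "b"), each = 10)
    fit <- fit_model(model_spec("lda"), x, y)
    expect_true(all(is.finite(fit$w)))
    expect_equal(mean(predict(fit, x) == y), 1.0)
  })
})

test_that("LDA decision function is invariant to duplicating the training set", {
  fm <- separable_fm(n_per_class = 12, p = 4, delta = 2, seed = 7)
  spec <- model_spec("lda", shrinkage = 0.2)
  one <- fit_model(spec, fm$values, fm$class_label)
  dup <- fit_model(spec, rbind(fm$values, fm$values),
                   c(fm$class_label, fm$class_label))
  expect_equal(dup$w, one$w, tolerance = 1e-10)
  expect_equal(dup$threshold, one$threshold, tolerance = 1e-10)
  # with auto shrinkage the predictions still agree
  auto1 <- fit_model(model_spec("lda"), fm$values, fm$class_label)
  auto2 <- fit_model(model_spec("lda"), rbind(fm$values, fm$values),
                     c(fm$class_label, fm$class_label))
  grid <- separable_fm(n_per_class = 30, p = 4, delta = 2, seed = 99)$values
  expect_equal(predict(auto2, grid), predict(auto1, grid))
})

test_that("LOOCV accuracy on permuted labels stays near chance", {
  fm <- null_fm(n_per_class = 25, p = 5, seed = 14)
  n <- 50
  for (kind in c("lda", "svm")) {
    r <- cross_validate(fm, model_spec(kind),
                        cv_scheme("loo", unit = "spectrum"))
    expect_lt(abs(r$accuracy - 0.5), 3 * sqrt(0.25 / n) + 1e-9)
  }
})

test_that("k-fold partitions are disjoint, exhaustive, near-equisized", {
  f <- make_folds(45, 4, seed = 2)
  expect_length(f, 45)
  expect_setequal(unique(f), 1:4)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(12L, 11L, 11L, 11L))
  # many shapes
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:80, 1); k <- sample(2:min(n, 10), 1)
    f <- make_folds(n, k, seed = i)
    sizes <- as.integer(table(factor(f, levels = 1:k)))
    expect_equal(sum(sizes), n)
    expect_lte(diff(range(sizes)), 1L)
  }
  # determinism and seed sensitivity
  expect_identical(make_folds(30, 5, seed = 7), make_folds(30, 5, seed = 7))
  expect_false(identical(make_folds(30, 5, seed = 7),
                         make_folds(30, 5, seed = 8)))
})

test_that("patient mean profiles average each patient's spectra in order", {
  vals <- rbind(c(1, 3), c(3, 5), c(10, 20))
  fm <- feature_matrix(vals, c(700, 710),
                       patient_id = c("p1", "p1", "p2"),
                       class_label = c("a", "a", "b"))
  prof <- patient_mean_profiles(fm)
  expect_equal(dim(prof), c(2L, 2L))
  expect_equal(unname(prof$values[1, ]), c(2, 4))
  expect_equal(unname(prof$values[2, ]), c(10, 20))  # single spectrum: identity
  expect_equal(prof$patient_id, c("p1", "p2"))
  # conflicting labels rejected
  bad <- feature_matrix(vals, c(700, 710), patient_id = rep("p1", 3),
                        class_label = c("a", "a", "b"))
  expect_error(patient_mean_profiles(bad), "conflicting")
})

test_that("a simulated three-genotype cohort yields one profile per patient", {
  cfg <- quick_config(classes = c("BRAF_MUT", "NRAS_MUT", "WT"),
                      n_patients_per_class = 15, spectra_per_patient = 3,
                      mz_min = 600, mz_max = 700, n_peaks = 5,
                      n_discriminative = 3)
  res <- quick_fm(cfg)
  prof <- patient_mean_profiles(res$fm)
  expect_equal(nrow(prof$values), 45)
})

test_that("leave-one-patient-out never splits a patient across train and test", {
  cfg <- quick_config(n_patients_per_class = 5, spectra_per_patient = 4)
  res <- quick_fm(cfg)
  prof <- cross_validate(res$fm, model_spec("lda"),
                         cv_scheme("loo", unit = "patient"))
  # at patient level each unit is a whole patient, so the confusion total
  # equals the number of patients
  expect_equal(sum(prof$confusion), 10)
  # and the collapse itself keeps one row per patient
  expect_equal(nrow(patient_mean_profiles(res$fm)$values), 10)
})

test_that("LOO equals k-fold with k = n on a deterministic model", {
  fm <- separable_fm(n_per_class = 8, p = 3, delta = 1.2, seed = 21)
  spec <- model_spec("lda", shrinkage = 0.3)
  loo <- cross_validate(fm, spec, cv_scheme("loo", unit = "spectrum"))
  kn <- cross_validate(fm, spec, cv_scheme("kfold", k = 16,
                                           unit = "spectrum", seed = 5))
  expect_equal(loo$accuracy, kn$accuracy)
  expect_equal(sort(loo$per_fold_accuracy), sort(kn$per_fold_accuracy))
})

test_that("accuracy equals trace over sum of the stored confusion table", {
  res <- quick_fm(quick_config())
  r <- cross_validate(res$fm, model_spec("lda"),
                      cv_scheme("kfold", k = 4, unit = "spectrum", seed = 2))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  expect_equal(sum(r$confusion), nrow(res$fm$values))
  expect_length(r$per_fold_accuracy, 4)
})

test_that("LOO on n units performs n fits with singleton test sets", {
  fm <- separable_fm(n_per_class = 6, p = 2, delta = 3)
  r <- cross_validate(fm, model_spec("lda"), cv_scheme("loo", unit = "spectrum"))
  expect_length(r$per_fold_accuracy, 12)
  expect_true(all(r$per_fold_accuracy %in% c(0, 1)))  # test sets of size 1
})

test_that("separable simulated cohort reaches high leave-one-patient-out accuracy", {
  cfg <- quick_config(n_patients_per_class = 10, spectra_per_patient = 5,
                      effect_log2fc = 2, noise_cv = 0.1, patient_cv = 0.1,
                      seed = 6)
  res <- quick_fm(cfg)
  r <- cross_validate(res$fm, model_spec("lda"),
                      cv_scheme("loo", unit = "patient"))
  expect_gte(r$accuracy, 0.95)
})

test_that("holdout evaluation is stratified, deterministic and honest on null data", {
  fm <- separable_fm(n_per_class = 20, p = 3, delta = 5)
  r <- holdout_evaluate(fm, model_spec("svm"), 0.3, seed = 1)
  expect_equal(r$accuracy, 1.0)
  expect_equal(sum(r$confusion), 12)  # 6 per class held out
  r2 <- holdout_evaluate(fm, model_spec("svm"), 0.3, seed = 1)
  expect_identical(r$confusion, r2$confusion)
  # null data: near chance
  nf <- null_fm(n_per_class = 40, p = 5, seed = 3)
  rn <- holdout_evaluate(nf, model_spec("lda"), 0.4, seed = 2)
  n_test <- sum(rn$confusion)
  expect_lt(abs(rn$accuracy - 0.5), 3 * sqrt(0.25 / n_test) + 1e-9)
  # degenerate fraction
  small <- separable_fm(n_per_class = 3, p = 2, delta = 5)
  expect_error(holdout_evaluate(small, model_spec("lda"), 0.05, seed = 1),
               "holdout fraction")
})

test_that("PCA scores capture structure and report sane variance fractions", {
  # exactly collinear data: one component explains everything
  line <- outer(seq(-2, 2, length.out = 10), c(1, 2, -1))
  fm <- feature_matrix(line + 5, c(700, 710, 720),
                       patient_id = sprintf("p%d", 1:10),
                       class_label = rep(c("a", "b"), 5))
  p <- pca_scores(fm, 3)
  expect_equal(p$explained_variance[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  # constant matrix errors
  const <- feature_matrix(matrix(2, 5, 4), c(700, 710, 720, 730),
                          patient_id = sprintf("p%d", 1:5),
                          class_label = rep(c("a", "b"), length.out = 5))
  expect_error(pca_scores(const), "degenerate")
  # separated classes separate along the leading components
  sep <- separable_fm(n_per_class = 15, p = 5, delta = 4, seed = 8)
  ps <- pca_scores(sep, 3)
  lab <- sep$class_label
  d_between <- abs(mean(ps$scores[lab == "pos", 1]) -
                   mean(ps$scores[lab == "neg", 1]))
  expect_gt(d_between, 2 * sd(ps$scores[lab == "pos", 1]))
})
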