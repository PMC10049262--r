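#' Run the full classification pipeline
#'
#' Executes the complete workflow for one pairwise comparison: obtain spectra
#' (simulate a cohort or read them from disk), subsample spectra per tumor
#' region, preprocess (TopHat -> TIC -> align -> bin), run PCA, select
#' features (AUROC threshold or forward selection, recomputed per analysis
#' level), and cross-validate the requested model x CV-design x level grid.
#' End-to-end deterministic under the configured seeds.
#'
#' @param config A named list, or the path of a YAML file, with entries
#' \describe{
#'   \item{simulation}{[cohort_config()] fields (mutually exclusive with
#'     `input_dir`);}
#'   \item{input_dir}{directory readable by [read_spectra()];}
#'   \item{comparison}{`class_a`, `class_b` — the two labels to classify;}
#'   \item{preprocess}{`n_per_region` (default 17), `window_points`,
#'     `tic_target` (1), `align` (TRUE), `max_shift` (1), `tolerance` (0.5),
#'     `bin_width` (2.0; ignored for simulated cohorts, which bin at the
#'     generator's peak list), `reference_mz` (optional explicit alignment
#'     peaks);}
#'   \item{selection}{`method` ("auroc" or "ffs"), `threshold` (0.8),
#'     `max_features` (30), `min_improvement` (0.001);}
#'   \item{models}{character subset of `c("lda", "svm")`;}
#'   \item{designs}{list of lists with `design` and optional `k`, e.g.
#'     `list(list(design = "loo"), list(design = "kfold", k = 4))`;}
#'   \item{levels}{character subset of `c("spectrum", "patient")`;}
#'   \item{seed}{integer master seed.}
#' }
#' @return An object of class `run_report`: the config snapshot, PCA
#'   explained variance, per-level selection output, the list of `cv_result`
#'   objects, the fold-change table of the selected features, package
#'   version and seed registry.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  cmp <- config$comparison
  if (is.null(cmp$class_a) || is.null(cmp$class_b))
    stop("config$comparison must name class_a and class_b", call. = FALSE)

  # --- input stage -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop(sprintf("input_dir '%s' does not exist", config$input_dir),
           call. = FALSE)
    spectra <- read_spectra(config$input_dir)
  } else {
    sim <- config$simulation
    if (is.null(sim)) sim <- list()
    if (is.null(sim$seed)) sim$seed <- seed
    cohort <- do.call(cohort_config, sim)
    cohort <- simulate_cohort(cohort)
    spectra <- cohort$spectra
    truth <- cohort$truth
  }

  # --- preprocessing ---------------------------------------------------
  pp <- config$preprocess
  if (is.null(pp)) pp <- list()
  n_per_region <- if (is.null(pp$n_per_region)) 17 else pp$n_per_region
  tolerance <- if (is.null(pp$tolerance)) 0.5 else pp$tolerance
  align <- if (is.null(pp$align)) TRUE else isTRUE(pp$align)
  refs <- pp$reference_mz
  peaks <- NULL
  bin_width <- NULL
  if (!is.null(truth)) {
    peaks <- truth$peak_mz
    if (align && is.null(refs)) refs <- truth$peak_mz
  } else {
    bin_width <- if (is.null(pp$bin_width)) 2.0 else pp$bin_width
  }
  fm_all <- preprocess_cohort(
    spectra,
    window_points = pp$window_points,
    tic_target = if (is.null(pp$tic_target)) 1 else pp$tic_target,
    reference_mz = if (align) refs else NULL,
    max_shift = if (is.null(pp$max_shift)) 1 else pp$max_shift,
    peaks = peaks, bin_width = bin_width, tolerance = tolerance,
    n_per_region = n_per_region, seed = seed
  )
  fm <- fm_classes(fm_all, c(cmp$class_a, cmp$class_b))

  pca <- pca_scores(fm, n_components = min(3, ncol(fm$values), nrow(fm$values)))

  # --- selection + classification grid ---------------------------------
  sel_cfg <- config$selection
  if (is.null(sel_cfg)) sel_cfg <- list()
  method <- if (is.null(sel_cfg$method)) "auroc" else sel_cfg$method
  threshold <- if (is.null(sel_cfg$threshold)) 0.8 else sel_cfg$threshold
  models <- if (is.null(config$models)) c("lda", "svm") else config$models
  levels <- if (is.null(config$levels)) c("spectrum", "patient") else config$levels
  designs <- if (is.null(config$designs))
    list(list(design = "loo"), list(design = "kfold", k = 4),
         list(design = "kfold", k = 10))
  else config$designs

  selection <- list()
  results <- list()
  for (lev in levels) {
    fm_lev <- cv_units(fm, lev)
    sel_mz <- if (method == "auroc") {
      sc <- auroc_per_feature(fm_lev, cmp$class_a)
      filter_by_auroc(sc, threshold)$feature_mz
    } else {
      tr <- forward_feature_selection(
        fm_lev, model_spec(models[1]),
        cv_scheme("kfold", k = 4, unit = lev, seed = seed),
        max_features = if (is.null(sel_cfg$max_features)) 30
                       else sel_cfg$max_features,
        min_improvement = if (is.null(sel_cfg$min_improvement)) 0.001
                          else sel_cfg$min_improvement)
      sort(tr$selected_mz)
    }
    if (length(sel_mz) == 0) sel_mz <- fm$feature_mz  # vacuous selection
    selection[[lev]] <- sel_mz
    fm_sel <- fm_subset(fm, features = sel_mz)
    for (mod in models) {
      for (d in designs) {
        scheme <- cv_scheme(d$design, k = d$k, unit = lev,
                            holdout_fraction = d$holdout_fraction,
                            seed = seed)
        results[[length(results) + 1L]] <-
          cross_validate(fm_sel, model_spec(mod), scheme)
      }
    }
  }

  fold_changes <- fold_change_table(fm, cmp$class_a, cmp$class_b,
                                    features = selection[[levels[1]]])

  structure(list(
    config = config,
    n_spectra = nrow(fm$values),
    pca_explained_variance = pca$explained_variance,
    selection = selection,
    cv_results = results,
    accuracy = accuracy_table(results, selection = method),
    fold_changes = fold_changes,
    truth = truth,
    version = as.character(packageVersion("maldiclass")),
    seed = seed
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s vs %s | %d spectra | seed %d | v%s\n",
              x$config$comparison$class_a, x$config$comparison$class_b,
              x$n_spectra, x$seed, x$version))
  cat(sprintf("features selected: %s\n",
              paste(sprintf("%s: %d", names(x$selection),
                            lengths(x$selection)), collapse = ", ")))
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `accuracy.csv`, `fold_changes.csv` and a `report.json` summary
#' (config snapshot, selected features, accuracies, version, seed).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_run_report <- function(report, directory) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write.csv(report$accuracy, file.path(directory, "accuracy.csv"),
            row.names = FALSE)
  write.csv(report$fold_changes, file.path(directory, "fold_changes.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config = report$config, selection = report$selection,
         accuracy = report$accuracy, n_spectra = report$n_spectra,
         pca_explained_variance = report$pca_explained_variance,
         version = report$version, seed = report$seed),
    file.path(directory, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}
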