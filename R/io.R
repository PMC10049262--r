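#' Write spectra as two-column text files with a CSV manifest
#'
#' Each spectrum becomes a whitespace-delimited two-column file (m/z,
#' intensity) written at full double precision; `manifest.csv` records the
#' file name and the patient / class / region metadata.
#'
#' @param spectra List of [maldi_spectrum()] objects.
#' @param directory Output directory (created if absent).
#' @return Path of the manifest file, invisibly.
#' @export
write_spectra <- function(spectra, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  files <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "maldi_spectrum"))
    files[i] <- sprintf("spectrum_%05d.txt", i)
    lines <- sprintf("%.17g %.17g", sp$mz, sp$intensity)
    writeLines(lines, file.path(directory, files[i]))
  }
  manifest <- data.frame(
    file = files,
    patient_id = vapply(spectra, `[[`, "", "patient_id"),
    class_label = vapply(spectra, `[[`, "", "class_label"),
    region_id = vapply(spectra, `[[`, "", "region_id"),
    stringsAsFactors = FALSE
  )
  path <- file.path(directory, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra written by [write_spectra()]
#'
#' @param directory Directory containing `manifest.csv` and the two-column
#'   spectrum files.
#' @return List of [maldi_spectrum()] objects (empty, with a warning, when no
#'   manifest is present).
#' @export
read_spectra <- function(directory) {
  manifest_path <- file.path(directory, "manifest.csv")
  if (!file.exists(manifest_path)) {
    warning(sprintf("no manifest found in '%s'; returning no spectra",
                    directory))
    return(list())
  }
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(directory, manifest$file[i])
    if (!file.exists(path))
      stop(sprintf("spectrum file '%s' listed in manifest is missing", path),
           call. = FALSE)
    m <- tryCatch(
      matrix(scan(path, what = double(), quiet = TRUE), ncol = 2, byrow = TRUE),
      error = function(e) stop(sprintf("malformed spectrum file '%s': %s",
                                       path, conditionMessage(e)),
                               call. = FALSE)
    )
    bad <- which(diff(m[, 1]) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone m/z in '%s' at line %d", path, bad[1] + 1L),
           call. = FALSE)
    if (any(m[, 2] < 0))
      stop(sprintf("negative intensity in '%s' at line %d", path,
                   which(m[, 2] < 0)[1]), call. = FALSE)
    maldi_spectrum(m[, 1], m[, 2],
                   patient_id = manifest$patient_id[i],
                   class_label = manifest$class_label[i],
                   region_id = manifest$region_id[i])
  })
}

#' Read a cohort configuration from a YAML-style key-value file
#'
#' Keys must match [cohort_config()] argument names.
#'
#' @param path File path.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(cohort_config)))
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(cohort_config, vals)
}
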