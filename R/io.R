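# delimited-text I/O for trials and cohorts ----------------------------------

#' Write a trial recording to delimited text plus a JSON sidecar
#'
#' The streams go to `<path>.csv` with columns `t, F, m1x, m1y, m1z, m2x,
#' m2y, m2z` (missing marker samples as empty fields); event timestamps,
#' patient metadata and (optionally) generator ground truth go to
#' `<path>.json`.
#'
#' @param trial A `trial_recording`.
#' @param path Output path without extension.
#' @param include_truth Include the generator's ground-truth parameters in
#'   the sidecar (default TRUE; synthetic data only).
#' @return Invisibly, the two file paths.
#' @export
write_trial <- function(trial, path, include_truth = TRUE) {
  stopifnot(inherits(trial, "trial_recording"))
  d <- trial$data
  out <- tibble(t = d$time, F = d$force,
                m1x = d$m1x, m1y = d$m1y, m1z = d$m1z,
                m2x = d$m2x, m2y = d$m2y, m2z = d$m2z)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  readr::write_csv(out, csv, na = "")
  side <- list(events = as.list(trial$events), patient = trial$patient)
  if (include_truth && !is.null(trial$truth)) {
    side$truth <- list(
      stiffness_k = trial$truth$capsule$stiffness_k,
      puncture_force_fmax = trial$truth$capsule$puncture_force_fmax,
      post_puncture_force = trial$truth$capsule$post_puncture_force,
      speed_effective = trial$truth$speed_effective
    )
  }
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a trial recording written by [write_trial()]
#'
#' @param path Path without extension (the `.csv` / `.json` pair).
#' @return A `trial_recording` (ground truth restored when present in the
#'   sidecar).
#' @export
read_trial <- function(path) {
  d <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE,
                       na = c("", "NA"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- list(
      capsule = capsule_model(side$truth$stiffness_k,
                              side$truth$puncture_force_fmax,
                              side$truth$post_puncture_force %||% 0),
      speed_effective = side$truth$speed_effective
    )
  }
  new_trial_recording(
    data = tibble(time = d$t, force = d$F,
                  m1x = d$m1x, m1y = d$m1y, m1z = d$m1z,
                  m2x = d$m2x, m2y = d$m2y, m2z = d$m2z),
    events = unlist(side$events),
    patient = side$patient,
    truth = truth
  )
}

#' Write a cohort as a directory of trials plus a manifest
#'
#' @param cohort A `trial_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    base <- sprintf("trial_%02d", i)
    write_trial(cohort[[i]], file.path(dir, base))
    files[i] <- base
  }
  spec <- attr(cohort, "spec")
  manifest <- list(n_trials = length(cohort), files = files,
                   spec = if (is.null(spec)) NULL else unclass(spec))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A `trial_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- lapply(manifest$files, function(f) read_trial(file.path(dir, f)))
  spec <- NULL
  if (!is.null(manifest$spec)) {
    spec <- manifest$spec
    spec$seed <- spec$seed %||% NULL
    spec <- do.call(cohort_spec, spec[!vapply(spec, is.null, logical(1))])
  }
  structure(trials, class = "trial_cohort", spec = spec)
}

#' Write a processed trial as a TSV table
#'
#' Columns: `t`, `F_filtered`, `travel_distance`, `phase_label`, `valid`.
#'
#' @param processed A `processed_trial`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_processed <- function(processed, path) {
  stopifnot(inherits(processed, "processed_trial"))
  d <- processed$data
  readr::write_tsv(
    tibble(t = d$time, F_filtered = d$force,
           travel_distance = d$travel_distance,
           phase_label = as.character(d$phase), valid = d$valid),
    path, na = ""
  )
  invisible(path)
}
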