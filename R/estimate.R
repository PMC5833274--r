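# stiffness, puncture force and cohort statistics ----------------------------

#' Fit joint-capsule stiffness by least squares
#'
#' Fits Hooke's law `F = k x` over the Phase-II loading window by
#' through-origin least squares, `k = sum(x F) / sum(x^2)`; the model has
#' no offset term, matching a spring loaded from the set point where both
#' force and displacement are zero. An intercept variant is available for
#' diagnostics but is not the default. Displacement is re-zeroed at the
#' first sample of the fit window.
#'
#' @param data A `processed_trial` or a data frame with columns `force`
#'   (N), `travel_distance` (m) and optionally `time`, `phase`, `valid`.
#' @param window Either `NULL` (use Phase-II valid samples) or a numeric
#'   `c(t_min, t_max)` time interval (requires a `time` column).
#' @param intercept Include an intercept term (default FALSE).
#' @return A `stiffness_fit` with `k_hat` (N/m), `intercept` (N, 0 for the
#'   through-origin fit), `residual_rms` (N), `n_samples`, `fit_window`.
#' @export
#' @examples
#' x <- seq(0, 0.02, by = 1e-3)
#' fit <- fit_stiffness(data.frame(force = 1000 * x, travel_distance = x))
#' fit$k_hat  # 1000
fit_stiffness <- function(data, window = NULL, intercept = FALSE) {
  if (inherits(data, "processed_trial")) data <- data$data
  stopifnot(all(c("force", "travel_distance") %in% names(data)))
  keep <- !is.na(data$travel_distance) & !is.na(data$force)
  if ("valid" %in% names(data)) keep <- keep & data$valid
  if (is.null(window)) {
    if ("phase" %in% names(data)) keep <- keep & data$phase == "II"
  } else {
    stopifnot("time" %in% names(data))
    keep <- keep & data$time >= window[1] & data$time <= window[2]
  }
  x <- data$travel_distance[keep]
  f <- data$force[keep]
  if (length(x) < 2L) {
    stop_portalsim("fit window has fewer than 2 valid samples",
                   class = "portalsim_degenerate_fit")
  }
  x <- x - x[1L]
  sxx <- sum(x^2)
  if (sxx <= .Machine$double.eps * max(1, max(abs(x)))^2 ||
      diff(range(x)) == 0) {
    stop_portalsim("degenerate displacement: no spread in the fit window",
                   class = "portalsim_degenerate_fit")
  }
  if (intercept) {
    cf <- coef(lm(f ~ x))
    b0 <- unname(cf[1]); k <- unname(cf[2])
    res <- f - (b0 + k * x)
  } else {
    k <- sum(x * f) / sxx
    b0 <- 0
    res <- f - k * x
  }
  tw <- if ("time" %in% names(data)) range(data$time[keep]) else c(NA_real_, NA_real_)
  structure(
    list(k_hat = k, intercept = b0,
         residual_rms = sqrt(mean(res^2)),
         n_samples = length(x), fit_window = tw,
         with_intercept = intercept),
    class = "stiffness_fit"
  )
}

#' Extract the peak puncture force of a trial
#'
#' The puncture force is the maximum of the filtered force over the
#' Phase-II loading window (the loading is monotone up to puncture, so
#' the maximum coincides with the force at the end of Phase II while
#' staying robust to filter ripple). Ties are resolved to the last
#' occurrence.
#'
#' @param data A `processed_trial` or a data frame with columns `force`
#'   and `time` (and optionally `phase`).
#' @param window `NULL` (use Phase II) or a `c(t_min, t_max)` interval.
#' @return A `puncture_fit` with `f_max_hat` (N) and `t_at_max` (s).
#' @export
extract_puncture_force <- function(data, window = NULL) {
  if (inherits(data, "processed_trial")) data <- data$data
  stopifnot(all(c("force", "time") %in% names(data)))
  keep <- !is.na(data$force)
  if (is.null(window)) {
    if ("phase" %in% names(data)) keep <- keep & data$phase == "II"
  } else {
    keep <- keep & data$time >= window[1] & data$time <= window[2]
  }
  if (!any(keep)) {
    stop_portalsim("empty extraction window",
                   class = "portalsim_degenerate_fit")
  }
  f <- data$force[keep]
  tt <- data$time[keep]
  fmax <- max(f)
  i <- max(which(f == fmax))   # last occurrence on ties
  structure(list(f_max_hat = fmax, t_at_max = tt[i]),
            class = "puncture_fit")
}

#' Estimate capsule parameters for every trial of a cohort
#'
#' Convenience wrapper: preprocesses each trial and returns one row per
#' patient with the peak-force and stiffness estimates (stiffness is `NA`
#' for position-invalid trials) together with the eligibility flags needed
#' by [summarize_cohort()].
#'
#' @param cohort A `trial_cohort` or list of `trial_recording`s.
#' @param ... Passed to [process_trial()].
#' @return A tibble with columns `patient_id`, `f_max_hat`, `t_at_max`,
#'   `k_hat`, `residual_rms`, `position_valid`, `rom_eligible`,
#'   `synovitis_excluded`, and (when generator truth is present) `k_true`,
#'   `fmax_true`.
#' @export
estimate_cohort <- function(cohort, ...) {
  rows <- map(cohort, function(tr) {
    pt <- process_trial(tr, ...)
    pf <- extract_puncture_force(pt)
    kf <- if (pt$position_valid) fit_stiffness(pt) else NULL
    tibble(
      patient_id = pt$patient$id %||% NA_character_,
      f_max_hat = pf$f_max_hat,
      t_at_max = pf$t_at_max,
      k_hat = if (is.null(kf)) NA_real_ else kf$k_hat,
      residual_rms = if (is.null(kf)) NA_real_ else kf$residual_rms,
      position_valid = pt$position_valid,
      rom_eligible = isTRUE(pt$patient$rom_eligible),
      synovitis_excluded = isTRUE(pt$patient$synovitis_excluded),
      k_true = pt$truth$capsule$stiffness_k %||% NA_real_,
      fmax_true = pt$truth$capsule$puncture_force_fmax %||% NA_real_
    )
  })
  bind_rows(rows)
}

#' Summarize cohort estimates with clinical exclusions
#'
#' Patients flagged `synovitis_excluded` (frozen shoulder confirmed on the
#' arthroscopic image) or failing the passive range-of-motion eligibility
#' screen are excluded from all statistics and logged with a reason.
#' Puncture force is summarized over every included patient; stiffness
#' only over included patients whose displacement stream is position-valid
#' (marker occlusion lost the others). Spread is the sample SD (n - 1).
#'
#' @param estimates A tibble as produced by [estimate_cohort()].
#' @return A `cohort_summary` with counts, per-parameter mean/SD/min/max,
#'   and an `exclusion_log` tibble.
#' @export
summarize_cohort <- function(estimates) {
  req <- c("patient_id", "f_max_hat", "k_hat", "position_valid",
           "rom_eligible", "synovitis_excluded")
  stopifnot(all(req %in% names(estimates)))
  excl <- dplyr::transmute(
    dplyr::filter(estimates, .data$synovitis_excluded | !.data$rom_eligible),
    patient_id = .data$patient_id,
    reason = dplyr::if_else(.data$synovitis_excluded,
                            "synovitis on arthroscopic image",
                            "failed passive ROM eligibility")
  )
  inc <- dplyr::filter(estimates, !.data$synovitis_excluded, .data$rom_eligible)
  if (nrow(inc) == 0L) {
    stop_portalsim("no patients remain after exclusions",
                   class = "portalsim_empty_cohort")
  }
  ks <- inc$k_hat[inc$position_valid & !is.na(inc$k_hat)]
  structure(
    list(
      n_included = nrow(inc), n_excluded = nrow(excl),
      n_position_valid = length(ks),
      fmax_mean = mean(inc$f_max_hat), fmax_sd = sample_sd(inc$f_max_hat),
      fmax_min = min(inc$f_max_hat), fmax_max = max(inc$f_max_hat),
      k_mean = if (length(ks)) mean(ks) else NA_real_,
      k_sd = if (length(ks) > 1L) sample_sd(ks) else NA_real_,
      k_min = if (length(ks)) min(ks) else NA_real_,
      k_max = if (length(ks)) max(ks) else NA_real_,
      exclusion_log = excl
    ),
    class = "cohort_summary"
  )
}
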