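# phase segmentation and puncture detection ----------------------------------

new_phase_segmentation <- function(t0, t_start, t_puncture, t_end, source) {
  structure(
    list(t0 = t0, t_start = t_start, t_puncture = t_puncture,
         t_end = t_end, source = source),
    class = "phase_segmentation"
  )
}

#' Segment a trial into the three phases of portal placement
#'
#' Phase boundaries come from the recorded event timestamps (as noted by
#' the circulating nurse in the operating-room protocol): Phase I is
#' `[t0, t_start)`, Phase II the closed loading interval
#' `[t_start, t_puncture]`, and Phase III `(t_puncture, t_end]`. Boundary
#' samples belong to Phase II. When timestamps are missing or unordered
#' and `auto_fallback = TRUE`, the puncture time is recovered from the
#' filtered force trace by [detect_puncture_auto()] (with `t_start` taken
#' as the recording start); otherwise the trial is rejected.
#'
#' @param trial A `trial_recording`.
#' @param auto_fallback Fall back to force-based puncture detection when
#'   timestamps are unusable (default FALSE).
#' @param cutoff Filter cut-off in Hz used by the fallback detector.
#' @param ... Passed to [detect_puncture_auto()] by the fallback.
#' @return A `phase_segmentation` with `source` `"timestamps"` or
#'   `"auto"`.
#' @export
segment_phases <- function(trial, auto_fallback = FALSE, cutoff = 5, ...) {
  stopifnot(inherits(trial, "trial_recording"))
  tt <- trial$data$time
  ev <- trial$events
  rate <- 1 / (tt[2] - tt[1])
  ok <- !is.null(ev) && all(c("t_start", "t_puncture", "t_end") %in% names(ev)) &&
    !anyNA(ev[c("t_start", "t_puncture", "t_end")]) &&
    ev["t_start"] <= ev["t_puncture"] && ev["t_puncture"] <= ev["t_end"] &&
    ev["t_start"] >= tt[1] && ev["t_end"] <= tt[length(tt)]
  if (ok) {
    if (ev[["t_puncture"]] - ev[["t_start"]] < 1 / rate) {
      stop_portalsim("zero-length Phase II: t_start equals t_puncture",
                     class = "portalsim_degenerate_phase")
    }
    return(new_phase_segmentation(tt[1], ev[["t_start"]], ev[["t_puncture"]],
                                  ev[["t_end"]], source = "timestamps"))
  }
  if (!auto_fallback) {
    stop_portalsim("missing or unordered event timestamps",
                   class = "portalsim_bad_timestamps")
  }
  f <- lowpass_filter(trial$data$force, rate = rate, cutoff = cutoff)
  tp <- detect_puncture_auto(f, rate = rate, time = tt, ...)
  new_phase_segmentation(tt[1], tt[1], tp, tt[length(tt)], source = "auto")
}

#' Label each sample of a time grid with its phase
#'
#' @param time Numeric vector of sample times.
#' @param segmentation A `phase_segmentation`.
#' @return Factor with levels `"I"`, `"II"`, `"III"`.
#' @export
phase_labels <- function(time, segmentation) {
  # tolerance absorbs float jitter from serialized timestamps so boundary
  # samples keep their Phase-II membership
  tol <- 1e-9 * max(1, abs(segmentation$t_end))
  out <- ifelse(time < segmentation$t_start - tol, "I",
                ifelse(time <= segmentation$t_puncture + tol, "II", "III"))
  factor(out, levels = c("I", "II", "III"))
}

#' Detect the puncture instant from a filtered force trace
#'
#' A convenience detector for recordings without event timestamps: the
#' puncture is declared at the earliest sample where the force has fallen
#' by more than `drop_fraction` of its running maximum, provided the
#' maximum was attained within the trailing `window` and exceeds
#' `min_peak` (so Phase-I contact jitter cannot trigger a detection).
#'
#' @param force Filtered force trace in N.
#' @param rate Sampling rate in Hz.
#' @param drop_fraction Fractional drop from the running maximum that
#'   qualifies as a puncture (default 0.25).
#' @param window Maximum time in s between the running maximum and the
#'   qualifying drop (default 0.5 s; must span at least 2 samples).
#' @param min_peak Minimum running-maximum force in N for a drop to count
#'   (default 10 N).
#' @param time Optional sample-time vector; defaults to a 0-based uniform
#'   grid at `rate`.
#' @return The puncture time in s (time of the qualifying drop sample).
#' @export
detect_puncture_auto <- function(force, rate, drop_fraction = 0.25,
                                 window = 0.5, min_peak = 10, time = NULL) {
  assert_number(drop_fraction, "drop_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(window, "window", lower = 2 / rate)
  if (is.null(time)) time <- (seq_along(force) - 1) / rate
  runmax <- cummax(force)
  t_at_max <- time[cummax(ifelse(force >= runmax, seq_along(force), 1L))]
  hit <- which(runmax >= min_peak &
                 force < (1 - drop_fraction) * runmax &
                 (time - t_at_max) <= window)
  if (length(hit) == 0L) {
    stop_portalsim("no puncture detected", class = "portalsim_no_puncture")
  }
  time[hit[1L]]
}
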