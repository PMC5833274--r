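# trial preprocessing orchestration ------------------------------------------

#' Preprocess a raw trial recording
#'
#' Turns a raw `trial_recording` into analysis-ready traces:
#' \enumerate{
#'   \item phases are segmented from the event timestamps
#'     ([segment_phases()]);
#'   \item force is low-pass filtered at `cutoff` Hz, zero-phase; by
#'     default each phase segment is filtered separately, because the
#'     event timestamps mark physical discontinuities (first contact,
#'     puncture) that a filter run across them would smear into the
#'     loading interval;
#'   \item shaft-projected travel distance is computed from the markers
#'     ([compute_travel_distance()]), referenced to zero at `t_start`, and
#'     filtered the same way wherever the phase span has no marker gaps;
#'   \item the trial is flagged `position_valid = FALSE` when its Phase II
#'     contains a marker gap longer than `gap_limit` seconds (an
#'     unrecoverable camera occlusion).
#' }
#'
#' @param trial A `trial_recording`.
#' @param cutoff Low-pass cut-off in Hz (default 5); `NULL` skips
#'   filtering.
#' @param by_phase Filter each phase segment separately (default TRUE).
#' @param max_gap Longest marker gap in samples repaired by linear
#'   interpolation (default 5).
#' @param gap_limit Longest tolerated Phase-II occlusion in seconds before
#'   the displacement stream is declared invalid (default 0.2).
#' @param auto_fallback Passed to [segment_phases()].
#' @return A `processed_trial`: list with `data` (tibble `time`,
#'   `force_raw`, `force`, `travel_distance`, `phase`, `valid`),
#'   `segmentation`, `position_valid`, `events`, `patient`, `truth`.
#' @export
#' @examples
#' tr <- generate_trial(capsule_model(1000, 50), sensor_noise(0, 0))
#' pt <- process_trial(tr)
#' max(pt$data$force[pt$data$phase == "II"])  # 50
process_trial <- function(trial, cutoff = 5, by_phase = TRUE,
                          max_gap = 5L, gap_limit = 0.2,
                          auto_fallback = FALSE) {
  stopifnot(inherits(trial, "trial_recording"))
  d <- trial$data
  n <- nrow(d)
  rate <- 1 / (d$time[2] - d$time[1])
  seg <- segment_phases(trial, auto_fallback = auto_fallback, cutoff = cutoff %||% 5)
  phase <- phase_labels(d$time, seg)

  i_start <- which.min(abs(d$time - seg$t_start))
  kin <- compute_travel_distance(d, reference_index = i_start,
                                 max_gap = max_gap)

  breaks <- sort(unique(c(max(which(phase == "I"), 0L),
                          max(which(phase == "II"), 0L))))
  breaks <- breaks[breaks > 0L & breaks < n]

  force_f <- d$force
  travel_f <- kin$travel_distance
  if (!is.null(cutoff)) {
    force_f <- if (by_phase) {
      filter_by_segment(d$force, rate, cutoff, breaks)
    } else {
      lowpass_filter(d$force, rate, cutoff)
    }
    # travel can only be filtered over gap-free spans
    travel_f <- if (by_phase) {
      filter_by_segment(kin$travel_distance, rate, cutoff, breaks)
    } else if (!anyNA(kin$travel_distance)) {
      lowpass_filter(kin$travel_distance, rate, cutoff)
    } else {
      kin$travel_distance
    }
  }

  in2 <- phase == "II"
  gap2 <- !kin$valid[in2]
  position_valid <- kin$valid[i_start] && !all(gap2) &&
    longest_run(gap2) <= round(gap_limit * rate)

  structure(
    list(
      data = tibble(
        time = d$time, force_raw = d$force, force = force_f,
        travel_distance = travel_f, phase = phase, valid = kin$valid
      ),
      segmentation = seg, position_valid = position_valid,
      events = trial$events, patient = trial$patient, truth = trial$truth
    ),
    class = "processed_trial"
  )
}

longest_run <- function(flag) {
  if (length(flag) == 0L || !any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}
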