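# shaft-projected travel distance --------------------------------------------

#' Shaft-projected cumulative travel distance from two shaft markers
#'
#' The instrument's travel is the cumulative sum of per-frame midpoint
#' displacements projected onto the instantaneous shaft axis: with markers
#' m1 and m2 on the shaft, the axis at frame i is the unit vector
#' `u_i = (m2_i - m1_i) / |m2_i - m1_i|`, the step is the midpoint change
#' `dp_i = mid_i - mid_{i-1}`, and the travel distance accumulates
#' `u_i . dp_i`. The result is re-referenced so travel is 0 at
#' `reference_index`. This projection is invariant under rigid rotation
#' and translation of the camera frame.
#'
#' Marker gaps of at most `max_gap` consecutive samples are filled by
#' linear interpolation; longer gaps (and frames with coincident markers)
#' are masked invalid, with the displacement bridged between the valid
#' frames on either side.
#'
#' @param markers Data frame with marker columns `m1x`, `m1y`, `m1z`,
#'   `m2x`, `m2y`, `m2z` (m); a `trial_recording` is also accepted.
#' @param reference_index Sample index at which travel distance is zeroed
#'   (must be a valid frame).
#' @param max_gap Longest marker gap, in samples, recovered by linear
#'   interpolation (default 5).
#' @return A tibble with one row per input frame: `travel_distance` (m,
#'   `NA` where invalid), `axis_x/y/z` (unit shaft axis), and `valid`.
#' @export
#' @examples
#' tr <- generate_trial(capsule_model(1000, 50), sensor_noise(0, 0))
#' kt <- compute_travel_distance(tr, reference_index = 201)
#' kt$travel_distance[201]  # 0
compute_travel_distance <- function(markers, reference_index = 1L,
                                    max_gap = 5L) {
  if (inherits(markers, "trial_recording")) markers <- markers$data
  cols <- c("m1x", "m1y", "m1z", "m2x", "m2y", "m2z")
  stopifnot(all(cols %in% names(markers)))
  m <- as.matrix(markers[cols])
  n <- nrow(m)
  assert_number(reference_index, "reference_index", lower = 1, upper = n)
  reference_index <- as.integer(reference_index)

  if (max_gap > 0L && anyNA(m)) {
    m <- apply(m, 2, function(col) {
      zoo::na.approx(col, maxgap = max_gap, na.rm = FALSE)
    })
  }

  d <- m[, 4:6, drop = FALSE] - m[, 1:3, drop = FALSE]
  sep <- sqrt(rowSums(d^2))
  valid <- stats::complete.cases(m) & sep > .Machine$double.eps^0.5
  axis <- d / ifelse(sep > 0, sep, NA_real_)
  mid <- (m[, 1:3, drop = FALSE] + m[, 4:6, drop = FALSE]) / 2

  if (!valid[reference_index]) {
    stop_portalsim("reference sample has no valid marker data",
                   class = "portalsim_invalid_reference")
  }

  # per-step projected increments between consecutive valid frames
  # (gaps longer than max_gap are bridged by the net displacement)
  travel <- rep(NA_real_, n)
  vidx <- which(valid)
  inc <- numeric(length(vidx))
  if (length(vidx) > 1L) {
    cur <- vidx[-1L]
    prev <- vidx[-length(vidx)]
    step <- mid[cur, , drop = FALSE] - mid[prev, , drop = FALSE]
    inc[-1L] <- rowSums(axis[cur, , drop = FALSE] * step)
  }
  cum <- cumsum(inc)
  travel[vidx] <- cum - cum[match(reference_index, vidx)]

  tibble(
    travel_distance = travel,
    axis_x = ifelse(valid, axis[, 1], NA_real_),
    axis_y = ifelse(valid, axis[, 2], NA_real_),
    axis_z = ifelse(valid, axis[, 3], NA_real_),
    valid = valid
  )
}
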