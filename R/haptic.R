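# virtual 1-DOF haptic device ------------------------------------------------

#' Quantize a tip position to the encoder grid
#'
#' The device senses tip position through a rotary encoder on the cable
#' reel; the linear resolution is
#' `2 pi reel_radius / (encoder_counts_per_rev * quadrature_multiplier)`.
#' Positions are floored to the grid (rounding toward -Inf), which makes
#' quantization a deterministic idempotent projection.
#'
#' @param x Position(s) in m.
#' @param spec A [haptic_device_spec()].
#' @return Quantized position(s) in m.
#' @export
#' @examples
#' quantize_position(1e-4, haptic_device_spec())  # 9.203e-05
quantize_position <- function(x, spec) {
  res <- encoder_resolution(spec)
  floor(x / res) * res
}

#' Initial state of the virtual device
#'
#' @param capsule_position Position of the virtual capsule surface along
#'   the insertion axis, in m.
#' @param tip_position Initial tip position in m.
#' @return A `haptic_state`.
#' @export
haptic_state <- function(capsule_position = 0, tip_position = 0) {
  structure(
    list(tip_position = tip_position, capsule_position = capsule_position,
         punctured = FALSE, commanded_force = 0, time = 0),
    class = "haptic_state"
  )
}

#' Advance the haptic rendering law by one control tick
#'
#' The rendering law of the simulated portal placement: penetration past
#' the virtual capsule surface commands a spring force `F = k * delta`
#' from the in vivo stiffness; the instant the commanded force reaches the
#' puncture threshold the device releases the force to zero within the
#' same tick (and stays released -- `punctured` never resets within a
#' trial); finally the force is clamped to the device's maximum. The clamp
#' is applied after the release logic, so saturation cannot mask a
#' puncture event. The law is static: no rate- or inertia-dependent terms.
#'
#' @param state A `haptic_state`.
#' @param capsule A [capsule_model()]; set `puncture_force_fmax = Inf` to
#'   disable release.
#' @param spec A [haptic_device_spec()].
#' @param new_tip Commanded tip position for this tick, in m.
#' @param quantize Apply encoder quantization to the tip (default TRUE).
#' @return The updated `haptic_state`.
#' @export
render_step <- function(state, capsule, spec, new_tip, quantize = TRUE) {
  tip <- if (quantize) quantize_position(new_tip, spec) else new_tip
  delta <- max(0, tip - state$capsule_position)
  if (!state$punctured) {
    f <- capsule$stiffness_k * delta
    if (f >= capsule$puncture_force_fmax) {
      state$punctured <- TRUE
      f <- capsule$post_puncture_force
    }
  } else {
    f <- capsule$post_puncture_force
  }
  f <- min(f, spec$max_force)
  state$tip_position <- tip
  state$commanded_force <- f
  state$time <- state$time + 1 / spec$loop_rate
  state
}

#' Run a tip trajectory through the virtual device
#'
#' Iterates [render_step()] over a commanded tip trajectory (one sample
#' per control tick) and returns the aligned force trace and state log.
#'
#' @param tip_trajectory Tip positions in m, one per tick; must stay
#'   within `[0, workspace]`.
#' @param capsule A [capsule_model()].
#' @param spec A [haptic_device_spec()].
#' @param capsule_position Virtual capsule surface position in m
#'   (default 0).
#' @param quantize Apply encoder quantization (default TRUE).
#' @return A `haptic_run`: tibble with `tick`, `time`, `tip`,
#'   `tip_quantized`, `penetration` (true handle penetration past the
#'   capsule surface; the rendering law itself sees only the quantized
#'   tip), `force`, `punctured`.
#' @export
#' @examples
#' traj <- seq(0, 0.05, length.out = 500)
#' log <- run_trajectory(traj, capsule_model(1000, 30))
#' max(log$force)  # just under 30 N, then release
run_trajectory <- function(tip_trajectory, capsule,
                           spec = haptic_device_spec(),
                           capsule_position = 0, quantize = TRUE) {
  if (any(tip_trajectory < 0 | tip_trajectory > spec$workspace)) {
    stop_portalsim(
      sprintf("trajectory leaves the device workspace [0, %g m]",
              spec$workspace),
      class = "portalsim_workspace_exceeded"
    )
  }
  n <- length(tip_trajectory)
  state <- haptic_state(capsule_position = capsule_position)
  tipq <- force <- pen <- numeric(n)
  punct <- logical(n)
  for (i in seq_len(n)) {
    state <- render_step(state, capsule, spec, tip_trajectory[i],
                         quantize = quantize)
    stopifnot(state$commanded_force >= 0,
              state$commanded_force <= spec$max_force)
    tipq[i] <- state$tip_position
    # true handle penetration; the device only sees the quantized tip
    pen[i] <- max(0, tip_trajectory[i] - capsule_position)
    force[i] <- state$commanded_force
    punct[i] <- state$punctured
  }
  structure(
    tibble(tick = seq_len(n), time = (seq_len(n) - 1) / spec$loop_rate,
           tip = tip_trajectory, tip_quantized = tipq,
           penetration = pen, force = force, punctured = punct),
    class = c("haptic_run", "tbl_df", "tbl", "data.frame")
  )
}

#' Coefficient of determination between target and reproduced values
#'
#' `R^2 = 1 - SS_res / SS_tot`, with residuals `target - reproduced` and
#' the total sum of squares taken about the target mean. Used as the
#' replication-fidelity score of the haptic device.
#'
#' @param target Target values (length >= 2, not constant).
#' @param reproduced Reproduced values, same length.
#' @return The R-squared value (<= 1; can be negative for a predictor
#'   worse than the target mean).
#' @export
compute_r_squared <- function(target, reproduced) {
  if (length(target) != length(reproduced) || length(target) < 2L) {
    stop_portalsim("target and reproduced must be equal length >= 2",
                   class = "portalsim_invalid_argument")
  }
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) {
    stop_portalsim("undefined R-squared: target values are constant",
                   class = "portalsim_constant_target")
  }
  1 - sum((target - reproduced)^2) / ss_tot
}

#' Validate force and stiffness replication across capsule targets
#'
#' For each target capsule model, a standard constant-speed insertion is
#' rendered on the virtual device; the reproduced puncture force is the
#' maximum rendered force and the reproduced stiffness is refit by
#' through-origin regression of rendered force on penetration over the
#' pre-release samples. Replication fidelity is scored by the coefficient
#' of determination of reproduced versus target values across the set.
#'
#' @param capsule_set List of [capsule_model()]s, or a data frame with
#'   columns `stiffness_k` and `puncture_force_fmax` (>= 2 rows spanning
#'   distinct targets).
#' @param spec A [haptic_device_spec()].
#' @param insertion_depth Depth of the standard insertion past the capsule
#'   surface, in m (default 0.05).
#' @param speed Insertion speed in m/s (default 0.01).
#' @param quantize Apply encoder quantization (default TRUE).
#' @return A `replication_report` with `r2_force`, `r2_stiffness` and a
#'   `results` tibble of paired target/reproduced values.
#' @export
#' @examples
#' targets <- replication_targets(5)
#' rep <- validate_replication(targets)
#' rep$r2_force
validate_replication <- function(capsule_set,
                                 spec = haptic_device_spec(),
                                 insertion_depth = 0.05,
                                 speed = 0.01,
                                 quantize = TRUE) {
  if (is.data.frame(capsule_set)) {
    capsule_set <- pmap(capsule_set[c("stiffness_k", "puncture_force_fmax")],
                        capsule_model)
  }
  stopifnot(length(capsule_set) >= 2L,
            all(map_lgl(capsule_set, inherits, "capsule_model")))
  n_ticks <- max(2L, ceiling(insertion_depth / speed * spec$loop_rate))
  traj <- seq(0, insertion_depth, length.out = n_ticks)
  rows <- map(capsule_set, function(cm) {
    if (cm$stiffness_k * insertion_depth < cm$puncture_force_fmax) {
      stop_portalsim(
        "insertion too shallow to reach the puncture force of a target",
        class = "portalsim_unreachable_puncture"
      )
    }
    log <- run_trajectory(traj, cm, spec, capsule_position = 0,
                          quantize = quantize)
    pre <- log$penetration > 0 & !log$punctured
    refit <- sum(log$penetration[pre] * log$force[pre]) /
      sum(log$penetration[pre]^2)
    tibble(target_fmax = cm$puncture_force_fmax,
           reproduced_fmax = max(log$force),
           target_k = cm$stiffness_k,
           reproduced_k = refit)
  })
  results <- bind_rows(rows)
  structure(
    list(
      r2_force = compute_r_squared(results$target_fmax,
                                   results$reproduced_fmax),
      r2_stiffness = compute_r_squared(results$target_k,
                                       results$reproduced_k),
      results = results,
      spec = spec, quantize = quantize
    ),
    class = "replication_report"
  )
}

#' Capsule targets spanning the in vivo parameter ranges
#'
#' Builds a set of capsule models whose puncture forces and stiffnesses
#' evenly span the observed in vivo ranges, for replication validation.
#'
#' @param n Number of targets (default 10).
#' @param fmax_range,k_range Ranges to span; default to the in vivo
#'   cohort ranges.
#' @return A list of [capsule_model()]s.
#' @export
replication_targets <- function(n = 10,
                                fmax_range = invivo_reference$fmax_range,
                                k_range = invivo_reference$k_range) {
  assert_number(n, "n", lower = 2)
  map2(seq(k_range[1], k_range[2], length.out = n),
       seq(fmax_range[1], fmax_range[2], length.out = n),
       ~ capsule_model(stiffness_k = .x, puncture_force_fmax = .y))
}
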