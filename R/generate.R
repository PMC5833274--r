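# synthetic trial generation --------------------------------------------------

new_trial_recording <- function(data, events, patient, truth = NULL) {
  stopifnot(all(c("time", "force", "m1x", "m1y", "m1z",
                  "m2x", "m2y", "m2z") %in% names(data)))
  structure(
    list(data = as_tibble(data), events = events, patient = patient,
         truth = truth),
    class = "trial_recording"
  )
}

#' Generate one synthetic portal-placement trial
#'
#' Produces a synchronous 100 Hz (configurable) force + marker recording
#' with the canonical three-phase profile:
#' \describe{
#'   \item{Phase I}{trocar seated on the soft spot; stationary markers and
#'     a small uniform contact jitter on the force channel.}
#'   \item{Phase II}{constant-speed advance; the capsule loads linearly,
#'     `F = k x`, peaking at `F_max` exactly at the puncture timestamp.}
#'   \item{Phase III}{post-puncture collapse of the force toward the
#'     residual level with an exponential time constant, while the trocar
#'     continues to advance.}
#' }
#' The two shaft markers ride a fixed distance apart on the instrument
#' axis; insertion is pure translation along that axis unless an off-axis
#' perturbation is requested. Event timestamps (start, puncture, end) are
#' snapped to the sampling grid, and the effective insertion speed is
#' adjusted by less than half a sample period so that the noiseless force
#' ramp attains `F_max` exactly at the puncture sample.
#'
#' @param capsule A [capsule_model()].
#' @param noise A [sensor_noise()]; use zero sigmas for a noiseless trial.
#' @param profile An [insertion_profile()].
#' @param patient Optional list of patient metadata; fields `id`,
#'   `rom_eligible` and `synovitis_excluded` are filled with defaults when
#'   absent.
#' @param seed Optional seed overriding `noise$seed`.
#' @return A `trial_recording`: a list with `data` (tibble of `time`,
#'   `force`, `m1x`..`m2z`), `events` (named vector `t_start`,
#'   `t_puncture`, `t_end`), `patient`, and `truth` (generator ground
#'   truth: the capsule, effective speed and profile).
#' @export
#' @examples
#' tr <- generate_trial(capsule_model(1000, 50),
#'                      noise = sensor_noise(0, 0),
#'                      profile = insertion_profile(speed = 0.01))
#' tr$events
generate_trial <- function(capsule,
                           noise = sensor_noise(),
                           profile = insertion_profile(),
                           patient = NULL,
                           seed = noise$seed) {
  stopifnot(inherits(capsule, "capsule_model"),
            inherits(noise, "sensor_noise"),
            inherits(profile, "insertion_profile"))
  dt <- 1 / profile$rate
  k <- capsule$stiffness_k
  fmax <- capsule$puncture_force_fmax
  if (!is.finite(fmax)) {
    stop_portalsim("cannot generate a trial for a capsule that never punctures",
                   class = "portalsim_invalid_argument")
  }
  t2_exact <- fmax / (k * profile$speed)
  if (!is.null(profile$phase2_max_duration) &&
      k * profile$speed * profile$phase2_max_duration < fmax) {
    stop_portalsim(
      sprintf(paste0("puncture force unreachable: k * speed * duration = ",
                     "%.3f N < F_max = %.3f N"),
              k * profile$speed * profile$phase2_max_duration, fmax),
      class = "portalsim_unreachable_puncture"
    )
  }
  n1 <- max(1L, as.integer(round(profile$phase1_duration / dt)))
  n2 <- max(2L, as.integer(round(t2_exact / dt)))
  n3 <- max(1L, as.integer(round(profile$phase3_duration / dt)))
  v_eff <- fmax / (k * n2 * dt)   # within dt/2 of profile$speed over Phase II

  n <- n1 + n2 + n3 + 1L
  time <- (seq_len(n) - 1L) * dt
  t_start <- n1 * dt
  t_puncture <- (n1 + n2) * dt
  t_end <- (n1 + n2 + n3) * dt

  # displacement of the shaft midpoint along the insertion axis
  disp <- pmax(0, time - t_start) * v_eff
  phase3 <- time > t_puncture + dt / 2

  force <- numeric(n)
  phase1 <- time < t_start - dt / 2
  phase2 <- !phase1 & !phase3
  force[phase2] <- k * v_eff * (time[phase2] - t_start)
  f0 <- capsule$post_puncture_force
  force[phase3] <- f0 + (fmax - f0) *
    exp(-(time[phase3] - t_puncture) / profile$phase3_tau)

  u <- profile$axis
  # any unit vector orthogonal to u, for the optional off-axis wobble
  w <- if (abs(u[1]) < 0.9) unit_vector(c(0, -u[3], u[2]) + c(1, 0, 0) * 0) else c(0, 1, 0)
  w <- unit_vector(w - sum(w * u) * u)
  lateral <- profile$lateral_amplitude *
    sin(2 * pi * profile$lateral_frequency * (time - t_start)) *
    as.numeric(!phase1)

  mid <- outer(disp, u) + outer(lateral, w)
  half <- profile$marker_separation / 2
  m1 <- sweep(mid, 2, half * u, `-`)
  m2 <- sweep(mid, 2, half * u, `+`)

  with_seed_if(seed, {
    if (profile$phase1_jitter > 0) {
      force[phase1] <- runif(sum(phase1), 0, profile$phase1_jitter)
    }
    if (noise$force_sigma > 0) {
      force <- force + rnorm(n, 0, noise$force_sigma)
    }
    if (noise$position_sigma > 0) {
      m1 <- m1 + matrix(rnorm(3L * n, 0, noise$position_sigma), ncol = 3)
      m2 <- m2 + matrix(rnorm(3L * n, 0, noise$position_sigma), ncol = 3)
    }
  })

  meta <- utils::modifyList(
    list(id = "P01", rom_eligible = TRUE, synovitis_excluded = FALSE),
    patient %||% list()
  )
  new_trial_recording(
    data = tibble(
      time = time, force = force,
      m1x = m1[, 1], m1y = m1[, 2], m1z = m1[, 3],
      m2x = m2[, 1], m2y = m2[, 2], m2z = m2[, 3]
    ),
    events = c(t_start = t_start, t_puncture = t_puncture, t_end = t_end),
    patient = meta,
    truth = list(capsule = capsule, speed_effective = v_eff,
                 profile = profile, noise = noise)
  )
}

# draw from a normal truncated to [lo, hi] by rejection; exact at sd = 0
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient capsule parameters from truncated normal
#' distributions (so every ground-truth parameter respects the configured
#' range), generates one trial per patient, inserts marker-occlusion gaps
#' into a `dropout_probability` fraction of trials (a contiguous run of
#' missing marker samples in Phase II, long enough to invalidate the
#' displacement stream), and flags `n_synovitis` randomly chosen patients
#' as excluded-by-synovitis.
#'
#' @param spec A [cohort_spec()].
#' @param noise A [sensor_noise()] applied to every trial.
#' @param profile An [insertion_profile()] shared by all trials.
#' @param gap_duration Length in s of the inserted occlusion gap
#'   (default 0.5 s, well past the 0.2 s recoverable-gap limit).
#' @return A list of `trial_recording` objects with class `trial_cohort`;
#'   the spec is attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            noise = sensor_noise(),
                            profile = insertion_profile(),
                            gap_duration = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  draws <- with_seed_if(spec$seed, {
    list(
      k = rtruncnorm1(n, spec$k_mean, spec$k_sd, spec$k_range[1], spec$k_range[2]),
      fmax = rtruncnorm1(n, spec$fmax_mean, spec$fmax_sd,
                         spec$fmax_range[1], spec$fmax_range[2]),
      dropout = runif(n) < spec$dropout_probability,
      synovitis = seq_len(n) %in% sample.int(n, spec$n_synovitis),
      child_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- generate_trial(
      capsule_model(draws$k[i], draws$fmax[i]),
      noise = noise, profile = profile,
      patient = list(id = sprintf("P%02d", i), rom_eligible = TRUE,
                     synovitis_excluded = draws$synovitis[i]),
      seed = if (is.null(spec$seed)) NULL else draws$child_seeds[i]
    )
    if (draws$dropout[i]) {
      tr <- insert_marker_gap(tr, gap_duration = gap_duration)
    }
    trials[[i]] <- tr
  }
  structure(trials, class = "trial_cohort", spec = spec)
}

# blank out a contiguous run of marker samples centered in Phase II
insert_marker_gap <- function(trial, gap_duration) {
  d <- trial$data
  rate <- 1 / (d$time[2] - d$time[1])
  gap_n <- max(1L, as.integer(round(gap_duration * rate)))
  mid_t <- mean(trial$events[c("t_start", "t_puncture")])
  center <- which.min(abs(d$time - mid_t))
  idx <- seq(max(1L, center - gap_n %/% 2L),
             min(nrow(d), center + (gap_n - 1L) %/% 2L))
  marker_cols <- c("m1x", "m1y", "m1z", "m2x", "m2y", "m2z")
  d[idx, marker_cols] <- NA_real_
  trial$data <- d
  trial
}

#' Generate one friction-bench push trial
#'
#' Models the friction characterization experiment: the simulator handle
#' is pushed to an initial speed and released, decelerating under a
#' constant friction force. By conservation of energy the kinetic energy
#' of the handle plus (when the cable is attached) the rotational energy
#' of the cable reel is dissipated over the travel distance:
#' `F_f d = 1/2 m v0^2 + 1/2 I (v0 / r)^2`.
#'
#' @param true_friction Ground-truth friction force in N (> 0).
#' @param initial_speed Release speed v0 in m/s (> 0).
#' @param handle_mass Handle mass in kg.
#' @param reel_inertia Cable reel inertia in kg m^2 (counted only when the
#'   cable is attached).
#' @param reel_radius Reel radius in m (must be > 0 when the cable is
#'   attached).
#' @param cable_attached Whether the cable couples the reel to the handle.
#' @param distance_noise_frac Relative SD of measurement noise on the
#'   recorded travel distance (default 0).
#' @param speed_noise_frac Relative SD of measurement noise on the
#'   recorded release speed (default 0).
#' @param rate Sampling rate in Hz of the speed trace.
#' @param seed Optional seed for the measurement noise.
#' @return An object of class `friction_trial` with the recorded (possibly
#'   noisy) `initial_speed` and `travel_distance`, the sampled
#'   `speed_trace`, bench constants, and `true_friction_force`.
#' @export
#' @examples
#' ft <- generate_friction_trial(5, 1, handle_mass = 0.5, reel_inertia = 0)
#' ft$travel_distance  # 0.05 m
generate_friction_trial <- function(true_friction,
                                    initial_speed,
                                    handle_mass = 0.5,
                                    reel_inertia = 34833.32e-9,
                                    reel_radius = 0.020,
                                    cable_attached = TRUE,
                                    distance_noise_frac = 0,
                                    speed_noise_frac = 0,
                                    rate = 100,
                                    seed = NULL) {
  assert_number(true_friction, "true_friction", lower = 0, strict_lower = TRUE)
  assert_number(initial_speed, "initial_speed", lower = 0, strict_lower = TRUE)
  assert_number(handle_mass, "handle_mass", lower = 0, strict_lower = TRUE)
  assert_number(reel_inertia, "reel_inertia", lower = 0)
  assert_flag(cable_attached, "cable_attached")
  if (cable_attached && reel_radius <= 0) {
    stop_portalsim("reel_radius must be > 0 when the cable is attached",
                   class = "portalsim_invalid_argument")
  }
  m_eff <- handle_mass +
    if (cable_attached) reel_inertia / reel_radius^2 else 0
  decel <- true_friction / m_eff
  duration <- initial_speed / decel
  d_true <- initial_speed^2 / (2 * decel)
  tt <- seq(0, duration, by = 1 / rate)
  v_true <- pmax(0, initial_speed - decel * tt)
  meas <- with_seed_if(seed, {
    list(
      d = d_true * (1 + if (distance_noise_frac > 0)
        rnorm(1, 0, distance_noise_frac) else 0),
      v0 = initial_speed * (1 + if (speed_noise_frac > 0)
        rnorm(1, 0, speed_noise_frac) else 0)
    )
  })
  structure(
    list(handle_mass = handle_mass, reel_inertia = reel_inertia,
         reel_radius = reel_radius, cable_attached = cable_attached,
         initial_speed = meas$v0, travel_distance = meas$d,
         speed_trace = v_true * (meas$v0 / initial_speed),
         time = tt, true_friction_force = true_friction),
    class = "friction_trial"
  )
}
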