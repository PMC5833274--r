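#' Linear-elastic joint-capsule model
#'
#' The capsule is modeled as a Hookean spring along the insertion axis:
#' the reaction force grows linearly with displacement past the contact
#' point, `F = k x`, until it reaches the puncture threshold `F_max`, at
#' which point the capsule gives way and the resisting force collapses.
#'
#' @param stiffness_k Capsule stiffness k in N/m. Default: the cohort mean
#'   stiffness from the in vivo posterior-portal measurements.
#' @param puncture_force_fmax Peak puncture force F_max in N at which the
#'   capsule gives way. Default: the cohort mean peak force.
#' @param post_puncture_force Residual force in N after puncture
#'   (default 0: full release).
#' @return An object of class `capsule_model`.
#' @export
#' @examples
#' capsule_model()
#' capsule_model(stiffness_k = 1000, puncture_force_fmax = 50)
capsule_model <- function(stiffness_k = invivo_reference$k_mean,
                          puncture_force_fmax = invivo_reference$fmax_mean,
                          post_puncture_force = 0) {
  assert_number(stiffness_k, "stiffness_k", lower = 0, strict_lower = TRUE)
  if (!identical(puncture_force_fmax, Inf)) {
    assert_number(puncture_force_fmax, "puncture_force_fmax",
                  lower = 0, strict_lower = TRUE)
  }
  assert_number(post_puncture_force, "post_puncture_force",
                lower = 0, upper = puncture_force_fmax, strict_upper = TRUE)
  structure(
    list(stiffness_k = stiffness_k,
         puncture_force_fmax = puncture_force_fmax,
         post_puncture_force = post_puncture_force),
    class = "capsule_model"
  )
}

#' Sensor noise specification
#'
#' Gaussian i.i.d. measurement noise for the force sensor and the optical
#' marker positions. The instruments' stated accuracies (1 N and 1 mm) are
#' read conservatively as 3-sigma bounds, giving the defaults
#' `force_sigma = 1/3` N and `position_sigma = 1/3` mm.
#'
#' @param force_sigma Force noise SD in N (>= 0).
#' @param position_sigma Per-coordinate marker noise SD in m (>= 0).
#' @param seed Optional integer seed for reproducible noise.
#' @return An object of class `sensor_noise`.
#' @export
sensor_noise <- function(force_sigma = 1 / 3,
                         position_sigma = 1e-3 / 3,
                         seed = NULL) {
  assert_number(force_sigma, "force_sigma", lower = 0)
  assert_number(position_sigma, "position_sigma", lower = 0)
  if (!is.null(seed)) assert_number(seed, "seed")
  structure(
    list(force_sigma = force_sigma, position_sigma = position_sigma,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sensor_noise"
  )
}

#' Insertion profile for a synthetic portal-placement trial
#'
#' Describes the trajectory shape of a simulated trial: a preparation
#' interval while the trocar is seated on the soft spot (Phase I), a
#' constant-speed advance that loads the capsule linearly until puncture
#' (Phase II), and a post-puncture interval (Phase III). The in vivo
#' protocol does not constrain the insertion speed or the Phase I/III
#' behavior, so these are free simulation parameters.
#'
#' @param phase1_duration Seconds of preparation before the set point
#'   (trocar seated, no load). Must be > 0.
#' @param phase3_duration Seconds recorded after puncture. Must be > 0.
#' @param speed Nominal insertion speed in m/s during Phase II. The
#'   generator adjusts it by less than half a sample period so the force
#'   ramp peaks exactly on a sample of the 100 Hz grid.
#' @param phase2_max_duration Optional cap on the Phase II duration in
#'   seconds; the trial is rejected if the puncture force cannot be reached
#'   within it at the given speed (`k * speed * duration < F_max`).
#' @param phase1_jitter Amplitude in N of the uniform contact jitter while
#'   the trocar is being seated (Phase I); default 5 N, set 0 for none.
#' @param phase3_tau Time constant in s of the exponential force collapse
#'   after puncture (default 0.1 s).
#' @param axis Insertion direction in the camera frame (3-vector, any
#'   length; normalized internally).
#' @param marker_separation Distance in m between the two shaft markers
#'   (default 0.08 m).
#' @param lateral_amplitude Amplitude in m of an optional sinusoidal
#'   off-axis perturbation of the shaft midpoint (default 0: pure
#'   translation along the axis).
#' @param lateral_frequency Frequency in Hz of the off-axis perturbation.
#' @param rate Sampling rate in Hz (force and markers are synchronous).
#' @return An object of class `insertion_profile`.
#' @export
insertion_profile <- function(phase1_duration = 2,
                              phase3_duration = 1,
                              speed = 0.01,
                              phase2_max_duration = NULL,
                              phase1_jitter = 5,
                              phase3_tau = 0.1,
                              axis = c(1, 0, 0),
                              marker_separation = 0.08,
                              lateral_amplitude = 0,
                              lateral_frequency = 1,
                              rate = 100) {
  assert_number(phase1_duration, "phase1_duration", lower = 0, strict_lower = TRUE)
  assert_number(phase3_duration, "phase3_duration", lower = 0, strict_lower = TRUE)
  assert_number(speed, "speed", lower = 0, strict_lower = TRUE)
  if (!is.null(phase2_max_duration)) {
    assert_number(phase2_max_duration, "phase2_max_duration",
                  lower = 0, strict_lower = TRUE)
  }
  assert_number(phase1_jitter, "phase1_jitter", lower = 0)
  assert_number(phase3_tau, "phase3_tau", lower = 0, strict_lower = TRUE)
  assert_number(marker_separation, "marker_separation", lower = 0, strict_lower = TRUE)
  assert_number(lateral_amplitude, "lateral_amplitude", lower = 0)
  assert_number(lateral_frequency, "lateral_frequency", lower = 0)
  assert_number(rate, "rate", lower = 0, strict_lower = TRUE)
  structure(
    list(phase1_duration = phase1_duration,
         phase3_duration = phase3_duration,
         speed = speed,
         phase2_max_duration = phase2_max_duration,
         phase1_jitter = phase1_jitter,
         phase3_tau = phase3_tau,
         axis = unit_vector(as.numeric(axis)),
         marker_separation = marker_separation,
         lateral_amplitude = lateral_amplitude,
         lateral_frequency = lateral_frequency,
         rate = rate),
    class = "insertion_profile"
  )
}

#' Cohort specification for the synthetic generator
#'
#' Per-patient capsule parameters are drawn from truncated normal
#' distributions whose means, SDs and truncation ranges default to the
#' in vivo cohort statistics. A configurable fraction of trials carries a
#' marker-occlusion gap long enough to invalidate the displacement stream
#' (mirroring the patients whose position data was lost to camera
#' occlusion), and a configurable number of patients carries an
#' arthroscopy-confirmed synovitis flag that excludes them from cohort
#' statistics.
#'
#' @param n_patients Number of patients (>= 1).
#' @param k_mean,k_sd Stiffness distribution in N/m.
#' @param fmax_mean,fmax_sd Puncture-force distribution in N.
#' @param k_range,fmax_range Truncation bounds (length-2 numeric, must
#'   bracket the means).
#' @param dropout_probability Probability that a trial's marker stream has
#'   an occlusion gap long enough to be flagged position-invalid.
#' @param n_synovitis Number of patients flagged `synovitis_excluded`
#'   (default 1, matching the single frozen-shoulder exclusion).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10,
                        k_mean = invivo_reference$k_mean,
                        k_sd = invivo_reference$k_sd,
                        fmax_mean = invivo_reference$fmax_mean,
                        fmax_sd = invivo_reference$fmax_sd,
                        k_range = invivo_reference$k_range,
                        fmax_range = invivo_reference$fmax_range,
                        dropout_probability = 0.5,
                        n_synovitis = 1,
                        seed = NULL) {
  assert_number(n_patients, "n_patients", lower = 1)
  assert_number(k_sd, "k_sd", lower = 0)
  assert_number(fmax_sd, "fmax_sd", lower = 0)
  assert_number(k_mean, "k_mean", lower = k_range[1], upper = k_range[2])
  assert_number(fmax_mean, "fmax_mean", lower = fmax_range[1], upper = fmax_range[2])
  assert_number(dropout_probability, "dropout_probability", lower = 0, upper = 1)
  assert_number(n_synovitis, "n_synovitis", lower = 0, upper = n_patients)
  structure(
    list(n_patients = as.integer(n_patients),
         k_mean = k_mean, k_sd = k_sd,
         fmax_mean = fmax_mean, fmax_sd = fmax_sd,
         k_range = as.numeric(k_range), fmax_range = as.numeric(fmax_range),
         dropout_probability = dropout_probability,
         n_synovitis = as.integer(n_synovitis),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Haptic device specification
#'
#' Constants of the 1-DOF cable-driven force-feedback device: force
#' capability, workspace, encoder resolution and control-loop rate, plus
#' the inertias used by the friction bench model. The linear position
#' resolution is derived from the rotary encoder as
#' `2 * pi * reel_radius / (encoder_counts_per_rev * quadrature_multiplier)`.
#' The reel radius is not part of the published device table; the default
#' of 20 mm is a plausible value for a compact cable reel and is
#' configurable.
#'
#' @param max_force Force saturation limit in N (default 137.1).
#' @param workspace Linear workspace in m (default 0.30).
#' @param encoder_counts_per_rev Encoder pulses per revolution (default 2048).
#' @param quadrature_multiplier Quadrature decoding factor (default 4).
#' @param reel_radius Cable reel radius in m (default 0.020).
#' @param loop_rate Control/rendering loop rate in Hz (default 100).
#' @param motor_inertia Motor rotor inertia in kg m^2.
#' @param reel_inertia Cable reel inertia in kg m^2.
#' @return An object of class `haptic_device_spec`.
#' @export
#' @examples
#' spec <- haptic_device_spec()
#' encoder_resolution(spec)  # ~1.53e-5 m
haptic_device_spec <- function(max_force = 137.1,
                               workspace = 0.30,
                               encoder_counts_per_rev = 2048,
                               quadrature_multiplier = 4,
                               reel_radius = 0.020,
                               loop_rate = 100,
                               motor_inertia = 0.05e-4,
                               reel_inertia = 34833.32e-9) {
  for (nm in c("max_force", "workspace", "encoder_counts_per_rev",
               "quadrature_multiplier", "reel_radius", "loop_rate",
               "motor_inertia", "reel_inertia")) {
    assert_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(
    list(max_force = max_force, workspace = workspace,
         encoder_counts_per_rev = encoder_counts_per_rev,
         quadrature_multiplier = quadrature_multiplier,
         reel_radius = reel_radius, loop_rate = loop_rate,
         motor_inertia = motor_inertia, reel_inertia = reel_inertia),
    class = "haptic_device_spec"
  )
}

#' Encoder-limited linear position resolution of the device
#'
#' @param spec A [haptic_device_spec()].
#' @return Resolution in m.
#' @export
encoder_resolution <- function(spec) {
  2 * pi * spec$reel_radius /
    (spec$encoder_counts_per_rev * spec$quadrature_multiplier)
}
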