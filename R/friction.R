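# energy-conservation friction characterization ------------------------------

#' Assemble friction components from condition means
#'
#' @param f_total Mean friction of the full mechanism, cable attached (N).
#' @param f_guide Mean friction of the linear guide alone, cable
#'   detached (N).
#' @return List with `f_total`, `f_guide`, and their difference `f_cable`,
#'   the friction contributed by the cable mechanism alone.
#' @export
#' @examples
#' friction_components(3.76, 1.91)$f_cable  # 1.85
friction_components <- function(f_total, f_guide) {
  list(f_total = f_total, f_guide = f_guide, f_cable = f_total - f_guide)
}

#' Estimate device friction from deceleration bench trials
#'
#' Each push trial releases the handle at speed `v0` and lets friction
#' bring it to rest over a travel distance `d`. Assuming all kinetic
#' energy of the handle and (cable attached) rotational energy of the
#' cable reel is dissipated by friction,
#' `F_f = (1/2 m v0^2 + 1/2 I (v0 / r)^2) / d`.
#' The total friction is the mean over cable-attached trials, the guide
#' friction the mean over detached trials, and their difference is the
#' friction of the cable mechanism alone.
#'
#' @param trials List of `friction_trial` objects (at least one per
#'   condition). Trials with non-positive travel distance are rejected and
#'   logged.
#' @return A `friction_estimate` with `f_total`, `f_guide`, `f_cable`
#'   (N), per-condition SDs (`f_cable_sd` by propagation), a `per_trial`
#'   tibble, and `rejected_log`.
#' @export
#' @examples
#' tr <- lapply(c(TRUE, FALSE), function(att)
#'   generate_friction_trial(5, 1, reel_inertia = 0, cable_attached = att))
#' estimate_friction(tr)$f_total  # 5
estimate_friction <- function(trials) {
  if (inherits(trials, "friction_trial")) trials <- list(trials)
  stopifnot(length(trials) >= 1L,
            all(map_lgl(trials, inherits, "friction_trial")))
  rejected <- character(0)
  rows <- imap(trials, function(tr, i) {
    if (!is.finite(tr$travel_distance) || tr$travel_distance <= 0) {
      rejected <<- c(rejected,
                     sprintf("trial %d: non-positive travel distance", i))
      return(NULL)
    }
    v0 <- tr$initial_speed
    energy <- 0.5 * tr$handle_mass * v0^2 +
      if (tr$cable_attached) {
        0.5 * tr$reel_inertia * (v0 / tr$reel_radius)^2
      } else 0
    tibble(trial = i, cable_attached = tr$cable_attached,
           initial_speed = v0, travel_distance = tr$travel_distance,
           friction = energy / tr$travel_distance)
  })
  per_trial <- bind_rows(rows)
  att <- per_trial$friction[per_trial$cable_attached]
  det <- per_trial$friction[!per_trial$cable_attached]
  if (length(att) == 0L || length(det) == 0L) {
    stop_portalsim(
      "need at least one trial per condition (cable attached and detached)",
      class = "portalsim_invalid_argument"
    )
  }
  comp <- friction_components(mean(att), mean(det))
  sd_t <- if (length(att) > 1L) sample_sd(att) else NA_real_
  sd_g <- if (length(det) > 1L) sample_sd(det) else NA_real_
  structure(
    c(comp,
      list(f_total_sd = sd_t, f_guide_sd = sd_g,
           f_cable_sd = sqrt(sd_t^2 + sd_g^2),   # error propagation
           per_trial = per_trial, rejected_log = rejected)),
    class = "friction_estimate"
  )
}

#' Check the friction-to-puncture-force ratio against a perceptual bound
#'
#' Device friction is imperceptible during simulated puncture if it is a
#' sufficiently small fraction of the rendered force; the bound used is
#' the just-noticeable-difference fraction, with the pass requiring a
#' strict inequality.
#'
#' @param f_total Total device friction in N.
#' @param mean_puncture Mean peak puncture force in N (> 0).
#' @param jnd_fraction Bound on the ratio (default 0.06).
#' @return A tibble with `ratio`, `threshold` and logical `pass`.
#' @export
#' @examples
#' friction_ratio_check(3.763, 66.46)
friction_ratio_check <- function(f_total, mean_puncture,
                                 jnd_fraction = invivo_reference$jnd_fraction) {
  assert_number(f_total, "f_total", lower = 0)
  assert_number(mean_puncture, "mean_puncture", lower = 0, strict_lower = TRUE)
  ratio <- f_total / mean_puncture
  tibble(ratio = ratio, threshold = jnd_fraction,
         pass = ratio < jnd_fraction)
}
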