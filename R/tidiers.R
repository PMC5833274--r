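# broom-style tidiers ---------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stiffness fit
#'
#' @param x A `stiffness_fit`.
#' @param ... Unused.
#' @return One row per model term with `term` and `estimate`.
#' @export
tidy.stiffness_fit <- function(x, ...) {
  out <- tibble(term = "stiffness_k", estimate = x$k_hat)
  if (isTRUE(x$with_intercept)) {
    out <- bind_rows(tibble(term = "(Intercept)", estimate = x$intercept), out)
  }
  out
}

#' @rdname tidy.stiffness_fit
#' @export
glance.stiffness_fit <- function(x, ...) {
  tibble(k_hat = x$k_hat, residual_rms = x$residual_rms,
         n_samples = x$n_samples,
         fit_start = x$fit_window[1], fit_end = x$fit_window[2])
}

#' Tidy a puncture-force estimate
#'
#' @param x A `puncture_fit`.
#' @param ... Unused.
#' @export
tidy.puncture_fit <- function(x, ...) {
  tibble(term = "puncture_force_fmax", estimate = x$f_max_hat,
         t_at_max = x$t_at_max)
}

#' Tidy a cohort summary
#'
#' One row per mechanical property with mean, SD, min and max, mirroring
#' the two-row published layout (mean +/- SD, range).
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  tibble(
    parameter = c("puncture_force", "stiffness"),
    mean = c(x$fmax_mean, x$k_mean),
    sd = c(x$fmax_sd, x$k_sd),
    min = c(x$fmax_min, x$k_min),
    max = c(x$fmax_max, x$k_max),
    n = c(x$n_included, x$n_position_valid)
  )
}

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n_included = x$n_included, n_excluded = x$n_excluded,
         n_position_valid = x$n_position_valid)
}

#' Tidy a friction estimate
#'
#' @param x A `friction_estimate`.
#' @param ... Unused.
#' @return One row per friction component (`total`, `guide`, `cable`).
#' @export
tidy.friction_estimate <- function(x, ...) {
  tibble(
    component = c("total", "guide", "cable"),
    estimate = c(x$f_total, x$f_guide, x$f_cable),
    sd = c(x$f_total_sd, x$f_guide_sd, x$f_cable_sd)
  )
}

#' @rdname tidy.friction_estimate
#' @export
glance.friction_estimate <- function(x, ...) {
  tibble(f_total = x$f_total, f_guide = x$f_guide, f_cable = x$f_cable,
         n_trials = nrow(x$per_trial), n_rejected = length(x$rejected_log))
}

#' Tidy a replication report
#'
#' @param x A `replication_report`.
#' @param ... Unused.
#' @return The paired target/reproduced values, one row per capsule
#'   target.
#' @export
tidy.replication_report <- function(x, ...) x$results

#' @rdname tidy.replication_report
#' @export
glance.replication_report <- function(x, ...) {
  tibble(r2_force = x$r2_force, r2_stiffness = x$r2_stiffness,
         n_targets = nrow(x$results), quantized = x$quantize)
}
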