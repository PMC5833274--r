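# compact print methods -------------------------------------------------------

#' @export
print.capsule_model <- function(x, ...) {
  cat(sprintf("<capsule_model> k = %.2f N/m, F_max = %.2f N, residual = %.2f N\n",
              x$stiffness_k, x$puncture_force_fmax, x$post_puncture_force))
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  ev <- x$events
  cat(sprintf(
    "<trial_recording> %s: %d samples, t_start %.2f s, t_puncture %.2f s, t_end %.2f s\n",
    x$patient$id %||% "?", nrow(x$data),
    ev[["t_start"]], ev[["t_puncture"]], ev[["t_end"]]))
  invisible(x)
}

#' @export
print.processed_trial <- function(x, ...) {
  cat(sprintf(
    "<processed_trial> %s: %d samples, source '%s', position %s\n",
    x$patient$id %||% "?", nrow(x$data), x$segmentation$source,
    if (x$position_valid) "valid" else "INVALID"))
  invisible(x)
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit> k = %.2f N/m (residual RMS %.3f N, n = %d)\n",
              x$k_hat, x$residual_rms, x$n_samples))
  invisible(x)
}

#' @export
print.puncture_fit <- function(x, ...) {
  cat(sprintf("<puncture_fit> F_max = %.2f N at t = %.2f s\n",
              x$f_max_hat, x$t_at_max))
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d included, %d excluded (%d position-valid)\n",
              x$n_included, x$n_excluded, x$n_position_valid))
  cat(sprintf("  puncture force: %.2f (±%.2f) N, range %.2f–%.2f\n",
              x$fmax_mean, x$fmax_sd, x$fmax_min, x$fmax_max))
  cat(sprintf("  stiffness:      %.2f (±%.2f) N/m, range %.2f–%.2f\n",
              x$k_mean, x$k_sd, x$k_min, x$k_max))
  invisible(x)
}

#' @export
print.friction_estimate <- function(x, ...) {
  cat(sprintf(
    "<friction_estimate> total %.3f N, guide %.3f N, cable %.3f N (%d trials)\n",
    x$f_total, x$f_guide, x$f_cable, nrow(x$per_trial)))
  invisible(x)
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(
    "<replication_report> %d targets: R² force %.4f, R² stiffness %.4f%s\n",
    nrow(x$results), x$r2_force, x$r2_stiffness,
    if (x$quantize) " (encoder quantization on)" else ""))
  invisible(x)
}

#' @export
print.portal_report_bundle <- function(x, ...) {
  cat("<portal_report_bundle>\n")
  if (!is.null(x$cohort_summary)) print(x$cohort_summary)
  if (!is.null(x$friction)) print(x$friction$estimate)
  if (!is.null(x$replication)) print(x$replication)
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}
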