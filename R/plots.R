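# ggplot2 figures -------------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   facet_wrap labs theme_bw geom_vline
#' @export
ggplot2::autoplot

#' Plot a trial recording
#'
#' Force versus time with the phase boundaries marked.
#'
#' @param object A `trial_recording`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trial_recording <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time, y = .data$force)) +
    geom_line(linewidth = 0.3) +
    geom_vline(xintercept = unname(object$events), linetype = "dashed",
               colour = "grey40") +
    labs(x = "Time (s)", y = "Force (N)",
         title = "Portal-placement trial",
         subtitle = "Dashed: start of procedure, puncture, end of procedure") +
    theme_bw()
}

#' Plot a processed trial
#'
#' Filtered force and travel distance versus time, colored by phase.
#'
#' @param object A `processed_trial`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.processed_trial <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::transmute(object$data, time = .data$time, phase = .data$phase,
                     `Force (N)` = .data$force,
                     `Travel distance (mm)` = .data$travel_distance * 1e3),
    cols = c("Force (N)", "Travel distance (mm)"),
    names_to = "channel", values_to = "value"
  )
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$phase)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "Time (s)", y = NULL, colour = "Phase") +
    theme_bw()
}

#' Force-displacement plot of the loading phase
#'
#' Phase-II filtered force against shaft-projected displacement for one or
#' several processed trials, with each trial's through-origin Hooke fit
#' overlaid; the standard way to visualize capsule stiffness.
#'
#' @param processed A `processed_trial` or a list of them.
#' @return A ggplot.
#' @export
plot_force_displacement <- function(processed) {
  if (inherits(processed, "processed_trial")) processed <- list(processed)
  d <- bind_rows(imap(processed, function(pt, i) {
    dd <- dplyr::filter(pt$data, .data$phase == "II", .data$valid)
    id <- pt$patient$id %||% as.character(i)
    k <- tryCatch(fit_stiffness(pt)$k_hat, error = function(e) NA_real_)
    mutate(dd, patient = id, k_hat = k)
  }))
  ggplot(d, aes(x = .data$travel_distance * 1e3, y = .data$force)) +
    geom_line(na.rm = TRUE) +
    geom_abline(aes(intercept = 0, slope = .data$k_hat / 1e3),
                colour = "red", na.rm = TRUE) +
    facet_wrap(~patient) +
    labs(x = "Displacement (mm)", y = "Force (N)",
         title = "Phase II force-displacement",
         subtitle = "Red: through-origin Hooke fit") +
    theme_bw()
}

#' Plot a replication report
#'
#' Target versus reproduced puncture force and stiffness for the virtual
#' device, with the identity line.
#'
#' @param object A `replication_report`.
#' @param ... Unused.
#' @return A ggplot (two panels).
#' @export
autoplot.replication_report <- function(object, ...) {
  r <- object$results
  d <- bind_rows(
    tibble(quantity = "Puncture force (N)", target = r$target_fmax,
           reproduced = r$reproduced_fmax),
    tibble(quantity = "Stiffness (N/m)", target = r$target_k,
           reproduced = r$reproduced_k)
  )
  ggplot(d, aes(x = .data$target, y = .data$reproduced)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point() +
    facet_wrap(~quantity, scales = "free") +
    labs(x = "Target", y = "Reproduced by virtual device",
         title = sprintf("Replication fidelity: R² force = %.3f, R² stiffness = %.3f",
                         object$r2_force, object$r2_stiffness)) +
    theme_bw()
}
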