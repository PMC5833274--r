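# end-to-end pipeline and reporting ------------------------------------------

#' Full pipeline configuration
#'
#' Bundles every stage's configuration: cohort generation, sensor noise,
#' preprocessing, the friction bench, and the haptic device. The friction
#' bench defaults simulate the characterized device: ground-truth total
#' friction with the cable attached and guide-only friction with it
#' detached, ten pushes per condition at release speeds drawn uniformly
#' from `speed_range`, with 1 % measurement noise on travel distance.
#'
#' @param seed Master seed; every stage's randomness derives from it.
#' @param cohort A [cohort_spec()] (its own seed is overridden by a seed
#'   derived from `seed`).
#' @param noise A [sensor_noise()].
#' @param profile An [insertion_profile()].
#' @param device A [haptic_device_spec()].
#' @param filter_cutoff Low-pass cut-off in Hz (default 5).
#' @param friction_bench List of bench settings: `n_per_condition`,
#'   `handle_mass` (kg), `true_total` / `true_guide` (N),
#'   `speed_range` (m/s), `distance_noise_frac`.
#' @param n_replication_targets Number of capsule targets for the
#'   replication validation (default 10).
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_spec(),
                       noise = sensor_noise(),
                       profile = insertion_profile(),
                       device = haptic_device_spec(),
                       filter_cutoff = 5,
                       friction_bench = list(),
                       n_replication_targets = 10) {
  fb <- utils::modifyList(
    list(n_per_condition = 10, handle_mass = 0.5,
         true_total = invivo_reference$friction_total,
         true_guide = invivo_reference$friction_guide,
         speed_range = c(0.5, 1.5), distance_noise_frac = 0.01),
    friction_bench
  )
  # normalize storage types so equal configs hash equally regardless of
  # whether values arrived as integer or double (e.g. from YAML)
  fb <- lapply(fb, as.numeric)
  fb$n_per_condition <- as.integer(fb$n_per_condition)
  structure(
    list(seed = as.integer(seed), cohort = cohort, noise = noise,
         profile = profile, device = device,
         filter_cutoff = as.numeric(filter_cutoff),
         friction_bench = fb,
         n_replication_targets = as.integer(n_replication_targets)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any of the top-level keys `seed`, `filter_cutoff`,
#' `n_replication_targets`, `friction_bench`, and nested mappings `cohort`,
#' `noise`, `profile`, `device` whose entries are the arguments of
#' [cohort_spec()], [sensor_noise()], [insertion_profile()] and
#' [haptic_device_spec()]; anything omitted keeps the package default.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$filter_cutoff)) args$filter_cutoff <- y$filter_cutoff
  if (!is.null(y$n_replication_targets)) {
    args$n_replication_targets <- y$n_replication_targets
  }
  if (!is.null(y$friction_bench)) args$friction_bench <- y$friction_bench
  # YAML parses whole numbers as integers; the constructors expect numerics
  num <- function(x) lapply(x, as.numeric)
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, num(y$cohort))
  if (!is.null(y$noise)) args$noise <- do.call(sensor_noise, num(y$noise))
  if (!is.null(y$profile)) {
    args$profile <- do.call(insertion_profile, num(y$profile))
  }
  if (!is.null(y$device)) {
    args$device <- do.call(haptic_device_spec, num(y$device))
  }
  do.call(run_config, args)
}

#' Hash of the semantically meaningful configuration fields
#'
#' @param config A [run_config()].
#' @return A character hash; changes iff a field that affects the computed
#'   numbers changes.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_portalsim(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "portalsim_stage_failure", parent = e
    )
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> estimate -> haptic validation in
#' order and collects a report bundle:
#' \enumerate{
#'   \item generate a synthetic cohort and friction-bench pushes;
#'   \item preprocess each trial and estimate per-patient peak force and
#'     stiffness;
#'   \item summarize the cohort with exclusions, estimate device friction
#'     and check the friction-to-force ratio;
#'   \item validate force/stiffness replication of the virtual device
#'     across targets spanning the cohort ranges.
#' }
#' All randomness derives from `config$seed`, so two runs with the same
#' config produce identical numbers.
#'
#' @param config A [run_config()].
#' @return A `portal_report_bundle` list: `cohort_summary`, `estimates`,
#'   `friction` (estimate + ratio check), `replication`, `provenance`.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(run_config(seed = 1))
#' bundle$cohort_summary$fmax_mean
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3L)

  cspec <- config$cohort
  cspec$seed <- seeds[[1]]
  cohort <- run_stage("simulate", generate_cohort(cspec, noise = config$noise,
                                                  profile = config$profile))

  estimates <- run_stage("estimate",
                         estimate_cohort(cohort, cutoff = config$filter_cutoff))
  summary <- run_stage("estimate", summarize_cohort(estimates))

  fb <- config$friction_bench
  bench <- run_stage("friction-bench", with_seed_if(seeds[[2]], {
    make_bench <- function(truth, attached, n) {
      lapply(seq_len(n), function(i) {
        generate_friction_trial(
          true_friction = truth,
          initial_speed = runif(1, fb$speed_range[1], fb$speed_range[2]),
          handle_mass = fb$handle_mass,
          reel_inertia = config$device$reel_inertia,
          reel_radius = config$device$reel_radius,
          cable_attached = attached,
          distance_noise_frac = fb$distance_noise_frac
        )
      })
    }
    c(make_bench(fb$true_total, TRUE, fb$n_per_condition),
      make_bench(fb$true_guide, FALSE, fb$n_per_condition))
  }))
  friction <- run_stage("friction-bench", estimate_friction(bench))
  ratio <- run_stage("friction-bench",
                     friction_ratio_check(friction$f_total, summary$fmax_mean))

  targets <- replication_targets(config$n_replication_targets,
                                 fmax_range = config$cohort$fmax_range,
                                 k_range = config$cohort$k_range)
  replication <- run_stage("haptic-validate",
                           validate_replication(targets, spec = config$device))

  structure(
    list(
      cohort_summary = summary, estimates = estimates,
      friction = list(estimate = friction, ratio = ratio),
      replication = replication,
      provenance = list(seed = config$seed,
                        config_hash = config_hash(config),
                        package_version = as.character(utils::packageVersion("portalsim")),
                        r_version = paste(R.version$major, R.version$minor, sep = "."))
    ),
    class = "portal_report_bundle"
  )
}

#' Render a report bundle to disk
#'
#' Writes the machine-readable and human-readable outputs of a pipeline
#' run: the cohort summary as a two-row table (mean +/- SD row and range
#' row, one column per mechanical property), the friction and replication
#' reports as JSON, the full bundle as JSON, and optional figures (per-
#' patient force-displacement curves and the target-versus-reproduced
#' scatter). Missing sections are flagged and the partial report is still
#' emitted. Every number written is taken from the bundle; nothing is
#' recomputed here.
#'
#' @param bundle A `portal_report_bundle` (sections may be `NULL`).
#' @param dir Output directory (created if needed).
#' @param plots Also write figures as PDF (default FALSE).
#' @return Invisibly, a list with `paths` of written files and
#'   `missing_sections` flags (e.g. `"friction: absent"`).
#' @export
render_report <- function(bundle, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  missing <- character(0)

  if (!is.null(bundle$cohort_summary)) {
    s <- bundle$cohort_summary
    tab <- tibble(
      statistic = c("Mean (±Std.)", "Range of data"),
      `Puncture Force (N)` = c(
        sprintf("%.2f (±%.2f)", s$fmax_mean, s$fmax_sd),
        sprintf("%.2f–%.2f", s$fmax_min, s$fmax_max)
      ),
      `Stiffness (N/m)` = c(
        sprintf("%.2f (±%.2f)", s$k_mean, s$k_sd),
        sprintf("%.2f–%.2f", s$k_min, s$k_max)
      )
    )
    p <- file.path(dir, "cohort_summary.tsv")
    readr::write_tsv(tab, p)
    paths <- c(paths, p)
    if (nrow(s$exclusion_log)) {
      p <- file.path(dir, "exclusions.tsv")
      readr::write_tsv(s$exclusion_log, p)
      paths <- c(paths, p)
    }
  } else missing <- c(missing, "cohort_summary: absent")

  if (!is.null(bundle$friction)) {
    p <- file.path(dir, "friction.json")
    fr <- bundle$friction$estimate
    jsonlite::write_json(
      list(f_total = fr$f_total, f_guide = fr$f_guide, f_cable = fr$f_cable,
           f_total_sd = fr$f_total_sd, f_guide_sd = fr$f_guide_sd,
           f_cable_sd = fr$f_cable_sd,
           per_trial = fr$per_trial,
           ratio_check = bundle$friction$ratio),
      p, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, p)
  } else missing <- c(missing, "friction: absent")

  if (!is.null(bundle$replication)) {
    p <- file.path(dir, "replication.json")
    jsonlite::write_json(
      list(r2_force = bundle$replication$r2_force,
           r2_stiffness = bundle$replication$r2_stiffness,
           results = bundle$replication$results),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  } else missing <- c(missing, "replication: absent")

  p <- file.path(dir, "report.json")
  jsonlite::write_json(bundle_to_json(bundle, missing), p,
                       auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)

  if (plots && !is.null(bundle$replication)) {
    p <- file.path(dir, "replication.pdf")
    ggplot2::ggsave(p, ggplot2::autoplot(bundle$replication),
                    width = 8, height = 4)
    paths <- c(paths, p)
  }
  if (length(missing)) {
    warning(paste(missing, collapse = "; "), call. = FALSE)
  }
  invisible(list(paths = paths, missing_sections = missing))
}

bundle_to_json <- function(bundle, missing = character(0)) {
  s <- bundle$cohort_summary
  list(
    cohort_summary = if (is.null(s)) NULL else
      s[c("n_included", "n_excluded", "n_position_valid",
          "fmax_mean", "fmax_sd", "fmax_min", "fmax_max",
          "k_mean", "k_sd", "k_min", "k_max")],
    exclusion_log = if (is.null(s)) NULL else s$exclusion_log,
    friction = if (is.null(bundle$friction)) NULL else
      bundle$friction$estimate[c("f_total", "f_guide", "f_cable")],
    friction_ratio = if (is.null(bundle$friction)) NULL else
      bundle$friction$ratio,
    replication = if (is.null(bundle$replication)) NULL else
      bundle$replication[c("r2_force", "r2_stiffness")],
    provenance = bundle$provenance,
    missing_sections = missing
  )
}

#' Read back a JSON report written by [render_report()]
#'
#' @param path Path to `report.json`.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
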