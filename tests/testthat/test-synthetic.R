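# synthetic trial, cohort and friction-bench generators

test_that("noiseless Phase II is an exact Hooke ramp peaking at F_max", {
  tr <- noiseless_trial(k = 1000, fmax = 50, speed = 0.01)
  d <- tr$data
  ev <- tr$events
  in2 <- d$time >= ev[["t_start"]] & d$time <= ev[["t_puncture"]]
  x <- d$time[in2] - ev[["t_start"]]
  # exact 10 N/s line through the origin
  expect_equal(d$force[in2], 10 * x, tolerance = 1e-12)
  expect_equal(max(d$force[in2]), 50, tolerance = 1e-12)
  expect_equal(d$force[d$time == ev[["t_puncture"]]], 50, tolerance = 1e-12)
  # phase I quiet, phase III decays toward the residual
  expect_true(all(d$force[d$time < ev[["t_start"]]] == 0))
  f3 <- d$force[d$time > ev[["t_puncture"]]]
  expect_true(all(diff(f3) < 0))
  expect_lt(tail(f3, 1), 50 * exp(-0.9 / 0.1) + 1e-6)
})

test_that("marker geometry is two points a fixed distance apart translating on the axis", {
  tr <- noiseless_trial()
  d <- tr$data
  sep <- sqrt((d$m2x - d$m1x)^2 + (d$m2y - d$m1y)^2 + (d$m2z - d$m1z)^2)
  expect_equal(sep, rep(0.08, nrow(d)), tolerance = 1e-12)
  # pure translation along +x: y and z never move
  expect_equal(var(d$m1y), 0)
  expect_equal(var(d$m1z), 0)
  expect_true(all(diff(d$m1x) >= 0))
})

test_that("identical seed reproduces a bit-identical recording", {
  a <- generate_trial(capsule_model(), sensor_noise(seed = 11))
  b <- generate_trial(capsule_model(), sensor_noise(seed = 11))
  expect_identical(a$data, b$data)
  c <- generate_trial(capsule_model(), sensor_noise(seed = 12))
  expect_false(identical(a$data$force, c$data$force))
})

test_that("generator rejects invalid profiles and unreachable puncture", {
  expect_error(insertion_profile(phase1_duration = 0), class = "portalsim_invalid_argument")
  expect_error(insertion_profile(speed = -1), class = "portalsim_invalid_argument")
  # k * speed * duration < fmax
  expect_error(
    generate_trial(capsule_model(1000, 50),
                   profile = insertion_profile(speed = 0.01,
                                               phase2_max_duration = 1)),
    class = "portalsim_unreachable_puncture"
  )
})

test_that("cohort draws respect truncation ranges and seeded determinism", {
  spec <- cohort_spec(n_patients = 12, dropout_probability = 0.5, seed = 99)
  co <- generate_cohort(spec)
  ks <- vapply(co, function(tr) tr$truth$capsule$stiffness_k, numeric(1))
  fs <- vapply(co, function(tr) tr$truth$capsule$puncture_force_fmax, numeric(1))
  expect_true(all(ks >= spec$k_range[1] & ks <= spec$k_range[2]))
  expect_true(all(fs >= spec$fmax_range[1] & fs <= spec$fmax_range[2]))
  # reproducible, including which trials carry marker gaps
  co2 <- generate_cohort(spec)
  expect_identical(lapply(co, `[[`, "data"), lapply(co2, `[[`, "data"))
  gaps <- vapply(co, function(tr) anyNA(tr$data$m1x), logical(1))
  expect_identical(gaps, vapply(co2, function(tr) anyNA(tr$data$m1x), logical(1)))
  expect_equal(sum(vapply(co, function(tr) tr$patient$synovitis_excluded,
                          logical(1))), 1)
})

test_that("zero spread collapses the cohort onto the means", {
  co <- generate_cohort(cohort_spec(n_patients = 4, k_sd = 0, fmax_sd = 0,
                                    dropout_probability = 0, seed = 1),
                        noise = sensor_noise(0, 0))
  ks <- vapply(co, function(tr) tr$truth$capsule$stiffness_k, numeric(1))
  fs <- vapply(co, function(tr) tr$truth$capsule$puncture_force_fmax, numeric(1))
  expect_equal(ks, rep(portal_reference()$k_mean, 4))
  expect_equal(fs, rep(portal_reference()$fmax_mean, 4))
})

test_that("cohort ground-truth mean stays within sampling error of the target mean", {
  # oracle: direct Monte-Carlo of the same truncated normal
  ref <- portal_reference()
  mc <- withr::with_seed(7, {
    x <- rnorm(2e5, ref$k_mean, ref$k_sd)
    x <- x[x >= ref$k_range[1] & x <= ref$k_range[2]]
    c(mean(x), sd(x))
  })
  co <- generate_cohort(cohort_spec(n_patients = 9, seed = 21),
                        noise = sensor_noise(0, 0))
  ks <- vapply(co, function(tr) tr$truth$capsule$stiffness_k, numeric(1))
  expect_lt(abs(mean(ks) - mc[1]), 3 * mc[2] / sqrt(9))
})

test_that("friction bench obeys the energy balance and the reel term", {
  # closed form: d = m v0^2 / (2 F) when the reel is massless
  ft <- generate_friction_trial(5, 1, handle_mass = 0.5, reel_inertia = 0)
  expect_equal(ft$travel_distance, 0.05, tolerance = 1e-12)
  # attached trial dissipates extra rotational energy but still balances
  att <- generate_friction_trial(5, 1, handle_mass = 0.5,
                                 reel_inertia = 34833.32e-9,
                                 reel_radius = 0.020, cable_attached = TRUE)
  det <- generate_friction_trial(5, 1, handle_mass = 0.5,
                                 reel_inertia = 34833.32e-9,
                                 reel_radius = 0.020, cable_attached = FALSE)
  energy <- 0.5 * 0.5 * 1^2 + 0.5 * 34833.32e-9 * (1 / 0.020)^2
  expect_equal(5 * att$travel_distance, energy, tolerance = 1e-12)
  # under the realistic per-condition frictions (cable adds drag), the
  # attached push stops strictly sooner than the detached one at the same v0
  ref <- portal_reference()
  att_real <- generate_friction_trial(ref$friction_total, 1, cable_attached = TRUE)
  det_real <- generate_friction_trial(ref$friction_guide, 1, cable_attached = FALSE)
  expect_lt(att_real$travel_distance, det_real$travel_distance)
  expect_true(all(diff(att$speed_trace) <= 0))
  expect_error(generate_friction_trial(5, 1, reel_radius = 0,
                                       cable_attached = TRUE),
               class = "portalsim_invalid_argument")
  expect_error(generate_friction_trial(-1, 1), class = "portalsim_invalid_argument")
})
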