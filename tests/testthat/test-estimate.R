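# stiffness fit, puncture force, cohort summary, friction estimation

test_that("through-origin fit recovers an exact Hooke line", {
  x <- seq(0, 0.02, by = 1e-3)
  fit <- fit_stiffness(data.frame(force = 1000 * x, travel_distance = x))
  expect_equal(fit$k_hat, 1000, tolerance = 1e-12)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-12)
  expect_error(
    fit_stiffness(data.frame(force = c(1, 2, 3), travel_distance = c(0, 0, 0))),
    class = "portalsim_degenerate_fit"
  )
  expect_error(
    fit_stiffness(data.frame(force = 1, travel_distance = 1)),
    class = "portalsim_degenerate_fit"
  )
})

test_that("fit matches a brute-force sum(xy)/sum(x^2) oracle on noisy data", {
  withr::with_seed(17, {
    x <- runif(80, 0, 0.03)
    f <- 1500 * x + rnorm(80, 0, 0.5)
  })
  fit <- fit_stiffness(data.frame(force = f, travel_distance = x))
  # independent oracle: explicit loop
  num <- 0; den <- 0
  x0 <- x - x[1]
  for (i in seq_along(x0)) {
    num <- num + x0[i] * f[i]
    den <- den + x0[i]^2
  }
  expect_equal(fit$k_hat, num / den, tolerance = 1e-12)
  res <- f - fit$k_hat * x0
  expect_equal(fit$residual_rms, sqrt(mean(res^2)), tolerance = 1e-12)
  # the intercept variant agrees with lm()
  fit_b <- fit_stiffness(data.frame(force = f, travel_distance = x),
                         intercept = TRUE)
  cf <- coef(lm(f ~ x0))
  expect_equal(fit_b$k_hat, unname(cf[2]), tolerance = 1e-10)
  expect_equal(fit_b$intercept, unname(cf[1]), tolerance = 1e-10)
})

test_that("noiseless trials at the cohort means round-trip to machine precision", {
  ref <- portal_reference()
  tr <- generate_trial(capsule_model(ref$k_mean, ref$fmax_mean),
                       noise = sensor_noise(0, 0))
  pt <- process_trial(tr, cutoff = 5)
  expect_equal(fit_stiffness(pt)$k_hat, ref$k_mean, tolerance = 1e-9)
  expect_equal(extract_puncture_force(pt)$f_max_hat, ref$fmax_mean,
               tolerance = 1e-9)
  # and over a 9-patient zero-spread cohort the mean is exact
  co <- generate_cohort(cohort_spec(n_patients = 9, k_sd = 0, fmax_sd = 0,
                                    dropout_probability = 0, n_synovitis = 0,
                                    seed = 1),
                        noise = sensor_noise(0, 0))
  est <- estimate_cohort(co)
  expect_equal(mean(est$k_hat), ref$k_mean, tolerance = 1e-9)
  expect_equal(mean(est$f_max_hat), ref$fmax_mean, tolerance = 1e-9)
})

test_that("round-trip recovery is exact for every generated parameter pair", {
  co <- generate_cohort(cohort_spec(n_patients = 5, dropout_probability = 0,
                                    n_synovitis = 0, seed = 77),
                        noise = sensor_noise(0, 0))
  est <- estimate_cohort(co)
  expect_equal(est$k_hat, est$k_true, tolerance = 1e-9)
  expect_equal(est$f_max_hat, est$fmax_true, tolerance = 1e-9)
})

test_that("peak extraction is a windowed max with last-occurrence ties", {
  d <- data.frame(time = seq(0, 1, by = 0.1),
                  force = c(0, 10, 20, 30, 40, 50, 50, 40, 30, 20, 10))
  pf <- extract_puncture_force(d, window = c(0, 1))
  expect_equal(pf$f_max_hat, 50)
  expect_equal(pf$t_at_max, 0.6)   # last of the tied samples
  expect_error(extract_puncture_force(d, window = c(2, 3)),
               class = "portalsim_degenerate_fit")
  # brute-force linear scan oracle on a noisy trace
  withr::with_seed(9, f <- cumsum(rnorm(100)))
  d2 <- data.frame(time = seq_along(f), force = f)
  best <- -Inf
  for (v in f) if (v > best) best <- v
  expect_equal(extract_puncture_force(d2, window = range(d2$time))$f_max_hat,
               best)
})

test_that("stiffness estimator is unbiased at the default sensor noise", {
  ref <- portal_reference()
  ks <- vapply(1:500, function(i) {
    tr <- generate_trial(capsule_model(), sensor_noise(seed = 20000 + i))
    fit_stiffness(process_trial(tr))$k_hat
  }, numeric(1))
  expect_lt(abs(mean(ks) - ref$k_mean), 0.005 * ref$k_mean)
})

test_that("stiffness estimator spread shrinks as sensor noise shrinks", {
  levels <- c(0.1, 1, 3)   # multiples of the default sensor noise
  spread <- vapply(seq_along(levels), function(j) {
    ks <- vapply(1:40, function(i) {
      nz <- sensor_noise(levels[j] / 3, levels[j] * 1e-3 / 3,
                         seed = 10000 * j + i)
      fit_stiffness(process_trial(generate_trial(capsule_model(), nz)))$k_hat
    }, numeric(1))
    sd(ks)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("cohort summary applies exclusions and matches a two-pass oracle", {
  withr::with_seed(23, {
    est <- tibble::tibble(
      patient_id = sprintf("P%02d", 1:10),
      f_max_hat = runif(10, 40, 80),
      t_at_max = runif(10, 3, 5),
      k_hat = runif(10, 2300, 2900),
      residual_rms = runif(10),
      position_valid = rep(c(TRUE, FALSE), 5),
      rom_eligible = TRUE,
      synovitis_excluded = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 6))
    )
  })
  s <- summarize_cohort(est)
  expect_equal(s$n_included, 9)
  expect_equal(s$n_excluded, 1)
  expect_identical(s$exclusion_log$patient_id, "P04")
  # independent streaming oracle for mean / sample SD over included patients
  inc <- est[!est$synovitis_excluded, ]
  n <- 0; m <- 0; ss <- 0
  for (v in inc$f_max_hat) {
    n <- n + 1; d <- v - m; m <- m + d / n; ss <- ss + d * (v - m)
  }
  expect_equal(s$fmax_mean, m, tolerance = 1e-12)
  expect_equal(s$fmax_sd, sqrt(ss / (n - 1)), tolerance = 1e-12)
  expect_equal(s$fmax_min, min(inc$f_max_hat))
  expect_equal(s$fmax_max, max(inc$f_max_hat))
  # stiffness only over position-valid included patients
  kv <- inc$k_hat[inc$position_valid]
  expect_equal(s$k_mean, mean(kv))
  expect_equal(s$n_position_valid, length(kv))
  # permutation invariance in patient order
  perm <- withr::with_seed(5, sample(10))
  s2 <- summarize_cohort(est[perm, ])
  expect_equal(s2[setdiff(names(s2), "exclusion_log")],
               s[setdiff(names(s), "exclusion_log")])
  # degenerate spread and empty-cohort rejection
  est0 <- est; est0$f_max_hat <- 60; est0$k_hat <- 2500
  s0 <- summarize_cohort(est0)
  expect_equal(s0$fmax_sd, 0)
  expect_equal(s0$fmax_min, s0$fmax_max)
  est_all <- est; est_all$synovitis_excluded <- TRUE
  expect_error(summarize_cohort(est_all), class = "portalsim_empty_cohort")
})

test_that("friction estimator reproduces closed forms and printed arithmetic", {
  # d = 0.05 m at m = 0.5 kg, v0 = 1 m/s, massless reel -> F = 5 N
  tr <- list(
    generate_friction_trial(5, 1, handle_mass = 0.5, reel_inertia = 0,
                            cable_attached = TRUE),
    generate_friction_trial(2, 1, handle_mass = 0.5, reel_inertia = 0,
                            cable_attached = FALSE)
  )
  fe <- estimate_friction(tr)
  expect_equal(fe$f_total, 5, tolerance = 1e-12)
  expect_equal(fe$f_guide, 2, tolerance = 1e-12)
  expect_equal(fe$f_cable, 3, tolerance = 1e-12)
  # construction identity and non-negativity on a noiseless bench
  expect_equal(fe$f_cable + fe$f_guide, fe$f_total)
  expect_true(all(c(fe$f_total, fe$f_guide, fe$f_cable) >= 0))
  # condition means from the published characterization
  expect_equal(friction_components(3.76, 1.91)$f_cable, 1.85, tolerance = 1e-12)
  expect_error(estimate_friction(tr[1]), class = "portalsim_invalid_argument")
})

test_that("ten noiseless bench pushes recover the device's total friction", {
  ref <- portal_reference()
  trials <- c(
    lapply(1:10, function(i)
      generate_friction_trial(ref$friction_total, 0.5 + 0.1 * i,
                              cable_attached = TRUE)),
    lapply(1:3, function(i)
      generate_friction_trial(ref$friction_guide, 1, cable_attached = FALSE))
  )
  fe <- estimate_friction(trials)
  expect_equal(fe$f_total, ref$friction_total, tolerance = 1e-12)
})

test_that("friction-to-force ratio check uses a strict threshold", {
  chk <- friction_ratio_check(3.763, 66.46)
  expect_equal(chk$ratio, 3.763 / 66.46, tolerance = 1e-12)
  expect_true(chk$pass)
  expect_true(friction_ratio_check(0, 60)$pass)
  expect_false(friction_ratio_check(6, 100, jnd_fraction = 0.06)$pass)
  expect_error(friction_ratio_check(1, 0), class = "portalsim_invalid_argument")
})
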