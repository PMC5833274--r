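# filtering, travel distance, segmentation, puncture detection

test_that("low-pass filter has unit DC gain and strong stop-band attenuation", {
  expect_equal(lowpass_filter(rep(10, 200), 100, 5), rep(10, 200))
  # 40 Hz sine on a 100 Hz grid: two Butterworth passes give far more than
  # the 20 dB bound; the analytic single-pass magnitude is the oracle
  tt <- seq(0, 5, by = 0.01)
  y <- lowpass_filter(sin(2 * pi * 40 * tt), 100, 5)
  out_amp <- max(abs(y[100:400]))
  expect_lt(out_amp, 0.1)   # >= 20 dB
  H <- signal::freqz(signal::butter(4, 0.1), Fs = 100)
  h40 <- abs(H$h[which.min(abs(H$f - 40))])^2   # two passes = |H|^2
  expect_lt(out_amp, 10 * h40 + 1e-9)
  expect_error(lowpass_filter(1:10, 100, 50), class = "portalsim_invalid_cutoff")
  expect_error(lowpass_filter(c(1, NA, 3, 4, 5), 100, 5),
               class = "portalsim_missing_samples")
})

test_that("filter is zero-phase: a symmetric pulse keeps its center of mass", {
  tt <- seq(0, 6, by = 0.01)
  pulse <- exp(-((tt - 3) / 0.3)^2)
  y <- lowpass_filter(pulse, 100, 5)
  com <- function(v) sum(tt * v) / sum(v)
  expect_lt(abs(com(y) - com(pulse)), 1e-9)
})

test_that("filtering shifts the peak of a noiseless trial by less than one sample", {
  tr <- noiseless_trial(k = 2000, fmax = 60)
  pt <- process_trial(tr, cutoff = 5)
  truth_peak <- tr$events[["t_puncture"]]
  in2 <- pt$data$phase == "II"
  t_peak <- pt$data$time[in2][which.max(pt$data$force[in2])]
  expect_lt(abs(t_peak - truth_peak), 0.01 + 1e-12)
})

test_that("travel distance projects midpoint motion onto the shaft axis", {
  n <- 50
  base <- tibble::tibble(
    m1x = rep(0, n), m1y = 0, m1z = 0,
    m2x = rep(0.08, n), m2y = 0, m2z = 0
  )
  # stationary markers: identically zero
  kt <- compute_travel_distance(base)
  expect_equal(kt$travel_distance, rep(0, n))
  expect_true(all(kt$valid))
  # 10 mm pure translation along the shaft axis
  shift <- seq(0, 0.010, length.out = n)
  along <- dplyr::mutate(base, m1x = m1x + shift, m2x = m2x + shift)
  expect_equal(max(compute_travel_distance(along)$travel_distance), 0.010,
               tolerance = 1e-12)
  # 10 mm path at 60 degrees to the axis projects to 5 mm
  oblique <- dplyr::mutate(base,
                           m1x = m1x + shift * cos(pi / 3),
                           m2x = m2x + shift * cos(pi / 3),
                           m1y = m1y + shift * sin(pi / 3),
                           m2y = m2y + shift * sin(pi / 3))
  expect_equal(max(compute_travel_distance(oblique)$travel_distance), 0.005,
               tolerance = 1e-12)
})

test_that("travel distance is invariant under rigid rotation and translation", {
  tr <- generate_trial(capsule_model(), sensor_noise(seed = 31),
                       profile = insertion_profile(lateral_amplitude = 2e-3))
  ref <- compute_travel_distance(tr$data, reference_index = 201)
  withr::with_seed(42, {
    for (rep in 1:5) {
      R <- random_rotation()
      moved <- transform_markers(tr$data, R, shift = rnorm(3))
      got <- compute_travel_distance(moved, reference_index = 201)
      expect_equal(got$travel_distance, ref$travel_distance, tolerance = 1e-9)
    }
  })
})

test_that("marker gaps are interpolated when short, masked and bridged when long", {
  tr <- noiseless_trial()
  d <- tr$data
  cols <- c("m1x", "m1y", "m1z", "m2x", "m2y", "m2z")
  # short gap (3 samples): recovered by interpolation
  d3 <- d; d3[300:302, cols] <- NA_real_
  kt3 <- compute_travel_distance(d3, reference_index = 201)
  expect_true(all(kt3$valid))
  # long gap (30 samples): masked invalid, displacement bridged across it
  d30 <- d; d30[300:329, cols] <- NA_real_
  kt30 <- compute_travel_distance(d30, reference_index = 201)
  expect_false(any(kt30$valid[300:329]))
  expect_true(all(is.na(kt30$travel_distance[300:329])))
  full <- compute_travel_distance(d, reference_index = 201)
  expect_equal(kt30$travel_distance[400], full$travel_distance[400],
               tolerance = 1e-9)
  # coincident markers invalidate the sample
  dc <- d; dc[100, c("m2x", "m2y", "m2z")] <- dc[100, c("m1x", "m1y", "m1z")]
  expect_false(compute_travel_distance(dc)$valid[100])
})

test_that("phase segmentation follows the recorded timestamps", {
  tr <- noiseless_trial()
  seg <- segment_phases(tr)
  expect_identical(seg$source, "timestamps")
  expect_equal(seg$t_start, tr$events[["t_start"]])
  expect_equal(seg$t_puncture, tr$events[["t_puncture"]])
  # phases partition the recording with boundary samples in Phase II
  lab <- phase_labels(tr$data$time, seg)
  expect_false(anyNA(lab))
  expect_identical(as.character(lab[tr$data$time == seg$t_start]), "II")
  expect_identical(as.character(lab[tr$data$time == seg$t_puncture]), "II")
  expect_true(all(diff(as.integer(lab)) >= 0))
  # degenerate and missing timestamps are rejected
  tr0 <- tr; tr0$events[["t_puncture"]] <- tr0$events[["t_start"]]
  expect_error(segment_phases(tr0), class = "portalsim_degenerate_phase")
  trna <- tr; trna$events[["t_puncture"]] <- NA_real_
  expect_error(segment_phases(trna), class = "portalsim_bad_timestamps")
})

test_that("timestampless segmentation can fall back to force-based detection", {
  tr <- default_trial(seed = 8)
  trna <- tr; trna$events[["t_puncture"]] <- NA_real_
  seg <- segment_phases(trna, auto_fallback = TRUE)
  expect_identical(seg$source, "auto")
  expect_lt(abs(seg$t_puncture - tr$events[["t_puncture"]]), 0.05)
})

test_that("puncture detector finds step drops and reports absence", {
  f <- c(seq(0, 50, by = 0.5), rep(0, 50))
  tp <- detect_puncture_auto(f, rate = 100)
  expect_equal(tp, 1.01)   # the first sample after the 50 N peak at t = 1.00
  expect_error(detect_puncture_auto(seq(0, 50, by = 0.5), rate = 100),
               class = "portalsim_no_puncture")
})

test_that("puncture detection lands within 0.05 s of truth on noisy trials", {
  hits <- vapply(1:200, function(i) {
    tr <- default_trial(seed = 5000 + i)
    f <- lowpass_filter(tr$data$force, rate = 100, cutoff = 5)
    tp <- detect_puncture_auto(f, rate = 100, time = tr$data$time)
    abs(tp - tr$events[["t_puncture"]]) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("long Phase-II occlusions flag the trial position-invalid", {
  co <- generate_cohort(cohort_spec(n_patients = 6, dropout_probability = 1,
                                    n_synovitis = 0, seed = 3))
  pts <- lapply(co, process_trial)
  expect_true(all(!vapply(pts, `[[`, logical(1), "position_valid")))
  co0 <- generate_cohort(cohort_spec(n_patients = 6, dropout_probability = 0,
                                     n_synovitis = 0, seed = 3))
  pts0 <- lapply(co0, process_trial)
  expect_true(all(vapply(pts0, `[[`, logical(1), "position_valid")))
})
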