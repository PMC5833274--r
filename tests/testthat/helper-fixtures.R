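# shared fixtures: all synthetic, generated at test time

# a clean noiseless trial with simple round numbers (k = 1000 N/m,
# F_max = 50 N, 0.01 m/s -> Phase II is an exact 10 N/s ramp over 5 s)
noiseless_trial <- function(k = 1000, fmax = 50, speed = 0.01, ...) {
  generate_trial(
    capsule_model(stiffness_k = k, puncture_force_fmax = fmax),
    noise = sensor_noise(0, 0),
    profile = insertion_profile(speed = speed, phase1_jitter = 0, ...)
  )
}

# a trial at the package-default (cohort mean) capsule parameters
default_trial <- function(seed = NULL, noise = sensor_noise(seed = seed)) {
  generate_trial(capsule_model(), noise = noise)
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform to the marker columns of a trial's data
transform_markers <- function(data, R = diag(3), shift = c(0, 0, 0)) {
  m1 <- as.matrix(data[c("m1x", "m1y", "m1z")]) %*% t(R)
  m2 <- as.matrix(data[c("m2x", "m2y", "m2z")]) %*% t(R)
  data$m1x <- m1[, 1] + shift[1]; data$m1y <- m1[, 2] + shift[2]
  data$m1z <- m1[, 3] + shift[3]
  data$m2x <- m2[, 1] + shift[1]; data$m2y <- m2[, 2] + shift[2]
  data$m2z <- m2[, 3] + shift[3]
  data
}

# a matched pair of friction-bench conditions
bench_pair <- function(total = 5, guide = 2, n = 3, v0 = 1, ...) {
  c(
    lapply(seq_len(n), function(i)
      generate_friction_trial(total, v0 + 0.1 * i, cable_attached = TRUE, ...)),
    lapply(seq_len(n), function(i)
      generate_friction_trial(guide, v0 + 0.1 * i, cable_attached = FALSE, ...))
  )
}
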