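# Seizure kinematics synthesis and the complementary orientation filter.

test_that("complementary filter has the closed-form limits and worked value", {
  p1 <- fusion_params(alpha = 1, dt = 0.01)
  expect_equal(fuse_orientation(0.1, 0.5, 99, p1), 0.1 + 0.5 * 0.01)
  p0 <- fusion_params(alpha = 0, dt = 0.01)
  expect_equal(fuse_orientation(0.1, 0.5, 0.12, p0), 0.12)
  p <- fusion_params(alpha = 0.98, dt = 0.01)
  expect_equal(fuse_orientation(0.1, 0.5, 0.12, p),
               0.98 * (0.1 + 0.5 * 0.01) + 0.02 * 0.12)
  expect_equal(round(fuse_orientation(0.1, 0.5, 0.12, p), 4), 0.1053)
  expect_error(fusion_params(alpha = 1.2, dt = 0.01), "alpha")
})

test_that("the filter is affine in each input (superposition)", {
  p <- fusion_params(alpha = 0.9, dt = 0.02)
  f <- function(tp, om, ta) fuse_orientation(tp, om, ta, p)
  base <- f(0.2, 1.0, 0.15)
  expect_equal(f(0.2 + 0.05, 1.0, 0.15) - base, 0.9 * 0.05)
  expect_equal(f(0.2, 1.0 + 0.5, 0.15) - base, 0.9 * 0.5 * 0.02)
  expect_equal(f(0.2, 1.0, 0.15 + 0.1) - base, 0.1 * 0.1)
  # full superposition
  expect_equal(f(0.1, 0.3, 0.2) + f(0.05, -0.1, 0.04),
               f(0.15, 0.2, 0.24) + f(0, 0, 0))
})

test_that("filtering a raw IMU table reduces to gyro integration at alpha = 1", {
  t <- seq(0, 2, by = 0.01)
  imu <- tibble::tibble(time_s = t,
                        gyro_rad_s = 0.5 * cos(2 * pi * t),
                        accel_angle_rad = 99)  # ignored at alpha = 1
  out <- apply_complementary_filter(imu, alpha = 1)
  integ <- 99 + cumsum(c(0, imu$gyro_rad_s[-1]) * 0.01)
  expect_equal(out$fused_rad, integ, tolerance = 1e-12)
})

test_that("a trace has the requested duration and sampling", {
  tr <- generate_seizure_roll(seizure_params(duration = 60, sample_rate = 100))
  expect_equal(nrow(tr), 6000L)
  expect_equal(diff(tr$time_s[1:2]), 0.01)
})

test_that("realized statistics hit the targets across seeds", {
  for (sd in 1:4) {
    tr <- generate_seizure_roll(seizure_params(seed = sd))
    r <- attr(tr, "realized")
    expect_equal(r$peak_angular_velocity, 9.5, tolerance = 0.01)
    expect_equal(r$angular_displacement_range, 0.50, tolerance = 0.01)
    expect_equal(r$dominant_frequency, 0.5, tolerance = 0.05)
  }
})

test_that("mean realized peak roll rate over many seeds is inside the reported band", {
  pk <- vapply(1:20, function(sd) {
    attr(generate_seizure_roll(seizure_params(seed = sd)),
         "realized")$peak_angular_velocity
  }, numeric(1))
  expect_gt(mean(pk), 9.5 - 1.1)
  expect_lt(mean(pk), 9.5 + 1.1)
})

test_that("angular velocity is consistent with the sampled angle derivative", {
  tr <- generate_seizure_roll(seizure_params(seed = 2))
  dt <- diff(tr$time_s[1:2])
  n <- nrow(tr)
  fd <- (tr$roll_rad[3:n] - tr$roll_rad[1:(n - 2)]) / (2 * dt)
  err <- fd - tr$roll_rate_rad_s[2:(n - 1)]
  # central differences of band-limited content are accurate to O((2 pi f dt)^2)
  expect_lt(sqrt(mean(err^2)) / sd(tr$roll_rate_rad_s), 0.05)
})

test_that("unreachable targets raise an informative calibration error", {
  bad <- seizure_params(peak_angular_velocity = 1e-6,
                        angular_displacement_range = 10)
  expect_error(generate_seizure_roll(bad, max_iter = 3), "calibration")
})

test_that("prescribed uterine motion is a rigid rotation of the driven ring", {
  model <- build_nested_model(nested_model_config())
  mesh <- model$uterus
  # constant pi/2: a node at (r, 0) maps to (0, r)
  tr90 <- tibble::tibble(time_s = c(0, 1), roll_rad = c(pi / 2, pi / 2))
  out <- prescribe_uterine_motion(tr90, mesh)
  x0 <- mesh$X[out$nodes, ]
  expect_equal(out$pos[1, , 1], -x0[, 2], tolerance = 1e-12)
  expect_equal(out$pos[1, , 2], x0[, 1], tolerance = 1e-12)
  # zero angle: stationary
  tr0 <- tibble::tibble(time_s = c(0, 1), roll_rad = c(0, 0))
  out0 <- prescribe_uterine_motion(tr0, mesh)
  expect_equal(out0$pos[2, , ], unname(x0), tolerance = 1e-14)
  # arbitrary angles preserve all pairwise distances
  tra <- tibble::tibble(time_s = c(0, 0.5, 1), roll_rad = c(0, 0.37, -1.2))
  outa <- prescribe_uterine_motion(tra, mesh)
  d0 <- dist(x0)
  for (k in 2:3) expect_lt(max(abs(dist(outa$pos[k, , ]) - d0)), 1e-12)
})

test_that("kinematics CSV round-trips", {
  tr <- generate_seizure_roll(seizure_params(duration = 2, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_kinematics_csv(tr, path)
  back <- read_kinematics_csv(path)
  expect_equal(back$roll_rad, tr$roll_rad, tolerance = 1e-12)
  expect_s3_class(back, "kin_trace")
})

test_that("dominant_frequency recovers a pure tone", {
  t <- seq(0, 30, by = 0.01)
  expect_equal(dominant_frequency(sin(2 * pi * 1.3 * t), 100), 1.3,
               tolerance = 0.05)
})
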