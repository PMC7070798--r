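# acquisition simulator: trajectory sampling, ray casting, scan frames, NMEA

test_that("trajectory sampling: spacing, perturbations, endpoint", {
  tr <- trajectory_spec(speed = 0.25, x_end = 5)
  p <- simulate_trajectory(tr, scan_rate = 25, seed = 1)
  expect_equal(diff(p$x), rep(0.010, nrow(p) - 1), tolerance = 1e-12)
  expect_true(all(p$roll == 0 & p$pitch == 0 & p$yaw == 0))

  tr2 <- trajectory_spec(speed = 0.5, x_end = 5)
  p2 <- simulate_trajectory(tr2, scan_rate = 50, seed = 1)
  expect_equal(max(p2$x), 5.0)
  expect_equal(max(p2$t), 10.0)
  expect_true(all(diff(p2$t) > 0))

  expect_error(trajectory_spec(speed = 0), "positive")
  expect_error(trajectory_spec(speed = -1), "positive")

  # perturbed runs stay deterministic per seed and bounded by amplitudes
  tr3 <- trajectory_spec(speed = 0.25, x_end = 2, roll_amp = 0.02,
                         yaw_amp = 0.01, wobble_amp = 0.05)
  a <- simulate_trajectory(tr3, 25, seed = 9)
  b <- simulate_trajectory(tr3, 25, seed = 9)
  expect_identical(a, b)
  expect_lte(max(abs(a$roll)), 0.02)
  expect_lte(max(abs(a$y)), 0.05)
})

test_that("cast_beam: closed-form cylinder intersection and window behavior", {
  scene <- cylinder_scene(x0 = 0, y0 = 1, radius = 0.05, height = 3)
  # horizontal beam from (0,0,1.2) along +Y: cylinder wall at y = 0.95
  expect_equal(cast_beam(c(0, 0, 1.2), c(0, 1, 0), scene), 0.95,
               tolerance = 1e-12)
  # away from all geometry: no return
  expect_equal(cast_beam(c(0, 0, 1.2), c(0, -1, 0), scene), Inf)
  # oblique beam: quadratic oracle
  d <- c(0, 1, 1) / sqrt(2)
  r <- cast_beam(c(0, 0, 1.2), d, scene)
  expect_equal(r, 0.95 * sqrt(2), tolerance = 1e-9)
})

test_that("scan frames carry one beam per angular step and honor the window", {
  scene <- cylinder_scene(x0 = 1, y0 = 1)
  sensor <- sensor_config(fov = 270, angular_step = 0.5, range_noise_sd = 0)
  expect_equal(sensor$n_beams, 541)
  traj <- trajectory_spec(speed = 0.5, x_end = 2, gnss_noise_sd = 0)
  run <- simulate_scan(scene, sensor, traj, seed = 1)
  fr <- scan_frame(run$scans, 1)
  expect_length(fr$angles, 541)
  expect_equal(range(fr$angles), c(-135, 135))
  ok <- run$scans$valid
  expect_true(all(run$scans$range_m[ok] >= 0.5 & run$scans$range_m[ok] <= 20))
  # a target beyond range_max gives no return
  far <- cylinder_scene(x0 = 0, y0 = 25)
  expect_equal(cast_beam(c(0, 0, 1.2), c(0, 1, 0), far), 25 - 0.05)
  expect_equal(cast_beam(c(0, 0, 1.2), c(0, 1, 0), far, sensor), Inf)
  run_far <- simulate_scan(far, sensor,
                           trajectory_spec(speed = 0.5, x_end = 0.1), seed = 1)
  expect_false(any(run_far$scans$valid))
})

test_that("zero noise reproduces exact geometric ranges (dense-beam oracle)", {
  scene <- cylinder_scene(x0 = 1, y0 = 1, radius = 0.1)
  sensor <- sensor_config(angular_step = 0.5, range_noise_sd = 0,
                          range_quantum = 0)
  traj <- trajectory_spec(speed = 0.5, x_end = 2, gnss_noise_sd = 0)
  run <- simulate_scan(scene, sensor, traj, seed = 1)
  poses <- run$poses
  # frame 101 sits at x = 1.0, the plane through the cylinder axis
  sub <- run$scans[run$scans$valid & run$scans$scan_index == 101, ]
  pose <- poses[101, ]
  expect_gt(nrow(sub), 10)
  # independent oracle: closed-form ray/cylinder quadratic per beam
  for (i in seq_len(nrow(sub))) {
    th <- sub$angle_deg[i] * pi / 180
    o <- c(pose$x, pose$y, pose$z + 1.2)
    v <- c(0, cos(th), sin(th))
    oc <- o[1:2] - c(1, 1)
    vv <- v[1:2]
    A <- sum(vv^2); B <- sum(oc * vv); C <- sum(oc^2) - 0.1^2
    tt <- (-B - sqrt(B^2 - A * C)) / A
    expect_equal(sub$range_m[i], tt, tolerance = 1e-9)
  }
})

test_that("mean inter-slice spacing equals speed/scan_rate within 1%", {
  scene <- cylinder_scene(x0 = 2.5, y0 = 1, radius = 0.3, height = 3)
  sensor <- sensor_config(scan_rate = 25, range_noise_sd = 0.012)
  traj <- trajectory_spec(speed = 0.25, x_end = 5, gnss_noise_sd = 0)
  run <- simulate_scan(scene, sensor, traj, seed = 2)
  dx <- diff(run$poses$x)
  expect_lt(abs(mean(dx) - 0.25 / 25) / (0.25 / 25), 0.01)
  expect_true(all(diff(unique(run$scans$timestamp_s)) > 0))
})

test_that("NMEA generation is seeded, checksummed, and zero-noise exact", {
  poses <- simulate_trajectory(trajectory_spec(speed = 0.25, x_end = 1), 25,
                               seed = 1)
  s1 <- generate_nmea(poses, 10, 0.02, seed = 4)
  s2 <- generate_nmea(poses, 10, 0.02, seed = 4)
  s3 <- generate_nmea(poses, 10, 0.02, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  # every sentence parses with a valid checksum
  for (s in s1) expect_s3_class(parse_gga(s), "data.frame")
})
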