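# registration: polar conversion, pose interpolation, rigid transform,
# end-to-end round trip against the simulator

test_that("polar_to_plane follows the scan-plane convention", {
  s <- sensor_config()  # mount height 1.2 m
  expect_equal(polar_to_plane(1.0, 0, s), cbind(y = 1.0, z = 1.2))
  expect_equal(polar_to_plane(1.0, 90, s), cbind(y = 0, z = 2.2),
               tolerance = 1e-12)
  expect_equal(polar_to_plane(1.41421356, 45, s), cbind(y = 1.0, z = 2.2),
               tolerance = 1e-7)
})

test_that("pose interpolation is linear, exact at fixes, with straight-run yaw", {
  fixes <- data.frame(t = c(0, 1, 2), east = c(0, 0.25, 0.5),
                      north = 0, up = 0)
  p <- interpolate_pose(fixes, 0.4)
  expect_equal(p$x, 0.10)
  expect_equal(interpolate_pose(fixes, 1)$x, 0.25)
  expect_equal(interpolate_pose(fixes, seq(0, 2, 0.25))$yaw, rep(0, 9))
  expect_error(interpolate_pose(fixes, 2.5), "outside")
  expect_error(interpolate_pose(fixes, -0.1), "outside")
  # reversed travel gives yaw = pi
  rev_fixes <- data.frame(t = c(0, 1, 2), east = c(1, 0.5, 0), north = 0,
                          up = 0)
  expect_equal(abs(interpolate_pose(rev_fixes, 1)$yaw), pi)
})

test_that("apply_pose: identity, translation, rotation oracle, shear", {
  pts <- matrix(rnorm(30), ncol = 3)
  id <- data.frame(x = 0, y = 0, z = 0, roll = 0, pitch = 0, yaw = 0)
  expect_equal(apply_pose(pts, id), pts)

  tr <- data.frame(x = 1, y = 2, z = 3, roll = 0, pitch = 0, yaw = 0)
  expect_equal(apply_pose(pts, tr), sweep(pts, 2, c(1, 2, 3), "+"))

  yaw90 <- data.frame(x = 0, y = 0, z = 0, roll = 0, pitch = 0, yaw = pi / 2)
  out <- apply_pose(matrix(c(0, 1, 0), 1), yaw90)
  expect_equal(as.numeric(out), c(-1, 0, 0), tolerance = 1e-12)

  # explicit rotation-matrix oracle for a general attitude
  ang <- c(roll = 0.3, pitch = -0.2, yaw = 1.1)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  pose <- data.frame(x = 0.5, y = -1, z = 2, roll = ang[1], pitch = ang[2],
                     yaw = ang[3])
  expected <- pts %*% t(Rz %*% Ry %*% Rx) +
    matrix(c(0.5, -1, 2), nrow(pts), 3, byrow = TRUE)
  expect_equal(apply_pose(pts, pose), expected, tolerance = 1e-12)

  # rigid transform preserves pairwise distances to 1e-9 (shear disabled)
  d0 <- dist(pts)
  d1 <- dist(apply_pose(pts, pose))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # the X-shear adds s_y*y + s_z*z to x
  sh <- apply_pose(pts, id, shear = c(0.1, -0.2))
  expect_equal(sh[, 1], pts[, 1] + 0.1 * pts[, 2] - 0.2 * pts[, 3])
  expect_equal(sh[, 2:3], pts[, 2:3])
})

test_that("zero-noise cylinder run reconstructs the surface within 2x quantum", {
  scene <- cylinder_scene(x0 = 2.5, y0 = 1, radius = 0.05, height = 3)
  sensor <- sensor_config(scan_rate = 25, range_noise_sd = 0,
                          range_quantum = 0.001)
  traj <- trajectory_spec(speed = 0.25, x_end = 5, gnss_rate = 10,
                          gnss_noise_sd = 0)
  run <- simulate_scan(scene, sensor, traj, seed = 3)
  f <- tempfile(fileext = ".nmea")
  writeLines(generate_nmea(run$poses, 10, 0, seed = 4,
                           origin = c(40.1333, -3.3667, 750)), f)
  fixes <- read_nmea(f, origin = c(40.1333, -3.3667, 750))
  cloud <- georeference(run$scans, fixes, sensor)
  expect_gt(nrow(cloud), 100)
  # distance from each point to the cylinder surface
  derr <- abs(sqrt((cloud$x - 2.5)^2 + (cloud$y - 1)^2) - 0.05)
  expect_lt(max(derr), 2 * sensor$range_quantum)
  # consecutive frame x-offsets: 10 mm at 0.25 m/s, 25 Hz
  fx <- tapply(cloud$x, cloud$scan_index, mean)
  # cloud points inherit exact frame positions; mean inter-frame offset
  expect_equal(mean(diff(sort(unique(run$poses$x)))), 0.010,
               tolerance = 1e-6)

  # point count conservation: every valid beam of a retained frame lands
  kept_frames <- unique(cloud$scan_index)
  nvalid <- sum(run$scans$valid & run$scans$scan_index %in% kept_frames)
  expect_equal(nrow(cloud), nvalid)
})

test_that("frames outside fix coverage are dropped with a message", {
  scene <- cylinder_scene(x0 = 1, y0 = 1)
  sensor <- sensor_config(range_noise_sd = 0)
  traj <- trajectory_spec(speed = 0.5, x_end = 2, gnss_noise_sd = 0)
  run <- simulate_scan(scene, sensor, traj, seed = 5)
  f <- tempfile(fileext = ".nmea")
  writeLines(generate_nmea(run$poses, 10, 0, seed = 6), f)
  fixes <- read_nmea(f)
  short <- fixes[fixes$t <= 2, ]
  attr(short, "origin") <- attr(fixes, "origin")
  expect_message(cl <- georeference(run$scans, short, sensor), "dropped")
  expect_true(all(cl$scan_index %in%
                  run$scans$scan_index[run$scans$timestamp_s <= 2]))
  none <- fixes[fixes$t > 1e5, ]
  expect_error(suppressMessages(georeference(run$scans, fixes[0, ], sensor)))
})
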