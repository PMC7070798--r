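# Acquisition-rig emulation: a sideways-mounted 2D time-of-flight scanner on
# a slow electric platform plus an RTK-GNSS stream.  The scanner sweeps a
# plane perpendicular to the travel direction; the beam angle is zero along
# +Y (horizontal, toward the crop row) and positive toward +Z, so the
# vertical transect is symmetric about the horizontal.

#' 2D laser scanner configuration
#'
#' Defaults follow a general-purpose outdoor time-of-flight scanner: 270
#' degree field of view at 0.25 or 0.5 degree angular steps, 0.5-20 m
#' measurement window, 12 mm range noise (1 s.d.), +-30 mm systematic bound,
#' 25 or 50 Hz scan rate.  The device is mounted 1.20 m above ground,
#' travelling about 1 m from the crop row, facing sideways; a different
#' mounting attitude (e.g. facing downwards) can be expressed through
#' `mount_attitude`.
#'
#' @param fov field of view, degrees
#' @param angular_step angular resolution, degrees (0.25 or 0.5 typical)
#' @param scan_rate sweeps per second, Hz
#' @param range_min,range_max measurement window, m
#' @param range_noise_sd Gaussian range noise, m (1 s.d.)
#' @param systematic_error_bound single-shot accuracy bound, m (documentation
#'   only; the simulator draws zero-mean noise)
#' @param mount_height sensor height above the platform ground contact, m
#' @param lateral_standoff nominal distance from the travel line to the crop
#'   row, m (used by scene/trajectory defaults)
#' @param range_quantum range discretization of the device output, m
#' @param mount_attitude `c(roll, pitch, yaw)` of the sensor relative to the
#'   platform, radians
#' @return list of class `sensor_config`
#' @export
sensor_config <- function(fov = 270, angular_step = 0.5, scan_rate = 50,
                          range_min = 0.5, range_max = 20,
                          range_noise_sd = 0.012,
                          systematic_error_bound = 0.030,
                          mount_height = 1.2, lateral_standoff = 1.0,
                          range_quantum = 0.001,
                          mount_attitude = c(0, 0, 0)) {
  if (angular_step <= 0 || angular_step > fov)
    stop("angular_step must be in (0, fov]")
  if (range_min >= range_max) stop("range_min must be below range_max")
  if (range_noise_sd < 0) stop("range_noise_sd must be >= 0")
  if (scan_rate <= 0) stop("scan_rate must be positive")
  cfg <- as.list(environment())
  cfg$n_beams <- floor(fov / angular_step) + 1L
  cfg$angles <- -fov / 2 + (seq_len(cfg$n_beams) - 1L) * angular_step
  class(cfg) <- "sensor_config"
  cfg
}

#' Platform trajectory specification
#'
#' A nominally straight, constant-speed run parallel to the row (+X), with
#' optional smooth attitude perturbations and lateral wobble emulating an
#' uneven inter-row surface.  Speeds are kept below 0.83 m/s (3 km/h), the
#' regime in which a slow electric platform yields ~10 mm inter-slice
#' spacing at typical scan rates.
#'
#' @param speed platform speed, m/s (positive; direction comes from
#'   `x_start`/`x_end`)
#' @param x_start,x_end run extent along the row axis, m
#' @param y_offset lateral offset of the travel line, m
#' @param roll_amp,pitch_amp,yaw_amp attitude perturbation amplitudes, rad
#' @param wobble_amp lateral wobble amplitude, m
#' @param perturb_freq frequency of the sinusoidal perturbations, Hz
#' @param gnss_rate GNSS fix rate, Hz (10 or 20; must divide 100 so fix
#'   times survive the 2-decimal NMEA time field)
#' @param gnss_noise_sd GNSS position noise per axis, m (1 s.d.)
#' @return list of class `trajectory_spec`
#' @export
trajectory_spec <- function(speed = 0.25, x_start = 0, x_end = 10,
                            y_offset = 0, roll_amp = 0, pitch_amp = 0,
                            yaw_amp = 0, wobble_amp = 0, perturb_freq = 0.2,
                            gnss_rate = 10, gnss_noise_sd = 0.02) {
  if (speed <= 0) stop("speed must be positive")
  if (speed > 0.83)
    warning("speed above 0.83 m/s (3 km/h); slice spacing will be coarse")
  if (x_end == x_start) stop("x_start and x_end must differ")
  if (gnss_rate <= 0) stop("gnss_rate must be positive")
  spec <- as.list(environment())
  class(spec) <- "trajectory_spec"
  spec
}

#' Sample platform poses along a trajectory
#'
#' Poses are sampled at the scan rate: position advances at constant speed
#' from `x_start` to `x_end`; the seeded perturbations are smooth sinusoids
#' with random phase.  Deterministic for a fixed seed.
#'
#' @param traj a [trajectory_spec()]
#' @param scan_rate sampling rate, Hz (use the sensor's scan rate so one
#'   pose exists per sweep)
#' @param seed integer seed for the perturbation phases
#' @return data frame of class `platform_poses`: `t`, `x`, `y`, `z`,
#'   `roll`, `pitch`, `yaw` (radians, in (-pi, pi])
#' @export
simulate_trajectory <- function(traj, scan_rate = 50, seed = 1L) {
  stopifnot(inherits(traj, "trajectory_spec"))
  with_seed(seed, {
    len <- abs(traj$x_end - traj$x_start)
    dirx <- sign(traj$x_end - traj$x_start)
    t <- seq(0, len / traj$speed, by = 1 / scan_rate)
    ph <- runif(4, 0, 2 * pi)
    w <- 2 * pi * traj$perturb_freq
    poses <- data.frame(
      t = t,
      x = traj$x_start + dirx * traj$speed * t,
      y = traj$y_offset + traj$wobble_amp * sin(w * t + ph[1]),
      z = 0,
      roll = traj$roll_amp * sin(w * t + ph[2]),
      pitch = traj$pitch_amp * sin(w * t + ph[3]),
      yaw = (if (dirx > 0) 0 else pi) + traj$yaw_amp * sin(w * t + ph[4]))
    class(poses) <- c("platform_poses", "data.frame")
    poses
  })
}

# rotation matrix R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)
.rot_zyx <- function(roll, pitch, yaw) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  matrix(c(cy * cp, cy * sp * sr - sy * cr, cy * sp * cr + sy * sr,
           sy * cp, sy * sp * sr + cy * cr, sy * sp * cr - cy * sr,
           -sp,     cp * sr,                cp * cr),
         3, 3, byrow = TRUE)
}

#' Cast a single beam into the scene
#'
#' Returns the smallest positive ray-primitive intersection distance over
#' all scene frusta, spheres and the ground plane, or `Inf` when nothing is
#' hit.  No measurement window or noise is applied here.
#'
#' @param origin,direction beam origin and unit direction (length-3)
#' @param scene a `vine_scene`
#' @param sensor optional [sensor_config()]; when given, hits outside the
#'   sensor's measurement window count as no-return
#' @return range in m (`Inf` = no return)
#' @export
cast_beam <- function(origin, direction, scene, sensor = NULL) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  pr <- .scene_prims(scene)
  r <- .cast_rays_cpp(matrix(origin, 1), matrix(direction, 1),
                      pr$type, pr$par, isTRUE(scene$ground), 0, Inf)[1, 1]
  if (!is.null(sensor) &&
      (r < sensor$range_min || r > sensor$range_max)) r <- Inf
  r
}

# beam origins/directions for a set of poses (vectorized)
.beam_geometry <- function(poses, sensor) {
  th <- sensor$angles * pi / 180
  nb <- sensor$n_beams
  np <- nrow(poses)
  d_local <- cbind(0, cos(th), sin(th))                # sensor frame
  Rm <- .rot_zyx(sensor$mount_attitude[1], sensor$mount_attitude[2],
                 sensor$mount_attitude[3])
  d_mount <- d_local %*% t(Rm)
  origins <- matrix(0, np * nb, 3)
  dirs <- matrix(0, np * nb, 3)
  off <- c(0, 0, sensor$mount_height)
  for (i in seq_len(np)) {
    Rp <- .rot_zyx(poses$roll[i], poses$pitch[i], poses$yaw[i])
    rows <- ((i - 1) * nb + 1):(i * nb)
    o <- c(poses$x[i], poses$y[i], poses$z[i]) + as.vector(Rp %*% off)
    origins[rows, ] <- matrix(o, nb, 3, byrow = TRUE)
    dirs[rows, ] <- d_mount %*% t(Rp)
  }
  list(origins = origins, dirs = dirs)
}

#' Simulate a full scan run over a scene
#'
#' One sweep per pose: each beam's true geometric range is perturbed by
#' Gaussian noise, quantized to the device's range quantum and clipped to
#' the measurement window (out-of-window and missed beams are flagged
#' invalid).  Deterministic for fixed seed.
#'
#' @param scene a `vine_scene`
#' @param sensor a [sensor_config()]
#' @param poses a `platform_poses` data frame (or a [trajectory_spec()],
#'   which is sampled at the sensor scan rate first)
#' @param seed integer seed (trajectory perturbations use `seed`, range
#'   noise uses `seed + 1`)
#' @param keep_labels keep the index/tag of the primitive hit by each beam
#'   (ground truth, available only in simulation)
#' @return list of class `scan_run`: `scans` (a `scan_set`), `poses`, and
#'   (optionally) `labels` — per-beam tag of the primitive hit
#' @export
simulate_scan <- function(scene, sensor = sensor_config(),
                          poses = trajectory_spec(),
                          seed = 1L, keep_labels = TRUE) {
  stopifnot(inherits(scene, "vine_scene"), inherits(sensor, "sensor_config"))
  if (inherits(poses, "trajectory_spec"))
    poses <- simulate_trajectory(poses, sensor$scan_rate, seed)
  nb <- sensor$n_beams
  np <- nrow(poses)
  g <- .beam_geometry(poses, sensor)
  pr <- .scene_prims(scene)
  hit <- .cast_rays_cpp(g$origins, g$dirs, pr$type, pr$par,
                        isTRUE(scene$ground), 0,
                        sensor$range_max + 4 * sensor$range_noise_sd + 0.1)
  rng <- hit[, 1]
  with_seed(seed + 1L, {
    noisy <- rng + rnorm(length(rng), 0, sensor$range_noise_sd)
  })
  if (sensor$range_quantum > 0)
    noisy <- round(noisy / sensor$range_quantum) * sensor$range_quantum
  valid <- is.finite(noisy) & noisy >= sensor$range_min &
           noisy <= sensor$range_max
  noisy[!is.finite(noisy)] <- NA_real_
  scans <- .as_scan_set(data.frame(
    scan_index = rep(seq_len(np), each = nb),
    timestamp_s = rep(poses$t, each = nb),
    angle_deg = rep(sensor$angles, np),
    range_m = noisy,
    valid = valid))
  run <- list(scans = scans, poses = poses, sensor = sensor)
  if (keep_labels) {
    tags <- c("ground", scene$segments$tag)
    run$labels <- tags[hit[, 2] + 1L]        # hit index 0 = ground
  }
  class(run) <- "scan_run"
  run
}

#' Generate an NMEA 0183 GGA stream for a pose sequence
#'
#' Positions are linearly interpolated at the GNSS rate, perturbed with
#' seeded Gaussian noise per axis, converted from the local frame to
#' latitude/longitude around `origin` with the same tangent-plane
#' approximation used by [read_nmea()], and emitted as checksummed GGA
#' sentences (quality 4, RTK fixed).  Fix times are seconds of day
#' `utc_start + t` written with two decimals, so rates that divide 100 Hz
#' round-trip exactly.
#'
#' @param poses a `platform_poses` data frame
#' @param gnss_rate fix rate, Hz
#' @param noise_sd per-axis position noise, m
#' @param seed integer seed
#' @param origin `c(lat, lon, alt)` of the local frame origin
#' @param utc_start fix time of `t = 0`, seconds of day
#' @return character vector of GGA sentences (one per fix)
#' @export
generate_nmea <- function(poses, gnss_rate = 10, noise_sd = 0.02, seed = 1L,
                          origin = c(40.1333, -3.3667, 750),
                          utc_start = 0) {
  stopifnot(is.data.frame(poses), nrow(poses) >= 2)
  if (any(diff(poses$t) <= 0)) stop("pose timestamps must be increasing")
  t <- seq(0, max(poses$t), by = 1 / gnss_rate)
  ex <- approx(poses$t, poses$x, t)$y
  ny <- approx(poses$t, poses$y, t)$y
  uz <- approx(poses$t, poses$z, t)$y
  with_seed(seed, {
    ex <- ex + rnorm(length(t), 0, noise_sd)
    ny <- ny + rnorm(length(t), 0, noise_sd)
    uz <- uz + rnorm(length(t), 0, noise_sd)
  })
  lat <- origin[1] + (ny / .R_EARTH) * 180 / pi
  lon <- origin[2] + (ex / (.R_EARTH * cos(origin[1] * pi / 180))) * 180 / pi
  alt <- origin[3] + uz
  tod <- utc_start + t
  hh <- floor(tod / 3600); mm <- floor((tod - hh * 3600) / 60)
  ss <- tod - hh * 3600 - mm * 60
  latdm <- .deg_to_dm(lat); londm <- .deg_to_dm(lon)
  body <- sprintf("GPGGA,%02d%02d%05.2f,%02d%010.7f,%s,%03d%010.7f,%s,4,12,0.6,%.3f,M,0.0,M,,",
                  hh, mm, ss,
                  latdm$d, latdm$m, ifelse(lat >= 0, "N", "S"),
                  londm$d, londm$m, ifelse(lon >= 0, "E", "W"),
                  alt)
  cs <- vapply(body, .nmea_checksum, character(1), USE.NAMES = FALSE)
  paste0("$", body, "*", cs)
}
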