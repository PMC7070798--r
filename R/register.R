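# Registration: raw 2D polar scans + GNSS fixes -> one georeferenced 3D
# point cloud.  The GNSS stream acts as the travel-axis encoder: each scan
# frame gets a pose interpolated at its timestamp, the polar beams are
# converted to Cartesian coordinates in the sensor plane, and the pose's
# 3D affine transform (plus an optional X-shear) places them in the local
# frame.

#' Convert a polar beam to sensor-plane Cartesian coordinates
#'
#' The sensor plane is perpendicular to travel: `y = r cos(theta)` (crop
#' depth), `z = mount_height + r sin(theta)` (up), with `theta = 0`
#' horizontal toward the row.
#'
#' @param range range(s), m
#' @param angle beam angle(s), degrees
#' @param sensor a [sensor_config()] (supplies the mount height)
#' @return matrix with columns `y`, `z`
#' @export
polar_to_plane <- function(range, angle, sensor = sensor_config()) {
  th <- angle * pi / 180
  cbind(y = range * cos(th), z = sensor$mount_height + range * sin(th))
}

#' Interpolate a platform pose at time t from GNSS fixes
#'
#' Positions are interpolated linearly between the bracketing fixes; yaw is
#' the local travel direction, estimated over a `yaw_window`-second baseline
#' centered on `t` (the platform holds a steady straight course, so a
#' longer baseline filters the centimeter fix noise that would otherwise
#' turn into tens of degrees of heading error between consecutive fixes);
#' roll and pitch come from `attitude` (default zero: no inertial unit in
#' the rig).  No extrapolation: `t` outside the fix time range is an error.
#'
#' @param fixes a data frame with `t`, `east`/`x`, `north`/`y`, `up`/`z`
#'   (as from [read_nmea()], already rotated so +X is the row direction, or
#'   any `platform_poses`-like table)
#' @param t time(s), s (same clock as the fixes)
#' @param attitude `c(roll, pitch)` radians applied to every pose
#' @param yaw_window baseline for the travel-direction estimate, s
#' @param smooth_window centered moving-average window applied to the fix
#'   positions before interpolation, s.  The platform advances at constant
#'   speed, so the average is exact for the nominal trajectory while
#'   attenuating the centimeter white noise of individual RTK fixes
#'   (partial windows shrink symmetrically at the run edges, which keeps a
#'   linear trajectory exact there too).  Set to 0 to use raw fixes.
#' @return data frame `t`, `x`, `y`, `z`, `roll`, `pitch`, `yaw`
#' @export
interpolate_pose <- function(fixes, t, attitude = c(0, 0), yaw_window = 1,
                             smooth_window = 0.5) {
  fx <- if ("east" %in% names(fixes))
    data.frame(t = fixes$t, x = fixes$east, y = fixes$north, z = fixes$up)
  else data.frame(t = fixes$t, x = fixes$x, y = fixes$y, z = fixes$z)
  if (any(diff(fx$t) <= 0)) stop("fix timestamps must be strictly increasing")
  if (smooth_window > 0 && nrow(fx) > 2) {
    k <- round(smooth_window / median(diff(fx$t)))
    fx$x <- .smooth_series(fx$x, k)
    fx$y <- .smooth_series(fx$y, k)
    fx$z <- .smooth_series(fx$z, k)
  }
  tmin <- fx$t[1]; tmax <- fx$t[nrow(fx)]
  if (any(t < tmin - 1e-9 | t > tmax + 1e-9))
    stop("t outside the fix time range (no extrapolation)")
  x <- approx(fx$t, fx$x, t, rule = 2)$y
  y <- approx(fx$t, fx$y, t, rule = 2)$y
  z <- approx(fx$t, fx$z, t, rule = 2)$y
  # travel direction over a window (clamped to coverage, never degenerate)
  w <- max(yaw_window, diff(range(fx$t)) / max(nrow(fx) - 1, 1))
  t0 <- pmax(t - w / 2, tmin); t1 <- pmin(t + w / 2, tmax)
  short <- (t1 - t0) < w / 2
  t0[short] <- pmax(t1[short] - w / 2, tmin)
  t1[short] <- pmin(t0[short] + w / 2, tmax)
  yaw <- atan2(approx(fx$t, fx$y, t1, rule = 2)$y -
                 approx(fx$t, fx$y, t0, rule = 2)$y,
               approx(fx$t, fx$x, t1, rule = 2)$y -
                 approx(fx$t, fx$x, t0, rule = 2)$y)
  data.frame(t = t, x = x, y = y, z = z,
             roll = attitude[1], pitch = attitude[2], yaw = yaw)
}

# centered running mean over 2*floor(k/2)+1 samples, with symmetrically
# shrinking windows at the edges (exact for linear series everywhere)
.smooth_series <- function(v, k) {
  half <- k %/% 2
  if (half < 1) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  w <- pmin(half, i - 1, n - i)
  (cs[i + w + 1] - cs[i - w]) / (2 * w + 1)
}

#' Apply a platform pose (3D affine transform + optional X-shear)
#'
#' `p_world = R(yaw, pitch, roll) p_sensor + position`, rotation order
#' intrinsic Z (yaw), Y (pitch), X (roll), followed by the configurable
#' shear along the travel axis: `x <- x + s_y y + s_z z`.  The shear
#' defaults to identity.
#'
#' @param pts n x 3 matrix of sensor-frame points
#' @param pose one-row pose (`x`, `y`, `z`, `roll`, `pitch`, `yaw`)
#' @param shear `c(s_y, s_z)`
#' @return n x 3 matrix in the local frame
#' @export
apply_pose <- function(pts, pose, shear = c(0, 0)) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  R <- .rot_zyx(pose$roll, pose$pitch, pose$yaw)
  out <- pts %*% t(R)
  out[, 1] <- out[, 1] + pose$x
  out[, 2] <- out[, 2] + pose$y
  out[, 3] <- out[, 3] + pose$z
  if (any(shear != 0))
    out[, 1] <- out[, 1] + shear[1] * out[, 2] + shear[2] * out[, 3]
  out
}

#' Georeference a scan set against a GNSS fix stream
#'
#' For every frame whose timestamp is covered by the fixes: drop invalid
#' beams, convert the remaining polar beams to the sensor plane, and apply
#' the pose interpolated at the frame time.  Frames outside fix coverage
#' are dropped with a message (mirroring acquisition scan loss at run
#' edges).
#'
#' @param scans a `scan_set`
#' @param fixes fixes accepted by [interpolate_pose()]
#' @param sensor a [sensor_config()]
#' @param shear `c(s_y, s_z)` passed to [apply_pose()]
#' @param attitude `c(roll, pitch)` passed to [interpolate_pose()]
#' @return a [point_cloud()] with per-point `scan_index` and `beam_index`
#' @export
georeference <- function(scans, fixes, sensor = sensor_config(),
                         shear = c(0, 0), attitude = c(0, 0)) {
  stopifnot(inherits(scans, "scan_set"))
  ft <- fixes$t
  frames <- unique(scans$scan_index)
  ftimes <- scans$timestamp_s[match(frames, scans$scan_index)]
  keep <- ftimes >= ft[1] & ftimes <= ft[length(ft)]
  if (!all(keep))
    message(sprintf("georeference: dropped %d/%d frames outside fix coverage",
                    sum(!keep), length(frames)))
  frames <- frames[keep]
  if (!length(frames)) stop("no scan frames covered by the GNSS fixes")
  poses <- interpolate_pose(fixes, ftimes[keep], attitude)

  Rm <- .rot_zyx(sensor$mount_attitude[1], sensor$mount_attitude[2],
                 sensor$mount_attitude[3])
  use <- scans$valid & scans$scan_index %in% frames
  sub <- scans[use, ]
  th <- sub$angle_deg * pi / 180
  p_sensor <- cbind(0, sub$range_m * cos(th), sub$range_m * sin(th)) %*% t(Rm)
  p_sensor[, 3] <- p_sensor[, 3] + sensor$mount_height
  # vectorized pose application: per-point angles recycled from the frames
  fidx <- match(sub$scan_index, frames)
  cr <- cos(poses$roll[fidx]); sr <- sin(poses$roll[fidx])
  cp <- cos(poses$pitch[fidx]); sp <- sin(poses$pitch[fidx])
  cy <- cos(poses$yaw[fidx]); sy <- sin(poses$yaw[fidx])
  px <- p_sensor[, 1]; py <- p_sensor[, 2]; pz <- p_sensor[, 3]
  out <- cbind(
    (cy * cp) * px + (cy * sp * sr - sy * cr) * py +
      (cy * sp * cr + sy * sr) * pz + poses$x[fidx],
    (sy * cp) * px + (sy * sp * sr + cy * cr) * py +
      (sy * sp * cr - cy * sr) * pz + poses$y[fidx],
    (-sp) * px + (cp * sr) * py + (cp * cr) * pz + poses$z[fidx])
  if (any(shear != 0))
    out[, 1] <- out[, 1] + shear[1] * out[, 2] + shear[2] * out[, 3]
  beam <- ave(seq_len(nrow(scans)), scans$scan_index, FUN = seq_along)[use]
  point_cloud(out[, 1], out[, 2], out[, 3],
              scan_index = sub$scan_index, beam_index = beam)
}
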