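# shared fixtures, all built in code

# a minimal hand-made scene: one vertical cylinder ("trunk") at (x0, y0),
# no ground plane unless asked — used by simulator and registration tests
cylinder_scene <- function(x0 = 5, y0 = 1, radius = 0.05, height = 3,
                           ground = FALSE, row_length = 10) {
  segments <- data.frame(x0 = x0, y0 = y0, z0 = 0, x1 = x0, y1 = y0,
                         z1 = height, r0 = radius, r1 = radius,
                         tag = "trunk", batch = 1L,
                         stringsAsFactors = FALSE)
  scene <- list(segments = segments,
                batches = data.frame(treatment = "S1", plot = 1L,
                                     xmin = 0, xmax = row_length),
                wood_density = 450, ground = ground,
                row_length = row_length,
                spec = NULL, seed = 0L)
  class(scene) <- "vine_scene"
  scene
}

# small random cloud helper
random_cloud <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  point_cloud(runif(n, 0, scale), runif(n, 0, scale), runif(n, 0, scale),
              scan_index = seq_len(n), beam_index = 1L)
}

# O(N^2) brute-force SOR oracle: mean distance to k nearest neighbors,
# threshold mean + nsigma * sd
sor_oracle <- function(cloud, k, nsigma = 1) {
  P <- as.matrix(cloud[, c("x", "y", "z")])
  n <- nrow(P)
  k <- min(k, n - 1)
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  d <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
  thr <- mean(d) + nsigma * sd(d)
  list(d = d, removed = which(d > thr), threshold = thr)
}

# a compact scanned vine batch shared by slower tests (built lazily once)
.small_batch_env <- new.env()
small_scanned_batch <- function() {
  if (!is.null(.small_batch_env$res)) return(.small_batch_env$res)
  scene <- build_scene(scene_spec(treatments = 1, plots_per_treatment = 1,
                                  vines_per_plot = 3, shoots_per_vine = 10),
                       seed = 11)
  sensor <- sensor_config()
  traj <- trajectory_spec(speed = 0.5, x_end = scene$row_length,
                          gnss_rate = 10)
  run <- simulate_scan(scene, sensor, traj, seed = 12)
  nmea <- generate_nmea(run$poses, 10, 0.02, seed = 13)
  f <- tempfile(fileext = ".nmea")
  writeLines(nmea, f)
  fixes <- read_nmea(f, origin = c(40.1333, -3.3667, 750))
  cloud <- georeference(run$scans, fixes, sensor)
  .small_batch_env$res <- list(scene = scene, sensor = sensor, run = run,
                               fixes = fixes, cloud = cloud)
  .small_batch_env$res
}

# simulate + write NMEA + register, in one go (one pass)
georeferenced_run <- function(scene, sensor, traj, seed,
                              origin = c(40.1333, -3.3667, 750),
                              gnss_noise_sd = traj$gnss_noise_sd) {
  run <- simulate_scan(scene, sensor, traj, seed = seed, keep_labels = FALSE)
  f <- tempfile(fileext = ".nmea")
  writeLines(generate_nmea(run$poses, traj$gnss_rate, gnss_noise_sd,
                           seed = seed + 1, origin = origin), f)
  fixes <- read_nmea(f, origin = origin)
  georeference(run$scans, fixes, sensor)
}
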