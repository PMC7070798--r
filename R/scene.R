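# Parametric synthetic vineyard scenes with analytically known shoot volume
# and dry biomass.  A scene is a set of tapered-cylinder segments (shoots,
# trunks, cordons, posts, wires) plus marker spheres, organised into
# treatment/plot batches along the row axis (X).

#' Default scene specification for a synthetic defoliated vineyard
#'
#' Describes a cordon-trained, spur-pruned vine row in its winter state:
#' one-year canes (shoots) thinner than 1 cm diameter rise from spur
#' positions spread along a horizontal cordon, supported by a vertical
#' trellis (posts and thin horizontal wires).  The row is divided into
#' batches (one per plot), each holding `vines_per_plot` vines, with a post
#' and a spherical marker at every batch boundary.
#'
#' All lengths are in meters, densities in kg/m3, angles in degrees.
#'
#' @param treatments number of treatments (default 5)
#' @param plots_per_treatment plots (= batches) per treatment (default 3)
#' @param vines_per_plot vines per plot (default 10)
#' @param treatment_labels optional character vector of treatment labels
#' @param vine_spacing in-row distance between vine trunks
#' @param plot_gap gap between consecutive batches along the row
#' @param row_y lateral offset of the row axis from the platform travel line
#' @param cordon_height height of the horizontal cordon
#' @param cordon_span fraction of `vine_spacing` covered by each cordon
#' @param cordon_radius,trunk_radius radii of cordon and trunk segments
#' @param shoots_per_vine mean number of canes per vine
#' @param shoot_length_mean,shoot_length_sd cane length distribution
#' @param shoot_base_radius_mean,shoot_base_radius_sd cane base radius
#'   distribution; radii are truncated at `shoot_radius_max` (0.005 m, i.e.
#'   diameters below 1 cm)
#' @param shoot_radius_max maximum shoot radius
#' @param shoot_tip_taper tip radius as a fraction of the base radius
#' @param shoot_tilt_sd s.d. of the cane tilt from vertical, degrees
#' @param shoot_plane_sd s.d. of the cane azimuth around the trellis plane,
#'   degrees: catch wires hold the canes close to the row plane, so tilt is
#'   mostly along the row (large values recover isotropic azimuth)
#' @param shoot_segments_range canes are chains of 2-4 frustum segments
#' @param treatment_vigor multiplier on shoot count and length per treatment
#'   (default evenly spaced on 0.7..1.3, so batch biomass varies)
#' @param post_radius,post_height,marker_radius trellis post and marker size
#' @param wire_heights,wire_radius heights and radius of horizontal wires
#'   (wires are flagged negligible and never counted in the volume truth)
#' @param wood_density dry wood density used to convert true shoot volume to
#'   dry biomass (a configuration default, 450 kg/m3)
#' @param ground logical; include a ground plane at z = 0 when ray casting
#' @return a list of class `scene_spec`
#' @export
scene_spec <- function(treatments = 5,
                       plots_per_treatment = 3,
                       vines_per_plot = 10,
                       treatment_labels = NULL,
                       vine_spacing = 1.0,
                       plot_gap = 0.6,
                       row_y = 1.0,
                       cordon_height = 1.0,
                       cordon_span = 0.95,
                       cordon_radius = 0.015,
                       trunk_radius = 0.025,
                       shoots_per_vine = 18,
                       shoot_length_mean = 1.2,
                       shoot_length_sd = 0.2,
                       shoot_base_radius_mean = 0.004,
                       shoot_base_radius_sd = 0.0005,
                       shoot_radius_max = 0.005,
                       shoot_tip_taper = 0.4,
                       shoot_tilt_sd = 8,
                       shoot_plane_sd = 15,
                       shoot_segments_range = c(2L, 4L),
                       treatment_vigor = NULL,
                       post_radius = 0.04,
                       post_height = 1.8,
                       marker_radius = 0.04,
                       wire_heights = c(1.4, 1.8),
                       wire_radius = 0.0015,
                       wood_density = 450,
                       ground = TRUE) {
  if (treatments < 1 || plots_per_treatment < 1 || vines_per_plot < 1)
    stop("treatments, plots_per_treatment and vines_per_plot must be positive")
  if (vine_spacing <= 0 || plot_gap < 0)
    stop("vine_spacing must be positive and plot_gap non-negative")
  if (shoot_radius_max > 0.005 + 1e-12)
    warning("shoot_radius_max above 0.005 m; default canes are < 1 cm diameter")
  if (is.null(treatment_labels))
    treatment_labels <- paste0("S", seq_len(treatments))
  if (length(treatment_labels) != treatments)
    stop("treatment_labels must have length `treatments`")
  if (is.null(treatment_vigor)) {
    treatment_vigor <- if (treatments == 1) 1
                       else seq(0.7, 1.3, length.out = treatments)
  }
  spec <- as.list(environment())
  class(spec) <- "scene_spec"
  spec
}

#' Volume of a conical frustum (tapered cylinder) segment
#'
#' @param segment a data frame with columns `x0,y0,z0,x1,y1,z1,r0,r1` (one
#'   row per segment), as stored in a scene's `segments` table
#' @return volume(s) in m3, `pi*h/3*(r0^2 + r0*r1 + r1^2)`
#' @export
frustum_volume <- function(segment) {
  h <- sqrt((segment$x1 - segment$x0)^2 +
            (segment$y1 - segment$y0)^2 +
            (segment$z1 - segment$z0)^2)
  if (any(h <= 0))
    stop("zero-length segment")
  if (any(segment$r0 <= 0 | segment$r1 <= 0))
    stop("segment radii must be positive")
  pi * h / 3 * (segment$r0^2 + segment$r0 * segment$r1 + segment$r1^2)
}

# one cane: a chain of frustum segments rising from (x, y, z0)
.grow_cane <- function(x, y, z0, len, r_base, r_tip, tilt_sd, plane_sd, nseg,
                       xmin, xmax) {
  seg_len <- len / nseg
  radii <- seq(r_base, r_tip, length.out = nseg + 1)
  for (attempt in 1:3) {
    theta <- abs(rnorm(1, 0, tilt_sd * pi / 180))
    # azimuth biased into the trellis plane (+x or -x along the row)
    phi <- sample(c(0, pi), 1) + rnorm(1, 0, plane_sd * pi / 180)
    dirs <- matrix(0, nseg, 3)
    for (s in seq_len(nseg)) {
      dirs[s, ] <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      theta <- abs(theta + rnorm(1, 0, tilt_sd / 2 * pi / 180))
      phi <- phi + rnorm(1, 0, 20 * pi / 180)
    }
    if (attempt == 2) dirs[, 1] <- -dirs[, 1]       # reflect inward
    if (attempt == 3) {                             # last resort: vertical in x
      dirs[, 1] <- 0
      dirs <- dirs / sqrt(rowSums(dirs^2))
    }
    cs <- apply(dirs * seg_len, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    pts <- rbind(c(x, y, z0),
                 matrix(c(x, y, z0), nseg, 3, byrow = TRUE) + cs)
    if (all(pts[, 1] >= xmin) && all(pts[, 1] < xmax)) break
  }
  data.frame(x0 = pts[-nrow(pts), 1], y0 = pts[-nrow(pts), 2],
             z0 = pts[-nrow(pts), 3],
             x1 = pts[-1, 1], y1 = pts[-1, 2], z1 = pts[-1, 3],
             r0 = radii[-length(radii)], r1 = radii[-1])
}

#' Build a synthetic vineyard scene
#'
#' Lays the plots of all treatments out as consecutive batches along a single
#' row (X axis), grows the vines, and places the training structures.  The
#' result is deterministic for a fixed seed.
#'
#' @param spec a [scene_spec()]
#' @param seed integer seed driving all scene randomness
#' @return an object of class `vine_scene`: a list with `segments` (data
#'   frame, one primitive per row: endpoints, radii, `tag`, `batch`),
#'   `batches` (treatment, plot, x-interval), `wood_density`, `ground`,
#'   `spec` and `seed`.  Marker spheres are stored as zero-length segments
#'   with `tag = "marker"`.
#' @export
build_scene <- function(spec = scene_spec(), seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    n_batches <- spec$treatments * spec$plots_per_treatment
    batch_w <- spec$vines_per_plot * spec$vine_spacing
    xmin <- spec$plot_gap + (seq_len(n_batches) - 1) * (batch_w + spec$plot_gap)
    batches <- data.frame(
      treatment = rep(spec$treatment_labels, each = spec$plots_per_treatment),
      plot = rep(seq_len(spec$plots_per_treatment), spec$treatments),
      xmin = xmin, xmax = xmin + batch_w,
      stringsAsFactors = FALSE)
    row_end <- batches$xmax[n_batches] + spec$plot_gap

    segs <- list()
    add <- function(df, tag, batch = NA_integer_) {
      df$tag <- tag
      df$batch <- batch
      segs[[length(segs) + 1L]] <<- df
    }

    y <- spec$row_y
    for (b in seq_len(n_batches)) {
      vig <- spec$treatment_vigor[(b - 1) %/% spec$plots_per_treatment + 1]
      vx <- batches$xmin[b] + (seq_len(spec$vines_per_plot) - 0.5) *
            spec$vine_spacing
      for (v in vx) {
        add(data.frame(x0 = v, y0 = y, z0 = 0, x1 = v, y1 = y,
                       z1 = spec$cordon_height,
                       r0 = spec$trunk_radius, r1 = spec$trunk_radius),
            "trunk", b)
        half <- spec$cordon_span * spec$vine_spacing / 2
        add(data.frame(x0 = v - half, y0 = y, z0 = spec$cordon_height,
                       x1 = v + half, y1 = y, z1 = spec$cordon_height,
                       r0 = spec$cordon_radius, r1 = spec$cordon_radius),
            "cordon", b)
        n_shoots <- max(0L, round(spec$shoots_per_vine * vig *
                                  runif(1, 0.8, 1.2)))
        if (n_shoots > 0) {
          spur_x <- v + seq(-half, half, length.out = max(n_shoots, 2))[
                      seq_len(n_shoots)] + rnorm(n_shoots, 0, 0.01)
          # spurs stay clear of the boundary posts and their masks
          spur_x <- pmin(pmax(spur_x, batches$xmin[b] + 0.18),
                         batches$xmax[b] - 0.18)
          for (sx in spur_x) {
            len <- max(0.3, rnorm(1, spec$shoot_length_mean * vig,
                                  spec$shoot_length_sd))
            rb <- min(spec$shoot_radius_max,
                      max(0.002, rnorm(1, spec$shoot_base_radius_mean,
                                       spec$shoot_base_radius_sd)))
            nseg <- sample(spec$shoot_segments_range[1]:
                           spec$shoot_segments_range[2], 1)
            # canes stay 0.1 m clear of the batch-boundary posts so that
            # the post masks never swallow shoot points
            cane <- .grow_cane(sx, y, spec$cordon_height + spec$cordon_radius,
                               len, rb, rb * spec$shoot_tip_taper,
                               spec$shoot_tilt_sd, spec$shoot_plane_sd, nseg,
                               batches$xmin[b] + 0.15, batches$xmax[b] - 0.15)
            add(cane, "shoot", b)
          }
        }
      }
    }

    # posts (with markers on top) stand exactly on the batch boundaries, so
    # each half-open batch interval contains its own start post
    post_x <- unique(c(batches$xmin, batches$xmax))
    for (px in post_x) {
      add(data.frame(x0 = px, y0 = y, z0 = 0, x1 = px, y1 = y,
                     z1 = spec$post_height,
                     r0 = spec$post_radius, r1 = spec$post_radius),
          "post")
      # marker sphere on top of the post (zero-length segment, r0 = radius)
      mz <- spec$post_height + spec$marker_radius
      add(data.frame(x0 = px, y0 = y, z0 = mz, x1 = px, y1 = y, z1 = mz,
                     r0 = spec$marker_radius, r1 = spec$marker_radius),
          "marker")
    }
    for (wz in spec$wire_heights)
      add(data.frame(x0 = 0, y0 = y, z0 = wz, x1 = row_end, y1 = y, z1 = wz,
                     r0 = spec$wire_radius, r1 = spec$wire_radius),
          "wire")

    segments <- do.call(rbind, segs)
    rownames(segments) <- NULL
    scene <- list(segments = segments, batches = batches,
                  wood_density = spec$wood_density, ground = spec$ground,
                  row_length = row_end, spec = spec, seed = seed)
    class(scene) <- "vine_scene"
    scene
  })
}

#' @export
print.vine_scene <- function(x, ...) {
  cat("Synthetic vineyard scene\n")
  cat(sprintf("  %d segments (%s)\n", nrow(x$segments),
              paste(sprintf("%s: %d", names(table(x$segments$tag)),
                            table(x$segments$tag)), collapse = ", ")))
  cat(sprintf("  %d batches over %.1f m of row; wood density %g kg/m3\n",
              nrow(x$batches), x$row_length, x$wood_density))
  invisible(x)
}

#' Analytic per-batch ground truth
#'
#' Sums the frustum volumes of every shoot segment in each batch and converts
#' to dry biomass with the scene's wood density.  Wires, posts, trunks,
#' cordons and markers are never counted: the truth covers the prunable
#' one-year canes only, mirroring what is weighed after pruning.
#'
#' @param scene a [build_scene()] result
#' @return data frame with `treatment`, `plot`, `true_shoot_volume` (m3) and
#'   `true_biomass` (kg)
#' @export
batch_truth <- function(scene) {
  stopifnot(inherits(scene, "vine_scene"))
  sh <- scene$segments[scene$segments$tag == "shoot", ]
  vol <- if (nrow(sh)) frustum_volume(sh) else numeric(0)
  out <- scene$batches[, c("treatment", "plot")]
  out$true_shoot_volume <- vapply(seq_len(nrow(out)), function(b)
    sum(vol[sh$batch == b]), numeric(1))
  out$true_biomass <- scene$wood_density * out$true_shoot_volume
  out
}

#' Cylindrical/spherical masks around the training structures
#'
#' Builds the masks used by [mask_training_structures()] from the known
#' geometry of a synthetic scene: a capsule of radius `radius + margin`
#' around each post axis and a sphere around each marker.  Horizontal wires
#' are not masked by default — their volume contribution is negligible and
#' a capsule around a wire would cut a slab out of the canes that cross it.
#'
#' @param scene a `vine_scene`
#' @param margin extra radius (m) so that range noise around a structure is
#'   captured
#' @param tags which structure tags to mask
#' @return data frame of masks (`type`, endpoints, `radius`)
#' @export
structure_masks <- function(scene, margin = 0.08,
                            tags = c("post", "marker")) {
  st <- scene$segments[scene$segments$tag %in% tags, ]
  if (!nrow(st))
    return(data.frame(type = character(0), x0 = numeric(0), y0 = numeric(0),
                      z0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      z1 = numeric(0), radius = numeric(0)))
  data.frame(type = ifelse(st$tag == "marker", "sphere", "capsule"),
             x0 = st$x0, y0 = st$y0, z0 = st$z0,
             x1 = st$x1, y1 = st$y1, z1 = st$z1,
             radius = pmax(st$r0, st$r1) + margin,
             stringsAsFactors = FALSE)
}

# internal: scene primitives in the layout expected by the C++ ray caster
.scene_prims <- function(scene) {
  s <- scene$segments
  type <- ifelse(s$tag == "marker", 1L, 0L)
  par <- cbind(s$x0, s$y0, s$z0, s$x1, s$y1, s$z1, s$r0, s$r1)
  list(type = type, par = par)
}
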