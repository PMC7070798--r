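# Cloud filtering: reduce a georeferenced cloud to vine-shoot points only.
# Pipeline default order: crop to the batch x-interval, cut below the bud
# height, split out training structures, then statistical outlier removal.

#' Crop a cloud to a batch x-interval
#'
#' Keeps points with `x` in the half-open interval `[x0, x1)`; half-open so
#' adjacent batches never double-count a point.
#'
#' @param cloud a [point_cloud()]
#' @param x_interval `c(x0, x1)`
#' @return the cropped `point_cloud`
#' @export
crop_batch <- function(cloud, x_interval) {
  stopifnot(inherits(cloud, "point_cloud"), length(x_interval) == 2)
  if (!(x_interval[2] > x_interval[1])) stop("empty x-interval")
  .as_cloud(cloud[cloud$x >= x_interval[1] & cloud$x < x_interval[2], ])
}

#' Remove points below the bud height
#'
#' Drops stump, cordon and soil returns by keeping only points with
#' `z >= z0` — the cross-section cut at the average bud height.  Ties at
#' `z0` are kept (deterministic).
#'
#' @param cloud a [point_cloud()]
#' @param z0 bud-height cut, m
#' @export
cut_below_height <- function(cloud, z0) {
  stopifnot(inherits(cloud, "point_cloud"), is.finite(z0))
  .as_cloud(cloud[cloud$z >= z0, ])
}

#' Statistical outlier removal (SOR)
#'
#' For each point, computes the mean Euclidean distance `d_i` to its `k`
#' nearest neighbors; points with `d_i > mean(d) + nsigma * sd(d)` are
#' removed in a single pass.  This is the conventional mean-plus-sigma rule
#' of point-cloud toolboxes; `rule = "sigma_only"` instead removes points
#' with `d_i > sd(d)` (a stricter, literal reading of the neighbor-distance
#' criterion).
#'
#' @param cloud a [point_cloud()] with at least 2 points
#' @param k neighbor count (clamped to n-1 for small clouds, with a message)
#' @param nsigma threshold multiplier (> 0)
#' @param rule `"mean_plus_sigma"` (default) or `"sigma_only"`
#' @return list with `kept` and `removed` clouds, `n_removed`, the
#'   `threshold` used and the per-point mean neighbor distances `d`
#' @export
sor_filter <- function(cloud, k = 64, nsigma = 1,
                       rule = c("mean_plus_sigma", "sigma_only")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud)
  if (n < 2) stop("sor_filter needs at least 2 points")
  if (nsigma <= 0) stop("nsigma must be positive")
  if (k > n - 1) {
    message(sprintf("sor_filter: k clamped from %d to %d (cloud has %d points)",
                    k, n - 1, n))
    k <- n - 1
  }
  d <- .knn_mean_dist_cpp(as.matrix(cloud[, c("x", "y", "z")]), as.integer(k))
  thr <- if (rule == "mean_plus_sigma") mean(d) + nsigma * sd(d) else sd(d)
  out <- d > thr
  list(kept = .as_cloud(cloud[!out, ]), removed = .as_cloud(cloud[out, ]),
       n_removed = sum(out), threshold = thr, d = d)
}

#' Split training-structure points from shoot points
#'
#' Points falling inside any mask (capsules around post/wire axes, spheres
#' around markers) are separated so that their alpha-shape volume can be
#' subtracted from the total, or simply dropped before volume estimation.
#'
#' @param cloud a [point_cloud()]
#' @param masks a data frame as from [structure_masks()] (`type`, endpoint
#'   columns, `radius`); `NULL` or empty means nothing is masked
#' @return list with `shoots` and `structures` clouds and the logical
#'   per-point indicator `is_structure`
#' @export
mask_training_structures <- function(cloud, masks = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(masks) || !nrow(masks))
    return(list(shoots = cloud, structures = .as_cloud(cloud[0, ]),
                is_structure = rep(FALSE, nrow(cloud))))
  inside <- rep(FALSE, nrow(cloud))
  P <- as.matrix(cloud[, c("x", "y", "z")])
  for (i in seq_len(nrow(masks))) {
    m <- masks[i, ]
    a <- c(m$x0, m$y0, m$z0)
    if (m$type == "sphere") {
      d2 <- (P[, 1] - a[1])^2 + (P[, 2] - a[2])^2 + (P[, 3] - a[3])^2
      inside <- inside | d2 <= m$radius^2
    } else {
      b <- c(m$x1, m$y1, m$z1)
      ab <- b - a
      L2 <- sum(ab^2)
      tt <- if (L2 > 0)
        pmin(pmax(((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
                   (P[, 3] - a[3]) * ab[3]) / L2, 0), 1)
      else 0
      d2 <- (P[, 1] - (a[1] + tt * ab[1]))^2 +
            (P[, 2] - (a[2] + tt * ab[2]))^2 +
            (P[, 3] - (a[3] + tt * ab[3]))^2
      inside <- inside | d2 <= m$radius^2
    }
  }
  list(shoots = .as_cloud(cloud[!inside, ]),
       structures = .as_cloud(cloud[inside, ]),
       is_structure = inside)
}

#' Default filter chain for one batch
#'
#' crop -> bud-height cut -> structure masking -> SOR, returning the shoot
#' cloud, the structure cloud (same cut and SOR settings applied) and a
#' per-stage count report.
#'
#' @param cloud georeferenced `point_cloud` of the full run
#' @param x_interval batch x-interval
#' @param z0 bud-height cut, m
#' @param masks structure masks (see [mask_training_structures()])
#' @param k,nsigma SOR parameters
#' @return list `shoots`, `structures`, `report` (named stage counts)
#' @export
filter_batch <- function(cloud, x_interval, z0, masks = NULL,
                         k = 64, nsigma = 1) {
  a <- crop_batch(cloud, x_interval)
  b <- cut_below_height(a, z0)
  m <- mask_training_structures(b, masks)
  shoots <- m$shoots
  n_sor <- 0L
  if (nrow(shoots) > 2) {
    s <- sor_filter(shoots, k, nsigma)
    shoots <- s$kept
    n_sor <- s$n_removed
  }
  list(shoots = shoots, structures = m$structures,
       report = c(input = nrow(cloud), cropped = nrow(a), cut = nrow(b),
                  structures = nrow(m$structures), sor_removed = n_sor,
                  shoots = nrow(shoots)))
}
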