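# 3D alpha shapes over a Delaunay tetrahedralization, built from first
# principles.  The convention throughout is that alpha is a LENGTH in
# meters: a tetrahedron belongs to the alpha complex when its circumsphere
# radius is at most alpha.  The enclosed volume is the sum of the retained
# tetrahedron volumes (tetrahedra of a tetrahedralization have disjoint
# interiors, so the sum is exact); as alpha grows the retained set is
# nested, so the volume is monotone and reaches the convex-hull volume.

#' Circumscribing sphere of a tetrahedron
#'
#' @param v 4 x 3 matrix of vertex coordinates
#' @return list with `center` (length 3) and `radius`; a (near-)coplanar
#'   tetrahedron is flagged degenerate with infinite radius
#' @export
circumsphere <- function(v) {
  v <- as.matrix(v)
  stopifnot(nrow(v) == 4, ncol(v) == 3)
  A <- 2 * (v[2:4, ] - matrix(v[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(v[2:4, ]^2) - sum(v[1, ]^2)
  det <- det(A)
  scale <- max(abs(A))
  if (!is.finite(det) || scale == 0 ||
      abs(det) <= 1e-12 * scale^3) {
    return(list(center = rep(NA_real_, 3), radius = Inf, degenerate = TRUE))
  }
  ctr <- solve(A, b)
  list(center = as.numeric(ctr),
       radius = sqrt(sum((v[1, ] - ctr)^2)),
       degenerate = FALSE)
}

#' @rdname circumsphere
#' @export
circumradius <- function(v) circumsphere(v)$radius

#' Delaunay tetrahedralization of a 3D point set
#'
#' Incremental Bowyer-Watson construction with extended-precision
#' predicates.  Points are jittered by a tiny seeded uniform offset
#' (default 1e-9 of the bounding-box extent) so that cospherical or
#' coplanar configurations — ubiquitous in gridded or quantized data — have
#' measure zero; the perturbation is orders of magnitude below the range
#' quantum of any scanner.
#'
#' @param points n x 3 matrix (or a [point_cloud()])
#' @param jitter relative jitter magnitude (0 disables)
#' @param seed integer seed for the jitter and insertion order
#' @return list of class `delaunay3d`: `points`, `tetra` (m x 4 vertex
#'   indices), `volume` and `circumradius` per tetrahedron
#' @export
delaunay3d <- function(points, jitter = 1e-9, seed = 1L) {
  pts <- .as_points_matrix(points)
  d <- .delaunay3d_cpp(pts, jitter, as.integer(seed))
  structure(list(points = pts, tetra = d$tetra, volume = d$volume,
                 circumradius = d$circumradius),
            class = "delaunay3d")
}

.as_points_matrix <- function(points) {
  if (inherits(points, "point_cloud"))
    return(as.matrix(points[, c("x", "y", "z")]))
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  pts
}

# the 4 faces of every tetra, vertex-sorted and encoded as one double each;
# exact for vertex counts below ~200000 (keys stay under 2^53)
.face_keys <- function(tetra) {
  m <- nrow(tetra)
  f <- rbind(tetra[, c(2, 3, 4), drop = FALSE],
             tetra[, c(1, 3, 4), drop = FALSE],
             tetra[, c(1, 2, 4), drop = FALSE],
             tetra[, c(1, 2, 3), drop = FALSE])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  fs <- cbind(lo, mid, hi)
  n1 <- as.numeric(max(tetra)) + 1
  key <- (as.numeric(lo) * n1 + mid) * n1 + hi
  list(key = key, tet = rep(seq_len(m), 4), face = fs)
}

# connected components of a tetra set under shared-face adjacency
.tet_components <- function(tetra) {
  m <- nrow(tetra)
  if (m == 0) return(integer(0))
  fk <- .face_keys(tetra)
  o <- order(fk$key)
  k <- fk$key[o]
  same <- which(k[-1] == k[-length(k)])
  if (!length(same)) return(seq_len(m))
  comp <- .components_cpp(m, cbind(fk$tet[o][same], fk$tet[o][same + 1]))
  comp
}

# unique vertex pairs (edges) of a tetra table
.tet_edges <- function(tetra) {
  e <- rbind(tetra[, c(1, 2)], tetra[, c(1, 3)], tetra[, c(1, 4)],
             tetra[, c(2, 3)], tetra[, c(2, 4)], tetra[, c(3, 4)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- as.numeric(lo) * (max(tetra) + 1) + hi
  keep <- !duplicated(key)
  cbind(lo[keep], hi[keep])
}

# Components of the alpha complex among covered points.  The solid part is
# the retained tetrahedra; chunks additionally count as connected when an
# alpha-exposed (Gabriel, diametral-sphere-empty) Delaunay edge of length
# <= 2 alpha joins them — the alpha complex contains lower-dimensional
# simplices too, and a shape bridged by such an edge has no void between
# its parts.
.alpha_components <- function(dt, tet, alpha) {
  cov <- sort(unique(as.vector(tet)))
  if (!length(cov)) return(0L)
  idx <- integer(max(cov)); idx[cov] <- seq_along(cov)
  edges <- .tet_edges(tet)
  all_e <- .tet_edges(dt$tetra)
  both_cov <- all_e[, 1] %in% cov & all_e[, 2] %in% cov
  len <- sqrt(rowSums((dt$points[all_e[, 1], , drop = FALSE] -
                       dt$points[all_e[, 2], , drop = FALSE])^2))
  cand <- all_e[both_cov & len <= 2 * alpha, , drop = FALSE]
  if (nrow(cand)) {
    gab <- .gabriel_edges_cpp(dt$points, cand)
    edges <- rbind(edges, cand[gab, , drop = FALSE])
  }
  comp <- .components_cpp(length(cov),
                          cbind(idx[edges[, 1]], idx[edges[, 2]]))
  length(unique(comp))
}

#' Alpha complex and enclosed volume of a 3D point set
#'
#' Retains the Delaunay tetrahedra whose circumsphere radius is at most
#' `alpha` (alpha in meters), sums their volumes, extracts the boundary
#' surface (faces belonging to exactly one retained tetrahedron) and counts
#' connected components and covered points.
#'
#' @param x an n x 3 matrix, a [point_cloud()], or a precomputed
#'   [delaunay3d()] (reuse it when sweeping several alpha values)
#' @param alpha circumradius threshold, m (> 0)
#' @param jitter,seed passed to [delaunay3d()] when `x` is raw points
#' @return object of class `alpha_shape`: `alpha`, `tetra` (retained),
#'   `volume` (m3), `n_components`, `boundary` (b x 3 vertex indices),
#'   `n_points`, `n_points_covered`, and the underlying `delaunay`
#' @export
alpha_complex <- function(x, alpha, jitter = 1e-9, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a single positive length (meters)")
  dt <- if (inherits(x, "delaunay3d")) x else delaunay3d(x, jitter, seed)
  n <- nrow(dt$points)
  if (n < 4 || nrow(dt$tetra) == 0) {
    if (n < 4) warning("fewer than 4 points: empty alpha complex")
    return(structure(list(alpha = alpha,
                          tetra = matrix(integer(0), 0, 4),
                          volume = 0, n_components = 0L,
                          boundary = matrix(integer(0), 0, 3),
                          n_points = n, n_points_covered = 0L,
                          delaunay = dt),
                     class = "alpha_shape"))
  }
  keep <- is.finite(dt$circumradius) & dt$circumradius <= alpha
  tet <- dt$tetra[keep, , drop = FALSE]
  vol <- sum(dt$volume[keep])
  n_comp <- .alpha_components(dt, tet, alpha)
  boundary <- matrix(integer(0), 0, 3)
  if (nrow(tet)) {
    fk <- .face_keys(tet)
    cnt <- ave(fk$key, fk$key, FUN = length)
    boundary <- fk$face[cnt == 1, , drop = FALSE]
  }
  structure(list(alpha = alpha, tetra = tet, volume = vol,
                 n_components = n_comp,
                 boundary = boundary,
                 n_points = n,
                 n_points_covered = length(unique(as.vector(tet))),
                 delaunay = dt),
            class = "alpha_shape")
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf(
    "alpha_shape: alpha = %g m, %d tetrahedra, volume %.6e m3\n",
    x$alpha, nrow(x$tetra), x$volume))
  cat(sprintf("  %d component(s); %d/%d points covered; %d boundary faces\n",
              x$n_components, x$n_points_covered, x$n_points,
              nrow(x$boundary)))
  invisible(x)
}

#' Select a suitable alpha from a candidate grid
#'
#' Implements the selection rule "the smallest enclosed volume whilst
#' maintaining a solid surface free from voids": since the retained set is
#' nested in alpha, this is the smallest candidate whose complex forms a
#' single connected component and covers at least `coverage_frac` of the
#' points.  If no candidate qualifies, the largest candidate is returned
#' with a warning.
#'
#' @param points points accepted by [alpha_complex()] (the Delaunay
#'   tetrahedralization is computed once and shared across candidates)
#' @param candidates increasing vector of alpha values, m
#' @param coverage_frac minimum fraction of points that must be covered by
#'   the retained tetrahedra (default 0.99)
#' @param jitter,seed passed to [delaunay3d()]
#' @return list with `alpha` (selected), `result` (its `alpha_shape`), and
#'   `sweep`: a data frame of per-candidate volume, components and coverage
#' @export
select_alpha <- function(points, candidates = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         coverage_frac = 0.99, jitter = 1e-9, seed = 1L) {
  if (!length(candidates)) stop("need at least one candidate alpha")
  if (is.unsorted(candidates, strictly = TRUE))
    stop("candidates must be strictly increasing")
  dt <- if (inherits(points, "delaunay3d")) points
        else delaunay3d(points, jitter, seed)
  shapes <- lapply(candidates, function(a) alpha_complex(dt, a))
  sweep <- data.frame(
    alpha = candidates,
    volume = vapply(shapes, `[[`, numeric(1), "volume"),
    n_components = vapply(shapes, `[[`, integer(1), "n_components"),
    coverage = vapply(shapes, function(s)
      if (s$n_points) s$n_points_covered / s$n_points else 0, numeric(1)))
  ok <- sweep$n_components == 1L & sweep$coverage >= coverage_frac
  if (any(ok)) {
    i <- which(ok)[1]
  } else {
    warning("no candidate alpha gives a single void-free component; ",
            "returning the largest candidate")
    i <- length(candidates)
  }
  list(alpha = candidates[i], result = shapes[[i]], sweep = sweep)
}

#' Volume with the training structures subtracted
#'
#' `max(0, V_total - V_structures)`, the subtraction step that removes the
#' trellis contribution from a batch's total enclosed volume.
#'
#' @param result_total,result_structures `alpha_shape` objects (or plain
#'   volumes in m3) from the same pipeline run
#' @return volume in m3
#' @export
volume_without_structures <- function(result_total, result_structures) {
  vt <- if (inherits(result_total, "alpha_shape")) result_total$volume
        else result_total
  vs <- if (inherits(result_structures, "alpha_shape"))
          result_structures$volume else result_structures
  if (vs > vt) {
    warning("structure volume exceeds total volume; clamping to 0")
    return(0)
  }
  vt - vs
}
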