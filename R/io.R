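# Readers and writers for every on-disk format the pipeline touches:
# scan-log CSV, NMEA 0183 GGA streams, PLY (binary little-endian) and XYZ
# point clouds.  The local frame is metric, double precision: X = travel
# direction along the row, Y = crop depth, Z = up.

#' Construct a georeferenced point cloud
#'
#' @param x,y,z coordinates in meters (local frame)
#' @param scan_index,beam_index per-point provenance (which scan sweep and
#'   which beam within the sweep produced the point)
#' @param label optional per-point label (e.g. the scene primitive hit,
#'   available for synthetic clouds)
#' @return a data frame of class `point_cloud`
#' @export
point_cloud <- function(x = numeric(0), y = numeric(0), z = numeric(0),
                        scan_index = NA_integer_, beam_index = NA_integer_,
                        label = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n && !all(is.finite(x) & is.finite(y) & is.finite(z)))
    stop("point coordinates must be finite")
  cl <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   scan_index = rep_len(as.integer(scan_index), n),
                   beam_index = rep_len(as.integer(beam_index), n))
  if (!is.null(label)) cl$label <- rep_len(label, n)
  class(cl) <- c("point_cloud", "data.frame")
  cl
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points", nrow(x)))
  if (nrow(x))
    cat(sprintf(", x [%.3f, %.3f] y [%.3f, %.3f] z [%.3f, %.3f] m",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  cat("\n")
  invisible(x)
}

.as_cloud <- function(df) {
  class(df) <- c("point_cloud", "data.frame")
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------- scan logs

#' Write / read a raw scan log
#'
#' The scan log is a CSV with one row per beam and columns `scan_index`,
#' `timestamp_s` (microsecond precision), `angle_deg`, `range_m`, `valid`.
#' Beams with no return keep their row (`valid = 0`, empty range), so a
#' frame always carries its full beam count.
#'
#' @param scans a `scan_set` as returned by [simulate_scan()]
#' @param path file path
#' @export
write_scan_log <- function(scans, path) {
  stopifnot(inherits(scans, "scan_set"))
  df <- scans
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("scan_index,timestamp_s,angle_deg,range_m,valid", con)
  rng <- ifelse(is.na(df$range_m), "",
                sub("\\.$", ".0", sub("0+$", "", sprintf("%.6f", df$range_m))))
  writeLines(sprintf("%d,%.6f,%.4f,%s,%d",
                     df$scan_index, df$timestamp_s, df$angle_deg,
                     rng, as.integer(df$valid)), con)
  invisible(path)
}

#' @rdname write_scan_log
#' @param sensor optional [sensor_config()]; if given, ranges outside the
#'   sensor's measurement window are re-flagged invalid on load
#' @return `read_scan_log()` returns a `scan_set`: a data frame with one row
#'   per beam plus the columns above
#' @export
read_scan_log <- function(path, sensor = NULL) {
  if (!file.exists(path)) stop("scan log not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "scan_index,timestamp_s,angle_deg,range_m,valid")
    stop("not a scan log (bad header): ", path)
  if (length(lines) == 1L)
    return(.as_scan_set(data.frame(scan_index = integer(0),
                                   timestamp_s = numeric(0),
                                   angle_deg = numeric(0),
                                   range_m = numeric(0),
                                   valid = logical(0))))
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 5L & nf != 4L)  # trailing empty range drops a field
  if (length(bad))
    stop(sprintf("malformed scan log row at line %d: '%s'",
                 bad[1] + 1L, body[bad[1]]))
  m <- matrix("", length(parts), 5)
  for (j in 1:5)
    m[, j] <- vapply(parts, function(p) if (length(p) >= j) p[j] else "",
                     character(1))
  suppressWarnings({
    df <- data.frame(scan_index = as.integer(m[, 1]),
                     timestamp_s = as.numeric(m[, 2]),
                     angle_deg = as.numeric(m[, 3]),
                     range_m = as.numeric(m[, 4]),
                     valid = as.integer(m[, 5]))
  })
  chk <- is.na(df$scan_index) | is.na(df$timestamp_s) | is.na(df$angle_deg) |
         is.na(df$valid) | (is.na(df$range_m) & m[, 4] != "")
  if (any(chk))
    stop(sprintf("malformed scan log row at line %d: '%s'",
                 which(chk)[1] + 1L, body[which(chk)[1]]))
  df$valid <- df$valid == 1L
  df$valid[is.na(df$range_m)] <- FALSE
  if (!is.null(sensor))
    df$valid <- df$valid & !is.na(df$range_m) &
      df$range_m >= sensor$range_min & df$range_m <= sensor$range_max
  .as_scan_set(df)
}

.as_scan_set <- function(df) {
  stopifnot(identical(names(df),
    c("scan_index", "timestamp_s", "angle_deg", "range_m", "valid")))
  class(df) <- c("scan_set", "data.frame")
  df
}

#' Extract one scan frame from a scan set
#'
#' @param scans a `scan_set`
#' @param i scan index
#' @return a list with `scan_index`, `timestamp`, `angles`, `ranges`, `valid`
#' @export
scan_frame <- function(scans, i) {
  f <- scans[scans$scan_index == i, ]
  if (!nrow(f)) stop("no such scan index: ", i)
  list(scan_index = i, timestamp = f$timestamp_s[1],
       angles = f$angle_deg, ranges = f$range_m, valid = f$valid)
}

# ---------------------------------------------------------------- NMEA 0183

.nmea_checksum <- function(body) {
  x <- 0L
  for (ch in utf8ToInt(body)) x <- bitwXor(x, ch)
  sprintf("%02X", x)
}

.deg_to_dm <- function(deg) {
  d <- floor(abs(deg))
  m <- (abs(deg) - d) * 60
  list(d = d, m = m)
}

# mean Earth radius; the same value must be used when projecting fixes back
# to the local tangent plane so that write -> parse round-trips
.R_EARTH <- 6371008.8

#' Parse one NMEA 0183 GGA sentence
#'
#' Verifies the checksum, decodes time (seconds of day), latitude, longitude,
#' fix quality and altitude.  Non-GGA sentences return `NULL` (callers skip
#' them); a corrupted checksum is an error.
#'
#' @param sentence a single `$..GGA` sentence
#' @return a one-row data frame (`t`, `lat`, `lon`, `alt`, `quality`) or
#'   `NULL` for non-GGA input
#' @export
parse_gga <- function(sentence) {
  s <- trimws(sentence)
  if (!nzchar(s) || substr(s, 1, 1) != "$") stop("not an NMEA sentence")
  star <- regexpr("*", s, fixed = TRUE)
  if (star < 0) stop("NMEA sentence without checksum")
  body <- substr(s, 2, star - 1)
  claimed <- toupper(substr(s, star + 1, star + 2))
  if (.nmea_checksum(body) != claimed)
    stop("NMEA checksum mismatch in: ", s)
  f <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (!grepl("GGA$", f[1])) return(NULL)
  tm <- f[2]
  tsec <- as.numeric(substr(tm, 1, 2)) * 3600 +
          as.numeric(substr(tm, 3, 4)) * 60 +
          as.numeric(substr(tm, 5, nchar(tm)))
  lat <- as.numeric(substr(f[3], 1, 2)) +
         as.numeric(substr(f[3], 3, nchar(f[3]))) / 60
  if (f[4] == "S") lat <- -lat
  lon <- as.numeric(substr(f[5], 1, 3)) +
         as.numeric(substr(f[5], 4, nchar(f[5]))) / 60
  if (f[6] == "W") lon <- -lon
  data.frame(t = tsec, lat = lat, lon = lon,
             alt = as.numeric(f[10]), quality = as.integer(f[7]))
}

#' Read a GGA stream into local tangent-plane fixes
#'
#' Parses every GGA sentence in `path` (other sentence types are skipped),
#' then projects to a local east/north/up frame with an equirectangular
#' tangent-plane approximation anchored at `origin` (default: the first
#' fix).
#'
#' @param path NMEA text file
#' @param origin optional `c(lat, lon, alt)` anchor; defaults to first fix
#' @return data frame of class `gnss_fixes`: `t` (s of day), `east`,
#'   `north`, `up` (m), `quality`, plus `lat`, `lon`, `alt`
#' @export
read_nmea <- function(path, origin = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    if (!grepl("GGA", substr(l, 1, 7), fixed = TRUE)) return(NULL)
    parse_gga(l)
  })
  fixes <- do.call(rbind, rows)
  if (is.null(fixes) || !nrow(fixes)) stop("no GGA sentences in ", path)
  if (any(diff(fixes$t) <= 0))
    stop("GGA timestamps are not strictly increasing")
  if (is.null(origin))
    origin <- c(fixes$lat[1], fixes$lon[1], fixes$alt[1])
  fixes$east <- (fixes$lon - origin[2]) * pi / 180 * .R_EARTH *
                cos(origin[1] * pi / 180)
  fixes$north <- (fixes$lat - origin[1]) * pi / 180 * .R_EARTH
  fixes$up <- fixes$alt - origin[3]
  attr(fixes, "origin") <- origin
  class(fixes) <- c("gnss_fixes", "data.frame")
  fixes
}

# ------------------------------------------------------------- point clouds

#' Write a point cloud to PLY (binary little-endian) or XYZ
#'
#' The PLY form stores `x`, `y`, `z` as doubles and the per-point provenance
#' (`scan_index`, `beam_index`) as 32-bit integers, so a registered cloud
#' survives a round trip bit-for-bit within 1e-6 m.
#'
#' @param cloud a [point_cloud()]
#' @param path output file
#' @param format `"ply"` or `"xyz"`
#' @export
write_cloud <- function(cloud, path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "point_cloud"))
  if (format == "xyz") {
    writeLines(sprintf("%.6f %.6f %.6f", cloud$x, cloud$y, cloud$z), path)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply", "format binary_little_endian 1.0",
              "comment vinescan point cloud",
              sprintf("element vertex %d", nrow(cloud)),
              "property double x", "property double y", "property double z",
              "property int scan_index", "property int beam_index",
              "end_header")
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  if (nrow(cloud)) {
    si <- cloud$scan_index; si[is.na(si)] <- -1L
    bi <- cloud$beam_index; bi[is.na(bi)] <- -1L
    # interleave: 3 doubles + 2 ints per vertex
    raw_xyz <- writeBin(as.numeric(t(cbind(cloud$x, cloud$y, cloud$z))),
                        raw(), size = 8, endian = "little")
    raw_idx <- writeBin(as.integer(t(cbind(si, bi))), raw(), size = 4,
                        endian = "little")
    rec <- raw(nrow(cloud) * 32L)
    dim(raw_xyz) <- NULL
    xi <- rep(seq_len(nrow(cloud)) - 1L, each = 24L) * 32L +
          rep(1:24, nrow(cloud))
    ii <- rep(seq_len(nrow(cloud)) - 1L, each = 8L) * 32L + 24L +
          rep(1:8, nrow(cloud))
    rec[xi] <- raw_xyz
    rec[ii] <- raw_idx
    writeBin(rec, con)
  }
  invisible(path)
}

#' Read a point cloud written by [write_cloud()]
#'
#' @param path a `.ply` (binary little-endian) or `.xyz` file
#' @return a [point_cloud()]
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    m <- as.matrix(read.table(path, col.names = c("x", "y", "z")))
    return(point_cloud(m[, 1], m[, 2], m[, 3]))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    if (!length(l)) stop("truncated PLY header in ", path)
    header <- c(header, l)
    if (l == "end_header") break
    if (length(header) > 100) stop("PLY header too long in ", path)
  }
  if (header[1] != "ply" || !any(grepl("binary_little_endian", header)))
    stop("not a binary little-endian PLY: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  props <- sub("^property ", "", grep("^property ", header, value = TRUE))
  sizes <- vapply(strsplit(props, " "), function(p)
    switch(p[1], double = 8L, float = 4L, int = 4L, uint = 4L,
           uchar = 1L, stop("unsupported PLY property type: ", p[1])),
    integer(1))
  rec_size <- sum(sizes)
  payload <- readBin(con, "raw", n = nv * rec_size + 1L)
  if (length(payload) < nv * rec_size)
    stop("truncated PLY payload in ", path, " (expected ",
         nv * rec_size, " bytes, got ", length(payload), ")")
  if (length(payload) > nv * rec_size)
    warning("trailing bytes after PLY payload in ", path)
  vals <- vector("list", length(props))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  for (j in seq_along(props)) {
    p <- strsplit(props[j], " ")[[1]]
    idx <- as.vector(outer(1:sizes[j], (seq_len(nv) - 1L) * rec_size + off[j],
                           "+"))
    bytes <- payload[idx]
    vals[[j]] <- switch(p[1],
      double = readBin(bytes, "double", n = nv, size = 8, endian = "little"),
      float = readBin(bytes, "double", n = nv, size = 4, endian = "little"),
      int = readBin(bytes, "integer", n = nv, size = 4, endian = "little"),
      uint = readBin(bytes, "integer", n = nv, size = 4, endian = "little"),
      uchar = as.integer(bytes))
    names(vals)[j] <- p[2]
  }
  si <- vals$scan_index %||% rep(NA_integer_, nv)
  bi <- vals$beam_index %||% rep(NA_integer_, nv)
  si[si < 0] <- NA_integer_
  bi[bi < 0] <- NA_integer_
  point_cloud(vals$x, vals$y, vals$z, si, bi)
}

#' Export the scene geometry as a PLY triangle mesh
#'
#' Tessellates each frustum with `sides` rectangular panels (two triangles
#' each) and each marker sphere with a UV sphere, for inspection in external
#' viewers.
#'
#' @param scene a `vine_scene`
#' @param path output `.ply`
#' @param sides number of panels around each frustum
#' @export
write_scene_ply <- function(scene, path, sides = 12) {
  segs <- scene$segments
  verts <- list(); faces <- list(); nv <- 0L
  th <- seq(0, 2 * pi, length.out = sides + 1)[-(sides + 1)]
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$tag == "marker") {
      # coarse UV sphere
      ph <- seq(0, pi, length.out = 7)
      grid <- expand.grid(th = th, ph = ph)
      v <- cbind(s$x0 + s$r0 * sin(grid$ph) * cos(grid$th),
                 s$y0 + s$r0 * sin(grid$ph) * sin(grid$th),
                 s$z0 + s$r0 * cos(grid$ph))
      f <- list()
      for (r in 1:(length(ph) - 1)) for (c in 1:sides) {
        a <- (r - 1) * sides + c; b <- (r - 1) * sides + (c %% sides) + 1
        cc <- r * sides + c; d <- r * sides + (c %% sides) + 1
        f[[length(f) + 1]] <- c(a, b, cc); f[[length(f) + 1]] <- c(b, d, cc)
      }
      fm <- do.call(rbind, f)
    } else {
      a <- c(s$x0, s$y0, s$z0); b <- c(s$x1, s$y1, s$z1)
      ax <- b - a; h <- sqrt(sum(ax^2)); ax <- ax / h
      ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * ax) * ax; u <- u / sqrt(sum(u^2))
      w <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
             ax[1] * u[2] - ax[2] * u[1])
      ring0 <- t(a + s$r0 * (outer(u, cos(th)) + outer(w, sin(th))))
      ring1 <- t(b + s$r1 * (outer(u, cos(th)) + outer(w, sin(th))))
      v <- rbind(ring0, ring1)
      f <- list()
      for (c in 1:sides) {
        c2 <- (c %% sides) + 1
        f[[length(f) + 1]] <- c(c, c2, sides + c)
        f[[length(f) + 1]] <- c(c2, sides + c2, sides + c)
      }
      fm <- do.call(rbind, f)
    }
    verts[[i]] <- v
    faces[[i]] <- fm + nv
    nv <- nv + nrow(v)
  }
  V <- do.call(rbind, verts); FF <- do.call(rbind, faces)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("element vertex %d", nrow(V)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(FF)),
              "property list uchar int vertex_indices", "end_header")
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(t(V)), con, size = 4, endian = "little")
  fraw <- raw(nrow(FF) * 13L)
  for (k in seq_len(nrow(FF))) {
    fraw[(k - 1) * 13L + 1L] <- as.raw(3L)
    fraw[(k - 1) * 13L + 2:13] <- writeBin(as.integer(FF[k, ] - 1L), raw(),
                                           size = 4, endian = "little")
  }
  writeBin(fraw, con)
  invisible(path)
}
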