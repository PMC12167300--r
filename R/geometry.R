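# C-arm geometry: tilted circular orbits, poses, pinhole projection and
# back-projection.
#
# Conventions (used consistently everywhere):
#   * world frame: isocenter at the origin; the untilted orbit revolves about
#     `orbit_axis` (default +z, patient cranio-caudal); the orbit plane is
#     tilted by delta about `tilt_axis` (default +x, patient left-right);
#     at theta' = 0, delta = 0 the source sits on tilt_axis x orbit_axis
#     (default -y, the anterior-posterior reference).
#   * detector pixels: continuous coordinates (u, v), u = column, v = row,
#     origin at the detector corner; pixel (i, j) covers [j, j+1) x [i, i+1)
#     with its center at (j + 0.5, i + 0.5); the detector center is
#     (cols/2, rows/2) and is where the isocenter projects.
#   * angles are degrees at every interface and converted internally.

#' C-arm imaging geometry
#'
#' Bundles the fixed parameters of a mobile C-arm CBCT system: source and
#' detector distances, detector grid, and the angular grids of candidate
#' orbital angles (theta', within the scan plane) and plane tilts (delta).
#' Defaults are typical mobile-C-arm values (source-isocenter 622 mm,
#' source-detector 1164 mm, 400 x 400 detector at 1 mm pitch) with the
#' candidate grids theta' in \[-100, 100\] degrees and delta in \[-30, 30\]
#' degrees at 1 degree spacing.
#'
#' @param source_isocenter_distance Source-to-isocenter distance in mm.
#' @param source_detector_distance Source-to-detector distance in mm; must
#'   exceed `source_isocenter_distance`.
#' @param detector_rows,detector_cols Detector size in pixels.
#' @param pixel_pitch Detector pixel size in mm.
#' @param theta_range,theta_step Orbital-angle grid in degrees.
#' @param delta_range,delta_step Tilt grid in degrees.
#' @param orbit_axis Unit 3-vector: axis the untilted orbit revolves around.
#' @param tilt_axis Unit 3-vector, perpendicular to `orbit_axis`: axis about
#'   which the whole orbit plane is tilted.
#' @return An object of class `carm_geometry`.
#' @examples
#' geom <- carm_geometry()
#' pose <- make_pose(geom, theta_prime = 0, delta = 0)
#' project(pose, c(0, 0, 0))  # isocenter lands on the detector center
#' @export
carm_geometry <- function(source_isocenter_distance = 622,
                          source_detector_distance = 1164,
                          detector_rows = 400,
                          detector_cols = 400,
                          pixel_pitch = 1,
                          theta_range = c(-100, 100),
                          theta_step = 1,
                          delta_range = c(-30, 30),
                          delta_step = 1,
                          orbit_axis = c(0, 0, 1),
                          tilt_axis = c(1, 0, 0)) {
  for (nm in c("source_isocenter_distance", "source_detector_distance",
               "pixel_pitch", "theta_step", "delta_step")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (!(source_isocenter_distance > 0 &&
          source_isocenter_distance < source_detector_distance)) {
    validation_error("need 0 < source_isocenter_distance < source_detector_distance")
  }
  if (pixel_pitch <= 0) validation_error("pixel_pitch must be > 0")
  if (detector_rows < 1 || detector_cols < 1) {
    validation_error("detector dimensions must be >= 1 pixel")
  }
  if (theta_step <= 0 || delta_step <= 0) {
    validation_error("angular steps must be > 0")
  }
  if (length(theta_range) != 2 || diff(theta_range) < 0 ||
        length(delta_range) != 2 || diff(delta_range) < 0) {
    validation_error("angular ranges must be non-empty [min, max] pairs")
  }
  orbit_axis <- unit3(as.numeric(orbit_axis))
  tilt_axis <- unit3(as.numeric(tilt_axis))
  if (abs(sum(orbit_axis * tilt_axis)) > 1e-9) {
    validation_error("orbit_axis and tilt_axis must be perpendicular")
  }
  structure(list(
    source_isocenter_distance = source_isocenter_distance,
    source_detector_distance = source_detector_distance,
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    pixel_pitch = pixel_pitch,
    theta_range = as.numeric(theta_range),
    theta_step = theta_step,
    delta_range = as.numeric(delta_range),
    delta_step = delta_step,
    orbit_axis = orbit_axis,
    tilt_axis = tilt_axis
  ), class = "carm_geometry")
}

#' @export
print.carm_geometry <- function(x, ...) {
  cat("C-arm geometry\n")
  cat(sprintf("  SID %g mm, SDD %g mm\n",
              x$source_isocenter_distance, x$source_detector_distance))
  cat(sprintf("  detector %d x %d px @ %g mm\n",
              x$detector_rows, x$detector_cols, x$pixel_pitch))
  cat(sprintf("  theta' [%g, %g] step %g deg; delta [%g, %g] step %g deg\n",
              x$theta_range[1], x$theta_range[2], x$theta_step,
              x$delta_range[1], x$delta_range[2], x$delta_step))
  invisible(x)
}

#' Angular grids of a geometry
#'
#' @param geom A [carm_geometry()].
#' @return Numeric vector of grid angles in degrees.
#' @export
theta_grid <- function(geom) {
  seq(geom$theta_range[1], geom$theta_range[2], by = geom$theta_step)
}

#' @rdname theta_grid
#' @export
delta_grid <- function(geom) {
  seq(geom$delta_range[1], geom$delta_range[2], by = geom$delta_step)
}

#' A C-arm pose on a tilted circular orbit
#'
#' Places the source on the circle of radius `source_isocenter_distance` in
#' the orbit plane tilted by `delta` about the tilt axis, at orbital angle
#' `theta_prime` measured within the tilted plane, and builds the 3x4
#' projection matrix mapping homogeneous world mm to homogeneous detector
#' pixels. The detector is perpendicular to the source-isocenter ray, beyond
#' the isocenter, and the isocenter projects to the detector center.
#'
#' @param geom A [carm_geometry()].
#' @param theta_prime Orbital angle in degrees.
#' @param delta Orbit-plane tilt in degrees.
#' @return An object of class `pmaa_pose` with fields `theta_prime`, `delta`,
#'   `source` (world mm) and `projection_matrix` (3x4).
#' @export
make_pose <- function(geom, theta_prime, delta) {
  stop_if_not_scalar_number(theta_prime, "theta_prime")
  stop_if_not_scalar_number(delta, "delta")
  a <- geom$orbit_axis
  b <- geom$tilt_axis
  r0 <- unit3(cross3(b, a))  # source direction at theta' = 0, delta = 0
  R <- rotation_about(b, delta) %*% rotation_about(a, theta_prime)
  src <- drop(R %*% (geom$source_isocenter_distance * r0))
  zc <- drop(R %*% (-r0))        # principal ray: source -> isocenter
  yc <- drop(R %*% a)            # detector v axis: tilted orbit normal
  xc <- cross3(yc, zc)           # detector u axis
  Rwc <- rbind(xc, yc, zc)
  f <- geom$source_detector_distance / geom$pixel_pitch
  cu <- geom$detector_cols / 2
  cv <- geom$detector_rows / 2
  K <- matrix(c(f, 0, 0, 0, f, 0, cu, cv, 1), 3, 3)
  P <- K %*% cbind(Rwc, -Rwc %*% src)
  new_pose(P, src,
           theta_prime = theta_prime, delta = delta,
           detector_rows = geom$detector_rows,
           detector_cols = geom$detector_cols,
           pixel_pitch = geom$pixel_pitch)
}

# Pose from an arbitrary finite projection matrix (e.g. an externally
# calibrated scout view). The camera center is the null space of P.
new_pose <- function(P, source = NULL, theta_prime = NA_real_, delta = NA_real_,
                     detector_rows = NA_integer_, detector_cols = NA_integer_,
                     pixel_pitch = NA_real_) {
  P <- matrix(as.numeric(P), 3, 4)
  if (qr(P)$rank < 3) validation_error("projection matrix must have rank 3")
  M <- P[, 1:3]
  if (abs(det(M)) < 1e-12) {
    validation_error("projection matrix has a degenerate left 3x3 block")
  }
  Minv <- solve(M)
  center <- drop(-Minv %*% P[, 4])
  if (is.null(source)) source <- center
  if (norm3(center - source) > 1e-6) {
    validation_error("projection matrix null space does not match the source")
  }
  structure(list(
    theta_prime = theta_prime,
    delta = delta,
    source = source,
    projection_matrix = P,
    Minv = Minv,
    detector_rows = detector_rows,
    detector_cols = detector_cols,
    pixel_pitch = pixel_pitch
  ), class = "pmaa_pose")
}

#' @export
print.pmaa_pose <- function(x, ...) {
  cat(sprintf("C-arm pose: theta' = %s deg, delta = %s deg\n",
              format(x$theta_prime), format(x$delta)))
  cat(sprintf("  source (mm): %.3f %.3f %.3f\n",
              x$source[1], x$source[2], x$source[3]))
  invisible(x)
}

#' A 3D ray
#'
#' @param origin 3-vector, mm.
#' @param direction 3-vector; normalized to unit length on construction.
#' @return An object of class `ray3d`.
#' @export
ray3d <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  if (length(origin) != 3 || length(direction) != 3 ||
        !all(is.finite(c(origin, direction)))) {
    validation_error("ray origin and direction must be finite 3-vectors")
  }
  structure(list(origin = origin, direction = unit3(direction)),
            class = "ray3d")
}

#' Project world points onto the detector
#'
#' Homogeneous pinhole projection with division by the third coordinate.
#'
#' @param pose A `pmaa_pose`.
#' @param point A 3-vector (mm) or an n x 3 matrix of points.
#' @return A 2-vector `(u, v)` in continuous pixel coordinates, or an n x 2
#'   matrix for matrix input.
#' @export
project <- function(pose, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  h <- pose$projection_matrix %*% rbind(t(pts), 1)
  w <- h[3, ]
  if (any(abs(w) < 1e-9)) {
    computation_error("point lies on the camera principal plane; projection is degenerate")
  }
  uv <- cbind(h[1, ] / w, h[2, ] / w)
  colnames(uv) <- c("u", "v")
  if (is.matrix(point)) uv else drop(uv)
}

#' Back-project a detector pixel to a 3D ray
#'
#' Returns the ray from the pose's source through the world point imaged at
#' the given continuous pixel coordinate, oriented from the source toward the
#' detector.
#'
#' @param pose A `pmaa_pose`.
#' @param pixel 2-vector `(u, v)` in pixels.
#' @return A [ray3d()].
#' @export
backproject <- function(pose, pixel) {
  if (length(pixel) != 2 || !all(is.finite(pixel))) {
    validation_error("pixel must be a finite 2-vector (u, v)")
  }
  d <- drop(pose$Minv %*% c(pixel[1], pixel[2], 1))
  ray3d(pose$source, d)
}

# unit ray directions for a grid of continuous pixel coordinates; rows follow
# expand.grid(u = us, v = vs) ordering (u varies fastest)
detector_directions <- function(pose, us, vs) {
  g <- expand.grid(u = us, v = vs)
  D <- t(pose$Minv %*% rbind(g$u, g$v, 1))
  D / sqrt(rowSums(D * D))
}

# ---- file formats ----------------------------------------------------------

geometry_fields <- c("source_isocenter_distance", "source_detector_distance",
                     "detector_rows", "detector_cols", "pixel_pitch",
                     "theta_range", "theta_step", "delta_range", "delta_step",
                     "orbit_axis", "tilt_axis")

#' Read or write a geometry configuration file
#'
#' JSON or YAML (chosen by file extension) with keys exactly the
#' [carm_geometry()] field names, in mm and degrees.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param geom A [carm_geometry()] (for writing).
#' @return `read_geometry()` returns a [carm_geometry()]; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) io_error(sprintf("geometry file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    io_error(sprintf("unsupported geometry config extension: .%s", ext))
  )
  unknown <- setdiff(names(cfg), geometry_fields)
  if (length(unknown)) {
    validation_error(sprintf("unknown geometry field(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  do.call(carm_geometry, cfg)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  cfg <- unclass(geom)[geometry_fields]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else {
    io_error(sprintf("unsupported geometry config extension: .%s", ext))
  }
  invisible(path)
}

geometry_hash <- function(geom) {
  fnv1a_hash(vapply(unclass(geom)[geometry_fields],
                    function(x) paste(fmt_full(as.numeric(x)), collapse = ","),
                    character(1)))
}

#' Write or read poses as plain-text projection-matrix blocks
#'
#' One pose per block: line 1 holds `theta_prime delta`, lines 2-4 the 3x4
#' projection matrix row-major, whitespace-delimited, full precision. The
#' format interoperates with externally calibrated scout views.
#'
#' @param poses A list of `pmaa_pose` objects.
#' @param path File path.
#' @param geom Optional [carm_geometry()] supplying detector dimensions for
#'   poses read back from file (needed for rendering, not for triangulation).
#' @return `read_poses()` returns a list of `pmaa_pose`; `write_poses()`
#'   returns `path` invisibly.
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "pmaa_pose")) poses <- list(poses)
  lines <- unlist(lapply(poses, function(p) {
    c(paste(fmt_full(p$theta_prime), fmt_full(p$delta)),
      apply(p$projection_matrix, 1, function(r) paste(fmt_full(r), collapse = " ")))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path, geom = NULL) {
  if (!file.exists(path)) io_error(sprintf("pose file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 4 != 0) {
    validation_error("pose file must consist of 4-line blocks (angles + 3x4 matrix)")
  }
  lapply(seq_len(length(lines) / 4), function(i) {
    blk <- lines[(i - 1) * 4 + 1:4]
    ang <- scan(text = blk[1], quiet = TRUE)
    P <- matrix(scan(text = paste(blk[2:4], collapse = " "), quiet = TRUE),
                3, 4, byrow = TRUE)
    new_pose(P, theta_prime = ang[1], delta = ang[2],
             detector_rows = if (is.null(geom)) NA_integer_ else geom$detector_rows,
             detector_cols = if (is.null(geom)) NA_integer_ else geom$detector_cols,
             pixel_pitch = if (is.null(geom)) NA_real_ else geom$pixel_pitch)
  })
}
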