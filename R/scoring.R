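# View scoring: the per-pose metric q_atten is the maximum X-ray path length
# through any single modeled implant for that C-arm pose.
#
# Three scorers are provided:
#   * analytic  — the maximum parallel chord of an ellipsoid in a given
#     direction passes through its centroid, so the per-object maximum path
#     is (to cone-beam divergence) the central chord along source -> centroid.
#     Cost: one chord evaluation per ellipsoid per pose, independent of
#     detector resolution. Evaluated whether or not the centroid projects
#     onto the physical detector (no field-of-view test).
#   * rendered  — per-pixel exact ray-ellipsoid path-length images, maximum
#     over sampled pixels and objects. Detector-limited. The reference for
#     quantifying the centroid approximation.
#   * voxel     — exact radiological path of detector rays through a binary
#     voxel mask (the segmentation-based baseline). Detector-limited; a ray
#     crossing several objects accumulates their sum.
#
# Per-object maximum (not sum) is the default semantics throughout; implant
# overlap is deliberately disregarded, and `q_atten_summed()` exists only to
# quantify that assumption.

assert_scene_nonempty <- function(es) {
  if (!inherits(es, "ellipsoid_set")) {
    validation_error("expected an ellipsoid_set")
  }
  if (length(es) == 0) {
    validation_error("empty scene: the view metric is undefined with no objects")
  }
  invisible(NULL)
}

assert_pose_has_detector <- function(pose) {
  if (is.na(pose$detector_rows) || is.na(pose$detector_cols)) {
    validation_error("pose carries no detector dimensions; detector-limited scoring needs them")
  }
  invisible(NULL)
}

#' Analytic view metric: maximum central chord toward the source
#'
#' For each ellipsoid the chord through its centroid along the unit vector
#' from the source to the centroid; the metric is the maximum over objects.
#' Cost is proportional to the number of ellipsoids only — no image is
#' rendered. Note the analytic scorer applies no field-of-view test: the
#' central chord is evaluated even if the centroid would project outside the
#' physical detector (the rendered and voxel scorers are detector-limited).
#'
#' @param ellipsoids An [ellipsoid_set()] with at least one member.
#' @param pose A `pmaa_pose`.
#' @return Metric value in mm.
#' @export
q_atten_analytic <- function(ellipsoids, pose) {
  assert_scene_nonempty(ellipsoids)
  max(vapply(ellipsoids$members, function(e) {
    chord_length(e, unit3(e$mu - pose$source))
  }, numeric(1)))
}

# clamped detector window (pixel units) around the projection of `points`;
# NULL when the window misses the detector entirely
detector_window <- function(pose, points, margin_px) {
  uv <- project(pose, points)
  u <- c(max(min(uv[, 1]) - margin_px, 0), min(max(uv[, 1]) + margin_px, pose$detector_cols))
  v <- c(max(min(uv[, 2]) - margin_px, 0), min(max(uv[, 2]) + margin_px, pose$detector_rows))
  if (u[1] >= u[2] || v[1] >= v[2]) return(NULL)
  list(u = u, v = v)
}

window_grid <- function(w, spacing_px) {
  list(us = seq(w$u[1], w$u[2], by = spacing_px),
       vs = seq(w$v[1], w$v[2], by = spacing_px))
}

#' Rendered view metric: per-pixel path-length maximum
#'
#' Renders each ellipsoid's exact path-length image at the given detector
#' sampling and returns the maximum over sampled pixels and over objects
#' (per-object maximum; overlapping projections are not summed). Only the
#' detector region each ellipsoid can project into is sampled; objects whose
#' projection misses the detector contribute 0.
#'
#' @param ellipsoids An [ellipsoid_set()].
#' @param pose A `pmaa_pose` with detector dimensions.
#' @param sampling Detector sampling spacing in mm.
#' @return Metric value in mm.
#' @export
q_atten_rendered <- function(ellipsoids, pose, sampling = 1) {
  assert_scene_nonempty(ellipsoids)
  assert_pose_has_detector(pose)
  if (sampling <= 0) validation_error("sampling must be > 0 mm")
  sp <- sampling / pose$pixel_pitch
  best <- 0
  for (e in ellipsoids$members) {
    w <- detector_window(pose, bbox_corners(ellipsoid_bbox(e)), margin_px = sp + 0.5)
    if (is.null(w)) next
    g <- window_grid(w, sp)
    D <- detector_directions(pose, g$us, g$vs)
    best <- max(best, path_lengths(e, pose$source, D))
  }
  best
}

#' Summed-overlap view metric (diagnostic)
#'
#' As [q_atten_rendered()], but per-pixel path lengths are summed over
#' objects before the maximum is taken, so overlapping projections
#' accumulate. Always `>=` the rendered metric; the difference quantifies
#' the overlap assumption behind the per-object-maximum semantics.
#'
#' @inheritParams q_atten_rendered
#' @return Metric value in mm.
#' @export
q_atten_summed <- function(ellipsoids, pose, sampling = 1) {
  assert_scene_nonempty(ellipsoids)
  assert_pose_has_detector(pose)
  if (sampling <= 0) validation_error("sampling must be > 0 mm")
  sp <- sampling / pose$pixel_pitch
  corners <- do.call(rbind, lapply(ellipsoids$members,
                                   function(e) bbox_corners(ellipsoid_bbox(e))))
  w <- detector_window(pose, corners, margin_px = sp + 0.5)
  if (is.null(w)) return(0)
  g <- window_grid(w, sp)
  D <- detector_directions(pose, g$us, g$vs)
  total <- numeric(nrow(D))
  for (e in ellipsoids$members) {
    total <- total + path_lengths(e, pose$source, D)
  }
  max(total, 0)
}

# ---- voxel mask baseline ---------------------------------------------------

#' Binary voxel mask
#'
#' @param origin Lower corner of the grid, world mm.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param occupancy 3D logical array.
#' @return Object of class `voxel_mask`.
#' @export
voxel_mask <- function(origin, voxel_size, occupancy) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3 ||
        length(occupancy) == 0) {
    validation_error("occupancy must be a non-empty 3D array")
  }
  stop_if_not_scalar_number(voxel_size, "voxel_size")
  if (voxel_size <= 0) validation_error("voxel_size must be > 0")
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 occupancy = (occupancy != 0)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("voxel mask: %d x %d x %d @ %g mm, %d occupied\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$occupancy)))
  invisible(x)
}

#' Voxelize an ellipsoid set into a binary mask
#'
#' A voxel is occupied when its center lies inside any ellipsoid. The grid
#' covers the joint bounding box of all ellipsoids plus `padding` on every
#' side.
#'
#' @param ellipsoids An [ellipsoid_set()] with at least one member.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param padding Extra margin around the joint bounding box, mm.
#' @return A [voxel_mask()].
#' @export
voxelize <- function(ellipsoids, voxel_size = 1, padding = 5) {
  assert_scene_nonempty(ellipsoids)
  if (voxel_size <= 0) validation_error("voxel_size must be > 0")
  boxes <- lapply(ellipsoids$members, ellipsoid_bbox)
  lo <- apply(do.call(rbind, lapply(boxes, function(b) b["lo", ])), 2, min) - padding
  hi <- apply(do.call(rbind, lapply(boxes, function(b) b["hi", ])), 2, max) + padding
  n <- pmax(ceiling((hi - lo) / voxel_size), 1)
  occ <- array(FALSE, dim = n)
  for (e in ellipsoids$members) {
    b <- ellipsoid_bbox(e)
    i0 <- pmax(floor((b["lo", ] - lo) / voxel_size) + 1, 1)
    i1 <- pmin(ceiling((b["hi", ] - lo) / voxel_size), n)
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    ctr <- expand.grid(x = lo[1] + (ix - 0.5) * voxel_size,
                       y = lo[2] + (iy - 0.5) * voxel_size,
                       z = lo[3] + (iz - 0.5) * voxel_size)
    W <- sweep(as.matrix(ctr), 2, e$mu)
    inside <- rowSums((W %*% e$sigma_inv) * W) <= 1
    occ[ix, iy, iz] <- occ[ix, iy, iz] |
      array(inside, dim = c(length(ix), length(iy), length(iz)))
  }
  voxel_mask(lo, voxel_size, occ)
}

#' Voxel-mask view metric: maximum radiological path
#'
#' Casts a source-to-pixel ray for every sampled detector position inside the
#' mask's projected footprint and accumulates the exact intersection length
#' with occupied voxels (Amanatides-Woo grid traversal); returns the maximum
#' over rays. This is the segmentation-style baseline the analytic scorer is
#' compared against.
#'
#' @param mask A [voxel_mask()].
#' @param pose A `pmaa_pose` with detector dimensions.
#' @param sampling Detector sampling spacing in mm.
#' @return Metric value in mm.
#' @export
q_atten_voxel <- function(mask, pose, sampling = 1) {
  if (!inherits(mask, "voxel_mask")) validation_error("expected a voxel_mask")
  assert_pose_has_detector(pose)
  if (sampling <= 0) validation_error("sampling must be > 0 mm")
  d <- dim(mask$occupancy)
  corners <- bbox_corners(rbind(lo = mask$origin,
                                hi = mask$origin + d * mask$voxel_size))
  sp <- sampling / pose$pixel_pitch
  w <- detector_window(pose, corners, margin_px = sp + 0.5)
  if (is.null(w)) return(0)
  g <- window_grid(w, sp)
  D <- detector_directions(pose, g$us, g$vs)
  bump_counter("voxel_rays", nrow(D))
  out <- .ray_grid_paths(as.logical(mask$occupancy), as.integer(d),
                         mask$origin, mask$voxel_size, pose$source, D)
  max(out, 0)
}

# ---- metric maps -----------------------------------------------------------

new_metric_map <- function(theta_values, delta_values, values, method) {
  method <- match.arg(method, c("analytic", "rendered", "voxel"))
  values <- as.matrix(values)
  if (any(values < 0) || any(!is.finite(values))) {
    validation_error("metric map values must be finite and >= 0")
  }
  if (any(diff(theta_values) <= 0) || any(diff(delta_values) <= 0)) {
    validation_error("metric map grids must be strictly increasing")
  }
  if (!all(dim(values) == c(length(delta_values), length(theta_values)))) {
    validation_error("metric map shape must be |delta| x |theta|")
  }
  structure(list(theta_values = as.numeric(theta_values),
                 delta_values = as.numeric(delta_values),
                 values = values, method = method),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric map (%s): %d tilts x %d orbital angles, range [%.2f, %.2f] mm\n",
              x$method, length(x$delta_values), length(x$theta_values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Score every candidate pose on the (theta', delta) grid
#'
#' Fills the |delta| x |theta'| matrix of per-view metrics using the chosen
#' scorer. The grids come from the geometry (defaults: theta' in
#' \[-100, 100\], delta in \[-30, 30\] degrees).
#'
#' @param x An [ellipsoid_set()], or a [voxel_mask()] when `method =
#'   "voxel"`. An ellipsoid set passed with `method = "voxel"` is voxelized
#'   first at `voxel_size`.
#' @param geom A [carm_geometry()] supplying the angular grids and detector.
#' @param method `"analytic"`, `"rendered"` or `"voxel"`.
#' @param sampling Detector sampling in mm (rendered/voxel scorers).
#' @param voxel_size,padding Voxelization parameters, mm.
#' @return A `metric_map`.
#' @export
metric_map <- function(x, geom, method = c("analytic", "rendered", "voxel"),
                       sampling = 1, voxel_size = 1, padding = 5) {
  method <- match.arg(method)
  thetas <- theta_grid(geom)
  deltas <- delta_grid(geom)
  scorer <- switch(method,
    analytic = {
      assert_scene_nonempty(x)
      function(pose) q_atten_analytic(x, pose)
    },
    rendered = {
      assert_scene_nonempty(x)
      function(pose) q_atten_rendered(x, pose, sampling)
    },
    voxel = {
      mask <- if (inherits(x, "voxel_mask")) x else voxelize(x, voxel_size, padding)
      function(pose) q_atten_voxel(mask, pose, sampling)
    })
  values <- matrix(0, length(deltas), length(thetas))
  for (j in seq_along(deltas)) {
    for (i in seq_along(thetas)) {
      values[j, i] <- scorer(make_pose(geom, thetas[i], deltas[j]))
    }
    pmaa_log("metric map [%s]: tilt %g deg done (%d/%d)",
             method, deltas[j], j, length(deltas))
  }
  new_metric_map(thetas, deltas, values, method)
}

#' Per-object metric maps
#'
#' One metric map per ellipsoid (same grid and method), used to decompose the
#' trajectory objective into individual implant contributions.
#'
#' @inheritParams metric_map
#' @param ellipsoids An [ellipsoid_set()].
#' @return A list of `metric_map` objects, one per member, in set order.
#' @export
per_object_metric_maps <- function(ellipsoids, geom,
                                   method = c("analytic", "rendered", "voxel"),
                                   sampling = 1, voxel_size = 1, padding = 5) {
  assert_scene_nonempty(ellipsoids)
  lapply(ellipsoids$members, function(e) {
    metric_map(ellipsoid_set(list(e)), geom, method,
               sampling = sampling, voxel_size = voxel_size, padding = padding)
  })
}

#' Do all ellipsoids project inside the detector for a pose?
#'
#' True when the projections of every ellipsoid's bounding-box corners fall
#' within the physical detector area. Comparisons between the analytic
#' scorer (which has no field-of-view test) and the detector-limited scorers
#' are only meaningful for such poses.
#'
#' @param ellipsoids An [ellipsoid_set()].
#' @param pose A `pmaa_pose` with detector dimensions.
#' @param margin Margin in pixels required inside the detector edge.
#' @return Logical scalar.
#' @export
all_in_field <- function(ellipsoids, pose, margin = 0) {
  assert_scene_nonempty(ellipsoids)
  assert_pose_has_detector(pose)
  for (e in ellipsoids$members) {
    uv <- project(pose, bbox_corners(ellipsoid_bbox(e)))
    if (min(uv[, 1]) < margin || max(uv[, 1]) > pose$detector_cols - margin ||
          min(uv[, 2]) < margin || max(uv[, 2]) > pose$detector_rows - margin) {
      return(FALSE)
    }
  }
  TRUE
}

# ---- metric map file format ------------------------------------------------

#' Write or read a metric map as delimited text
#'
#' First row: the theta' grid. Each following row: the delta value followed
#' by that tilt's metric values. Full precision (`%.17g`), so write -> read
#' -> write is byte-identical. A JSON sidecar `<path>.json` records the
#' scoring method and a geometry fingerprint.
#'
#' @param map A `metric_map`.
#' @param path Output text file; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @param geom Optional [carm_geometry()] fingerprinted in the sidecar.
#' @return `read_metric_map()` returns a `metric_map`; `write_metric_map()`
#'   returns `path` invisibly.
#' @export
write_metric_map <- function(map, path, geom = NULL) {
  lines <- c(paste(fmt_full(map$theta_values), collapse = " "),
             vapply(seq_along(map$delta_values), function(j) {
               paste(fmt_full(c(map$delta_values[j], map$values[j, ])),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  sidecar <- list(method = map$method,
                  geometry_hash = if (is.null(geom)) NA else geometry_hash(geom))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' @rdname write_metric_map
#' @export
read_metric_map <- function(path) {
  if (!file.exists(path)) io_error(sprintf("metric map file not found: %s", path))
  lines <- readLines(path)
  thetas <- scan(text = lines[1], quiet = TRUE)
  body <- do.call(rbind, lapply(lines[-1], function(l) scan(text = l, quiet = TRUE)))
  method <- "analytic"
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    method <- jsonlite::fromJSON(sidecar_path)$method
  }
  new_metric_map(thetas, body[, 1], body[, -1, drop = FALSE], method)
}
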