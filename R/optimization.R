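# Trajectory objective and tilt selection.
#
# Q(delta) = max over theta' of the per-view metric: the worst view of the
# orbit at tilt delta. The selected tilt is not the global argmin but the
# smallest tilt achieving 95% (configurable) of the possible reduction from
# the worst to the best trajectory score — large tilts risk table collisions
# and degrade geometric calibration, so the smallest sufficient tilt is
# preferred; fraction = 1 recovers the plain min-max argmin.

#' Collapse a metric map to the trajectory objective
#'
#' `Q(delta) = max over theta' of q(theta', delta)`. When per-object maps
#' are supplied, their curves are computed identically and the collective
#' curve must equal their elementwise maximum (validated).
#'
#' @param map A `metric_map`.
#' @param per_object_maps Optional list of per-object `metric_map`s on the
#'   same grid (see [per_object_metric_maps()]).
#' @return An `objective_curve` with `delta_values`, `q_values` and
#'   optionally `per_object_curves` (M x |delta| matrix).
#' @export
objective_curve <- function(map, per_object_maps = NULL) {
  if (!inherits(map, "metric_map")) validation_error("expected a metric_map")
  q <- apply(map$values, 1, max)
  per <- NULL
  if (!is.null(per_object_maps)) {
    per <- do.call(rbind, lapply(per_object_maps, function(m) {
      if (!isTRUE(all.equal(m$delta_values, map$delta_values))) {
        validation_error("per-object maps must share the collective map's tilt grid")
      }
      apply(m$values, 1, max)
    }))
    if (max(abs(q - apply(per, 2, max))) > 1e-12 * max(q, 1)) {
      validation_error("collective objective does not equal the per-object maximum")
    }
  }
  structure(list(delta_values = map$delta_values, q_values = q,
                 per_object_curves = per),
            class = "objective_curve")
}

#' @export
print.objective_curve <- function(x, ...) {
  cat(sprintf("objective curve: %d tilts, Q in [%.2f, %.2f] mm\n",
              length(x$delta_values), min(x$q_values), max(x$q_values)))
  invisible(x)
}

#' Select the scan tilt by the fractional-improvement heuristic
#'
#' The threshold is `q_max - fraction * (q_max - q_min)`; among grid tilts
#' whose objective is at or below it, the one with the smallest magnitude is
#' selected (ties broken toward positive tilt). A flat curve — no possible
#' improvement — selects the grid tilt nearest 0, the standard untilted
#' procedure. With `fraction = 1` the rule reduces to the min-max argmin.
#'
#' @param curve An [objective_curve()].
#' @param fraction Fraction of the maximum possible reduction to require,
#'   in (0, 1]; default 0.95.
#' @return A `tilt_selection` with `delta_star` (degrees), `q_at_star`,
#'   `q_min`, `q_max`, `threshold` (mm) and `fraction`.
#' @export
select_tilt <- function(curve, fraction = 0.95) {
  if (!inherits(curve, "objective_curve") || length(curve$delta_values) == 0) {
    validation_error("expected a non-empty objective_curve")
  }
  stop_if_not_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    validation_error("fraction must be in (0, 1]")
  }
  d <- curve$delta_values
  q <- curve$q_values
  q_min <- min(q)
  q_max <- max(q)
  # a curve flat to floating-point noise offers no real improvement
  if (q_max - q_min <= 1e-12 * max(abs(q_max), 1)) {
    threshold <- q_max
    eligible <- seq_along(d)
  } else {
    threshold <- q_max - fraction * (q_max - q_min)
    eligible <- which(q <= threshold)
  }
  # smallest |delta| wins; exact magnitude ties go to the positive tilt
  ord <- eligible[order(abs(d[eligible]), -sign(d[eligible]))]
  k <- ord[1]
  structure(list(delta_star = d[k], q_at_star = q[k],
                 q_min = q_min, q_max = q_max,
                 threshold = threshold, fraction = fraction),
            class = "tilt_selection")
}

#' @export
print.tilt_selection <- function(x, ...) {
  cat(sprintf("selected tilt delta* = %g deg (Q = %.2f mm; curve [%.2f, %.2f], threshold %.2f mm, fraction %g)\n",
              x$delta_star, x$q_at_star, x$q_min, x$q_max, x$threshold,
              x$fraction))
  invisible(x)
}

#' Run the full tilt-planning pipeline
#'
#' Accepts any one input modality and executes the remaining stages:
#' 2D keypoint observations (an [observe_scene()] result, or a list with
#' `proposals_A`, `proposals_B`, `poses`) are triangulated and fitted;
#' a synthetic scene or a list of `screw_endpoints` is fitted; an
#' [ellipsoid_set()] is scored directly. Scoring uses the analytic method
#' by default, the objective is collapsed over the orbit, and the tilt is
#' selected by the fractional-improvement heuristic.
#'
#' @param input An observation set, list of `screw_endpoints`, `pmaa_scene`,
#'   or [ellipsoid_set()].
#' @param geom A [carm_geometry()].
#' @param method Scoring method, `"analytic"` (default), `"rendered"` or
#'   `"voxel"`.
#' @param fraction Improvement fraction for [select_tilt()].
#' @param minor_full_axis Minor full axis for ellipsoid fitting, mm.
#' @param match_tolerance Triangulation gate, mm.
#' @param sampling Detector sampling for rendered/voxel scoring, mm.
#' @param voxel_size,padding Voxelization parameters, mm.
#' @param per_object Also compute per-object objective curves.
#' @return A `pmaa_report`: `ellipsoids`, `map`, `curve`, `selection`.
#' @export
run_pmaa <- function(input, geom,
                     method = c("analytic", "rendered", "voxel"),
                     fraction = 0.95, minor_full_axis = 5,
                     match_tolerance = 5, sampling = 1,
                     voxel_size = 1, padding = 5, per_object = FALSE) {
  method <- match.arg(method)
  stage <- function(name, expr) {
    tryCatch(expr, pmaa_error = function(e) {
      pmaa_error(sprintf("[%s] %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  es <- stage("localize", {
    if (inherits(input, "ellipsoid_set")) {
      input
    } else if (inherits(input, "pmaa_scene")) {
      scene_to_ellipsoids(input, minor_full_axis = minor_full_axis)
    } else if (is.list(input) && !is.null(input$proposals_A)) {
      eps <- match_and_triangulate(input$proposals_A, input$proposals_B,
                                   input$poses[[1]], input$poses[[2]],
                                   tolerance = match_tolerance)
      ellipsoid_set(lapply(eps, function(s) {
        fit_ellipsoid(s$head, s$tip, minor_full_axis)
      }))
    } else if (is.list(input) && length(input) &&
                 all(vapply(input, inherits, logical(1), "screw_endpoints"))) {
      ellipsoid_set(lapply(input, function(s) {
        fit_ellipsoid(s$head, s$tip, minor_full_axis)
      }))
    } else {
      validation_error("unrecognized input modality")
    }
  })
  pmaa_log("pipeline: %d ellipsoid(s) in scene", length(es))
  map <- stage("score", metric_map(es, geom, method, sampling = sampling,
                                   voxel_size = voxel_size, padding = padding))
  per_maps <- if (per_object && length(es) > 0) {
    stage("score", per_object_metric_maps(es, geom, method, sampling = sampling,
                                          voxel_size = voxel_size,
                                          padding = padding))
  }
  curve <- stage("objective", objective_curve(map, per_maps))
  sel <- stage("select", select_tilt(curve, fraction))
  pmaa_log("pipeline: delta* = %g deg", sel$delta_star)
  structure(list(ellipsoids = es, map = map, curve = curve, selection = sel),
            class = "pmaa_report")
}

#' @export
print.pmaa_report <- function(x, ...) {
  cat("P-MAA report\n")
  cat(sprintf("  %d ellipsoid(s); %s scoring\n", length(x$ellipsoids),
              x$map$method))
  print(x$selection)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Keys: `delta_star_deg`, `fraction`, `q_min_mm`, `q_max_mm`,
#' `threshold_mm`, `ellipsoids` (mu/sigma records) and `objective`
#' (`delta`, `Q`). Writing the same report twice is byte-identical.
#'
#' @param report A `pmaa_report` from [run_pmaa()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  sel <- report$selection
  out <- list(
    delta_star_deg = sel$delta_star,
    fraction = sel$fraction,
    q_min_mm = sel$q_min,
    q_max_mm = sel$q_max,
    threshold_mm = sel$threshold,
    ellipsoids = lapply(report$ellipsoids$members, function(e) {
      list(mu = e$mu, sigma = lapply(1:3, function(i) e$sigma[i, ]))
    }),
    objective = list(delta = report$curve$delta_values,
                     Q = report$curve$q_values)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
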