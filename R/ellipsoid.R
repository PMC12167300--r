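# Ellipsoidal implant surrogates and exact ray/chord path lengths.
#
# An implant is modeled as the solid { x : (x - mu)' Sigma^-1 (x - mu) <= 1 };
# the eigenvalues of Sigma are squared semi-axis lengths and its eigenvectors
# the axis directions. For a screw, the major full axis equals the head-tip
# distance and the two minor full axes default to 5 mm, a typical screw
# diameter (clinical screws run about 4-7.5 mm).

#' Ellipsoid surrogate
#'
#' @param mu Centroid, 3-vector mm.
#' @param sigma Symmetric positive-definite 3x3 shape matrix, mm^2; its
#'   eigenvalues are squared semi-axis lengths.
#' @return Object of class `ellipsoid` with fields `mu`, `sigma` and the
#'   cached inverse `sigma_inv`.
#' @export
ellipsoid <- function(mu, sigma) {
  mu <- as.numeric(mu)
  sigma <- matrix(as.numeric(sigma), 3, 3)
  if (length(mu) != 3 || !all(is.finite(mu)) || !all(is.finite(sigma))) {
    validation_error("ellipsoid needs a finite 3-vector mu and 3x3 sigma")
  }
  if (max(abs(sigma - t(sigma))) > 1e-9) {
    validation_error("sigma must be symmetric (within 1e-9)")
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) validation_error("sigma must be positive definite")
  if (any(sqrt(ev) > 200)) {
    validation_error("semi-axes exceed 200 mm; not a plausible surgical implant")
  }
  structure(list(mu = mu, sigma = sigma, sigma_inv = solve(sigma)),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  ax <- sqrt(eigen(x$sigma, symmetric = TRUE, only.values = TRUE)$values)
  cat(sprintf("ellipsoid: mu (%.2f, %.2f, %.2f) mm, semi-axes %.2f/%.2f/%.2f mm\n",
              x$mu[1], x$mu[2], x$mu[3], ax[1], ax[2], ax[3]))
  invisible(x)
}

#' Ordered set of ellipsoids
#'
#' @param members List of [ellipsoid()] objects; the list index is the object
#'   identity.
#' @return Object of class `ellipsoid_set`.
#' @export
ellipsoid_set <- function(members = list()) {
  if (!all(vapply(members, inherits, logical(1), "ellipsoid"))) {
    validation_error("all members must be ellipsoid objects")
  }
  structure(list(members = members), class = "ellipsoid_set")
}

#' @export
length.ellipsoid_set <- function(x) length(x$members)

#' @export
print.ellipsoid_set <- function(x, ...) {
  cat(sprintf("ellipsoid set with %d member(s)\n", length(x)))
  for (e in x$members) print(e)
  invisible(x)
}

#' Fit an implant ellipsoid to triangulated head and tip points
#'
#' The centroid is the head-tip midpoint, the major full axis spans the
#' head-tip distance, and the two minor full axes are `minor_full_axis`
#' (default 5 mm, a common screw diameter).
#'
#' @param head,tip 3-vectors, mm; must be more than 1 mm apart.
#' @param minor_full_axis Minor full-axis length in mm.
#' @return An [ellipsoid()].
#' @examples
#' e <- fit_ellipsoid(c(0, 0, 0), c(0, 0, 50))
#' e$sigma  # diag(6.25, 6.25, 625)
#' @export
fit_ellipsoid <- function(head, tip, minor_full_axis = 5) {
  head <- as.numeric(head)
  tip <- as.numeric(tip)
  stop_if_not_scalar_number(minor_full_axis, "minor_full_axis")
  if (minor_full_axis <= 0) validation_error("minor_full_axis must be > 0")
  L <- norm3(head - tip)
  if (!is.finite(L) || L <= 1) {
    validation_error("degenerate screw: head and tip are within 1 mm")
  }
  u <- (head - tip) / L
  a2 <- (L / 2)^2
  w2 <- (minor_full_axis / 2)^2
  # Sigma = a^2 uu' + w^2 (I - uu'): major axis along u, isotropic minor axes
  sigma <- a2 * tcrossprod(u) + w2 * (diag(3) - tcrossprod(u))
  ellipsoid((head + tip) / 2, sigma)
}

#' Central chord length of an ellipsoid along a direction
#'
#' The chord through the centroid along unit direction `d` has length
#' `2 / sqrt(d' Sigma^-1 d)`; it is the longest chord of the ellipsoid among
#' all chords parallel to `d`. One call increments the `chord_evals` counter
#' by one (see [path_counters()]).
#'
#' @param e An [ellipsoid()].
#' @param direction Unit 3-vector.
#' @return Chord length in mm (strictly positive).
#' @export
chord_length <- function(e, direction) {
  direction <- as.numeric(direction)
  if (length(direction) != 3 || abs(norm3(direction) - 1) > 1e-9) {
    validation_error("direction must be a unit 3-vector")
  }
  bump_counter("chord_evals")
  2 / sqrt(sum(direction * (e$sigma_inv %*% direction)))
}

#' Exact intersection length of a ray with a solid ellipsoid
#'
#' Substituting `x = o + t d` into the ellipsoid inequality gives a quadratic
#' in `t`; the intersection length is the span of real roots clipped to
#' `t >= 0` (the ray is a half-line). Returns 0 for a miss or tangency.
#'
#' @param e An [ellipsoid()].
#' @param ray A [ray3d()].
#' @return Path length in mm (>= 0).
#' @export
ray_path_length <- function(e, ray) {
  drop(path_lengths(e, ray$origin, matrix(ray$direction, 1, 3)))
}

# vectorized ray-ellipsoid path lengths for unit direction rows of D;
# increments the rendered-ray counter by nrow(D)
path_lengths <- function(e, origin, D) {
  bump_counter("rendered_rays", nrow(D))
  w <- origin - e$mu
  Mi <- e$sigma_inv
  A <- rowSums((D %*% Mi) * D)
  B <- 2 * drop(D %*% (Mi %*% w))
  C <- sum(w * (Mi %*% w)) - 1
  disc <- B^2 - 4 * A * C
  out <- numeric(nrow(D))
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- (-B[hit] - sq) / (2 * A[hit])
    t2 <- (-B[hit] + sq) / (2 * A[hit])
    t1 <- pmax(t1, 0)
    out[hit] <- pmax(t2 - t1, 0)
  }
  out
}

#' Render the path-length image of an ellipsoid in a pose
#'
#' For every sampled detector pixel center, the exact [ray_path_length()] of
#' the source-to-pixel ray, in mm. This is the per-pixel reference against
#' which the analytic centroid-chord scorer is compared.
#'
#' @param e An [ellipsoid()].
#' @param pose A `pmaa_pose` carrying detector dimensions.
#' @param row_stride,col_stride Sample every n-th pixel (>= 1).
#' @return Matrix of mm values (sampled rows x sampled columns).
#' @export
render_path_length_image <- function(e, pose, row_stride = 1, col_stride = 1) {
  if (row_stride < 1 || col_stride < 1) {
    validation_error("strides must be >= 1")
  }
  if (is.na(pose$detector_rows) || is.na(pose$detector_cols)) {
    validation_error("pose carries no detector dimensions; rendering needs them")
  }
  us <- seq(0.5, pose$detector_cols - 0.5, by = col_stride)
  vs <- seq(0.5, pose$detector_rows - 0.5, by = row_stride)
  D <- detector_directions(pose, us, vs)
  vals <- path_lengths(e, pose$source, D)
  matrix(vals, nrow = length(vs), ncol = length(us), byrow = TRUE)
}

# Tight axis-aligned bounding box of an ellipsoid: mu +/- sqrt(diag(Sigma))
ellipsoid_bbox <- function(e) {
  half <- sqrt(diag(e$sigma))
  rbind(lo = e$mu - half, hi = e$mu + half)
}

bbox_corners <- function(bbox) {
  as.matrix(expand.grid(x = bbox[, 1], y = bbox[, 2], z = bbox[, 3]))
}

# ---- ellipsoid set JSON ----------------------------------------------------

#' Read or write an ellipsoid set as JSON
#'
#' A JSON array of records. Each record is either
#' `{"mu": [x,y,z], "sigma": [[...3x3...]]}` (mm / mm^2) or
#' `{"head": [...], "tip": [...]}` (optionally with `"minor_full_axis"`),
#' which is fitted on load via [fit_ellipsoid()].
#'
#' @param path JSON file path.
#' @param es An [ellipsoid_set()] (for writing).
#' @param minor_full_axis Minor full axis used for head/tip records, mm.
#' @return `read_ellipsoids()` returns an [ellipsoid_set()];
#'   `write_ellipsoids()` returns `path` invisibly.
#' @export
read_ellipsoids <- function(path, minor_full_axis = 5) {
  if (!file.exists(path)) io_error(sprintf("ellipsoid file not found: %s", path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  members <- lapply(recs, function(r) {
    if (!is.null(r$mu)) {
      ellipsoid(unlist(r$mu), do.call(rbind, lapply(r$sigma, unlist)))
    } else if (!is.null(r$head)) {
      fit_ellipsoid(unlist(r$head), unlist(r$tip),
                    if (is.null(r$minor_full_axis)) minor_full_axis
                    else r$minor_full_axis)
    } else {
      validation_error("ellipsoid record needs either mu/sigma or head/tip")
    }
  })
  ellipsoid_set(members)
}

#' @rdname read_ellipsoids
#' @export
write_ellipsoids <- function(es, path) {
  recs <- lapply(es$members, function(e) {
    list(mu = e$mu, sigma = lapply(1:3, function(i) e$sigma[i, ]))
  })
  jsonlite::write_json(recs, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}
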