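# Seeded synthetic surgical scenes and scout-view keypoint observations.
#
# Scenes emulate randomly instrumented pedicle-screw fields: screw lengths
# uniform on 35-65 mm and shaft diameters uniform on 4-7.5 mm (typical
# clinical ranges), placed uniformly inside a volume around the isocenter
# with a minimum centroid separation. Observations emulate the output of a
# 2D keypoint detector on two scout views: projected head/tip pixels with
# isotropic Gaussian noise, whole-object dropouts, spurious head/tip pairs,
# and per-view shuffled object identities (so correspondence is unknown).

default_scene_bounds <- function() {
  rbind(lo = c(-60, -60, -60), hi = c(60, 60, 60))
}

#' Generate a random pedicle-screw scene
#'
#' Screws are placed by rejection sampling: centroid uniform in `bounds`,
#' orientation uniform on the sphere (or biased anterior-posterior in the
#' `"clinical"` preset), length and diameter uniform in their ranges; a
#' candidate is rejected unless both endpoints lie inside `bounds` and its
#' centroid is at least `min_separation` from all previously placed screws.
#' The `"paired"` placement arranges screws in bilateral left/right pairs at
#' successive levels along the orbit axis, mimicking lumbar pedicle
#' instrumentation.
#'
#' @param n_screws Number of screws (>= 0).
#' @param length_range Screw length range, mm.
#' @param diameter_range Screw diameter range, mm.
#' @param bounds 2 x 3 matrix `rbind(lo, hi)`, mm; default a 120 mm cube
#'   centered on the isocenter.
#' @param min_separation Minimum pairwise centroid distance, mm.
#' @param seed Integer seed; the scene is a pure function of the arguments
#'   and this seed.
#' @param placement `"uniform"` (random placement) or `"paired"` (bilateral
#'   pairs per vertebral level).
#' @param orientation `"uniform"` (uniform on the sphere) or `"clinical"`
#'   (anterior-posterior within about 30 degrees).
#' @return A `pmaa_scene`: list of screws (`head`, `tip`, `diameter`),
#'   `volume_bounds`, `seed`.
#' @export
generate_scene <- function(n_screws,
                           length_range = c(35, 65),
                           diameter_range = c(4, 7.5),
                           bounds = default_scene_bounds(),
                           min_separation = 20,
                           seed = 1,
                           placement = c("uniform", "paired"),
                           orientation = c("uniform", "clinical")) {
  placement <- match.arg(placement)
  orientation <- match.arg(orientation)
  if (n_screws < 0) validation_error("n_screws must be >= 0")
  if (diff(length_range) < 0 || diff(diameter_range) < 0 ||
        length_range[1] <= 1) {
    validation_error("invalid length/diameter ranges")
  }
  bounds <- matrix(as.numeric(bounds), 2, 3,
                   dimnames = list(c("lo", "hi"), NULL))
  with_seed(seed, {
    screws <- list()
    centroids <- matrix(numeric(0), 0, 3)
    for (k in seq_len(n_screws)) {
      placed <- FALSE
      # size is drawn once per screw (outside the placement loop) so the
      # length/diameter marginals stay uniform under rejection
      L <- runif(1, length_range[1], length_range[2])
      diam <- runif(1, diameter_range[1], diameter_range[2])
      for (attempt in seq_len(10000)) {
        u <- sample_direction(orientation)
        ctr <- if (placement == "paired") {
          paired_centroid(k, n_screws, bounds) + rnorm(3, sd = 2)
        } else {
          runif(3, bounds["lo", ], bounds["hi", ])
        }
        head <- ctr + (L / 2) * u
        tip <- ctr - (L / 2) * u
        inside <- all(head >= bounds["lo", ] & head <= bounds["hi", ] &
                        tip >= bounds["lo", ] & tip <= bounds["hi", ])
        sep_ok <- nrow(centroids) == 0 ||
          min(sqrt(rowSums(sweep(centroids, 2, ctr)^2))) >= min_separation
        if (inside && sep_ok) {
          screws[[k]] <- list(head = head, tip = tip, diameter = diam)
          centroids <- rbind(centroids, ctr)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        computation_error(sprintf(
          "scene generation infeasible: screw %d not placed in 10000 attempts", k))
      }
    }
    structure(list(screws = screws, volume_bounds = bounds,
                   seed = as.integer(seed)),
              class = "pmaa_scene")
  })
}

# uniform on the sphere via uniform z and azimuth; the clinical preset draws
# the axis within ~30 degrees of the anterior-posterior (-y) direction
sample_direction <- function(orientation) {
  if (orientation == "clinical") {
    cap <- cos(deg2rad(30))
    z <- runif(1, cap, 1)           # polar angle about -y within 30 deg
    phi <- runif(1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    # frame with pole at -y
    drop(cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)) %*%
           c(r * cos(phi), r * sin(phi), z))
  } else {
    z <- runif(1, -1, 1)
    phi <- runif(1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    c(r * cos(phi), r * sin(phi), z)
  }
}

# bilateral pairs per level: levels stacked along +z (cranio-caudal, up to
# ~32 mm apart as in lumbar vertebrae), left/right offset along x
paired_centroid <- function(k, n_screws, bounds) {
  n_levels <- max(ceiling(n_screws / 2), 1)
  level <- (k - 1) %/% 2
  side <- if (k %% 2 == 1) -1 else 1
  span <- bounds["hi", 3] - bounds["lo", 3]
  spacing <- min(32, span / n_levels)
  z0 <- mean(bounds[, 3]) - (n_levels - 1) * spacing / 2
  c(side * 14, 0, z0 + level * spacing)
}

#' @export
print.pmaa_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d screw(s), seed %d\n",
              length(x$screws), x$seed))
  invisible(x)
}

#' Observe a scene in two scout views
#'
#' Projects each screw's head and tip through both poses and emulates a
#' keypoint detector's output: isotropic Gaussian pixel noise, whole-object
#' dropouts per view, spurious head/tip pairs uniform on the detector, and
#' per-view random permutation of object identifiers (correspondence across
#' views is genuinely unknown). The mapping from per-view object ids back to
#' scene screws is kept in the `truth_A` / `truth_B` attributes for
#' evaluation.
#'
#' @param scene A [generate_scene()] result.
#' @param pose_A,pose_B The two scout `pmaa_pose`s.
#' @param noise_sigma Keypoint noise standard deviation, pixels.
#' @param dropout_rate Probability a screw is missed entirely in a view.
#' @param spurious_rate Per-screw probability of injecting a spurious
#'   head/tip pair into a view.
#' @param seed Integer seed.
#' @return An `observation_set`: `proposals_A`, `proposals_B` (keypoint data
#'   frames), `poses`, and the noise parameters.
#' @export
observe_scene <- function(scene, pose_A, pose_B, noise_sigma = 0,
                          dropout_rate = 0, spurious_rate = 0, seed = 1) {
  if (dropout_rate < 0 || dropout_rate > 1 ||
        spurious_rate < 0 || spurious_rate > 1) {
    validation_error("rates must be in [0, 1]")
  }
  if (noise_sigma < 0) validation_error("noise_sigma must be >= 0")
  n <- length(scene$screws)
  with_seed(seed, {
    one_view <- function(pose, view_id) {
      kept <- if (n > 0) which(runif(n) >= dropout_rate) else integer(0)
      rows <- list()
      for (i in kept) {
        s <- scene$screws[[i]]
        for (kind in c("head", "tip")) {
          uv <- project(pose, s[[kind]]) + rnorm(2, sd = noise_sigma)
          rows[[length(rows) + 1]] <- data.frame(
            view_id = view_id, scene_index = i, kind = kind,
            u = uv[1], v = uv[2], score = 1)
        }
      }
      n_spur <- if (n > 0) rbinom(1, n, spurious_rate) else 0L
      for (k in seq_len(n_spur)) {
        for (kind in c("head", "tip")) {
          rows[[length(rows) + 1]] <- data.frame(
            view_id = view_id, scene_index = -k, kind = kind,
            u = runif(1, 0, pose$detector_cols),
            v = runif(1, 0, pose$detector_rows), score = 0.5)
        }
      }
      df <- if (length(rows)) do.call(rbind, rows) else {
        data.frame(view_id = character(0), scene_index = integer(0),
                   kind = character(0), u = numeric(0), v = numeric(0),
                   score = numeric(0))
      }
      # shuffle per-view object identities (negative indices mark spurious)
      src <- unique(df$scene_index)
      ids <- if (length(src)) paste0(view_id, sample(length(src))) else character(0)
      truth <- data.frame(object_id = ids,
                          scene_index = ifelse(src > 0, src, NA_integer_))
      df$object_id <- truth$object_id[match(df$scene_index, src)]
      df$scene_index <- NULL
      list(df = df[, c("view_id", "object_id", "kind", "u", "v", "score")],
           truth = truth)
    }
    A <- one_view(pose_A, "A")
    B <- one_view(pose_B, "B")
    structure(list(proposals_A = A$df, proposals_B = B$df,
                   poses = list(pose_A, pose_B),
                   noise_sigma = noise_sigma, dropout_rate = dropout_rate,
                   spurious_rate = spurious_rate, seed = as.integer(seed),
                   truth_A = A$truth, truth_B = B$truth),
              class = "observation_set")
  })
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation set: %d + %d keypoints (sigma %g px, dropout %g, spurious %g)\n",
              nrow(x$proposals_A), nrow(x$proposals_B), x$noise_sigma,
              x$dropout_rate, x$spurious_rate))
  invisible(x)
}

#' Ground-truth ellipsoids of a scene
#'
#' Fits one ellipsoid per screw via [fit_ellipsoid()], in scene order.
#'
#' @param scene A `pmaa_scene`.
#' @param minor_from_diameter Use each screw's true diameter as the minor
#'   full axis instead of the fixed value.
#' @param minor_full_axis Fixed minor full axis, mm (ignored when
#'   `minor_from_diameter` is set).
#' @return An [ellipsoid_set()].
#' @export
scene_to_ellipsoids <- function(scene, minor_from_diameter = FALSE,
                                minor_full_axis = 5) {
  ellipsoid_set(lapply(scene$screws, function(s) {
    fit_ellipsoid(s$head, s$tip,
                  if (minor_from_diameter) s$diameter else minor_full_axis)
  }))
}

#' Read or write a scene as JSON
#'
#' Records `screws` (head/tip/diameter), `volume_bounds` (lo/hi), `seed`.
#'
#' @param scene A `pmaa_scene`.
#' @param path JSON file path.
#' @return `read_scene()` returns a `pmaa_scene`; `write_scene()` returns
#'   `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  out <- list(
    seed = scene$seed,
    volume_bounds = list(lo = scene$volume_bounds["lo", ],
                         hi = scene$volume_bounds["hi", ]),
    screws = lapply(scene$screws, function(s) {
      list(head = s$head, tip = s$tip, diameter = s$diameter)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) io_error(sprintf("scene file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(
    screws = lapply(raw$screws, function(s) {
      list(head = unlist(s$head), tip = unlist(s$tip), diameter = s$diameter)
    }),
    volume_bounds = rbind(lo = unlist(raw$volume_bounds$lo),
                          hi = unlist(raw$volume_bounds$hi)),
    seed = as.integer(raw$seed)
  ), class = "pmaa_scene")
}
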