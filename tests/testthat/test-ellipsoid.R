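test_that("fit_ellipsoid builds the stated axis-aligned shape matrix", {
  e <- fit_ellipsoid(c(0, 0, 0), c(0, 0, 50))
  expect_equal(e$mu, c(0, 0, 25))
  expect_equal(e$sigma, diag(c(6.25, 6.25, 625)), tolerance = 1e-12)
  # central symmetry: swapping head and tip changes nothing
  e2 <- fit_ellipsoid(c(0, 0, 50), c(0, 0, 0))
  expect_equal(e2$mu, e$mu)
  expect_equal(e2$sigma, e$sigma, tolerance = 1e-12)
  expect_error(fit_ellipsoid(c(0, 0, 0), c(0, 0, 0.5)),
               class = "pmaa_validation_error")
})

test_that("fitted eigenstructure matches the head-tip geometry", {
  head <- c(10, -5, 3)
  tip <- c(40, 25, 3)
  e <- fit_ellipsoid(head, tip)
  L <- sqrt(sum((head - tip)^2))
  ed <- eigen(e$sigma, symmetric = TRUE)
  expect_equal(sort(ed$values), sort(c((L / 2)^2, 6.25, 6.25)),
               tolerance = 1e-9)
  v <- ed$vectors[, which.max(ed$values)]
  u <- (tip - head) / L
  expect_equal(abs(sum(v * u)), 1, tolerance = 1e-9)
  # the diameter-mode convention: minor semi-axis = diameter / 2
  e75 <- fit_ellipsoid(head, tip, minor_full_axis = 7.5)
  expect_equal(sort(eigen(e75$sigma, symmetric = TRUE, only.values = TRUE)$values)[1:2],
               c(14.0625, 14.0625), tolerance = 1e-9)
})

test_that("ellipsoid constructor enforces symmetry and positive definiteness", {
  expect_error(ellipsoid(c(0, 0, 0), matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               class = "pmaa_validation_error")
  expect_error(ellipsoid(c(0, 0, 0), diag(c(1, -1, 1))),
               class = "pmaa_validation_error")
  expect_error(ellipsoid(c(0, 0, 0), diag(c(1e6, 1, 1))),
               class = "pmaa_validation_error")
})

test_that("central chord length matches the numeric surface-crossing oracle", {
  expect_equal(chord_length(sphere(7), c(0, 1, 0)), 14)
  e <- ellipsoid(c(0, 0, 0), diag(c(625, 6.25, 6.25)))
  expect_equal(chord_length(e, c(1, 0, 0)), 50)
  # oracle: find the surface crossing by root bracketing along mu + t d
  for (d in list(c(1, 1, 0) / sqrt(2), c(0.2, -0.5, 0.3) / sqrt(0.38))) {
    qf <- function(t) {
      x <- e$mu + t * d
      drop(t(x - e$mu) %*% solve(e$sigma) %*% (x - e$mu)) - 1
    }
    t_hi <- uniroot(qf, c(0, 1000), tol = 1e-12)$root
    expect_equal(chord_length(e, d), 2 * t_hi, tolerance = 1e-6)
  }
  expect_error(chord_length(e, c(1, 1, 0)), class = "pmaa_validation_error")
})

test_that("chord length is invariant to sign flips and joint rotation", {
  set.seed(11)
  e <- fit_ellipsoid(c(4, -20, 7), c(-12, 30, 9))
  for (i in 1:25) {
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    expect_equal(chord_length(e, d), chord_length(e, -d), tolerance = 1e-12)
    ax <- rnorm(3)
    R <- pmaa:::rotation_about(ax, runif(1, 0, 360))
    e_rot <- ellipsoid(e$mu, R %*% e$sigma %*% t(R))
    expect_equal(chord_length(e_rot, drop(R %*% d)), chord_length(e, d),
                 tolerance = 1e-9)
  }
})

test_that("the maximum chord over directions is the full major axis", {
  set.seed(12)
  z <- runif(10000, -1, 1)
  phi <- runif(10000, 0, 2 * pi)
  D <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  # moderate anisotropy (a/b = 1.5): the direction-sampling error near the
  # pole, (eps^2/2)((a/b)^2 - 1), stays well below the 0.1% tolerance
  R <- pmaa:::rotation_about(c(1, 2, -1), 33)
  e <- ellipsoid(c(5, -3, 8), R %*% diag(c(30, 24, 20)^2) %*% t(R))
  chords <- apply(D, 1, function(d) chord_length(e, d))
  lmax <- max(eigen(e$sigma, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(max(chords) - 2 * sqrt(lmax)) / (2 * sqrt(lmax)), 1e-3)
  # a 10:1 screw surrogate: the major axis bounds every chord and the sample
  # maximum approaches it at the resolution 1e4 directions can deliver
  es <- fit_ellipsoid(c(0, 0, 0), c(20, 35, -10), minor_full_axis = 6)
  chords_s <- apply(D, 1, function(d) chord_length(es, d))
  major <- 2 * sqrt(max(eigen(es$sigma, symmetric = TRUE,
                              only.values = TRUE)$values))
  expect_lte(max(chords_s), major + 1e-9)
  expect_gt(max(chords_s), 0.9 * major)
})

test_that("ray path lengths are exact and bounded by the central chord", {
  e <- fit_ellipsoid(c(0, 0, 0), c(0, 0, 50))
  # ray through the centroid equals the central chord
  d <- c(1, 0, 1) / sqrt(2)
  r <- ray3d(e$mu - 300 * d, d)
  expect_equal(ray_path_length(e, r), chord_length(e, d), tolerance = 1e-9)
  # miss beyond the maximum semi-axis
  expect_identical(ray_path_length(e, ray3d(c(0, 30, 25), c(0, 0, 1))), 0)
  # tangent ray grazes with zero length
  expect_lt(ray_path_length(e, ray3d(c(2.5, -100, 25), c(0, 1, 0))), 1e-9)
  # dominance: every parallel ray is no longer than the central chord
  set.seed(13)
  for (i in 1:50) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    o <- e$mu + runif(3, -30, 30)
    expect_lte(ray_path_length(e, ray3d(o - 500 * d, d)),
               chord_length(e, d) + 1e-12)
  }
})

test_that("rendered path-length images respect diameter and volume bounds", {
  geom <- carm_geometry()
  pose <- make_pose(geom, 20, 5)
  # far outside the field of view: all-zero image
  far <- sphere(5, c(0, 0, 5000))
  img <- render_path_length_image(far, pose, row_stride = 8, col_stride = 8)
  expect_true(all(img == 0))
  # sphere at isocenter: max bounded by the diameter, approaching it
  sp <- sphere(10)
  img1 <- render_path_length_image(sp, pose, row_stride = 4, col_stride = 4)
  expect_lte(max(img1), 20)
  img2 <- render_path_length_image(sp, pose)
  expect_lte(max(img2), 20)
  expect_gt(max(img2), max(img1) - 1e-9)
  expect_gt(max(img2), 20 * 0.999)
  # integral check: sum x pixel area / magnification^2 ~ ellipsoid volume
  mag <- 1164 / 622
  vol_est <- sum(img2) * 1^2 / mag^2
  expect_equal(vol_est, 4 / 3 * pi * 1000, tolerance = 0.2)
})

test_that("ellipsoid sets round-trip through JSON including head/tip records", {
  es <- ellipsoid_set(list(fit_ellipsoid(c(0, 0, 0), c(0, 0, 50)),
                           sphere(7, c(10, 10, 10))))
  f <- withr::local_tempfile(fileext = ".json")
  write_ellipsoids(es, f)
  back <- read_ellipsoids(f)
  expect_length(back, 2)
  expect_equal(back$members[[1]]$sigma, es$members[[1]]$sigma, tolerance = 0)
  # head/tip records are fitted on load
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(head = c(0, 0, 0), tip = c(0, 0, 50))),
                              auto_unbox = TRUE, digits = NA), f2)
  fitted <- read_ellipsoids(f2)
  expect_equal(fitted$members[[1]]$sigma, diag(c(6.25, 6.25, 625)),
               tolerance = 1e-12)
})
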