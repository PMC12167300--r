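test_that("the analytic metric is exact for spheres and aligned screws", {
  geom <- carm_geometry()
  spheres <- ellipsoid_set(list(sphere(3, c(20, 0, 10)), sphere(7, c(-15, 5, 0))))
  for (th in c(-100, 0, 45)) {
    for (de in c(-30, 0, 30)) {
      expect_equal(q_atten_analytic(spheres, make_pose(geom, th, de)), 14,
                   tolerance = 1e-12)
    }
  }
  # a pose whose central ray runs along the screw axis sees the full 50 mm
  pose <- make_pose(geom, 0, 0)
  axis_dir <- (c(0, 0, 0) - pose$source) / 622
  screw <- fit_ellipsoid(c(0, 0, 0) - 25 * axis_dir, c(0, 0, 0) + 25 * axis_dir)
  expect_equal(q_atten_analytic(ellipsoid_set(list(screw)), pose), 50,
               tolerance = 1e-9)
  expect_error(q_atten_analytic(ellipsoid_set(), pose),
               class = "pmaa_validation_error")
})

test_that("rendered metric agrees with the analytic centroid chord in-field", {
  geom <- carm_geometry()
  set.seed(21)
  for (i in 1:5) {
    scene <- generate_scene(sample(1:4, 1), seed = 20 + i)
    es <- scene_to_ellipsoids(scene)
    pose <- make_pose(geom, runif(1, -100, 100), runif(1, -30, 30))
    if (!all_in_field(es, pose)) next
    qa <- q_atten_analytic(es, pose)
    qr <- q_atten_rendered(es, pose, sampling = 0.5)
    expect_lt(abs(qa - qr) / qr, 0.02)
  }
  # out-of-field semantics: rendered goes to 0, analytic does not
  far <- ellipsoid_set(list(sphere(5, c(0, 0, 4000))))
  pose <- make_pose(geom, 0, 0)
  expect_identical(q_atten_rendered(far, pose), 0)
  expect_equal(q_atten_analytic(far, pose), 10)
})

test_that("summed variant dominates and doubles for coincident objects", {
  geom <- carm_geometry()
  pose <- make_pose(geom, 10, -5)
  two <- ellipsoid_set(list(sphere(6, c(0, 0, 0)), sphere(6, c(0, 0, 0))))
  qs <- q_atten_summed(two, pose, sampling = 0.5)
  qr <- q_atten_rendered(two, pose, sampling = 0.5)
  expect_equal(qs, 2 * qr, tolerance = 1e-9)
  # disjoint projections: summed equals rendered
  apart <- ellipsoid_set(list(sphere(4, c(0, 0, 40)), sphere(6, c(0, 0, -40))))
  expect_equal(q_atten_summed(apart, pose, sampling = 0.5),
               q_atten_rendered(apart, pose, sampling = 0.5), tolerance = 1e-9)
  # crossing screws: summed dominates rendered
  cross <- ellipsoid_set(list(fit_ellipsoid(c(-25, 0, -25), c(25, 0, 25)),
                              fit_ellipsoid(c(-25, 0, 25), c(25, 0, -25))))
  expect_gte(q_atten_summed(cross, pose, sampling = 0.5) + 1e-9,
             q_atten_rendered(cross, pose, sampling = 0.5))
})

test_that("voxelization reproduces volumes and converges with refinement", {
  sp <- ellipsoid_set(list(sphere(10)))
  m1 <- voxelize(sp, voxel_size = 1)
  vol_true <- 4 / 3 * pi * 1000
  vol1 <- sum(m1$occupancy) * 1^3
  expect_lt(abs(vol1 - vol_true) / vol_true, 0.05)
  m05 <- voxelize(sp, voxel_size = 0.5)
  vol05 <- sum(m05$occupancy) * 0.5^3
  expect_lt(abs(vol05 - vol_true), abs(vol1 - vol_true))
  expect_error(voxelize(ellipsoid_set()), class = "pmaa_validation_error")
})

test_that("voxel raytracing matches analytic geometry on simple masks", {
  geom <- carm_geometry()
  pose <- make_pose(geom, 0, 0)
  # a 20 mm cube with the central ray perpendicular to a face
  occ <- array(FALSE, dim = c(40, 40, 40))
  occ[11:30, 11:30, 11:30] <- TRUE
  cube <- voxel_mask(origin = c(-20, -20, -20), voxel_size = 1, occupancy = occ)
  expect_lt(abs(q_atten_voxel(cube, pose, sampling = 1) - 20), 1)
  # all-false mask scores zero
  empty_mask <- voxel_mask(c(-10, -10, -10), 1, array(FALSE, c(20, 20, 20)))
  expect_identical(q_atten_voxel(empty_mask, pose), 0)
  # single screw at the pose that maximizes its metric (the long-path regime
  # the objective consumes; short oblique chords of ~5-10 mm sit below the
  # +/- 1 voxel discretization resolution): voxel within 5% of analytic
  geom_c <- carm_geometry(theta_step = 20, delta_step = 10)
  for (seed in c(3, 4)) {
    es <- scene_to_ellipsoids(generate_scene(1, seed = seed))
    mask <- voxelize(es, voxel_size = 1)
    ma <- metric_map(es, geom_c, "analytic")
    peak <- which(ma$values == max(ma$values), arr.ind = TRUE)[1, ]
    pose_pk <- make_pose(geom_c, ma$theta_values[peak[2]],
                         ma$delta_values[peak[1]])
    qa <- q_atten_analytic(es, pose_pk)
    qv <- q_atten_voxel(mask, pose_pk, sampling = 1)
    expect_lt(abs(qv - qa) / qa, 0.05)
  }
})

test_that("metric maps reflect scene isotropy and screw orientation", {
  geom <- coarse_geom()
  iso <- metric_map(ellipsoid_set(list(sphere(8, c(5, -5, 10)))), geom)
  expect_lt(max(iso$values) - min(iso$values), 1e-9 * max(iso$values))
  # screw along the orbit axis: tilting aligns rays with the screw
  es <- ellipsoid_set(list(fit_ellipsoid(c(0, 0, -25), c(0, 0, 25))))
  m <- metric_map(es, carm_geometry(theta_step = 25, delta_step = 30))
  row0 <- m$values[m$delta_values == 0, ]
  row30 <- m$values[m$delta_values == 30, ]
  rowm30 <- m$values[m$delta_values == -30, ]
  expect_true(all(outer(row0, row30, `<`)))
  expect_true(all(outer(row0, rowm30, `<`)))
})

test_that("analytic and rendered maps agree on a multi-screw scene", {
  geom <- coarse_geom(theta_step = 50, delta_step = 15)
  es <- scene_to_ellipsoids(generate_scene(6, seed = 77))
  poses_in_field <- all(vapply(delta_grid(geom), function(de) {
    all(vapply(theta_grid(geom), function(th) {
      all_in_field(es, make_pose(geom, th, de))
    }, logical(1)))
  }, logical(1)))
  expect_true(poses_in_field)
  ma <- metric_map(es, geom, "analytic")
  mr <- metric_map(es, geom, "rendered", sampling = 0.5)
  expect_lt(max(abs(ma$values - mr$values) / mr$values), 0.02)
})

test_that("analytic scores have a parallel-beam limit and scale equivariance", {
  geom <- carm_geometry()
  big <- carm_geometry(source_isocenter_distance = 62200,
                       source_detector_distance = 116400)
  huge <- carm_geometry(source_isocenter_distance = 622e4,
                        source_detector_distance = 1164e4)
  vast <- carm_geometry(source_isocenter_distance = 622e6,
                        source_detector_distance = 1164e6)
  es <- scene_to_ellipsoids(generate_scene(4, seed = 31))
  for (th in c(-60, 0, 80)) {
    # converged under further scaling once in the parallel-beam regime
    q2 <- q_atten_analytic(es, make_pose(huge, th, 10))
    q3 <- q_atten_analytic(es, make_pose(vast, th, 10))
    expect_lt(abs(q2 - q3) / q3, 1e-3)
    # in the parallel-beam limit the rendered max equals the central chord
    pose_big <- make_pose(big, th, 10)
    qr <- q_atten_rendered(es, pose_big, sampling = 0.5)
    expect_lt(abs(q_atten_analytic(es, pose_big) - qr) / qr, 0.005)
  }
  # scaling all geometry and ellipsoids by k scales the metric by k
  k <- 2.5
  geom_k <- carm_geometry(source_isocenter_distance = 622 * k,
                          source_detector_distance = 1164 * k)
  es_k <- ellipsoid_set(lapply(es$members, function(e) {
    ellipsoid(k * e$mu, k^2 * e$sigma)
  }))
  expect_equal(q_atten_analytic(es_k, make_pose(geom_k, 20, -10)),
               k * q_atten_analytic(es, make_pose(geom, 20, -10)),
               tolerance = 1e-9)
})

test_that("evaluation counters expose the scorers' cost structure", {
  es <- scene_to_ellipsoids(generate_scene(3, seed = 51))
  geom_small <- carm_geometry(theta_step = 50, delta_step = 15,
                              detector_rows = 100, detector_cols = 100)
  geom_large <- carm_geometry(theta_step = 50, delta_step = 15,
                              detector_rows = 800, detector_cols = 800)
  n_poses <- length(theta_grid(geom_small)) * length(delta_grid(geom_small))
  reset_path_counters()
  invisible(metric_map(es, geom_small, "analytic"))
  c1 <- path_counters()
  expect_identical(c1$chord_evals, 3 * n_poses)
  expect_identical(c1$rendered_rays, 0)
  # detector resolution does not change the analytic cost
  reset_path_counters()
  invisible(metric_map(es, geom_large, "analytic"))
  expect_identical(path_counters()$chord_evals, 3 * n_poses)
  # rendered cost scales with the sampled pixel count
  pose <- make_pose(carm_geometry(), 0, 0)
  reset_path_counters()
  invisible(q_atten_rendered(es, pose, sampling = 1))
  coarse_rays <- path_counters()$rendered_rays
  reset_path_counters()
  invisible(q_atten_rendered(es, pose, sampling = 0.5))
  fine_rays <- path_counters()$rendered_rays
  expect_gt(coarse_rays, 0)
  expect_gt(fine_rays, 2.5 * coarse_rays)
  reset_path_counters()
})

test_that("metric map text format round-trips bit-exactly", {
  geom <- coarse_geom(theta_step = 40, delta_step = 15)
  es <- scene_to_ellipsoids(generate_scene(2, seed = 8))
  m <- metric_map(es, geom, "analytic")
  f <- withr::local_tempfile(fileext = ".txt")
  write_metric_map(m, f, geom)
  back <- read_metric_map(f)
  expect_identical(back$values, m$values)
  expect_identical(back$method, "analytic")
  expect_identical(back$theta_values, m$theta_values)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_metric_map(back, f2, geom)
  expect_identical(readLines(f), readLines(f2))
})
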