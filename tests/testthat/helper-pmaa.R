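# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# coarse angular grids keep analytic metric maps cheap in unit tests
coarse_geom <- function(theta_step = 25, delta_step = 10, ...) {
  carm_geometry(theta_step = theta_step, delta_step = delta_step, ...)
}

scout_pair <- function(geom = carm_geometry()) {
  list(A = make_pose(geom, 0, 0), B = make_pose(geom, 90, 0))
}

sphere <- function(r, center = c(0, 0, 0)) {
  ellipsoid(center, diag(r^2, 3))
}

dist_point_ray <- function(p, ray) {
  w <- p - ray$origin
  sqrt(sum((w - sum(w * ray$direction) * ray$direction)^2))
}

# brute-force min-cost assignment by permutation enumeration (oracle for the
# Hungarian solver); cost must be square or wide
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    best <- min(best, tot)
  }
  best
}

# centroid/endpoint recovery errors of triangulated screws vs scene truth
match_errors <- function(eps, scene) {
  vapply(eps, function(s) {
    min(vapply(scene$screws, function(sc) {
      sqrt(sum(((sc$head + sc$tip) / 2 - (s$head + s$tip) / 2)^2))
    }, numeric(1)))
  }, numeric(1))
}

# map matched pairs back to scene indices using observation truth tables;
# returns data.frame(idx_a, idx_b) with NA for spurious objects
correspondence_indices <- function(eps, obs) {
  data.frame(
    idx_a = obs$truth_A$scene_index[match(vapply(eps, `[[`, character(1), "object_a"),
                                          obs$truth_A$object_id)],
    idx_b = obs$truth_B$scene_index[match(vapply(eps, `[[`, character(1), "object_b"),
                                          obs$truth_B$object_id)]
  )
}
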