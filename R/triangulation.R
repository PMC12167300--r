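# Two-view keypoint matching and triangulation.
#
# Head and tip keypoints detected in two calibrated scout views are
# back-projected into rays; a cross-view object pair is admissible when the
# two head rays and the two tip rays each pass within a tolerance (5 mm by
# default) of one another, with closest approach in front of both sources.
# Among admissible pairs a min-cost one-to-one assignment (total head + tip
# gap) resolves epipolar ambiguity; the midpoint of the closest-approach
# segment is the triangulated 3D coordinate.

#' Closest point between two rays
#'
#' Computes the shortest segment connecting the two lines carrying the rays
#' and returns its midpoint and length, together with the line parameters of
#' the closest points (negative parameters indicate closest approach behind
#' a ray's origin).
#'
#' @param r1,r2 [ray3d()] objects.
#' @return A list with `midpoint` (3-vector, mm), `gap` (mm), and the ray
#'   parameters `t1`, `t2` (mm along each unit direction).
#' @export
closest_point_between_rays <- function(r1, r2) {
  d1 <- r1$direction
  d2 <- r2$direction
  if (norm3(cross3(d1, d2)) < 1e-12) {
    computation_error("rays are parallel; closest point is not unique")
  }
  b <- sum(d1 * d2)
  w <- r2$origin - r1$origin
  denom <- 1 - b^2
  t1 <- (sum(w * d1) - b * sum(w * d2)) / denom
  t2 <- (b * sum(w * d1) - sum(w * d2)) / denom
  p1 <- r1$origin + t1 * d1
  p2 <- r2$origin + t2 * d2
  list(midpoint = (p1 + p2) / 2, gap = norm3(p1 - p2), t1 = t1, t2 = t2)
}

# Min-cost assignment for a rectangular cost matrix (Hungarian algorithm with
# potentials, O(n^2 m)). Returns, for each row, the assigned column index.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(0))
  if (n > m) {
    # transpose, then invert the row->col map
    colmap <- solve_assignment(t(cost))
    out <- integer(n)
    out[colmap] <- seq_len(m)
    return(out)
  }
  u <- numeric(n)
  v <- numeric(m + 1)        # m + 1 is the virtual column
  p <- integer(m + 1)        # row assigned to each column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assign[p[j]] <- j
  assign
}

# Normalize a proposals input (data.frame with view_id, object_id, kind, u, v
# [, score]) into a per-object list of head/tip pixels, validating pairing.
collect_objects <- function(proposals, label) {
  if (is.null(proposals) || NROW(proposals) == 0) return(list())
  df <- as.data.frame(proposals)
  needed <- c("object_id", "kind", "u", "v")
  if (!all(needed %in% names(df))) {
    validation_error(sprintf("proposals for view %s need columns %s",
                             label, paste(needed, collapse = ", ")))
  }
  if (!all(df$kind %in% c("head", "tip"))) {
    validation_error("proposal kind must be 'head' or 'tip'")
  }
  if (!all(is.finite(df$u)) || !all(is.finite(df$v))) {
    validation_error("proposal pixel coordinates must be finite")
  }
  out <- list()
  for (oid in unique(df$object_id)) {
    sub <- df[df$object_id == oid, ]
    h <- sub[sub$kind == "head", ]
    t <- sub[sub$kind == "tip", ]
    if (nrow(h) != 1 || nrow(t) != 1) {
      validation_error(sprintf(
        "view %s object '%s' must have exactly one head and one tip proposal",
        label, oid))
    }
    out[[length(out) + 1]] <- list(
      object_id = oid,
      head = c(h$u, h$v),
      tip = c(t$u, t$v)
    )
  }
  out
}

#' Match keypoint proposals across two views and triangulate screw endpoints
#'
#' Back-projects all head/tip proposals of both scout views, gates cross-view
#' object pairs on the closest-approach distance of their head rays and tip
#' rays (both must be within `tolerance`, with closest approach in front of
#' both sources), and resolves ambiguities by a min-cost one-to-one
#' assignment on total gap. Unmatched proposals are dropped (logged when
#' `options(pmaa.verbose = TRUE)`).
#'
#' @param proposals_A,proposals_B Data frames with columns `object_id`,
#'   `kind` (`"head"`/`"tip"`), `u`, `v` (and optionally `view_id`, `score`),
#'   one head and one tip row per object.
#' @param pose_A,pose_B The calibrated `pmaa_pose` of each view.
#' @param tolerance Gate on both ray gaps, mm.
#' @return A list of `screw_endpoints` records: `head`, `tip` (3-vectors,
#'   mm), `head_gap`, `tip_gap` (mm), and the matched `object_a`,
#'   `object_b` identifiers. Empty list when either view has no proposals.
#' @export
match_and_triangulate <- function(proposals_A, proposals_B, pose_A, pose_B,
                                  tolerance = 5) {
  stop_if_not_scalar_number(tolerance, "tolerance")
  objs_A <- collect_objects(proposals_A, "A")
  objs_B <- collect_objects(proposals_B, "B")
  nA <- length(objs_A)
  nB <- length(objs_B)
  if (nA == 0 || nB == 0) {
    pmaa_log("triangulation: %d + %d proposals, nothing to match", nA, nB)
    return(list())
  }
  rays_A <- lapply(objs_A, function(o) list(head = backproject(pose_A, o$head),
                                            tip = backproject(pose_A, o$tip)))
  rays_B <- lapply(objs_B, function(o) list(head = backproject(pose_B, o$head),
                                            tip = backproject(pose_B, o$tip)))
  BIG <- 1e9  # forbidden-pair cost; dwarfs any physical gap sum
  cost <- matrix(BIG, nA, nB)
  cand <- vector("list", nA * nB)
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      h <- closest_point_between_rays(rays_A[[i]]$head, rays_B[[j]]$head)
      t <- closest_point_between_rays(rays_A[[i]]$tip, rays_B[[j]]$tip)
      forward <- min(h$t1, h$t2, t$t1, t$t2) >= -1e-9
      if (forward && h$gap <= tolerance && t$gap <= tolerance) {
        cost[i, j] <- h$gap + t$gap
        cand[[(i - 1) * nB + j]] <- list(head = h, tip = t)
      }
    }
  }
  assign <- solve_assignment(cost)
  out <- list()
  for (i in seq_along(assign)) {
    j <- assign[i]
    if (j > 0 && cost[i, j] < BIG) {
      ht <- cand[[(i - 1) * nB + j]]
      rec <- structure(list(
        head = ht$head$midpoint,
        tip = ht$tip$midpoint,
        head_gap = ht$head$gap,
        tip_gap = ht$tip$gap,
        object_a = objs_A[[i]]$object_id,
        object_b = objs_B[[j]]$object_id
      ), class = "screw_endpoints")
      if (norm3(rec$head - rec$tip) <= 0) {
        validation_error("triangulated head and tip coincide")
      }
      out[[length(out) + 1]] <- rec
    }
  }
  pmaa_log("triangulation: matched %d of %d x %d proposals (tolerance %g mm)",
           length(out), nA, nB, tolerance)
  out
}

#' @export
print.screw_endpoints <- function(x, ...) {
  cat(sprintf("screw: head (%.2f, %.2f, %.2f) tip (%.2f, %.2f, %.2f) mm, gaps %.3g/%.3g mm\n",
              x$head[1], x$head[2], x$head[3], x$tip[1], x$tip[2], x$tip[3],
              x$head_gap, x$tip_gap))
  invisible(x)
}

#' Read or write keypoint proposals as CSV
#'
#' Header `view_id,object_id,kind,u,v,score`; one row per keypoint.
#'
#' @param path CSV file path.
#' @param proposals Data frame to write.
#' @return `read_keypoints()` returns the data frame (all views);
#'   `write_keypoints()` returns `path` invisibly.
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) io_error(sprintf("keypoints file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("view_id", "object_id", "kind", "u", "v")
  if (!all(needed %in% names(df))) {
    validation_error(sprintf("keypoints CSV must have columns %s",
                             paste(c(needed, "score"), collapse = ",")))
  }
  if (is.null(df$score)) df$score <- rep(1, nrow(df))
  df
}

#' @rdname read_keypoints
#' @export
write_keypoints <- function(proposals, path) {
  df <- as.data.frame(proposals)
  if (is.null(df$score)) df$score <- rep(1, NROW(df))
  cols <- c("view_id", "object_id", "kind", "u", "v", "score")
  if (nrow(df) == 0) {
    df <- df[, intersect(cols, names(df)), drop = FALSE]
    for (cl in setdiff(cols, names(df))) df[[cl]] <- numeric(0)
  }
  df <- df[, cols]
  df$u <- fmt_full(df$u)
  df$v <- fmt_full(df$v)
  df$score <- fmt_full(as.numeric(df$score))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
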