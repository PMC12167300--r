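# Internal helpers: error conditions, evaluation counters, small linear algebra,
# seed scoping, and a plain-text hash for file sidecars.

pmaa_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pmaa_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

validation_error <- function(message) pmaa_error(message, "pmaa_validation_error")
computation_error <- function(message) pmaa_error(message, "pmaa_computation_error")
io_error <- function(message) pmaa_error(message, "pmaa_io_error")

# evaluation counters backing the cost-mechanism checks: the analytic scorer
# counts central-chord evaluations, the rendered/voxel scorers count rays cast
.counters <- new.env(parent = emptyenv())

#' Reset the path-evaluation counters
#'
#' The package keeps global counters of how many ellipsoid chord evaluations
#' and how many detector rays have been computed since the last reset. They
#' exist to make the cost structure of the scorers observable: the analytic
#' scorer performs exactly one chord evaluation per ellipsoid per pose,
#' independent of detector resolution, while the rendered and voxel scorers
#' cast one ray per sampled detector position.
#'
#' @return Invisibly, the zeroed counter list.
#' @seealso [path_counters()]
#' @export
reset_path_counters <- function() {
  .counters$chord_evals <- 0
  .counters$rendered_rays <- 0
  .counters$voxel_rays <- 0
  invisible(path_counters())
}

#' Read the path-evaluation counters
#'
#' @return A list with elements `chord_evals`, `rendered_rays`, `voxel_rays`.
#' @export
path_counters <- function() {
  if (is.null(.counters$chord_evals)) reset_path_counters()
  list(
    chord_evals = .counters$chord_evals,
    rendered_rays = .counters$rendered_rays,
    voxel_rays = .counters$voxel_rays
  )
}

bump_counter <- function(name, by = 1) {
  if (is.null(.counters[[name]])) reset_path_counters()
  .counters[[name]] <- .counters[[name]] + by
  invisible(NULL)
}

deg2rad <- function(deg) deg * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) validation_error("cannot normalize a zero vector")
  v / n
}

# Rodrigues rotation about a unit axis, angle in degrees
rotation_about <- function(axis, deg) {
  a <- unit3(axis)
  th <- deg2rad(deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a over a character scalar; used for geometry fingerprints in sidecars.
# Arithmetic is kept in doubles below 2^53 (the xor only touches the low byte,
# the modular multiply is split into 16-bit halves).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f")) %% 256
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_verbose <- function() isTRUE(getOption("pmaa.verbose", FALSE))

pmaa_log <- function(...) {
  if (is_verbose()) message(sprintf(...))
  invisible(NULL)
}

fmt_full <- function(x) sprintf("%.17g", x)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(sprintf("`%s` must be a finite numeric scalar", name))
  }
  invisible(NULL)
}
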