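# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed: must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and a stage name, so that
# pipeline stages draw from independent streams regardless of run order.
# Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1977326743  # 7^11, < 2^31
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Validation helper: stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("%s: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at continuous
# 0-based pixel-center coordinates (x, y).  Out-of-bounds samples return
# `outside`.
bilinear_sample <- function(m, x, y, outside = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp integer corners; mark fully outside points
  out <- x < 0 | y < 0 | x > (nc - 1) | y > (nr - 1)
  x0c <- pmin(pmax(x0, 0), nc - 1); x1c <- pmin(x0c + 1, nc - 1)
  y0c <- pmin(pmax(y0, 0), nr - 1); y1c <- pmin(y0c + 1, nr - 1)
  idx <- function(yy, xx) yy + 1L + nrow(m) * xx  # column-major linear index
  v <- (1 - fx) * (1 - fy) * m[idx(y0c, x0c)] +
    fx * (1 - fy) * m[idx(y0c, x1c)] +
    (1 - fx) * fy * m[idx(y1c, x0c)] +
    fx * fy * m[idx(y1c, x1c)]
  v[out] <- outside
  v
}

# Shift a matrix by (dy, dx), padding with `fill`.
shift_mat <- function(m, dy, dx, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys + dy, xs + dx] <- m[ys, xs]
  out
}
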