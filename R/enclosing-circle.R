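#' Smallest enclosing circle of a point set
#'
#' Computes the minimum-radius circle containing every input point, using
#' Welzl's incremental algorithm.  This circle defines the optic disc
#' diameter DD: the diameter of the smallest circle circumscribing the disc
#' boundary contour.
#'
#' @param points numeric matrix or data.frame with two columns (x, y), one
#'   row per point.
#' @return list with `center` (numeric length-2) and `radius` (scalar).
#'   The result is deterministic: points are processed in input order.
#' @examples
#' smallest_enclosing_circle(rbind(c(0, 0), c(2, 0)))  # center (1,0), r = 1
#' @export
smallest_enclosing_circle <- function(points) {
  p <- as.matrix(points)
  if (length(p) == 0L || nrow(p) == 0L) {
    stop("points: empty point set", call. = FALSE)
  }
  if (ncol(p) != 2L || !is.numeric(p) || anyNA(p)) {
    stop("points: must be a numeric n x 2 matrix without NAs", call. = FALSE)
  }
  eps <- 1e-10
  inside <- function(c, pt) {
    sqrt(sum((pt - c$center)^2)) <= c$radius * (1 + 1e-12) + eps
  }
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c) {
    # circumcircle; NULL when (near) collinear
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(NULL)
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  n <- nrow(p)
  circ <- list(center = p[1, ], radius = 0)
  for (i in seq_len(n)) {
    if (inside(circ, p[i, ])) next
    # circle through p[i]
    circ <- list(center = p[i, ], radius = 0)
    for (j in seq_len(i - 1L)) {
      if (inside(circ, p[j, ])) next
      circ <- circ2(p[i, ], p[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(circ, p[k, ])) next
        c3 <- circ3(p[i, ], p[j, ], p[k, ])
        if (is.null(c3)) {
          # collinear triple: smallest circle on the two extreme points
          trio <- rbind(p[i, ], p[j, ], p[k, ])
          dd <- as.matrix(stats::dist(trio))
          w <- which(dd == max(dd), arr.ind = TRUE)[1, ]
          c3 <- circ2(trio[w[1], ], trio[w[2], ])
        }
        circ <- c3
      }
    }
  }
  circ
}
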