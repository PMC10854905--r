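# Shared synthetic fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

# standard rendered tree + image used across pipeline/geometry tests
std_scene <- function(seed = 3, dd = 80) {
  key <- paste0("scene-", seed, "-", dd)
  if (!exists(key, envir = .fixtures)) {
    spec <- vessel_tree_spec(seed = seed, disc_diameter_px = dd)
    truth <- generate_vessel_tree(spec)
    rendering <- render_fundus(truth)
    assign(key, list(spec = spec, truth = truth, rendering = rendering),
           envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# distance of a point to a segment (for matching measurements to truth)
point_seg_dist2 <- function(p, a, b) {
  v <- b - a
  t <- max(0, min(1, sum((p - a) * v) / sum(v * v)))
  sum((p - (a + t * v))^2)
}

# truth width of the segment nearest to each profile point
truth_width_at <- function(profile, truth) {
  segs <- truth$segments
  vapply(seq_len(nrow(profile)), function(i) {
    p <- c(profile$x[i], profile$y[i])
    d2 <- vapply(seq_len(nrow(segs)), function(j) {
      point_seg_dist2(p, c(segs$x0[j], segs$y0[j]), c(segs$x1[j], segs$y1[j]))
    }, numeric(1))
    segs$width_px[which.min(d2)]
  }, numeric(1))
}

# rescale a truth tree geometrically by factor s (same retina, finer grid)
scale_truth <- function(tr, s) {
  tr$segments[, c("x0", "y0", "x1", "y1")] <-
    tr$segments[, c("x0", "y0", "x1", "y1")] * s
  tr$segments$width_px <- tr$segments$width_px * s
  tr$bifurcations$x <- tr$bifurcations$x * s
  tr$bifurcations$y <- tr$bifurcations$y * s
  tr$disc$center <- tr$disc$center * s
  tr$disc$diameter_px <- tr$disc$diameter_px * s
  tr$image_size <- as.integer(tr$image_size * s)
  tr
}

# brute-force smallest enclosing circle over all 2- and 3-point candidates
brute_force_mec <- function(p) {
  n <- nrow(p)
  covers <- function(ctr, r) all(sqrt((p[, 1] - ctr[1])^2 +
                                        (p[, 2] - ctr[2])^2) <= r + 1e-9)
  best <- list(radius = Inf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ctr <- (p[i, ] + p[j, ]) / 2
    r <- sqrt(sum((p[i, ] - p[j, ])^2)) / 2
    if (r < best$radius && covers(ctr, r)) best <- list(center = ctr, radius = r)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- p[i, ]; b <- p[j, ]; cc <- p[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
               sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
               sum(cc^2) * (b[1] - a[1])) / d
      ctr <- c(ux, uy)
      r <- sqrt(sum((a - ctr)^2))
      if (r < best$radius && covers(ctr, r)) best <- list(center = ctr, radius = r)
    }
  }
  best
}
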