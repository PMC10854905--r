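# Synthetic fundus vasculature with exact geometric ground truth.
#
# Trees are grown outward from the optic disc as straight tapering segments.
# Each bifurcation's apex angle (the first angle subtended between the two
# daughter vessels) is drawn from the configured range and recorded exactly,
# so rendered images carry known centerlines, widths, artery/vein identity,
# branching angles, and disc geometry for validating the measurement
# pipeline.

#' Specification for a synthetic vessel tree
#'
#' @param n_roots number of vessel trees rooted at the disc margin.
#' @param branching_depth generations of bifurcations per tree; each tree
#'   carries `2^branching_depth - 1` bifurcations.
#' @param angle_range_deg length-2 interval (degrees, within (0, 180)) from
#'   which bifurcation apex angles are drawn uniformly.
#' @param width_root_px root vessel width in pixels; a length-2 range means
#'   per-tree uniform draw.
#' @param width_taper multiplicative width decay per generation, in (0, 1].
#' @param av_fraction fraction of trees labeled artery (arteries are
#'   narrowed by `artery_width_factor`, the usual arteriolar appearance).
#' @param image_size side of the square target image in pixels.
#' @param disc_diameter_px optic disc diameter DD (diameter of the smallest
#'   circumscribed circle, i.e. the major axis of the rendered ellipse).
#' @param disc_aspect_range minor/major axis ratio range for the rendered
#'   disc ellipse; values below 1 exercise the circumscribed-circle rule.
#' @param segment_len_dd root segment length in DD units.
#' @param len_taper multiplicative length decay per generation.
#' @param artery_width_factor width multiplier applied to artery trees.
#' @param dev_max_deg maximum angular deviation of any segment direction
#'   from its tree's root direction (keeps trees inside disjoint sectors so
#'   trees never cross and bifurcation counts stay exact).
#' @param jitter_deg half-range of the random rotation applied jointly to
#'   each daughter pair (does not change the recorded apex angle).
#' @param seed integer seed; identical specs yield identical trees.
#' @return object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_roots = 2L,
                             branching_depth = 2L,
                             angle_range_deg = c(40, 110),
                             width_root_px = c(9, 12),
                             width_taper = 0.67,
                             av_fraction = 0.5,
                             image_size = 512L,
                             disc_diameter_px = 80,
                             disc_aspect_range = c(0.9, 1),
                             segment_len_dd = 0.65,
                             len_taper = 0.8,
                             artery_width_factor = 0.8,
                             dev_max_deg = 70,
                             jitter_deg = 12,
                             seed = 1L) {
  check_that(is.numeric(n_roots) && n_roots >= 1, "n_roots", "must be >= 1")
  check_that(is.numeric(branching_depth) && branching_depth >= 0,
             "branching_depth", "must be >= 0")
  check_that(length(angle_range_deg) == 2 && angle_range_deg[1] > 0 &&
               angle_range_deg[2] < 180 &&
               angle_range_deg[1] <= angle_range_deg[2],
             "angle_range_deg", "must be an interval within (0, 180)")
  check_that(all(width_root_px >= 1), "width_root_px", "must be >= 1 px")
  check_that(width_taper > 0 && width_taper <= 1, "width_taper",
             "must lie in (0, 1]")
  check_that(av_fraction >= 0 && av_fraction <= 1, "av_fraction",
             "must lie in [0, 1]")
  check_that(image_size >= 64, "image_size", "must be >= 64 px")
  check_that(disc_diameter_px > 0, "disc_diameter_px", "must be > 0")
  check_that(angle_range_deg[2] <= 2 * dev_max_deg, "dev_max_deg",
             "sector half-width must be >= half the maximal apex angle")
  structure(list(
    n_roots = as.integer(n_roots), branching_depth = as.integer(branching_depth),
    angle_range_deg = as.numeric(angle_range_deg),
    width_root_px = as.numeric(width_root_px),
    width_taper = width_taper, av_fraction = av_fraction,
    image_size = as.integer(image_size), disc_diameter_px = disc_diameter_px,
    disc_aspect_range = disc_aspect_range, segment_len_dd = segment_len_dd,
    len_taper = len_taper, artery_width_factor = artery_width_factor,
    dev_max_deg = dev_max_deg, jitter_deg = jitter_deg,
    seed = as.integer(seed)
  ), class = "vessel_tree_spec")
}

#' Generate a ground-truth vascular tree
#'
#' Grows `n_roots` non-crossing trees outward from the disc margin.  Every
#' segment is straight; daughters of a bifurcation are placed symmetrically
#' about a jittered bisector so the recorded apex angle is exact.  A
#' rejection step keeps any two non-adjacent segments at least one vessel
#' radius plus a clearance apart, which guarantees the rendered mask has
#' exactly the recorded bifurcations and no spurious crossings.
#'
#' @param spec a [vessel_tree_spec()].
#' @return object of class `vessel_tree_truth`: list with `segments`
#'   (data.frame: tree, id, parent, gen, x0, y0, x1, y1, width_px, label),
#'   `bifurcations` (data.frame: x, y, angle_deg, label, tree, at the
#'   parent-segment endpoint), and `disc` (center, diameter_px, aspect,
#'   theta_deg).
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "vessel_tree_spec"))
  with_seed(spec$seed, {
    # a rare layout draw cannot satisfy the clearance constraints; retry
    # with fresh draws from the same seeded stream (still deterministic)
    last <- NULL
    for (attempt in 1:25) {
      out <- tryCatch(generate_vessel_tree_impl(spec),
                      error = function(e) e)
      if (!inherits(out, "error")) return(out)
      last <- out
    }
    stop(conditionMessage(last), call. = FALSE)
  })
}

generate_vessel_tree_impl <- function(spec) {
  size <- spec$image_size
  dd <- spec$disc_diameter_px
  cx <- (size - 1) / 2
  cy <- (size - 1) / 2
  aspect <- stats::runif(1, spec$disc_aspect_range[1], spec$disc_aspect_range[2])
  disc <- list(center = c(cx, cy), diameter_px = dd, aspect = aspect,
               theta_deg = stats::runif(1, 0, 180))

  n <- spec$n_roots
  base <- stats::runif(1, 0, 360) + (seq_len(n) - 1) * 360 / n
  root_dirs <- base + stats::runif(n, -8, 8)
  n_art <- round(spec$av_fraction * n)
  labels <- rep("vein", n)
  if (n_art > 0) labels[round(seq(1, n, length.out = n_art))] <- "artery"

  segs <- list()
  bifs <- list()
  acc_pts <- matrix(numeric(0), 0, 2)  # sampled points of accepted segments
  acc_w <- numeric(0)
  seg_id <- 0L

  sample_seg <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    k <- max(2L, ceiling(len / 1.5))
    t <- seq(0, 1, length.out = k)
    cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  }

  clear_of_others <- function(pts, w, node) {
    if (nrow(acc_pts) == 0L) return(TRUE)
    d_ex <- 1.5 * w + 5  # ignore the junction neighbourhood
    keep_c <- sqrt((pts[, 1] - node[1])^2 + (pts[, 2] - node[2])^2) > d_ex
    keep_a <- sqrt((acc_pts[, 1] - node[1])^2 + (acc_pts[, 2] - node[2])^2) > d_ex
    if (!any(keep_c) || !any(keep_a)) return(TRUE)
    pc <- pts[keep_c, , drop = FALSE]
    pa <- acc_pts[keep_a, , drop = FALSE]
    wa <- acc_w[keep_a]
    dx <- outer(pc[, 1], pa[, 1], "-")
    dy <- outer(pc[, 2], pa[, 2], "-")
    dmin <- sqrt(dx^2 + dy^2)
    lim <- matrix((w + rep(wa, each = nrow(pc))) / 2 + 2, nrow(pc))
    all(dmin > lim)
  }

  in_bounds <- function(pts, w) {
    m <- w / 2 + 2
    all(pts[, 1] >= m & pts[, 1] <= size - 1 - m &
          pts[, 2] >= m & pts[, 2] <= size - 1 - m)
  }

  grow <- function(tree, p0, rel_dir, root_dir, gen, w, parent_id, label) {
    len <- spec$segment_len_dd * dd * spec$len_taper^gen
    dir_abs <- root_dir + rel_dir
    placed <- FALSE
    p1 <- NULL
    for (try in 1:40) {
      p1_try <- p0 + len * c(cos(deg2rad(dir_abs)), sin(deg2rad(dir_abs)))
      pts <- sample_seg(p0, p1_try)
      if (in_bounds(pts, w) && clear_of_others(pts, w, p0)) {
        placed <- TRUE; p1 <- p1_try
        break
      }
      # nudge the direction inside the sector and retry
      rel_dir <- max(-spec$dev_max_deg, min(spec$dev_max_deg,
                                            rel_dir + stats::runif(1, -20, 20)))
      dir_abs <- root_dir + rel_dir
    }
    if (!placed) {
      stop(sprintf(
        "unable to place tree %d generation %d segment without overlap", tree, gen),
        call. = FALSE)
    }
    seg_id <<- seg_id + 1L
    id <- seg_id
    segs[[id]] <<- data.frame(tree = tree, id = id, parent = parent_id,
                              gen = gen, x0 = p0[1], y0 = p0[2],
                              x1 = p1[1], y1 = p1[2],
                              width_px = w, label = label)
    acc_pts <<- rbind(acc_pts, sample_seg(p0, p1))
    acc_w <<- c(acc_w, rep(w, nrow(sample_seg(p0, p1))))
    if (gen < spec$branching_depth) {
      theta <- stats::runif(1, spec$angle_range_deg[1], spec$angle_range_deg[2])
      delta <- stats::runif(1, -spec$jitter_deg, spec$jitter_deg)
      centre <- rel_dir + delta
      lo <- centre - theta / 2
      hi <- centre + theta / 2
      if (lo < -spec$dev_max_deg) centre <- -spec$dev_max_deg + theta / 2
      if (hi > spec$dev_max_deg) centre <- spec$dev_max_deg - theta / 2
      bifs[[length(bifs) + 1L]] <<- data.frame(
        x = p1[1], y = p1[2], angle_deg = theta, label = label,
        tree = tree, parent_seg = id)
      wd <- max(1, w * spec$width_taper)
      grow(tree, p1, centre - theta / 2, root_dir, gen + 1L, wd, id, label)
      grow(tree, p1, centre + theta / 2, root_dir, gen + 1L, wd, id, label)
    }
    invisible(NULL)
  }

  for (t in seq_len(n)) {
    w0 <- if (length(spec$width_root_px) == 2) {
      stats::runif(1, spec$width_root_px[1], spec$width_root_px[2])
    } else spec$width_root_px[1]
    if (labels[t] == "artery") w0 <- w0 * spec$artery_width_factor
    p0 <- c(cx, cy) + (dd / 2 + 2) *
      c(cos(deg2rad(root_dirs[t])), sin(deg2rad(root_dirs[t])))
    grow(t, p0, 0, root_dirs[t], 0L, w0, NA_integer_, labels[t])
  }

  segments <- do.call(rbind, segs)
  bifurcations <- if (length(bifs)) do.call(rbind, bifs) else
    data.frame(x = numeric(0), y = numeric(0), angle_deg = numeric(0),
               label = character(0), tree = integer(0), parent_seg = integer(0))
  rownames(segments) <- NULL
  rownames(bifurcations) <- NULL
  structure(list(segments = segments, bifurcations = bifurcations,
                 disc = disc, image_size = size),
            class = "vessel_tree_truth")
}

#' Render a synthetic fundus image from ground truth
#'
#' Vessels are stroked with an anti-aliased circular brush of diameter equal
#' to the truth width, so the half-coverage contour of the rendered profile
#' sits exactly half a width from the centerline.  The disc is a bright
#' ellipse, the field of view a darker circular ROI on black, veins are
#' rendered darker than arteries by `av_contrast`.
#'
#' @param truth a [generate_vessel_tree()] result (may have zero segments).
#' @param image_size output side length in pixels (defaults to the truth's).
#' @param noise_sd Gaussian pixel noise SD on the 0-255 scale, added inside
#'   the field of view.
#' @param av_contrast artery-minus-vein intensity difference (0-255 units).
#' @param seed seed for the noise field.
#' @return list: `image` (0-255 matrix, rows = y), `vessel_mask` (0/1
#'   integer), `av_mask` (0 background, 1 artery, 2 vein), `disc_mask`,
#'   `roi_mask`, plus the rendering intensities used.
#' @export
render_fundus <- function(truth, image_size = NULL, noise_sd = 5,
                          av_contrast = 30, seed = 0L) {
  stopifnot(inherits(truth, "vessel_tree_truth"))
  size <- if (is.null(image_size)) truth$image_size else as.integer(image_size)
  segs <- truth$segments
  if (!is.null(segs) && nrow(segs) > 0) {
    margin <- segs$width_px / 2 + 1
    bad <- which(pmin(segs$x0, segs$x1) < margin - 1 |
                   pmax(segs$x0, segs$x1) > size - margin |
                   pmin(segs$y0, segs$y1) < margin - 1 |
                   pmax(segs$y0, segs$y1) > size - margin)
    if (length(bad)) {
      stop(sprintf("segments outside image bounds: %s",
                   paste(segs$id[bad], collapse = ", ")), call. = FALSE)
    }
  }

  xs <- matrix(rep(0:(size - 1), each = size), size)   # col index (x)
  ys <- matrix(rep(0:(size - 1), times = size), size)  # row index (y)

  # field of view
  cx <- (size - 1) / 2; cy <- (size - 1) / 2
  roi_r <- 0.48 * size
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  roi <- rr <= roi_r
  bg_level <- 110
  img <- ifelse(roi, bg_level * (1 - 0.12 * (rr / roi_r)^2), 0)

  # optic disc: bright ellipse with a soft ~1 px edge
  disc_cov <- matrix(0, size, size)
  if (!is.null(truth$disc)) {
    d <- truth$disc
    a <- d$diameter_px / 2
    b <- a * d$aspect
    th <- deg2rad(d$theta_deg)
    xr <- (xs - d$center[1]) * cos(th) + (ys - d$center[2]) * sin(th)
    yr <- -(xs - d$center[1]) * sin(th) + (ys - d$center[2]) * cos(th)
    q <- sqrt((xr / a)^2 + (yr / b)^2)
    disc_cov <- pmin(pmax((1 - q) * b + 0.5, 0), 1)
    img <- img * (1 - disc_cov) + 200 * disc_cov
  }

  stroke_class <- function(lab) {
    cov <- matrix(0, size, size)
    if (is.null(segs) || nrow(segs) == 0) return(cov)
    for (i in which(segs$label == lab)) {
      s <- segs[i, ]
      w <- s$width_px
      x0 <- s$x0; y0 <- s$y0; x1 <- s$x1; y1 <- s$y1
      pad <- ceiling(w / 2 + 2)
      cmin <- max(0, floor(min(x0, x1)) - pad); cmax <- min(size - 1, ceiling(max(x0, x1)) + pad)
      rmin <- max(0, floor(min(y0, y1)) - pad); rmax <- min(size - 1, ceiling(max(y0, y1)) + pad)
      ci <- (cmin:cmax) + 1L; ri <- (rmin:rmax) + 1L
      px <- xs[ri, ci]; py <- ys[ri, ci]
      vx <- x1 - x0; vy <- y1 - y0
      L2 <- vx^2 + vy^2
      t <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / L2, 0), 1)
      dist <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
      c_loc <- pmin(pmax(w / 2 + 0.5 - dist, 0), 1)
      cov[ri, ci] <- pmax(cov[ri, ci], c_loc)
    }
    cov
  }

  art_cov <- stroke_class("artery")
  vein_cov <- stroke_class("vein")
  vein_level <- bg_level - 65
  art_level <- vein_level + av_contrast
  img <- img * (1 - art_cov) + art_level * art_cov
  img <- img * (1 - vein_cov) + vein_level * vein_cov

  img <- with_seed(derive_seed(seed, "render-noise"), {
    n <- matrix(stats::rnorm(size * size, 0, noise_sd), size)
    ifelse(roi, pmin(pmax(img + n, 0), 255), img)
  })

  all_cov <- pmax(art_cov, vein_cov)
  vessel_mask <- (all_cov >= 0.5) * 1L
  av_mask <- matrix(0L, size, size)
  av_mask[vessel_mask == 1L & art_cov >= vein_cov] <- 1L
  av_mask[vessel_mask == 1L & art_cov < vein_cov] <- 2L
  list(image = img, vessel_mask = vessel_mask, av_mask = av_mask,
       disc_mask = (disc_cov >= 0.5) * 1L, roi_mask = roi * 1L,
       levels = c(background = bg_level, artery = art_level,
                  vein = vein_level, disc = 200))
}
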