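# Optic disc localization and segmentation.  The disc is localized as the
# brightest compact blob, its boundary is traced as the outermost strong
# radial edge in a polar unwrapping of the image, and the disc diameter DD
# is the diameter of the smallest circle circumscribing the boundary.

#' Locate and segment the optic disc
#'
#' Localization: the largest connected component of the top-intensity
#' pixels inside the (eroded) ROI.  Segmentation: the image is resampled
#' in polar coordinates around the candidate center (1 degree angular
#' resolution, 0.5 px radial step) and for each angle the boundary is the
#' outermost radius where the inward-smoothed radial derivative is
#' strongly negative (bright disc to darker fundus), an edge-extraction
#' rule in the polar frame.  The unwrapped contour is smoothed, and the
#' smallest enclosing circle of its points gives the center and DD.
#'
#' @param pp a [preprocess()] result (or plain intensity matrix).
#' @param quantile_loc intensity quantile defining "brightest" for
#'   localization (default 0.985).
#' @param edge_frac fraction of the strongest per-angle gradient that
#'   still counts as a strong edge (default 0.4).
#' @param r_max_frac maximal search radius as a fraction of the ROI radius.
#' @param contour_override optional n x 2 matrix of (x, y) boundary points
#'   supplied by the user in place of automatic tracing (manual disc
#'   margin correction); center/DD are then computed from it directly.
#' @return object of class `optic_disc`: list with `center` (x, y), `dd`
#'   (diameter, px), `boundary` (closed contour, n x 2, counter-clockwise),
#'   `circularity` (4*pi*A/P^2), `low_confidence` (TRUE when the blob
#'   touches the frame or ROI edge).
#' @export
locate_and_segment_disc <- function(pp, quantile_loc = 0.985,
                                    edge_frac = 0.4, r_max_frac = 0.45,
                                    contour_override = NULL) {
  img <- if (inherits(pp, "preprocessed_image")) pp$intensity else as_gray_matrix(pp)
  roi <- if (inherits(pp, "preprocessed_image")) pp$roi_mask else
    matrix(1L, nrow(img), ncol(img))

  if (!is.null(contour_override)) {
    b <- as.matrix(contour_override)
    mec <- smallest_enclosing_circle(b)
    return(new_optic_disc(mec$center, 2 * mec$radius, close_ccw(b), FALSE))
  }

  inner <- EBImage::erode(roi, EBImage::makeBrush(9, "disc"))
  vals <- img[inner == 1L]
  if (!length(vals)) stop("disc not found: empty ROI", call. = FALSE)
  thr <- stats::quantile(vals, quantile_loc)
  cand <- (img >= thr & inner == 1L) * 1L
  lab <- EBImage::bwlabel(cand)
  if (max(lab) == 0) stop("disc not found: no bright candidate blob", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < 20) stop("disc not found: candidate blob too small", call. = FALSE)
  w <- which(lab == big, arr.ind = TRUE)
  c0 <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)

  touches <- any(w[, 1] <= 2 | w[, 1] >= nrow(img) - 1 |
                   w[, 2] <= 2 | w[, 2] >= ncol(img) - 1)
  roi_r <- sqrt(sum(roi) / pi)
  low_conf <- touches

  # suppress dark vessels before edge tracing: grayscale closing with a
  # brush wider than a vessel leaves the bright disc edge as the only
  # strong bright-to-dark radial transition
  img <- as.matrix(EBImage::closing(img / 255, EBImage::makeBrush(17, "disc"))) * 255

  # polar unwrapping: rows = angles (1 deg), cols = radii (0.5 px);
  # search radius bounded by the candidate blob scale
  r_blob <- sqrt(sizes[big] / pi)
  r_max <- min(2.5 * r_blob, r_max_frac * roi_r)
  radii <- seq(0, r_max, by = 0.5)
  th <- deg2rad(seq(0, 359, by = 1))
  P <- length(th); R <- length(radii)
  xs <- outer(cos(th), radii) + c0[1]
  ys <- outer(sin(th), radii) + c0[2]
  polar <- matrix(bilinear_sample(img, as.vector(xs), as.vector(ys)), P, R)
  # smooth along the radius, then radial derivative
  k <- stats::dnorm(-4:4, sd = 1.5); k <- k / sum(k)
  sm <- t(apply(polar, 1, function(row) stats::filter(row, k, sides = 2)))
  dr <- t(apply(sm, 1, function(row) c(NA, diff(row))))
  r_edge <- numeric(P)
  for (i in seq_len(P)) {
    d <- dr[i, ]
    d[is.na(d)] <- 0
    strongest <- min(d)
    if (strongest >= 0) { r_edge[i] <- NA; next }
    strong <- which(d <= edge_frac * strongest)
    # outermost strong inward-dark edge: take the contiguous strong run
    # containing the outermost strong sample, then refine to the sub-pixel
    # extremum of the derivative (the inflection of a smoothed step sits
    # exactly on the boundary)
    outer_end <- max(strong)
    run_start <- outer_end
    while (run_start > 1 && (run_start - 1) %in% strong) run_start <- run_start - 1
    run <- run_start:outer_end
    j <- run[which.min(d[run])]
    if (j > 1 && j < length(d)) {
      den <- d[j - 1] - 2 * d[j] + d[j + 1]
      delta <- if (abs(den) > 1e-12) 0.5 * (d[j - 1] - d[j + 1]) / den else 0
      delta <- max(-0.5, min(0.5, delta))
    } else delta <- 0
    r_edge[i] <- radii[j] + delta * 0.5  # radial step is 0.5 px
  }
  if (all(is.na(r_edge))) stop("disc not found: no radial edge", call. = FALSE)
  # fill gaps and smooth the radius profile circularly (median, window 9)
  r_edge <- fill_circular_na(r_edge)
  r_s <- circular_median(r_edge, 9)
  boundary <- cbind(x = c0[1] + r_s * cos(th), y = c0[2] + r_s * sin(th))
  if (any(boundary[, 1] < 0 | boundary[, 1] > ncol(img) - 1 |
            boundary[, 2] < 0 | boundary[, 2] > nrow(img) - 1)) {
    low_conf <- TRUE
  }
  mec <- smallest_enclosing_circle(boundary)
  new_optic_disc(mec$center, 2 * mec$radius, close_ccw(boundary), low_conf)
}

new_optic_disc <- function(center, dd, boundary, low_confidence) {
  a <- polygon_area(boundary)
  per <- polygon_perimeter(boundary)
  structure(list(center = as.numeric(center), dd = dd,
                 diameter_px = dd, boundary = boundary,
                 circularity = 4 * pi * abs(a) / per^2,
                 low_confidence = low_confidence),
            class = "optic_disc")
}

close_ccw <- function(b) {
  # ensure closed and counter-clockwise in image coordinates (y down):
  # counter-clockwise on screen = negative shoelace area in (x, y-down)
  if (any(b[1, ] != b[nrow(b), ])) b <- rbind(b, b[1, ])
  if (polygon_area(b) > 0) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  b
}

polygon_area <- function(b) {
  n <- nrow(b)
  x <- b[, 1]; y <- b[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

polygon_perimeter <- function(b) {
  sum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2))
}

fill_circular_na <- function(r) {
  if (!anyNA(r)) return(r)
  n <- length(r)
  idx <- which(is.na(r))
  good <- which(!is.na(r))
  for (i in idx) {
    d <- pmin(abs(good - i), n - abs(good - i))
    r[i] <- r[good[which.min(d)]]
  }
  r
}

circular_median <- function(r, win) {
  n <- length(r)
  h <- (win - 1) / 2
  ext <- c(r[(n - h + 1):n], r, r[1:h])
  vapply(seq_len(n), function(i) stats::median(ext[i:(i + win - 1)]),
         numeric(1))
}
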