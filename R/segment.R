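# Vessel segmentation behind a pluggable backend registry, with a
# classical multiscale vesselness baseline, and artery/vein discrimination
# by intensity plus topological label propagation.

.backends <- new.env(parent = emptyenv())

#' Register a vessel segmentation backend
#'
#' A backend is a function `(pp, ...) -> binary mask` taking a
#' [preprocess()]ed image.  Two backends ship with the package:
#' `"baseline"` (multiscale Hessian vesselness, hysteresis threshold,
#' small-object removal) and `"truth"` (passes a supplied mask through
#' unchanged, for testing).  Deep-learning segmenters can be plugged in by
#' registering a wrapper; no weights ship with the package.
#'
#' @param name backend name.
#' @param fn backend function.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .backends)
  invisible(name)
}

#' List registered segmentation backends
#' @return character vector of names.
#' @export
list_backends <- function() sort(ls(.backends))

#' Segment retinal vessels
#'
#' @param pp a [preprocess()] result.
#' @param backend backend name (see [register_backend()]).
#' @param ... passed to the backend (the `"truth"` backend takes
#'   `mask = <binary matrix>`).
#' @return integer 0/1 vessel mask confined to the ROI.
#' @export
segment_vessels <- function(pp, backend = "baseline", ...) {
  stopifnot(inherits(pp, "preprocessed_image"))
  if (!exists(backend, envir = .backends, inherits = FALSE)) {
    stop(sprintf("unknown backend '%s'; registered: %s", backend,
                 paste(list_backends(), collapse = ", ")), call. = FALSE)
  }
  fn <- get(backend, envir = .backends)
  mask <- fn(pp, ...)
  mask <- (as.matrix(mask) > 0) * 1L
  mask[pp$roi_mask == 0L] <- 0L
  mask
}

#' Multiscale Hessian vesselness (Frangi-type) response
#'
#' Dark tubular structures: per scale, Gaussian-smoothed Hessian
#' eigenvalues (|l1| <= |l2|); response
#' exp(-Rb^2/(2 b^2)) * (1 - exp(-S^2/(2 c^2))) where Rb = l1/l2 and S is
#' the Frobenius norm, gated to l2 > 0 (dark ridge).  The maximum over
#' scales is returned, rescaled to [0, 1].
#'
#' @param img intensity matrix.
#' @param scales Gaussian sigmas in px (default 1:4 plus 6).
#' @param beta,c_frac vesselness shape parameters (c is `c_frac` times the
#'   max Frobenius norm per scale).
#' @return matrix in [0, 1].
#' @export
vesselness <- function(img, scales = c(1, 1.5, 2, 3, 4, 6), beta = 0.5,
                       c_frac = 0.25) {
  img <- as.matrix(img)
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    g <- as.matrix(EBImage::gblur(img, sigma = s))
    gx <- (shift_mat(g, 0, -1, 0) - shift_mat(g, 0, 1, 0)) / 2
    gxx <- shift_mat(g, 0, -1, 0) + shift_mat(g, 0, 1, 0) - 2 * g
    gyy <- shift_mat(g, -1, 0, 0) + shift_mat(g, 1, 0, 0) - 2 * g
    gxy <- (shift_mat(g, -1, -1, 0) + shift_mat(g, 1, 1, 0) -
              shift_mat(g, -1, 1, 0) - shift_mat(g, 1, -1, 0)) / 4
    # scale-normalized Hessian
    gxx <- gxx * s^2; gyy <- gyy * s^2; gxy <- gxy * s^2
    tmp <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
    l1 <- (gxx + gyy + tmp) / 2   # larger algebraic eigenvalue
    l2 <- (gxx + gyy - tmp) / 2
    # order by magnitude: lam1 small, lam2 large
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    rb2 <- (lam1 / ifelse(lam2 == 0, 1e-9, lam2))^2
    s2 <- gxx^2 + 2 * gxy^2 + gyy^2
    cc <- c_frac * sqrt(max(s2))
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[lam2 <= 0] <- 0  # bright-on-dark ridges rejected; vessels are dark
    best <- pmax(best, v)
  }
  if (max(best) > 0) best <- best / max(best)
  best
}

#' Hysteresis thresholding
#'
#' Keeps connected components of `v >= low` that contain at least one
#' pixel with `v >= high`.  Lowering `low` (with `high` fixed) can only
#' grow the result.
#'
#' @param v response matrix.
#' @param low,high thresholds, `low <= high`.
#' @return integer 0/1 matrix.
#' @export
hysteresis_threshold <- function(v, low, high) {
  stopifnot(low <= high)
  weak <- (v >= low) * 1L
  lab <- label8(weak == 1L)
  strong_labs <- unique(lab[v >= high & lab > 0])
  out <- (lab %in% strong_labs)
  matrix(as.integer(out), nrow(v), ncol(v))
}

baseline_backend <- function(pp, scales = c(1, 1.5, 2, 3, 4),
                             low = 0.3, high = 0.35, min_object_px = 60,
                             tophat_brush = 17, min_contrast = 30) {
  # dark top-hat: closing minus image responds only to dark structures
  # thinner than the brush, cancelling the step edge around the bright
  # disc that would otherwise ring in the Hessian response
  img <- pp$intensity
  th <- as.matrix(EBImage::closing(img / 255,
                                   EBImage::makeBrush(tophat_brush, "disc"))) * 255 - img
  v <- vesselness(-th, scales = scales)
  # absolute-contrast gate: the vesselness map is normalized per image, so
  # on a vessel-free image it would rescale noise; require a minimum
  # smoothed top-hat depth (0-255 units) under every vessel pixel
  th_s <- as.matrix(EBImage::gblur(th, sigma = 1.5))
  v[th_s < min_contrast] <- 0
  # suppress the ROI rim (strong circular edge)
  er <- EBImage::erode(pp$roi_mask, EBImage::makeBrush(15, "disc"))
  v[er == 0] <- 0
  mask <- hysteresis_threshold(v, low, high)
  lab <- label8(mask == 1L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
  }
  mask
}

truth_backend <- function(pp, mask) {
  (as.matrix(mask) > 0) * 1L
}

#' Classify vessels into arteries and veins
#'
#' Per-edge median image intensity classifies edges (veins run darker);
#' labels are then made consistent along each connected tree by majority
#' vote, so a single connected tree always carries a single label.  When at
#' least two trees are present the artery/vein intensity threshold is the
#' midpoint between the two 2-means cluster centers of tree-level median
#' intensities; a lone tree falls back to `invert`-aware comparison with
#' the global vessel median.
#'
#' @param image intensity matrix (or a [preprocess()] result).
#' @param vessel_mask binary mask.
#' @param graph optional precomputed [extract_centerline()] graph.
#' @param invert set TRUE if arteries are the darker class in your imaging
#'   setup (default FALSE: veins darker).
#' @return integer matrix: 0 background, 1 artery, 2 vein (an `av_mask`).
#' @export
classify_arteries_veins <- function(image, vessel_mask, graph = NULL,
                                    invert = FALSE) {
  if (inherits(image, "preprocessed_image")) image <- image$intensity
  img <- as.matrix(image)
  mask <- (as.matrix(vessel_mask) > 0) * 1L
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (sum(mask) == 0) return(out)
  if (is.null(graph)) graph <- extract_centerline(mask)
  if (length(graph$edges) == 0) return(out)

  # median centerline intensity per edge
  med <- vapply(graph$edges, function(e) {
    stats::median(img[cbind(e$path[, 2] + 1L, e$path[, 1] + 1L)])
  }, numeric(1))

  # connected components of the graph (trees)
  comp <- graph_components(graph)
  comp <- match(comp, sort(unique(comp)))  # 1..k component index
  tree_med <- as.numeric(tapply(med, comp, stats::median))

  if (length(tree_med) >= 2 && stats::sd(tree_med) > 1e-9) {
    # exact 1-D 2-means: scan every split of the sorted tree intensities
    vein_tree <- two_means_dark(tree_med)
  } else {
    vein_tree <- tree_med < stats::median(img[mask == 1L])
  }
  if (invert) vein_tree <- !vein_tree

  # paint mask pixels by the label of the nearest edge's tree: assign each
  # vessel component of the MASK the label of the skeleton tree inside it
  mask_lab <- label8(mask == 1L)
  edge_comp_label <- ifelse(vein_tree[comp], 2L, 1L)
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    ml <- mask_lab[cbind(e$path[, 2] + 1L, e$path[, 1] + 1L)]
    ml <- ml[ml > 0]
    if (!length(ml)) next
    comp_id <- ml[1]
    sel <- mask_lab == comp_id & out == 0L
    out[sel] <- edge_comp_label[i]
  }
  # any mask pixels left (components without skeleton): nearest labeled class
  out[mask == 1L & out == 0L] <- 2L
  out
}

# exact 1-D two-means: returns TRUE for members of the darker cluster
two_means_dark <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- Inf; bi <- 1L
  for (i in seq_len(n - 1)) {
    ss <- sum((xs[1:i] - mean(xs[1:i]))^2) +
      sum((xs[(i + 1):n] - mean(xs[(i + 1):n]))^2)
    if (ss < best) { best <- ss; bi <- i }
  }
  dark <- logical(n)
  dark[o[1:bi]] <- TRUE
  dark
}

# connected components over graph nodes/edges; returns per-edge component id
graph_components <- function(graph) {
  n <- nrow(graph$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in graph$edges) {
    a <- find(e$from); b <- find(e$to)
    if (a != b) parent[a] <- b
  }
  vapply(graph$edges, function(e) find(e$from), integer(1))
}
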