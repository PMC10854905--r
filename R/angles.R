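# Bifurcation detection, branching angles, and disc-relative quadrants.

#' Detect vascular bifurcations in a centerline graph
#'
#' Bifurcations are graph nodes of degree 3.  Nodes of degree 4 or more are
#' artery/vein crossings (or complex junctions) and are excluded but
#' tallied.
#'
#' @param graph a [extract_centerline()] result.
#' @return data.frame: node id, x, y, with attribute `n_crossings` (count
#'   of degree >= 4 nodes).
#' @export
detect_bifurcations <- function(graph) {
  nodes <- graph$nodes
  bif <- nodes[nodes$degree == 3, c("id", "x", "y")]
  rownames(bif) <- NULL
  attr(bif, "n_crossings") <- sum(nodes$degree >= 4)
  bif
}

#' Branching angle at a bifurcation
#'
#' The first angle subtended between the two daughter vessels at the
#' bifurcation apex.  The parent is the incident edge with the largest
#' mean diameter (tie-break: longer edge); each daughter direction is the
#' total-least-squares line fit over the first `probe_len` chain pixels
#' from the node, oriented away from it.
#'
#' @param node node id (must have degree 3).
#' @param graph a [extract_centerline()] result.
#' @param vessel_mask mask the graph came from (for parent identification
#'   by diameter); pass a precomputed profile instead via `profile`.
#' @param probe_len chain length (px) used for the direction fit
#'   (default 15).
#' @param apex_skip chain length (px) skipped right at the node before the
#'   fit starts (default 3): thinning of the wide junction blob biases the
#'   first skeleton pixels toward the bisector, so the fit uses the chain
#'   from `apex_skip` to `apex_skip + probe_len`.
#' @param profile optional [measure_diameters()] result to avoid
#'   remeasuring.
#' @return list: angle_deg in (0, 180), parent_edge, daughter_edges,
#'   short (TRUE when a daughter was shorter than probe_len).
#' @export
branching_angle <- function(node, graph, vessel_mask = NULL, probe_len = 15,
                            apex_skip = 3, profile = NULL) {
  deg <- graph$nodes$degree
  check_that(deg[node] == 3, "node", "must have degree 3")
  inc <- which(vapply(graph$edges, function(e) e$from == node || e$to == node,
                      logical(1)))
  stopifnot(length(inc) == 3)
  if (is.null(profile) && !is.null(vessel_mask)) {
    profile <- measure_diameters(vessel_mask, graph)
  }
  mean_diam <- vapply(inc, function(i) {
    if (is.null(profile)) return(NA_real_)
    d <- profile$diameter_px[profile$edge == i]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  lens <- vapply(inc, function(i) graph$edges[[i]]$length, numeric(1))
  ord <- order(-ifelse(is.na(mean_diam), -Inf, mean_diam), -lens)
  parent <- inc[ord[1]]
  daughters <- setdiff(inc, parent)
  dirs <- lapply(daughters, function(i) {
    e <- graph$edges[[i]]
    path <- e$path
    if (e$to == node) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
    # fit window along the chain, past the junction-biased apex pixels
    s <- c(0, cumsum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)))
    keep <- which(s >= apex_skip & s <= apex_skip + probe_len)
    short <- max(s) < apex_skip + probe_len
    pts <- path[keep, , drop = FALSE]
    if (nrow(pts) < 2) pts <- path[seq_len(min(nrow(path), max(2, length(keep) + 2))), , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    v <- sv$v[, 1]
    # orient away from the node
    ref <- pts[nrow(pts), ] - pts[1, ]
    if (sum(v * ref) < 0) v <- -v
    list(v = v, short = short)
  })
  v1 <- dirs[[1]]$v; v2 <- dirs[[2]]$v
  ang <- rad2deg(acos(pmin(pmax(sum(v1 * v2), -1), 1)))
  list(angle_deg = ang, parent_edge = parent, daughter_edges = daughters,
       short = dirs[[1]]$short || dirs[[2]]$short)
}

#' Assign a retinal quadrant relative to the optic disc
#'
#' Superior/inferior by the vertical offset from the disc center (image-up,
#' i.e. smaller y, is superior); nasal/temporal by the horizontal offset
#' with a laterality-dependent mapping: for a right eye (OD) nasal is
#' image-right, for a left eye (OS) the mapping is mirrored.
#'
#' @param position numeric length-2 (x, y), pixel coordinates.
#' @param disc disc with `center`.
#' @param laterality "OD" (right eye) or "OS" (left eye).
#' @return character such as "superior temporal".
#' @export
assign_quadrant <- function(position, disc, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  ctr <- disc$center
  dx <- position[1] - ctr[1]
  dy <- position[2] - ctr[2]
  if (dx == 0 && dy == 0) stop("undefined quadrant: position equals disc center",
                               call. = FALSE)
  vert <- if (dy < 0) "superior" else "inferior"
  nasal_right <- laterality == "OD"
  horiz <- if ((dx > 0) == nasal_right) "nasal" else "temporal"
  # on the vertical axis (dx == 0) fall back to temporal, the convention
  # for points straight above/below the disc being rare and arbitrary
  if (dx == 0) horiz <- "temporal"
  paste(vert, horiz)
}

#' Quadrant-stratified branching angles for one eye
#'
#' Measures every bifurcation angle in the graph, classifies each by
#' vessel class (the parent edge's label) and disc-relative quadrant, and
#' returns per-(class, quadrant) means, the per-eye aggregation used for
#' reporting.
#'
#' @param graph a [extract_centerline()] result with A/V edge labels.
#' @param disc disc with `center`.
#' @param laterality "OD" or "OS".
#' @param vessel_mask mask for parent identification by diameter.
#' @param probe_len see [branching_angle()].
#' @return list with `angles` (data.frame: node, x, y, angle_deg, label,
#'   quadrant) and `by_quadrant` (data.frame: label, quadrant, mean_deg, n).
#' @export
quadrant_angles <- function(graph, disc, laterality = "OD",
                            vessel_mask = NULL, probe_len = 15) {
  bif <- detect_bifurcations(graph)
  profile <- if (!is.null(vessel_mask)) measure_diameters(vessel_mask, graph)
  rows <- lapply(seq_len(nrow(bif)), function(i) {
    node <- bif$id[i]
    ba <- branching_angle(node, graph, probe_len = probe_len, profile = profile)
    lab <- graph$edges[[ba$parent_edge]]$label
    data.frame(node = node, x = bif$x[i], y = bif$y[i],
               angle_deg = ba$angle_deg,
               label = if (is.null(lab)) NA_character_ else lab,
               quadrant = assign_quadrant(c(bif$x[i], bif$y[i]), disc,
                                          laterality))
  })
  angles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), x = numeric(0), y = numeric(0),
               angle_deg = numeric(0), label = character(0),
               quadrant = character(0))
  if (nrow(angles)) {
    by_q <- stats::aggregate(angle_deg ~ label + quadrant, data = angles,
                             FUN = mean)
    names(by_q)[names(by_q) == "angle_deg"] <- "mean_deg"
    by_q$n <- stats::aggregate(angle_deg ~ label + quadrant, data = angles,
                               FUN = length)$angle_deg
  } else {
    by_q <- data.frame(label = character(0), quadrant = character(0),
                       mean_deg = numeric(0), n = integer(0))
  }
  list(angles = angles, by_quadrant = by_q)
}
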