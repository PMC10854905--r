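# Vessel diameters along the centerline, and DD-relative caliber summaries
# in the peripapillary annulus.

#' Measure vessel diameters along a centerline graph
#'
#' At each centerline point the local tangent is estimated by centered
#' finite differences over +/-3 chain pixels; the diameter is the chord
#' length along the orthogonal through the point, between the two
#' sub-pixel half-maximum crossings of the vessel mask (found by linear
#' interpolation of bilinear samples taken every 0.25 px).  Points within
#' `junction_excl` px of a junction-side chain end are excluded.
#'
#' @param vessel_mask binary (or continuous coverage) matrix; crossings are
#'   located at value 0.5.
#' @param graph a [extract_centerline()] result from this mask.
#' @param disc optional optic disc (list with `center`, `diameter_px` or an
#'   `optic_disc` object); adds DD-unit distances from the disc center.
#' @param junction_excl exclusion zone near junctions, px (default 2).
#' @param max_width largest measurable diameter, px.
#' @param step chain subsampling step (measure every `step`-th point).
#' @return data.frame of class `diameter_profile`: edge, x, y, tx, ty,
#'   diameter_px, label, dist_px, dist_dd; attribute `n_skipped` counts
#'   points where the orthogonal failed to cross the boundary.
#' @export
measure_diameters <- function(vessel_mask, graph, disc = NULL,
                              junction_excl = 2, max_width = 40, step = 1L) {
  m <- as.matrix(vessel_mask)
  storage.mode(m) <- "double"
  offs <- seq(0.25, max_width, by = 0.25)
  out <- list()
  n_skipped <- 0L
  deg <- graph$nodes$degree
  for (ei in seq_along(graph$edges)) {
    e <- graph$edges[[ei]]
    path <- e$path
    n <- nrow(path)
    if (n < 7) next
    # exclusion near junction-side ends
    lo <- 4L; hi <- n - 3L
    excl_from <- if (deg[e$from] >= 3) junction_excl else 0
    excl_to <- if (deg[e$to] >= 3) junction_excl else 0
    # arc length from each end
    seglen <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
    s_from <- c(0, cumsum(seglen))
    s_to <- rev(s_from[n] - s_from)
    idx <- seq(lo, hi, by = step)
    idx <- idx[s_from[idx] > excl_from + 2 & s_to[idx] > excl_to + 2]
    if (!length(idx)) next
    sf <- s_from[idx]; st <- s_to[idx]
    px <- path[idx, 1]; py <- path[idx, 2]
    tx <- path[idx + 3L, 1] - path[idx - 3L, 1]
    ty <- path[idx + 3L, 2] - path[idx - 3L, 2]
    tl <- sqrt(tx^2 + ty^2)
    tx <- tx / tl; ty <- ty / tl
    nx <- -ty; ny <- tx
    half_width <- function(sgn) {
      # samples along the normal: rows = points, cols = offsets
      xo <- sweep(outer(sgn * nx, offs), 1, px, "+")
      yo <- sweep(outer(sgn * ny, offs), 1, py, "+")
      v <- matrix(bilinear_sample(m, as.vector(xo), as.vector(yo)),
                  nrow = length(px))
      v <- cbind(bilinear_sample(m, px, py), v)
      below <- v < 0.5
      first <- apply(below, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
      o <- c(0, offs)
      w <- rep(NA_real_, length(px))
      okp <- !is.na(first) & first > 1
      f <- first[okp]
      v0 <- v[cbind(which(okp), f - 1L)]
      v1 <- v[cbind(which(okp), f)]
      w[okp] <- o[f - 1L] + (v0 - 0.5) / pmax(v0 - v1, 1e-9) * (o[f] - o[f - 1L])
      w
    }
    w1 <- half_width(1); w2 <- half_width(-1)
    d <- w1 + w2
    bad <- is.na(d)
    n_skipped <- n_skipped + sum(bad)
    # junction bulge suppression: the fused region at a junction extends
    # roughly one vessel diameter from the branch point, so points whose
    # distance from a junction-side end is less than their own measured
    # diameter are excluded as well (scale-free, self-limiting)
    dd <- ifelse(is.na(d), Inf, d)
    if (excl_from > 0) bad <- bad | sf < pmax(excl_from, 1.2 * dd)
    if (excl_to > 0) bad <- bad | st < pmax(excl_to, 1.2 * dd)
    if (all(bad)) next
    keep <- !bad
    res <- data.frame(edge = ei, x = px[keep], y = py[keep],
                      tx = tx[keep], ty = ty[keep],
                      diameter_px = d[keep],
                      label = if (is.null(e$label)) NA_character_ else e$label)
    out[[length(out) + 1L]] <- res
  }
  prof <- if (length(out)) do.call(rbind, out) else
    data.frame(edge = integer(0), x = numeric(0), y = numeric(0),
               tx = numeric(0), ty = numeric(0), diameter_px = numeric(0),
               label = character(0))
  if (!is.null(disc)) {
    ctr <- disc$center
    dd <- if (!is.null(disc$diameter_px)) disc$diameter_px else disc$dd
    prof$dist_px <- sqrt((prof$x - ctr[1])^2 + (prof$y - ctr[2])^2)
    prof$dist_dd <- prof$dist_px / dd
  }
  attr(prof, "n_skipped") <- n_skipped
  class(prof) <- c("diameter_profile", class(prof))
  prof
}

#' Annulus-zone relative calibers and AVR
#'
#' Keeps profile points whose radial distance from the disc center lies in
#' `zone` DD units (the measurement annulus around the optic disc), splits
#' each vessel's retained run into at least `min_sections` equal-arc-length
#' sections, averages the diameter within sections, averages each vessel's
#' section means, then averages vessels per artery/vein class (each vessel
#' weighted equally).  Runs shorter than `min_run_dd` DD units are sliver
#' crossings of the annulus boundary and are dropped — the criterion is in
#' DD units so the summary is invariant to image scale.  Relative calibers
#' are class means divided by DD; the arteriolar-to-venular ratio AVR is
#' their ratio, identically equal to mean arteriolar / mean venular
#' diameter.
#'
#' @param profile a [measure_diameters()] result with `dist_dd` present.
#' @param disc disc list with `diameter_px` (DD).
#' @param zone annulus bounds in DD units from the disc center
#'   (default c(1.0, 1.5)).
#' @param min_sections minimum number of equal-arc sections per vessel
#'   (default 10).
#' @param min_run_dd minimum retained run length per vessel, DD units
#'   (default 0.1).
#' @return list of class `caliber_summary`: mean_artery_px, mean_vein_px,
#'   rel_arteriolar, rel_venular, avr, n_sections (per class), dd_px,
#'   complete (FALSE when a class is absent in the annulus; `avr` is then
#'   NA).
#' @export
annulus_calibers <- function(profile, disc, zone = c(1.0, 1.5),
                             min_sections = 10L, min_run_dd = 0.1) {
  stopifnot(zone[1] > 0, zone[1] < zone[2])
  dd <- if (!is.null(disc$diameter_px)) disc$diameter_px else disc$dd
  if (is.null(profile$dist_dd)) {
    ctr <- disc$center
    profile$dist_dd <- sqrt((profile$x - ctr[1])^2 +
                              (profile$y - ctr[2])^2) / dd
  }
  keep <- profile$dist_dd >= zone[1] & profile$dist_dd <= zone[2] &
    !is.na(profile$label)
  p <- profile[keep, , drop = FALSE]
  min_run_pts <- min_run_dd * dd  # chain points are ~1 px apart
  vessel_means <- function(lab) {
    q <- p[p$label == lab, , drop = FALSE]
    if (nrow(q) == 0) return(list(means = numeric(0), n_sections = 0L))
    runs <- Filter(function(run) nrow(run) >= min_run_pts, split(q, q$edge))
    # outlier guard: a centerline kink can swing the measurement normal
    # obliquely through a junction, producing chords far wider than the
    # vessel; within a run the true width is near-constant, so points
    # beyond 1.5x the run median are artifacts
    runs <- lapply(runs, function(run) {
      run[run$diameter_px <= 1.5 * stats::median(run$diameter_px), ,
          drop = FALSE]
    })
    ns <- 0L
    means <- vapply(runs, function(run) {
      # equal-count bins along the (ordered) run approximate equal arc
      # length because chain points are near-uniformly spaced
      bins <- cut(seq_len(nrow(run)), breaks = max(min_sections, 1L),
                  labels = FALSE)
      sm <- tapply(run$diameter_px, bins, mean, na.rm = TRUE)
      ns <<- ns + sum(!is.na(sm))
      mean(sm, na.rm = TRUE)
    }, numeric(1))
    list(means = means, n_sections = ns)
  }
  va <- vessel_means("artery")
  vv <- vessel_means("vein")
  sa <- va$means; sv <- vv$means
  mean_a <- if (length(sa)) mean(sa, na.rm = TRUE) else NA_real_
  mean_v <- if (length(sv)) mean(sv, na.rm = TRUE) else NA_real_
  complete <- length(sa) > 0 && length(sv) > 0
  rel_a <- mean_a / dd
  rel_v <- mean_v / dd
  structure(list(
    mean_artery_px = mean_a, mean_vein_px = mean_v,
    rel_arteriolar = rel_a, rel_venular = rel_v,
    avr = if (complete) rel_a / rel_v else NA_real_,
    n_sections = c(artery = va$n_sections, vein = vv$n_sections),
    dd_px = dd, zone = zone, complete = complete
  ), class = "caliber_summary")
}
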