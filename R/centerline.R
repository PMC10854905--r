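# Centerline extraction: topology-preserving thinning of the vessel mask
# to a 1-px skeleton, spur pruning, and conversion to a node/edge graph.
# Pure morphological erosion does not leave a connected 1-px medial line,
# so the classical Zhang-Suen iterative thinning is used instead; it erodes
# the mask from both sides while preserving connectivity.

# One pass of Guo-Hall thinning; `sub` selects the subiteration.
# Neighbours p2..p9 run clockwise from north.  Guo-Hall is preferred over
# Zhang-Suen here because it does not leave two-pixel-wide diagonal
# staircases, which would otherwise litter 45-degree vessels with spurious
# junction pixels.
gh_pass <- function(m, sub) {
  p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
  p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
  p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
  p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
  C <- (1 - p2) * pmin(p3 + p4, 1) + (1 - p4) * pmin(p5 + p6, 1) +
    (1 - p6) * pmin(p7 + p8, 1) + (1 - p8) * pmin(p9 + p2, 1)
  n1 <- pmin(p9 + p2, 1) + pmin(p3 + p4, 1) + pmin(p5 + p6, 1) +
    pmin(p7 + p8, 1)
  n2 <- pmin(p2 + p3, 1) + pmin(p4 + p5, 1) + pmin(p6 + p7, 1) +
    pmin(p8 + p9, 1)
  nn <- pmin(n1, n2)
  mm <- if (sub == 1L) pmin(p6 + p7 + (1 - p9), 1) * p8
  else pmin(p2 + p3 + (1 - p5), 1) * p4
  del <- m == 1 & C == 1 & nn >= 2 & nn <= 3 & mm == 0
  m[del] <- 0L
  list(m = m, changed = any(del))
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Guo-Hall iterative thinning: two alternating parallel subiterations
#' peel boundary pixels whose removal does not break 8-connectivity, until
#' stable.
#'
#' @param mask binary matrix (0/1 or logical).
#' @return integer 0/1 matrix of the same size.
#' @export
thin_mask <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1L
  repeat {
    r1 <- gh_pass(m, 1L); m <- r1$m
    r2 <- gh_pass(m, 2L); m <- r2$m
    if (!r1$changed && !r2$changed) break
  }
  m
}

neighbor_count <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) +
    shift_mat(m, 0, -1) + shift_mat(m, 1, 1) + shift_mat(m, 1, -1) +
    shift_mat(m, -1, 1) + shift_mat(m, -1, -1)
}

# offsets of the 8-neighbourhood as (dy, dx); orthogonal steps before
# diagonal ones so chain walking prefers 4-connected moves
.nb8 <- cbind(dy = c(-1, 0, 0, 1, -1, -1, 1, 1),
              dx = c(0, -1, 1, 0, -1, 1, -1, 1))

#' Build a centerline graph from a binary vessel mask
#'
#' Thins the mask, prunes terminal spurs shorter than `spur_len`, and
#' builds a graph whose nodes are skeleton endpoints and junction clusters
#' and whose edges are the ordered 8-connected pixel chains between nodes.
#' Thinning artifacts (staircase pixels with three neighbours mid-line,
#' tiny loops at junctions) are absorbed by clustering junction pixels with
#' their immediate skeleton neighbourhood, dropping short self-loops, and
#' splicing out spurious interior nodes of degree 2.  Optionally labels
#' each edge with the majority artery/vein class from `av_mask`.
#'
#' @param vessel_mask binary matrix.
#' @param spur_len prune terminal branches shorter than this many pixels
#'   (default 5); pruning is iterated until stable.
#' @param av_mask optional 0/1/2 label matrix for edge A/V labels.
#' @return object of class `centerline_graph`: list with `nodes`
#'   (data.frame: id, x, y, degree), `edges` (list; each a list with
#'   `from`, `to`, `path` (n x 2 matrix of 0-based x,y), `length` (arc
#'   length px), `label`), and `skeleton` (the pruned 0/1 matrix).
#' @export
extract_centerline <- function(vessel_mask, spur_len = 5, av_mask = NULL) {
  sk <- thin_mask(vessel_mask)
  g <- skeleton_graph(sk, av_mask)
  repeat {
    pruned <- prune_spurs(g, sk, spur_len)
    if (!pruned$changed) break
    sk <- pruned$skeleton
    g <- skeleton_graph(sk, av_mask)
  }
  g$skeleton <- sk
  g
}

# Remove terminal edges (endpoint on exactly one side) shorter than
# spur_len; never erases a whole isolated component.
prune_spurs <- function(g, sk, spur_len) {
  changed <- FALSE
  if (length(g$edges) == 0) return(list(skeleton = sk, changed = FALSE))
  deg <- g$nodes$degree
  for (e in g$edges) {
    if (e$from == e$to) next
    d_from <- deg[e$from]; d_to <- deg[e$to]
    terminal <- xor(d_from == 1, d_to == 1)
    if (terminal && e$length < spur_len) {
      path <- e$path
      keep_end <- if (d_from == 1) nrow(path) else 1L
      drop <- setdiff(seq_len(nrow(path)), keep_end)
      sk[path[drop, 2] + 1L + nrow(sk) * (path[drop, 1])] <- 0L
      changed <- TRUE
    }
  }
  list(skeleton = sk, changed = changed)
}

skeleton_graph <- function(sk, av_mask = NULL) {
  nr <- nrow(sk); nc <- ncol(sk)
  empty <- structure(list(
    nodes = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       degree = integer(0)),
    edges = list(), skeleton = sk), class = "centerline_graph")
  if (sum(sk) == 0) return(empty)

  nb <- neighbor_count(sk)
  junction <- sk == 1L & nb >= 3L
  endpoint <- sk == 1L & nb <= 1L
  # absorb skeleton pixels adjacent to a junction pixel into the junction
  # cluster, so triangle/staircase artifacts at wide junctions collapse
  # into a single node
  jd <- junction
  if (any(junction)) {
    jd <- EBImage::dilate(junction * 1, EBImage::makeBrush(3, "box")) > 0 & sk == 1L
  }
  is_node_px <- jd | endpoint
  # a simple closed loop has no natural node; break it at an arbitrary pixel
  if (!any(is_node_px)) is_node_px[which(sk == 1L)[1]] <- TRUE

  node_lab <- label8(is_node_px)
  n_nodes <- max(node_lab)
  node_xy <- matrix(0, n_nodes, 2)
  for (i in seq_len(n_nodes)) {
    w <- which(node_lab == i, arr.ind = TRUE)
    node_xy[i, ] <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)  # x, y 0-based
  }
  px_node <- node_lab

  visited <- matrix(FALSE, nr, nc)
  used_dir <- array(FALSE, c(nr, nc, 8))
  dir_index <- function(dy, dx) which(.nb8[, 1] == dy & .nb8[, 2] == dx)

  edges <- list()
  for (lin in which(px_node > 0)) {
    r0 <- ((lin - 1) %% nr) + 1L
    c0 <- ((lin - 1) %/% nr) + 1L
    for (k in 1:8) {
      if (used_dir[r0, c0, k]) next
      r <- r0 + .nb8[k, 1]; cc <- c0 + .nb8[k, 2]
      if (r < 1 || r > nr || cc < 1 || cc > nc || sk[r, cc] == 0L) next
      if (px_node[r, cc] > 0L) next  # intra/adjacent-cluster contact, not a chain
      if (visited[r, cc]) next
      chain_r <- c(r0, r); chain_c <- c(c0, cc)
      used_dir[r0, c0, k] <- TRUE
      pr <- r0; pc <- c0
      while (px_node[r, cc] == 0L) {
        visited[r, cc] <- TRUE
        found <- FALSE
        for (k2 in 1:8) {
          r2 <- r + .nb8[k2, 1]; c2 <- cc + .nb8[k2, 2]
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (sk[r2, c2] == 0L) next
          if (r2 == pr && c2 == pc) next
          if (px_node[r2, c2] == 0L && visited[r2, c2]) next
          pr <- r; pc <- cc; r <- r2; cc <- c2
          chain_r <- c(chain_r, r); chain_c <- c(chain_c, cc)
          found <- TRUE
          break
        }
        if (!found) break  # stranded tail left by a diagonal shortcut
      }
      at_node <- px_node[r, cc] > 0L
      if (at_node) {
        kk <- dir_index(pr - r, pc - cc)
        if (length(kk)) used_dir[r, cc, kk] <- TRUE
      }
      from <- px_node[r0, c0]
      to <- if (at_node) px_node[r, cc] else from
      path <- cbind(x = chain_c - 1, y = chain_r - 1)
      len <- sum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2))
      if (from == to && len < 8) next  # artifact micro-loop
      edges[[length(edges) + 1L]] <- list(
        from = from, to = to, path = path, length = len,
        label = edge_label(path, av_mask))
    }
  }

  # splice out interior nodes of degree 2 (staircase pixels flagged as
  # junctions mid-line): merge their two incident chains into one edge
  repeat {
    deg <- integer(n_nodes)
    inc <- vector("list", n_nodes)
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      deg[e$from] <- deg[e$from] + 1L
      inc[[e$from]] <- c(inc[[e$from]], i)
      if (e$to != e$from) {
        deg[e$to] <- deg[e$to] + 1L
        inc[[e$to]] <- c(inc[[e$to]], i)
      } else {
        deg[e$to] <- deg[e$to] + 1L
      }
    }
    splice <- which(deg == 2 & vapply(inc, length, 1L) == 2)
    if (!length(splice)) break
    n <- splice[1]
    i1 <- inc[[n]][1]; i2 <- inc[[n]][2]
    e1 <- edges[[i1]]; e2 <- edges[[i2]]
    p1 <- if (e1$to == n) e1$path else e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
    a1 <- if (e1$to == n) e1$from else e1$to
    p2 <- if (e2$from == n) e2$path else e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
    a2 <- if (e2$from == n) e2$to else e2$from
    path <- rbind(p1, p2[-1, , drop = FALSE])
    lab <- if (is.na(e1$label) || (!is.na(e2$label) && e2$length > e1$length))
      e2$label else e1$label
    merged <- list(from = a1, to = a2, path = path,
                   length = sum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)),
                   label = lab)
    edges[[i1]] <- merged
    edges[[i2]] <- NULL
  }

  deg <- integer(n_nodes)
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
    if (e$to == e$from) next
  }
  nodes <- data.frame(id = seq_len(n_nodes), x = node_xy[, 1],
                      y = node_xy[, 2], degree = deg)
  structure(list(nodes = nodes, edges = edges, skeleton = sk),
            class = "centerline_graph")
}

# 8-connected labeling of a sparse logical matrix (flood fill over the
# TRUE pixels; intended for small node-pixel sets)
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  nxt <- 0L
  for (lin in todo) {
    if (lab[lin] > 0L) next
    nxt <- nxt + 1L
    queue <- lin
    lab[lin] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1) %% nr) + 1L
      c <- ((cur - 1) %/% nr) + 1L
      for (k in 1:8) {
        rr <- r + .nb8[k, 1]; cc <- c + .nb8[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!mask[rr, cc] || lab[rr, cc] > 0L) next
        lab[rr, cc] <- nxt
        queue <- c(queue, rr + nr * (cc - 1L))
      }
    }
  }
  lab
}

edge_label <- function(path, av_mask) {
  if (is.null(av_mask)) return(NA_character_)
  vals <- av_mask[cbind(path[, 2] + 1L, path[, 1] + 1L)]
  vals <- vals[vals > 0]
  if (!length(vals)) return(NA_character_)
  c("artery", "vein")[which.max(tabulate(vals, 2))]
}
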