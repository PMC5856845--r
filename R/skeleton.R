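# Medial-axis skeletonization (Zhang-Suen thinning) and skeleton-graph
# construction. The graph is the substrate for all length/branch morphometry:
# nodes are fiber endpoints and junction clusters, edges are ordered pixel
# paths between them.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

neighbor_offsets <- cbind(
  dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
  dc = c(0, 1, 1, 1, 0, -1, -1, -1)
)

# Zhang-Suen thinning to a 1-px-wide, 8-connected medial axis.
thin_mask <- function(m) {
  img <- m != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      del <- img & B >= 2 & B <= 6 & A == 1
      del <- if (step == 1) {
        del & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        del & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_cleanup(img)
}

# Pairwise 8-adjacency between the 8 ring positions around a pixel
# (diagonally neighboring ring positions touch even when the position
# between them is empty).
ring_adjacency <- local({
  off <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                ncol = 2L, byrow = TRUE)
  adj <- matrix(FALSE, 8L, 8L)
  for (i in 1:8) for (j in 1:8) {
    adj[i, j] <- i != j && max(abs(off[i, ] - off[j, ])) <= 1L
  }
  adj
})

# Number of 8-connected components among the active ring positions.
neighbor_components <- function(v) {
  act <- which(v)
  if (!length(act)) return(0L)
  comp <- 0L
  seen <- logical(8L)
  for (s in act) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      nb <- act[ring_adjacency[q, act] & !seen[act]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

ring_values <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  v <- logical(8L)
  off <- neighbor_offsets
  for (k in 1:8) {
    rr <- r + off[k, 1]; cc <- c + off[k, 2]
    v[k] <- rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && img[rr, cc]
  }
  v
}

# Zhang-Suen leaves redundant staircase pixels that read as spurious
# junctions. Sequentially remove any non-endpoint pixel whose neighbors
# form a single 8-connected component: removing such a pixel cannot break
# connectivity, and the result is a minimal 8-connected skeleton.
thin_cleanup <- function(img) {
  repeat {
    changed <- FALSE
    px <- which(img, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      if (!img[r, c]) next
      v <- ring_values(img, r, c)
      if (sum(v) >= 2L && neighbor_components(v) == 1L) {
        img[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

neighbor_count <- function(sk) {
  n <- matrix(0L, nrow(sk), ncol(sk))
  for (i in seq_len(nrow(neighbor_offsets))) {
    n <- n + shift_mat(sk, neighbor_offsets[i, 1], neighbor_offsets[i, 2])
  }
  n
}

# Moving-average smoothing of an ordered pixel path (endpoints pinned);
# removes the staircase quantization of the digital medial axis so
# Euclidean segment sums estimate the true curve length without the
# chain-code bias, while edges keep their exact endpoints.
smooth_path <- function(path, window = 5L) {
  n <- nrow(path)
  if (n < 3L) return(path)
  half <- window %/% 2L
  out <- path
  for (i in 2:(n - 1L)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i, ] <- colMeans(path[j, , drop = FALSE])
  }
  out
}

path_length_px <- function(path, method = "smoothed", window = 5L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  p <- if (method == "smoothed") smooth_path(path, window) else path
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  sum(d)
}

# Per-pixel step lengths (px) along the (smoothed) path; ends carry half
# segments so the sum equals the path length.
path_steps_px <- function(path, method = "smoothed", window = 5L) {
  n <- nrow(path)
  if (n == 1L) return(0)
  p <- if (method == "smoothed") smooth_path(path, window) else path
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  c(d[1] / 2, (head(d, -1) + tail(d, -1)) / 2, d[n - 1L] / 2)
}

empty_graph <- function(sk, cal, length_method) {
  structure(list(nodes = list(), edges = list(), skeleton = sk,
                 calibration = cal, length_method = length_method),
            class = "skeleton_graph")
}

#' Skeletonize a nerve mask into a medial-axis graph
#'
#' Thins the binary mask to a one-pixel-wide medial axis (Zhang-Suen), then
#' classifies skeleton pixels by their 8-neighbor count: count 1 = fiber
#' endpoint, count >= 3 = junction. Adjacent junction pixels are merged into
#' a single junction node. Edges are the ordered pixel paths between nodes.
#'
#' Edge lengths are geometric. By default each traced path is lightly
#' smoothed (moving average over `smooth_window` pixels) before summing
#' Euclidean segment lengths, which removes the staircase bias of the raw
#' 8-connected chain; `length_method = "chain"` gives the classic rule
#' (axial step = pitch, diagonal step = sqrt(2) * pitch).
#'
#' Terminal twigs shorter than `prune_um` that hang off a junction are
#' pruned (thinning artefacts of rough boundaries), and junctions left with
#' exactly two edges are dissolved by merging their edges.
#'
#' @param mask A `nerve_mask` (or 0/1 matrix, HRT III calibration assumed).
#' @param prune_um Prune terminal spurs shorter than this (set 0 to disable).
#' @param fill_holes_px Before thinning, fill interior background holes
#'   smaller than this (px). Isolated sub-threshold pixels inside a bundle
#'   would otherwise force the medial axis to wrap around them, producing
#'   spurious loops and junctions; the nerve mask itself (and hence the
#'   pixel-counting area) is not modified.
#' @param length_method `"smoothed"` or `"chain"`.
#' @param smooth_window Moving-average window for `"smoothed"` lengths.
#' @return A `skeleton_graph`: `nodes` (list of id/type/member pixels),
#'   `edges` (list of id/from/to/path/length_um/chain_um), the thinned
#'   `skeleton` matrix, and the calibration.
#' @export
skeletonize_mask <- function(mask, prune_um = 5, fill_holes_px = 9L,
                             length_method = c("smoothed", "chain"),
                             smooth_window = 5L) {
  length_method <- match.arg(length_method)
  if (is.matrix(mask)) mask <- nerve_mask(mask)
  stopifnot(inherits(mask, "nerve_mask"))
  cal <- mask$calibration
  pitch <- cal$pixel_pitch_um
  m <- mask$mask
  if (fill_holes_px > 0L && any(m > 0)) {
    bg <- cc_label(1L - m)
    if (max(bg) > 1L) {
      sizes <- tabulate(bg[bg > 0])
      # keep the big outer background; fill small enclosed components
      fill <- which(sizes < fill_holes_px)
      if (length(fill)) m[matrix(bg %in% fill, nrow(m))] <- 1L
    }
  }
  sk <- thin_mask(m)
  if (!any(sk)) return(empty_graph(sk, cal, length_method))

  deg <- neighbor_count(sk)
  nr <- nrow(sk); nc <- ncol(sk)
  # classify by the number of 8-connected neighbor components: 1 =
  # endpoint, 2 = path, >= 3 = junction (robust against residual staircase
  # configurations where the raw neighbor count overshoots)
  ncomp <- matrix(0L, nr, nc)
  skpx <- which(sk, arr.ind = TRUE)
  for (i in seq_len(nrow(skpx))) {
    ncomp[skpx[i, 1], skpx[i, 2]] <-
      neighbor_components(ring_values(sk, skpx[i, 1], skpx[i, 2]))
  }

  node_id <- matrix(0L, nr, nc)
  nodes <- list()
  add_node <- function(px, type) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, type = type,
                         px = matrix(px, ncol = 2L),
                         centroid = colMeans(matrix(px, ncol = 2L)))
    node_id[matrix(px, ncol = 2L)] <<- id
    id
  }

  ep <- which(sk & deg == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(ep))) add_node(ep[i, ], "endpoint")
  iso <- which(sk & deg == 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(iso))) add_node(iso[i, ], "endpoint")

  # merge adjacent junction pixels into one node (BFS clustering)
  jmat <- sk & ncomp >= 3L
  jpix <- which(jmat, arr.ind = TRUE)
  jseen <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(jpix))) {
    r0 <- jpix[i, 1]; c0 <- jpix[i, 2]
    if (jseen[r0, c0]) next
    queue <- list(c(r0, c0)); jseen[r0, c0] <- TRUE
    members <- NULL
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, q)
      for (k in seq_len(8L)) {
        rr <- q[1] + neighbor_offsets[k, 1]; cc <- q[2] + neighbor_offsets[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            jmat[rr, cc] && !jseen[rr, cc]) {
          jseen[rr, cc] <- TRUE
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
    add_node(members, "junction")
  }

  sk_at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && sk[r, c]
  nbrs <- function(r, c) {
    out <- NULL
    for (k in seq_len(8L)) {
      rr <- r + neighbor_offsets[k, 1]; cc <- c + neighbor_offsets[k, 2]
      if (sk_at(rr, cc)) out <- rbind(out, c(rr, cc))
    }
    out
  }

  edges <- list()
  seen_pair <- new.env(parent = emptyenv())
  visited <- matrix(FALSE, nr, nc)
  add_edge <- function(from, to, path) {
    id <- length(edges) + 1L
    edges[[id]] <<- list(id = id, from = from, to = to, path = path)
    id
  }

  for (nd in nodes) {
    for (m in seq_len(nrow(nd$px))) {
      q <- nd$px[m, ]
      nb <- nbrs(q[1], q[2])
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        p <- nb[j, ]
        pid <- node_id[p[1], p[2]]
        if (pid > 0L) {
          if (pid == nd$id) next
          key <- paste(min(nd$id, pid), max(nd$id, pid),
                       paste(sort(c(paste(q, collapse = ","),
                                    paste(p, collapse = ","))),
                             collapse = "|"))
          if (!is.null(seen_pair[[key]])) next
          seen_pair[[key]] <- TRUE
          add_edge(nd$id, pid, rbind(q, p))
        } else {
          if (visited[p[1], p[2]]) next
          path <- rbind(q, p)
          prev <- q; cur <- p
          repeat {
            visited[cur[1], cur[2]] <- TRUE
            nb2 <- nbrs(cur[1], cur[2])
            keep <- !(nb2[, 1] == prev[1] & nb2[, 2] == prev[2])
            nb2 <- nb2[keep, , drop = FALSE]
            if (nrow(nb2) == 0L) {        # dead end not marked as node
              to <- add_node(cur, "endpoint")
              add_edge(nd$id, to, path)
              break
            }
            nids <- node_id[nb2]
            if (any(nids > 0L)) {
              pick <- which(nids > 0L)[1]
              path <- rbind(path, nb2[pick, ])
              add_edge(nd$id, nids[pick], path)
              break
            }
            unv <- !visited[nb2]
            if (!any(unv)) {
              # path curls back on itself with no node to land on; anchor
              # the free end so the geometry is kept
              to <- add_node(cur, "endpoint")
              add_edge(nd$id, to, path)
              break
            }
            nxt <- nb2[which(unv)[1], ]
            path <- rbind(path, nxt)
            prev <- cur; cur <- nxt
          }
        }
      }
    }
  }

  # isolated cycles: degree-2 pixels never visited and not nodes
  left <- which(sk & !visited & node_id == 0L & deg == 2L, arr.ind = TRUE)
  for (i in seq_len(nrow(left))) {
    q <- left[i, ]
    if (visited[q[1], q[2]]) next
    nid <- add_node(q, "junction")
    nb <- nbrs(q[1], q[2])
    p <- nb[1, ]
    path <- rbind(q, p)
    prev <- q; cur <- p
    repeat {
      visited[cur[1], cur[2]] <- TRUE
      nb2 <- nbrs(cur[1], cur[2])
      keep <- !(nb2[, 1] == prev[1] & nb2[, 2] == prev[2])
      nb2 <- nb2[keep, , drop = FALSE]
      if (nrow(nb2) == 0L) break
      if (any(node_id[nb2] == nid)) {
        path <- rbind(path, q)
        break
      }
      nxt <- nb2[1, ]
      path <- rbind(path, nxt)
      prev <- cur; cur <- nxt
    }
    add_edge(nid, nid, path)
  }

  g <- structure(list(nodes = nodes, edges = edges, skeleton = sk,
                      calibration = cal, length_method = length_method,
                      smooth_window = smooth_window),
                 class = "skeleton_graph")
  g <- reconnect_ends(g)
  g <- set_edge_lengths(g)
  if (prune_um > 0) g <- prune_graph(g, prune_um)
  g
}

# Digital skeletons of shallow-angle junctions often trace as a smooth
# pass-through plus a dangling end: the through-going pair of arms reads as
# one path and the third arm stops dead beside it without a junction pixel
# ever being classified. Snap each degree-1 endpoint that touches another
# edge's interior onto that edge, splitting it and creating the junction
# the geometry implies.
reconnect_ends <- function(g) {
  if (length(g$edges) < 2L) return(g)
  nr <- nrow(g$skeleton); nc <- ncol(g$skeleton)
  repeat {
    edge_at <- matrix(0L, nr, nc)    # edge id covering each interior pixel
    idx_at <- matrix(0L, nr, nc)
    for (e in g$edges) {
      n <- nrow(e$path)
      if (n < 3L) next
      ii <- 2:(n - 1L)
      edge_at[e$path[ii, , drop = FALSE]] <- e$id
      idx_at[e$path[ii, , drop = FALSE]] <- ii
    }
    degs <- node_degree(g)
    done <- TRUE
    for (nid in seq_along(g$nodes)) {
      nd <- g$nodes[[nid]]
      if (nd$type != "endpoint" || degs[nid] != 1L) next
      ei <- which(vapply(g$edges, function(e)
        e$from == nid || e$to == nid, logical(1)))[1]
      if (is.na(ei)) next
      px <- nd$px[1, ]
      hit_edge <- 0L; hit_idx <- 0L
      for (k in seq_len(8L)) {
        rr <- px[1] + neighbor_offsets[k, 1]
        cc <- px[2] + neighbor_offsets[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        id <- edge_at[rr, cc]
        if (id > 0L && id != g$edges[[ei]]$id) {
          hit_edge <- id; hit_idx <- idx_at[rr, cc]
          break
        }
      }
      if (hit_edge == 0L) next
      fi <- which(vapply(g$edges, function(e) e$id == hit_edge,
                         logical(1)))[1]
      f <- g$edges[[fi]]
      n <- nrow(f$path)
      jpx <- f$path[hit_idx, ]
      if (hit_idx <= 2L) {               # effectively at f's start node
        jid <- f$from
      } else if (hit_idx >= n - 1L) {
        jid <- f$to
      } else {
        jid <- length(g$nodes) + 1L
        g$nodes[[jid]] <- list(id = jid, type = "junction",
                               px = matrix(jpx, ncol = 2L),
                               centroid = jpx)
        f1 <- list(id = f$id, from = f$from, to = jid,
                   path = f$path[1:hit_idx, , drop = FALSE])
        f2 <- list(id = length(g$edges) + 1L, from = jid, to = f$to,
                   path = f$path[hit_idx:n, , drop = FALSE])
        g$edges[[fi]] <- f1
        g$edges[[length(g$edges) + 1L]] <- f2
      }
      e <- g$edges[[ei]]
      if (e$to == nid) {
        e$path <- rbind(e$path, jpx); e$to <- jid
      } else {
        e$path <- rbind(jpx, e$path); e$from <- jid
      }
      g$edges[[ei]] <- e
      g$nodes[[nid]]$type <- "merged"    # detached; no longer referenced
      done <- FALSE
      break                              # indices changed; rescan
    }
    if (done) break
  }
  for (i in seq_along(g$edges)) g$edges[[i]]$id <- i
  g
}

set_edge_lengths <- function(g) {
  pitch <- g$calibration$pixel_pitch_um
  g$edges <- lapply(g$edges, function(e) {
    e$chain_um <- path_length_px(e$path, "chain") * pitch
    e$length_um <- path_length_px(e$path, g$length_method,
                                  g$smooth_window) * pitch
    e
  })
  g
}

node_degree <- function(g) {
  degs <- integer(length(g$nodes))
  for (e in g$edges) {
    degs[e$from] <- degs[e$from] + 1L
    degs[e$to] <- degs[e$to] + 1L
  }
  degs
}

# Remove terminal twigs shorter than prune_um that hang off a junction, then
# dissolve junctions left with exactly two edges by merging their edges.
prune_graph <- function(g, prune_um) {
  for (iter in 1:5) {
    if (!length(g$edges)) break
    degs <- node_degree(g)
    types <- vapply(g$nodes, function(n) n$type, character(1))
    drop <- vapply(g$edges, function(e) {
      # tiny self-loops are thinning artefacts at crossings
      if (e$from == e$to) return(e$length_um < 2 * prune_um)
      spur_from <- types[e$from] == "endpoint" && degs[e$from] == 1L &&
        types[e$to] == "junction"
      spur_to <- types[e$to] == "endpoint" && degs[e$to] == 1L &&
        types[e$from] == "junction"
      (spur_from || spur_to) && e$length_um < prune_um
    }, logical(1))
    merged <- FALSE
    if (any(drop)) g$edges <- g$edges[!drop]
    # dissolve junctions that now join exactly two edges
    degs <- node_degree(g)
    for (nid in seq_along(g$nodes)) {
      if (g$nodes[[nid]]$type != "junction" || degs[nid] != 2L) next
      inc <- which(vapply(g$edges, function(e)
        e$from == nid || e$to == nid, logical(1)))
      if (length(inc) != 2L) next   # both ends of a loop on this node
      e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
      # orient e1 to end at nid and e2 to start at nid
      if (e1$from == nid) {
        e1$path <- e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
        e1$from <- e1$to
      }
      if (e2$to == nid) {
        e2$path <- e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
        e2$to <- e2$from
      }
      new_edge <- list(id = e1$id, from = e1$from, to = e2$to,
                       path = rbind(e1$path,
                                    e2$path[-1, , drop = FALSE]))
      g$edges[[inc[1]]] <- new_edge
      g$edges <- g$edges[-inc[2]]
      merged <- TRUE
      break                         # degrees changed; restart scan
    }
    for (i in seq_along(g$edges)) g$edges[[i]]$id <- i
    g <- set_edge_lengths(g)
    if (!any(drop) && !merged) break
  }
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  types <- vapply(x$nodes, function(n) n$type, character(1))
  cat(sprintf(
    "Skeleton graph: %d edges, %d endpoints, %d junctions, %.1f um total\n",
    length(x$edges), sum(types == "endpoint"), sum(types == "junction"),
    total_skeleton_length_um(x)))
  invisible(x)
}

#' Total geometric skeleton length
#'
#' @param graph A `skeleton_graph`.
#' @return Total edge length in micrometres.
#' @export
total_skeleton_length_um <- function(graph) {
  if (!length(graph$edges)) return(0)
  sum(vapply(graph$edges, function(e) e$length_um, numeric(1)))
}
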