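# Main-fiber / branch classification on the skeleton graph. Main nerve
# fiber bundles are reconstructed by chaining edges across junctions along
# the straightest continuation; stubs attached to a main fiber are branches.

# Outward unit direction of an edge at one of its end nodes. Estimated
# over a stretch of the smoothed path that skips the first couple of
# pixels: digital junctions typically jog sideways for 1-3 px before the
# path settles on the fiber's true course, and a direction read off those
# pixels alone badly misjudges the turning angle.
edge_direction <- function(edge, at_node, window = 5L,
                           skip = 2L, span = 14L) {
  p <- smooth_path(edge$path, window)
  n <- nrow(p)
  a <- min(n - 1L, skip + 1L)
  b <- min(n, skip + span)
  if (edge$from == at_node && edge$to == at_node) {
    v <- p[min(2L, n), ] - p[1L, ]          # loop: arbitrary but defined
  } else if (edge$from == at_node) {
    v <- p[b, ] - p[a, ]
    if (all(v == 0)) v <- p[n, ] - p[1L, ]
  } else {
    v <- p[n - b + 1L, ] - p[n - a + 1L, ]
    if (all(v == 0)) v <- p[1L, ] - p[n, ]
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(1, 0) else v / nv
}

#' Classify skeleton edges into main fibers, branches and orphans
#'
#' Main nerve fiber bundles are maximal chains of edges. At every junction,
#' incident edges are paired greedily by straightest continuation: the pair
#' with the smallest turning angle is joined first, then the next, while the
#' turning angle stays below `max_turn_deg`. Chains whose total length
#' reaches `main_min_length_um` are main fibers. Remaining edges of length
#' at least `branch_min_length_um` that touch a main fiber at a junction are
#' branches (each attached to exactly one main fiber; ties go to the longest
#' main). Everything else is an orphan; orphans still count towards total
#' fiber length but not towards fiber or branch counts.
#'
#' Chains whose free ends face each other across a small gap (within
#' `bridge_gap_um`, directions aligned within `bridge_angle_deg`) are
#' counted as one fiber: segmentation can drop a few pixels of a bundle at
#' a dim stretch, and without linking each fragment would be counted as a
#' separate fiber. The gap itself contributes no length.
#'
#' @param graph A [skeletonize_mask()] result.
#' @param main_min_length_um Minimum chain length of a main fiber.
#' @param branch_min_length_um Minimum edge length of a counted branch.
#' @param max_turn_deg Largest turning angle regarded as a continuation.
#' @param bridge_gap_um Maximum gap between facing chain ends to link
#'   across (0 disables linking).
#' @param bridge_angle_deg Maximum misalignment for linking.
#' @return A `fiber_set`: `main_fibers` (list of edge-id chains with
#'   lengths), `branches` (data.frame edge_id/main_id/length_um), `orphans`
#'   (edge ids), plus counts.
#' @export
classify_fibers <- function(graph, main_min_length_um = 50,
                            branch_min_length_um = 10,
                            max_turn_deg = 75,
                            bridge_gap_um = 15,
                            bridge_angle_deg = 40) {
  edges <- graph$edges
  empty <- structure(list(main_fibers = list(),
                          branches = data.frame(edge_id = integer(),
                                                main_id = integer(),
                                                length_um = numeric()),
                          orphans = integer(),
                          n_main = 0L, n_branch = 0L,
                          calibration = graph$calibration),
                     class = "fiber_set")
  if (!length(edges)) return(empty)

  # pairing[edge, end] -> id of the edge continued into (0 = chain stops);
  # ends: 1 = "from" side, 2 = "to" side
  n_e <- length(edges)
  pair_edge <- matrix(0L, n_e, 2L)
  pair_end <- matrix(0L, n_e, 2L)
  end_of <- function(e, nid) if (edges[[e]]$from == nid) 1L else 2L

  for (nid in seq_along(graph$nodes)) {
    if (graph$nodes[[nid]]$type != "junction") next
    inc <- NULL     # rows: edge id, end index
    for (e in seq_len(n_e)) {
      if (edges[[e]]$from == nid) inc <- rbind(inc, c(e, 1L))
      if (edges[[e]]$to == nid && edges[[e]]$from != nid)
        inc <- rbind(inc, c(e, 2L))
    }
    if (is.null(inc) || nrow(inc) < 2L) next
    dirs <- t(apply(inc, 1L, function(x)
      edge_direction(edges[[x[1]]], nid, graph$smooth_window %||% 5L)))
    m <- nrow(inc)
    cand <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        # turning angle between entering along edge i and leaving along j
        cosang <- sum(-dirs[i, ] * dirs[j, ])
        turn <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        cand <- rbind(cand, c(i, j, turn))
      }
    }
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    used <- logical(m)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used[i] || used[j] || cand[k, 3] > max_turn_deg) next
      used[i] <- used[j] <- TRUE
      ei <- inc[i, 1]; si <- inc[i, 2]
      ej <- inc[j, 1]; sj <- inc[j, 2]
      pair_edge[ei, si] <- ej; pair_end[ei, si] <- sj
      pair_edge[ej, sj] <- ei; pair_end[ej, sj] <- si
    }
  }

  # walk chains through the pairings
  assigned <- logical(n_e)
  chains <- list()
  for (e0 in seq_len(n_e)) {
    if (assigned[e0]) next
    chain <- e0
    assigned[e0] <- TRUE
    for (side in 1:2) {
      e <- e0; s <- side
      repeat {
        nxt <- pair_edge[e, s]
        if (nxt == 0L || assigned[nxt]) break
        assigned[nxt] <- TRUE
        chain <- if (side == 1L) c(nxt, chain) else c(chain, nxt)
        # continue out of the far end of nxt
        s <- 3L - pair_end[e, s]
        e <- nxt
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }

  lens <- vapply(edges, function(e) e$length_um, numeric(1))

  # link chains whose free ends face each other across a small gap
  if (bridge_gap_um > 0 && length(chains) > 1L) {
    pitch <- graph$calibration$pixel_pitch_um
    node_deg <- integer(length(graph$nodes))
    for (e in edges) {
      node_deg[e$from] <- node_deg[e$from] + 1L
      node_deg[e$to] <- node_deg[e$to] + 1L
    }
    ends <- NULL
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      for (eid in unique(c(ch[1], ch[length(ch)]))) {
        e <- edges[[eid]]
        for (nid in c(e$from, e$to)) {
          if (node_deg[nid] != 1L) next
          if (graph$nodes[[nid]]$type != "endpoint") next
          o <- edge_direction(e, nid, graph$smooth_window %||% 5L)
          ends <- rbind(ends, data.frame(
            chain = ci, r = graph$nodes[[nid]]$centroid[1],
            c = graph$nodes[[nid]]$centroid[2], or = o[1], oc = o[2]))
        }
      }
    }
    parent <- seq_along(chains)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (!is.null(ends) && nrow(ends) > 1L) {
      cand <- NULL
      for (i in seq_len(nrow(ends) - 1L)) {
        for (j in (i + 1L):nrow(ends)) {
          if (ends$chain[i] == ends$chain[j]) next
          v <- c(ends$r[j] - ends$r[i], ends$c[j] - ends$c[i])
          gap <- sqrt(sum(v^2)) * pitch
          if (gap > bridge_gap_um || gap == 0) next
          u <- v / sqrt(sum(v^2))
          ang <- function(a, b) acos(pmin(1, pmax(-1, sum(a * b)))) * 180 / pi
          # ends must point away from their chains, towards each other
          if (ang(c(-ends$or[i], -ends$oc[i]), u) > bridge_angle_deg) next
          if (ang(c(-ends$or[j], -ends$oc[j]), -u) > bridge_angle_deg) next
          cand <- rbind(cand, c(i, j, gap))
        }
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand[, 3]), , drop = FALSE]
        used <- logical(nrow(ends))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used[i] || used[j]) next
          used[i] <- used[j] <- TRUE
          parent[find(ends$chain[i])] <- find(ends$chain[j])
        }
      }
    }
    groups <- vapply(seq_along(chains), find, integer(1))
    merged <- lapply(unique(groups), function(gid)
      unlist(chains[groups == gid]))
    chains <- merged
  }

  chain_len <- vapply(chains, function(ch) sum(lens[ch]), numeric(1))
  is_main_chain <- chain_len >= main_min_length_um
  main_fibers <- lapply(which(is_main_chain), function(i)
    list(edge_ids = chains[[i]], length_um = chain_len[i]))

  main_edge_ids <- unlist(lapply(main_fibers, function(f) f$edge_ids))
  # nodes touched by each main fiber
  main_nodes <- lapply(main_fibers, function(f)
    unique(unlist(lapply(edges[f$edge_ids], function(e) c(e$from, e$to)))))

  branches <- NULL
  orphans <- integer()
  rest <- setdiff(seq_len(n_e), main_edge_ids)
  main_len <- vapply(main_fibers, function(f) f$length_um, numeric(1))
  for (e in rest) {
    if (lens[e] >= branch_min_length_um && length(main_fibers)) {
      touch <- which(vapply(main_nodes, function(nd)
        edges[[e]]$from %in% nd || edges[[e]]$to %in% nd, logical(1)))
      if (length(touch)) {
        mid <- touch[which.max(main_len[touch])]
        branches <- rbind(branches,
                          data.frame(edge_id = e, main_id = mid,
                                     length_um = lens[e]))
        next
      }
    }
    orphans <- c(orphans, e)
  }
  if (is.null(branches)) branches <- empty$branches

  structure(list(main_fibers = main_fibers, branches = branches,
                 orphans = orphans,
                 n_main = length(main_fibers), n_branch = nrow(branches),
                 calibration = graph$calibration),
            class = "fiber_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("Fiber set: %d main fibers, %d branches, %d orphan segments\n",
              x$n_main, x$n_branch, length(x$orphans)))
  invisible(x)
}
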