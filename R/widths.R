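# Per-skeleton-pixel fiber bundle width from the Euclidean distance
# transform of the nerve mask.

#' Measure fiber bundle widths along the skeleton
#'
#' The width at each skeleton pixel is twice the Euclidean distance from the
#' pixel to the mask boundary: with `d` the distance-transform value
#' (distance to the nearest background pixel centre), width = `2 d - 1`
#' pixels, rounded to the nearest integer and clamped to 1..8 pixels - a
#' one-pixel line reads 1, a five-pixel bar reads 5, anything 8 px or wider
#' saturates at 8. The distance values are averaged over a 5-pixel window
#' along each edge before rounding, which removes the odd/even parity
#' artefact of the discrete distance transform on oblique fibers. Each
#' edge-path pixel also carries its local step length `dl_um` (half the
#' distance to each path neighbour), used for length-weighted integrals.
#'
#' @param mask The `nerve_mask` the skeleton was derived from.
#' @param graph The [skeletonize_mask()] result for that mask.
#' @param max_width_px Saturation width (px).
#' @return A `width_profile`: data.frame with columns `edge_id`, `r`, `c`,
#'   `width_px`, `width_um`, `dl_um`, plus the calibration as an attribute.
#' @export
measure_widths <- function(mask, graph, max_width_px = 8L) {
  if (is.matrix(mask)) mask <- nerve_mask(mask)
  stopifnot(inherits(mask, "nerve_mask"),
            inherits(graph, "skeleton_graph"))
  cal <- mask$calibration
  pitch <- cal$pixel_pitch_um
  if (!length(graph$edges)) {
    out <- data.frame(edge_id = integer(), r = integer(), c = integer(),
                      width_px = integer(), width_um = numeric(),
                      dl_um = numeric())
    attr(out, "calibration") <- cal
    class(out) <- c("width_profile", "data.frame")
    return(out)
  }
  dmap <- edt(mask$mask)
  rows <- lapply(graph$edges, function(e) {
    d <- dmap[e$path]
    # average the distance values over a short window along the path
    # before rounding: on a digitized oblique fiber the raw values
    # alternate with sub-pixel position, which would otherwise push even
    # widths systematically onto odd bins
    if (length(d) > 2L) {
      half <- 2L
      d <- vapply(seq_along(d), function(i) {
        mean(d[max(1L, i - half):min(length(d), i + half)])
      }, numeric(1))
    }
    w <- pmin(max_width_px, pmax(1L, as.integer(round(2 * d - 1))))
    data.frame(edge_id = e$id, r = e$path[, 1], c = e$path[, 2],
               width_px = w, width_um = w * pitch,
               dl_um = path_steps_px(e$path, graph$length_method,
                                     graph$smooth_window) * pitch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calibration") <- cal
  class(out) <- c("width_profile", "data.frame")
  out
}

# Width by explicit perpendicular ray casting at a skeleton pixel; used as a
# cross-check of the distance-transform estimator on simple fixtures.
# tangent: unit vector along the fiber at (r, c).
width_raycast <- function(mask, r, c, tangent, step = 0.1, max_px = 20) {
  m <- if (inherits(mask, "nerve_mask")) mask$mask else mask
  normal <- c(-tangent[2], tangent[1])
  inside <- function(p) {
    ri <- round(p[1]); ci <- round(p[2])
    ri >= 1 && ri <= nrow(m) && ci >= 1 && ci <= ncol(m) && m[ri, ci] > 0
  }
  reach <- function(sgn) {
    t <- 0
    while (t < max_px && inside(c(r, c) + sgn * (t + step) * normal)) {
      t <- t + step
    }
    t
  }
  reach(1) + reach(-1) + 1   # +1: the pixel itself
}
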