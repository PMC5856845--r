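#' Per-image CCM morphometry endpoints
#'
#' Combines a fiber classification, a width profile and the nerve mask into
#' the five standard endpoints, all normalized by the imaged field area:
#'
#' * `nfd` - main nerve fiber bundles per mm^2;
#' * `nbd` - branches per mm^2;
#' * `nfl` - total skeleton length, mm per mm^2 (main + branch + orphan);
#' * `nfa_wxl` - fiber bundle width integrated along the skeleton,
#'   um^2 per mm^2 (the width-times-length area);
#' * `nfa_fiji` - pixel-counting mask area, um^2 per mm^2
#'   ([compute_nfa_fiji()]);
#' * `mean_width_um` - length-weighted mean bundle width, so that
#'   `nfa_wxl = 1000 * nfl * mean_width_um` by construction.
#'
#' A literal product variant of the width-times-length area (sum of width
#' pixels times the number of skeleton pixels) is attached as attribute
#' `nfa_wxl_literal` when `literal = TRUE`; it is kept for comparison only,
#' since its magnitude is not an area density.
#'
#' @param fibers A [classify_fibers()] result.
#' @param widths A [measure_widths()] result from the same mask.
#' @param mask The `nerve_mask` both were derived from.
#' @param literal Also compute the literal sum-times-sum product.
#' @return A one-row data.frame of class `ccm_variables`.
#' @export
compute_variables <- function(fibers, widths, mask, literal = FALSE) {
  if (is.matrix(mask)) mask <- nerve_mask(mask)
  stopifnot(inherits(fibers, "fiber_set"),
            inherits(widths, "width_profile"),
            inherits(mask, "nerve_mask"))
  cal <- mask$calibration
  wcal <- attr(widths, "calibration")
  if (!isTRUE(all.equal(cal$pixel_pitch_um, wcal$pixel_pitch_um)) ||
      cal$field_width_px != wcal$field_width_px ||
      cal$field_height_px != wcal$field_height_px) {
    stop("width profile and mask carry different calibrations",
         call. = FALSE)
  }
  area <- cal$field_area_mm2
  total_len_um <- sum(widths$dl_um)
  nfl <- total_len_um / 1000 / area
  nfa_wxl <- sum(widths$width_um * widths$dl_um) / area
  mean_w <- if (total_len_um > 0) {
    sum(widths$width_um * widths$dl_um) / total_len_um
  } else 0
  out <- data.frame(
    nfd = fibers$n_main / area,
    nbd = fibers$n_branch / area,
    nfl = nfl,
    nfa_wxl = nfa_wxl,
    nfa_fiji = compute_nfa_fiji(mask),
    mean_width_um = mean_w
  )
  if (literal) {
    dedup <- !duplicated(widths[, c("r", "c")])
    attr(out, "nfa_wxl_literal") <-
      sum(widths$width_px[dedup]) * sum(dedup)
  }
  class(out) <- c("ccm_variables", "data.frame")
  out
}
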