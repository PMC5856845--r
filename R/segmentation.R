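#' Segmentation parameters for the pixel-counting nerve fiber area algorithm
#'
#' The segmentation pipeline is: (1) Gaussian contrast enhancement at
#' `enhance_sigma_px`; (2) an adaptive threshold against a large-scale
#' Gaussian estimate of local background brightness, with the margin set to
#' `threshold_k` times the local contrast spread - the local peak contrast
#' above background (greyscale dilation over a disc of `spread_radius_px`),
#' floored at `noise_floor_k` times the robust global noise scale (MAD of
#' the contrast image); (3) a tubularity gate - a Hessian-eigenvalue
#' (Frangi-type) ridge filter evaluated at `tubularity_scales_px`,
#' thresholded at `tubularity_cutoff`; (4) removal of connected components
#' smaller than `min_component_px`.
#'
#' Because the local spread tracks each bundle's own peak contrast, the
#' default `threshold_k = 0.5` cuts every bundle near half of its peak
#' brightness, which makes the mask width track the full width at half
#' maximum of the bundle's intensity profile independent of how bright it
#' is; the noise floor keeps background noise out in fiber-free regions.
#'
#' Defaults were calibrated on seeded synthetic plexus phantoms (widths
#' 2-6 px, signal-to-noise >= 5) so that mask area, skeleton length and
#' distance-transform widths recover the phantom ground truth; see the
#' package vignette for the calibration procedure.
#'
#' @param enhance_sigma_px Gaussian scale (px) of the contrast-enhancement
#'   blur applied before thresholding.
#' @param bg_sigma_px Gaussian scale (px) of the background-brightness
#'   estimate; should be much larger than any fiber width.
#' @param spread_radius_px Disc radius (px) of the local peak-contrast
#'   (greyscale dilation) window; should exceed half the largest expected
#'   bundle width.
#' @param noise_floor_k Noise floor in units of the MAD of the contrast
#'   image; `threshold_k * noise_floor_k * MAD` is the minimum margin
#'   applied in fiber-free regions.
#' @param threshold_k Multiplier on the local contrast spread added to the
#'   background before thresholding.
#' @param tubularity_scales_px Hessian scales (px) of the ridge filter;
#'   chosen to bracket expected fiber half-widths.
#' @param tubularity_smooth_px Gaussian scale (px) applied to the ridge
#'   response before gating. Eigenvalue ridge filters respond weakly
#'   exactly at crossings and branch points (both principal curvatures are
#'   strongly negative there, which the blobness term penalizes); a little
#'   smoothing lets the strong response on the adjoining fiber arms carry
#'   the junction pixels, so bundles are not disconnected at junctions.
#' @param tubularity_cutoff Cutoff on ridge strength. Interpreted as a
#'   quantile of the nonzero response when `cutoff_type = "quantile"`
#'   (default), or as an absolute response value.
#' @param cutoff_type `"quantile"` or `"absolute"`.
#' @param min_component_px Minimum connected-component size kept (px).
#' @param beta Frangi blobness parameter.
#' @return A `seg_params` object.
#' @export
seg_params <- function(enhance_sigma_px = 0.9,
                       bg_sigma_px = 32,
                       spread_radius_px = 6L,
                       noise_floor_k = 6,
                       threshold_k = 0.43,
                       tubularity_scales_px = c(1, 2, 3),
                       tubularity_smooth_px = 1.5,
                       tubularity_cutoff = 0.5,
                       cutoff_type = c("quantile", "absolute"),
                       min_component_px = 30L,
                       beta = 0.5) {
  cutoff_type <- match.arg(cutoff_type)
  stopifnot(enhance_sigma_px > 0, bg_sigma_px > 0, spread_radius_px > 0,
            noise_floor_k >= 0,
            length(tubularity_scales_px) >= 1L,
            all(tubularity_scales_px > 0), min_component_px >= 0)
  structure(list(enhance_sigma_px = enhance_sigma_px,
                 bg_sigma_px = bg_sigma_px,
                 spread_radius_px = as.integer(spread_radius_px),
                 noise_floor_k = noise_floor_k,
                 threshold_k = threshold_k,
                 tubularity_scales_px = tubularity_scales_px,
                 tubularity_smooth_px = tubularity_smooth_px,
                 tubularity_cutoff = tubularity_cutoff,
                 cutoff_type = cutoff_type,
                 min_component_px = as.integer(min_component_px),
                 beta = beta),
            class = "seg_params")
}

#' Hessian-eigenvalue tubularity (ridge strength) map
#'
#' Computes a Frangi-type vesselness response for bright curvilinear
#' structures on a dark background. At each pixel and scale the two
#' eigenvalues of the scale-normalized Hessian are ordered by magnitude
#' (|lambda1| <= |lambda2|); a response is produced only where lambda2 < 0
#' (bright ridge) and combines a blobness term exp(-(l1/l2)^2 / (2 beta^2))
#' with a structure-strength term 1 - exp(-S^2 / (2 c^2)), where S is the
#' Frobenius norm of the Hessian and c is half its image maximum. The final
#' map is the pixel-wise maximum over scales; flat regions map to 0.
#'
#' @param image A [ccm_image()] or a numeric intensity matrix.
#' @param scales Positive Hessian scales in pixels.
#' @param beta Blobness selectivity.
#' @return Non-negative matrix of ridge strength, same shape as the image.
#' @export
tubularity_map <- function(image, scales = c(1, 2, 3), beta = 0.5) {
  img <- if (inherits(image, "ccm_image")) image$intensities else image
  stopifnot(is.matrix(img), length(scales) >= 1L, all(scales > 0))
  if (max(img) == min(img)) return(matrix(0, nrow(img), ncol(img)))
  resp <- matrix(0, nrow(img), ncol(img))
  for (s in scales) resp <- pmax(resp, frangi_at_scale(img, s, beta))
  resp
}

#' Segment nerve fiber bundles from a CCM image
#'
#' Produces a binary nerve mask by Gaussian contrast enhancement, adaptive
#' background thresholding, a tubularity gate, and small-component removal
#' (see [seg_params()] for the pipeline). The result is deterministic for a
#' given image and parameter set; an empty mask is a valid result.
#'
#' @param image A [ccm_image()].
#' @param params A [seg_params()] object.
#' @return A `nerve_mask` object: list with `mask` (0/1 integer matrix),
#'   `params` and `calibration`.
#' @export
segment_nerves <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "ccm_image"), inherits(params, "seg_params"))
  img <- image$intensities
  enhanced <- gblur2(img, params$enhance_sigma_px)
  background <- gblur2(enhanced, params$bg_sigma_px)
  contrast <- enhanced - background
  brush <- EBImage::makeBrush(2L * params$spread_radius_px + 1L, "disc")
  peak <- EBImage::dilate(contrast, brush)
  if (!is.matrix(peak)) peak <- EBImage::imageData(peak)
  spread <- pmax(peak, params$noise_floor_k * mad(contrast))
  candidate <- contrast > params$threshold_k * spread

  tub <- tubularity_map(img, params$tubularity_scales_px, params$beta)
  if (params$tubularity_smooth_px > 0) {
    tub <- gblur2(tub, params$tubularity_smooth_px)
  }
  cutoff <- if (params$cutoff_type == "quantile") {
    nz <- tub[tub > 0]
    if (length(nz)) unname(quantile(nz, params$tubularity_cutoff)) else Inf
  } else {
    params$tubularity_cutoff
  }
  mask <- candidate & (tub > cutoff)

  if (any(mask) && params$min_component_px > 0L) {
    lab <- cc_label(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_component_px)
    mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  }
  structure(list(mask = mask * 1L, params = params,
                 calibration = image$calibration),
            class = "nerve_mask")
}

#' @export
print.nerve_mask <- function(x, ...) {
  cat(sprintf("Nerve mask %dx%d px, %d foreground px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Construct a nerve mask from a binary matrix
#'
#' Convenience constructor used when a mask is produced elsewhere (phantom
#' truth, file input) and endpoints are to be computed from it.
#'
#' @param mask 0/1 matrix.
#' @param calibration A [calibration()]; defaults to one matching the mask
#'   shape at HRT III pixel pitch.
#' @return A `nerve_mask`.
#' @export
nerve_mask <- function(mask, calibration = NULL) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  if (is.null(calibration)) {
    calibration <- calibration(field_width_px = ncol(mask),
                               field_height_px = nrow(mask))
  }
  stopifnot(nrow(mask) == calibration$field_height_px,
            ncol(mask) == calibration$field_width_px)
  structure(list(mask = mask * 1L, params = NULL,
                 calibration = calibration),
            class = "nerve_mask")
}

#' Pixel-counting nerve fiber area (NFA FIJI)
#'
#' The image area covered by the binary nerve mask, in square micrometres,
#' normalized per square millimetre of corneal surface:
#' `NFA = foreground px * pitch^2 / field_area_mm2`.
#'
#' @param mask A `nerve_mask`.
#' @return NFA in um^2/mm^2.
#' @examples
#' m <- nerve_mask(matrix(1L, 384, 384))   # full field
#' compute_nfa_fiji(m)                     # 1e6 um^2 per mm^2
#' @export
compute_nfa_fiji <- function(mask) {
  stopifnot(inherits(mask, "nerve_mask"))
  cal <- mask$calibration
  sum(mask$mask) * cal$pixel_pitch_um^2 / cal$field_area_mm2
}
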