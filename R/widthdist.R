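#' Fiber bundle width frequency distribution
#'
#' Counts skeleton pixels per integer pixel-width bin (1..8), normalizes the
#' counts to sum to one, and converts bin centers to micrometres via the
#' pixel pitch. Pixels shared by two edges at a junction are counted once.
#'
#' @param widths A [measure_widths()] profile, or an integer vector of pixel
#'   widths (then `calibration` is required).
#' @param calibration A [calibration()]; taken from the profile if absent.
#' @param n_bins Number of integer width bins.
#' @return A `width_distribution`: data.frame with `bin_px`,
#'   `bin_center_um`, `frequency` (and `count`).
#' @examples
#' wd <- width_histogram(c(2L, 2L, 3L, 3L, 3L, 4L), calibration())
#' wd$frequency[2:4]   # 2/6, 3/6, 1/6
#' @export
width_histogram <- function(widths, calibration = NULL, n_bins = 8L) {
  if (inherits(widths, "width_profile")) {
    calibration <- calibration %||% attr(widths, "calibration")
    dedup <- !duplicated(widths[, c("r", "c")])
    w <- widths$width_px[dedup]
  } else {
    w <- as.integer(widths)
  }
  if (!length(w)) stop("empty width profile", call. = FALSE)
  stopifnot(inherits(calibration, "ccm_calibration"))
  w <- pmin(n_bins, pmax(1L, w))
  counts <- tabulate(w, nbins = n_bins)
  out <- data.frame(bin_px = seq_len(n_bins),
                    bin_center_um = seq_len(n_bins) *
                      calibration$pixel_pitch_um,
                    count = counts,
                    frequency = counts / sum(counts))
  attr(out, "calibration") <- calibration
  class(out) <- c("width_distribution", "data.frame")
  out
}

#' Average width distributions across images or subjects
#'
#' Unweighted mean of per-image normalized frequencies (each image
#' contributes equally, so the average still sums to one), with the
#' standard error of the mean per bin.
#'
#' @param dists List of [width_histogram()] results on identical binning.
#' @return A `width_distribution` with columns `frequency` and `sem`.
#' @export
average_width_distributions <- function(dists) {
  stopifnot(length(dists) >= 1L)
  f <- vapply(dists, function(d) d$frequency, numeric(nrow(dists[[1]])))
  f <- matrix(f, nrow = nrow(dists[[1]]))
  out <- dists[[1]]
  out$count <- NULL
  out$frequency <- rowMeans(f)
  out$sem <- apply(f, 1L, sd) / sqrt(ncol(f))
  out
}

#' Fit a parametric model to a width distribution
#'
#' Least-squares fit of `amplitude * exp(-(x - location)^2 / (2 scale^2))`
#' (gaussian) or the same bell on log-width,
#' `amplitude * exp(-(log x - location)^2 / (2 scale^2))` (lognormal), to the
#' binned frequencies. Needs at least four non-zero bins for the
#' three-parameter fit. Non-convergence is flagged, not raised.
#'
#' @param dist A [width_histogram()] result.
#' @param model `"gaussian"` or `"lognormal"`.
#' @return A `width_model_fit`: model, location, scale, amplitude, `rss`,
#'   `converged`.
#' @export
fit_width_model <- function(dist, model = c("gaussian", "lognormal")) {
  model <- match.arg(model)
  stopifnot(inherits(dist, "width_distribution"))
  x <- dist$bin_center_um
  y <- dist$frequency
  if (sum(y > 0) < 4L) {
    stop("need at least 4 non-zero bins for a 3-parameter fit",
         call. = FALSE)
  }
  xs <- if (model == "lognormal") log(x) else x
  loc0 <- sum(xs * y) / sum(y)
  sc0 <- sqrt(max(1e-4, sum((xs - loc0)^2 * y) / sum(y)))
  amp0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(xs - m)^2 / (2 * s^2)),
      start = list(A = amp0, m = loc0, s = sc0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(model = model, location = loc0, scale = sc0,
                amplitude = amp0, rss = sum((y - amp0 *
                  exp(-(xs - loc0)^2 / (2 * sc0^2)))^2),
                converged = FALSE)
  } else {
    cf <- coef(fit)
    out <- list(model = model, location = unname(cf["m"]),
                scale = abs(unname(cf["s"])),
                amplitude = unname(cf["A"]),
                rss = sum(resid(fit)^2), converged = TRUE)
  }
  class(out) <- "width_model_fit"
  out
}

#' @export
print.width_model_fit <- function(x, ...) {
  cat(sprintf("%s width model: location %.3f, scale %.3f, amplitude %.4f (RSS %.3g%s)\n",
              x$model, x$location, x$scale, x$amplitude, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Mid-width band mass ratio (dropout index)
#'
#' Ratio of the width-frequency mass inside a band (default 2.8-4.0 um,
#' inclusive left edge, exclusive right edge on bin centers) between a
#' distribution and a reference. In small fiber neuropathy the mid-width
#' band around the normal-subject mean is preferentially lost, so the ratio
#' falls below one with increasing severity.
#'
#' @param dist,reference [width_histogram()] results on the same binning.
#' @param band_um Numeric length-2 band in micrometres.
#' @return Scalar mass ratio `dist / reference`.
#' @export
midwidth_dropout <- function(dist, reference, band_um = c(2.8, 4.0)) {
  stopifnot(inherits(dist, "width_distribution"),
            inherits(reference, "width_distribution"))
  if (!isTRUE(all.equal(dist$bin_center_um, reference$bin_center_um))) {
    stop("distributions are on different binnings", call. = FALSE)
  }
  inband <- dist$bin_center_um >= band_um[1] &
    dist$bin_center_um < band_um[2]
  ref_mass <- sum(reference$frequency[inband])
  if (ref_mass <= 0) stop("reference has no mass in the band",
                          call. = FALSE)
  sum(dist$frequency[inband]) / ref_mass
}

#' @export
plot.width_distribution <- function(x, ..., add = FALSE, col = 1) {
  if (!add) {
    plot(x$bin_center_um, x$frequency, type = "b", col = col,
         xlab = "bundle width (um)", ylab = "normalized frequency", ...)
  } else {
    lines(x$bin_center_um, x$frequency, type = "b", col = col, ...)
  }
  invisible(x)
}
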