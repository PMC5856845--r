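# Seeded synthetic plexus phantoms with known ground truth, and cohort
# table simulation. Phantoms emulate the sub-basal plexus as seen on HRT
# III confocal frames: bright, gently curving, roughly parallel fiber
# bundles of 1-8 px width with side branches, periodic beading, an uneven
# background and Gaussian noise.

#' Specification of a synthetic plexus phantom
#'
#' @param fibers List of fiber descriptions; each a list with control points
#'   `x`, `y` (pixel coordinates, x = column, y = row), `width_um` (scalar,
#'   or vector along the control points for varying caliber), optional
#'   `branches` (list of `t` attachment parameter in (0,1), `length_px`,
#'   `width_um`, `angle_deg` offset from the parent tangent), and optional
#'   `beading_amp` / `beading_period_px`.
#' @param background List: `level` (gray value), `gradient` (length-2,
#'   added linearly across x then y over the full field), `noise_sd`
#'   (Gaussian noise standard deviation in gray values).
#' @param amplitude Peak fiber brightness above background.
#' @param calibration A [calibration()].
#' @param seed Integer; fixes all randomness of rendering.
#' @return A `plexus_spec`.
#' @export
plexus_spec <- function(fibers = list(),
                        background = list(level = 40, gradient = c(0, 0),
                                          noise_sd = 15),
                        amplitude = 120,
                        calibration = ccmorph::calibration(),
                        seed = 1L) {
  for (f in fibers) {
    stopifnot(length(f$x) == length(f$y), length(f$x) >= 2L,
              all(f$width_um > 0))
  }
  structure(list(fibers = fibers, background = background,
                 amplitude = amplitude, calibration = calibration,
                 seed = as.integer(seed)),
            class = "plexus_spec")
}

#' Random control-like plexus specification
#'
#' Draws `n_fibers` gently curving, roughly horizontal fiber bundles
#' spanning the field, with widths from a right-skewed (log-normal)
#' distribution centered near 3.2 um - the width-frequency peak of healthy
#' sub-basal plexi - and a random number of side branches per fiber.
#'
#' @param n_fibers Number of main fiber bundles.
#' @param width_um Optional fixed width(s); recycled over fibers. Default
#'   draws log-normal widths (median ~3.1 um, log-sd 0.25) clamped to the
#'   measurable 1-8 px range.
#' @param branches_range Integer range of branches per fiber (inclusive).
#' @param beading_amp,beading_period_px Beading modulation (fraction of the
#'   amplitude; period along the fiber).
#' @param seed RNG seed (also stored in the spec).
#' @inheritParams plexus_spec
#' @return A `plexus_spec`.
#' @export
random_plexus_spec <- function(n_fibers = 6L, width_um = NULL,
                               branches_range = c(0L, 2L),
                               beading_amp = 0.1,
                               beading_period_px = 25,
                               amplitude = 120,
                               background = list(level = 40,
                                                 gradient = c(0, 0),
                                                 noise_sd = 15),
                               calibration = ccmorph::calibration(),
                               seed = 1L) {
  set.seed(seed)
  W <- calibration$field_width_px
  H <- calibration$field_height_px
  pitch <- calibration$pixel_pitch_um
  margin <- 10
  max_w_um <- 8 * pitch * 0.98
  fibers <- vector("list", n_fibers)
  if (n_fibers > 0) {
    slots <- margin + (seq_len(n_fibers) - 0.5) / n_fibers * (H - 2 * margin)
    for (i in seq_len(n_fibers)) {
      k <- 5L
      xs <- seq(margin, W - margin, length.out = k)
      y0 <- min(H - margin, max(margin, slots[i] + runif(1, -6, 6)))
      ys <- y0 + cumsum(c(0, rnorm(k - 1L, 0, 6)))
      ys <- pmin(H - margin, pmax(margin, ys))
      w <- if (is.null(width_um)) {
        min(max_w_um, max(1.2, exp(rnorm(1, log(3.1), 0.25))))
      } else {
        rep(width_um, length.out = n_fibers)[i]
      }
      nb <- if (branches_range[2] > branches_range[1]) {
        sample(branches_range[1]:branches_range[2], 1L)
      } else branches_range[1]
      branches <- lapply(seq_len(nb), function(b) {
        list(t = runif(1, 0.2, 0.8),
             length_px = runif(1, 25, 45),
             width_um = min(max_w_um, max(1.2, 0.75 * w)),
             angle_deg = sample(c(-1, 1), 1L) * runif(1, 30, 55))
      })
      fibers[[i]] <- list(x = xs, y = ys, width_um = w, branches = branches,
                          beading_amp = beading_amp,
                          beading_period_px = beading_period_px)
    }
  }
  plexus_spec(fibers, background, amplitude, calibration, seed)
}

# Densely sampled smooth curve through the control points.
# Returns x, y (px), arc length s (px), per-sample width (um).
sample_fiber_curve <- function(fiber, ds = 0.5) {
  k <- length(fiber$x)
  t0 <- c(0, cumsum(sqrt(diff(fiber$x)^2 + diff(fiber$y)^2)))
  n_out <- max(8L, ceiling(t0[k] / ds) * 4L)
  sx <- spline(t0, fiber$x, n = n_out)
  sy <- spline(t0, fiber$y, n = n_out)
  s <- c(0, cumsum(sqrt(diff(sx$y)^2 + diff(sy$y)^2)))
  # resample at uniform arc length
  stot <- s[length(s)]
  su <- seq(0, stot, by = ds)
  x <- approx(s, sx$y, xout = su)$y
  y <- approx(s, sy$y, xout = su)$y
  w <- if (length(fiber$width_um) == 1L) {
    rep(fiber$width_um, length(su))
  } else {
    approx(seq(0, 1, length.out = length(fiber$width_um)) * stot,
           fiber$width_um, xout = su, rule = 2)$y
  }
  list(x = x, y = y, s = su, width_um = w, length_px = stot)
}

# All curves (main fibers + their branches) of a spec, each with geometry,
# width and role.
spec_curves <- function(spec, ds = 0.5) {
  curves <- list()
  for (i in seq_along(spec$fibers)) {
    f <- spec$fibers[[i]]
    cv <- sample_fiber_curve(f, ds)
    cv$role <- "main"; cv$fiber <- i
    cv$beading_amp <- f$beading_amp %||% 0
    cv$beading_period_px <- f$beading_period_px %||% 25
    curves[[length(curves) + 1L]] <- cv
    n <- length(cv$x)
    for (b in f$branches %||% list()) {
      j <- max(2L, min(n - 1L, round(b$t * n)))
      tang <- c(cv$x[j + 1L] - cv$x[j - 1L], cv$y[j + 1L] - cv$y[j - 1L])
      tang <- tang / sqrt(sum(tang^2))
      a <- b$angle_deg * pi / 180
      dir <- c(cos(a) * tang[1] - sin(a) * tang[2],
               sin(a) * tang[1] + cos(a) * tang[2])
      # clip branch to stay inside the field
      W <- spec$calibration$field_width_px
      H <- spec$calibration$field_height_px
      len <- b$length_px
      for (step in seq(len, 5, by = -2)) {
        ex <- cv$x[j] + dir[1] * step; ey <- cv$y[j] + dir[2] * step
        if (ex >= 3 && ex <= W - 2 && ey >= 3 && ey <= H - 2) {
          len <- step
          break
        }
        len <- 0
      }
      if (len < 5) next
      su <- seq(0, len, by = ds)
      curves[[length(curves) + 1L]] <- list(
        x = cv$x[j] + dir[1] * su, y = cv$y[j] + dir[2] * su, s = su,
        width_um = rep(b$width_um, length(su)), length_px = len,
        role = "branch", fiber = i,
        beading_amp = f$beading_amp %||% 0,
        beading_period_px = f$beading_period_px %||% 25)
    }
  }
  curves
}

#' Render a plexus phantom image with ground truth
#'
#' Fibers are rendered as smooth curves with a Gaussian intensity
#' cross-section whose full width at half maximum equals the nominal bundle
#' width (sigma = width / 2.355), so the nominal width is recovered by a
#' half-maximum-style width estimator. Beading modulates the amplitude
#' periodically along the fiber. Background (level plus linear gradient)
#' and Gaussian noise are added after the truth is recorded. The same seed
#' always produces the same image.
#'
#' @param spec A [plexus_spec()] / [random_plexus_spec()].
#' @return List with `image` (a [ccm_image()]) and `truth`: true mask, NFD
#'   / NBD / NFL (field-area-normalized, like [compute_variables()]),
#'   `nfa_analytic` (sum of width x length per curve, um^2/mm^2), per-curve
#'   widths and lengths, and counts.
#' @export
generate_plexus <- function(spec) {
  stopifnot(inherits(spec, "plexus_spec"))
  cal <- spec$calibration
  W <- cal$field_width_px; H <- cal$field_height_px
  pitch <- cal$pixel_pitch_um
  area <- cal$field_area_mm2
  set.seed(spec$seed)
  curves <- spec_curves(spec)
  for (cv in curves) {
    if (any(cv$x < 1.5) || any(cv$x > W - 0.5) ||
        any(cv$y < 1.5) || any(cv$y > H - 0.5)) {
      stop("fiber extends outside the imaging field", call. = FALSE)
    }
  }
  ds <- if (length(curves)) diff(curves[[1]]$s[1:2]) else 0.5

  response <- matrix(0, H, W)
  truth_mask <- matrix(FALSE, H, W)
  # group samples by quantized width so each group shares one blur scale
  if (length(curves)) {
    samples <- do.call(rbind, lapply(curves, function(cv) {
      phase <- runif(1, 0, 2 * pi)
      amp <- spec$amplitude *
        (1 + cv$beading_amp * sin(2 * pi * cv$s / cv$beading_period_px +
                                    phase))
      data.frame(r = round(cv$y), c = round(cv$x),
                 amp = amp, w_um = round(cv$width_um / 0.1) * 0.1)
    }))
    for (w in unique(samples$w_um)) {
      sub <- samples[samples$w_um == w, , drop = FALSE]
      sigma <- (w / pitch) / 2.355
      imp <- matrix(0, H, W)
      idx <- (sub$c - 1L) * H + sub$r
      acc <- rowsum(sub$amp * ds, idx)
      imp[as.integer(rownames(acc))] <- acc
      prof <- gblur2(imp, max(sigma, 0.4)) * sqrt(2 * pi) * max(sigma, 0.4)
      response <- pmax(response, prof)
      center <- matrix(TRUE, H, W)
      center[idx] <- FALSE
      d <- edt(center)
      truth_mask <- truth_mask | (d < (w / pitch) / 2 + 0.5)
    }
  }

  bg <- spec$background
  gx <- bg$gradient[1] %||% 0; gy <- (bg$gradient[2] %||% 0)
  base <- bg$level +
    outer(rep(1, H), (seq_len(W) - 1) / max(1, W - 1)) * gx +
    outer((seq_len(H) - 1) / max(1, H - 1), rep(1, W)) * gy
  img <- base + response + rnorm(H * W, 0, bg$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))

  lens_um <- vapply(curves, function(cv) cv$length_px, numeric(1)) * pitch
  widths_um <- vapply(curves, function(cv) mean(cv$width_um), numeric(1))
  roles <- vapply(curves, function(cv) cv$role, character(1))
  truth <- list(
    mask = truth_mask * 1L,
    n_fibers = sum(roles == "main"),
    n_branches = sum(roles == "branch"),
    nfd = sum(roles == "main") / area,
    nbd = sum(roles == "branch") / area,
    nfl = sum(lens_um) / 1000 / area,
    nfa_analytic = sum(widths_um * lens_um) / area,
    curve_widths_um = widths_um,
    curve_lengths_um = lens_um,
    curve_roles = roles
  )
  list(image = ccm_image(img, cal), truth = truth, spec = spec)
}

#' Degrade a plexus specification to emulate small fiber neuropathy
#'
#' Removes fiber bundles with a probability peaked around the mid-width
#' range (Gaussian kernel centered at `center_um`, default 3.2 um with sd
#' 0.4 um, matching the preferentially lost ~2.8-4.0 um band), scaled by
#' `severity`. Surviving widths are mildly inflated (`swelling` fraction at
#' full severity) to emulate the individual fiber swelling that accompanies
#' small fiber neuropathy and shifts the width distribution towards thicker
#' bundles; set `swelling = 0` for pure dropout. Branches follow their
#' parent fiber. Severity 0 returns the spec unchanged; randomness is fixed
#' by the spec's seed.
#'
#' @param spec A [plexus_spec()].
#' @param severity Degradation severity in \[0, 1\].
#' @param center_um,sd_um Center and width of the removal kernel.
#' @param swelling Relative width inflation of survivors at severity 1.
#' @return A degraded `plexus_spec`.
#' @export
apply_neuropathy <- function(spec, severity, center_um = 3.2, sd_um = 0.4,
                             swelling = 0.08) {
  stopifnot(inherits(spec, "plexus_spec"),
            severity >= 0, severity <= 1)
  if (severity == 0) return(spec)
  set.seed(spec$seed + 7919L)
  w <- vapply(spec$fibers, function(f) mean(f$width_um), numeric(1))
  p_rm <- severity * exp(-(w - center_um)^2 / (2 * sd_um^2))
  keep <- runif(length(w)) >= p_rm
  fibers <- spec$fibers[keep]
  if (swelling > 0) {
    fibers <- lapply(fibers, function(f) {
      f$width_um <- f$width_um * (1 + swelling * severity)
      f$branches <- lapply(f$branches %||% list(), function(b) {
        b$width_um <- b$width_um * (1 + swelling * severity)
        b
      })
      f
    })
  }
  plexus_spec(fibers, spec$background, spec$amplitude, spec$calibration,
              spec$seed)
}

#' Ground-truth width distribution of a plexus specification
#'
#' Length-weighted histogram of the nominal bundle widths (main fibers and
#' branches) over the integer pixel bins, without rendering or segmenting
#' the image. Useful for studying width-dropout behavior analytically.
#'
#' @param spec A [plexus_spec()].
#' @return A `width_distribution` (or error when the spec has no fibers).
#' @export
truth_width_distribution <- function(spec) {
  curves <- spec_curves(spec)
  if (!length(curves)) stop("spec has no fibers", call. = FALSE)
  pitch <- spec$calibration$pixel_pitch_um
  w_px <- pmin(8L, pmax(1L, as.integer(round(
    vapply(curves, function(cv) mean(cv$width_um), numeric(1)) / pitch))))
  len <- vapply(curves, function(cv) cv$length_px, numeric(1))
  counts <- vapply(1:8, function(b) sum(len[w_px == b]), numeric(1))
  out <- data.frame(bin_px = 1:8, bin_center_um = (1:8) * pitch,
                    count = counts, frequency = counts / sum(counts))
  attr(out, "calibration") <- spec$calibration
  class(out) <- c("width_distribution", "data.frame")
  out
}

#' Simulate a cohort table of per-subject CCM endpoints
#'
#' Draws correlated multivariate-normal endpoint vectors per group
#' (truncated at zero) from stated group means, standard deviations and an
#' inter-endpoint correlation matrix, yielding a subject table suitable for
#' the diagnostic and longitudinal analyses.
#'
#' @param groups List of group specifications: each a list with `label`,
#'   `n`, `mean` and `sd` (named numeric vectors over the endpoints) and
#'   optionally `cor` (correlation matrix; defaults to `default_cor`).
#' @param default_cor Either a single off-diagonal correlation or a full
#'   matrix, used when a group omits `cor`.
#' @param seed RNG seed.
#' @return Data.frame: `subject_id`, `group`, endpoint columns.
#' @examples
#' g <- ccm_reference_groups()[c("control", "nds_9_10")]
#' tab <- generate_cohort(g, seed = 1)
#' @export
generate_cohort <- function(groups, default_cor = 0.85, seed = 1L) {
  set.seed(seed)
  rows <- list()
  sid <- 0L
  for (g in groups) {
    vars <- names(g$mean)
    stopifnot(!is.null(vars), identical(vars, names(g$sd)))
    p <- length(vars)
    R <- g$cor %||% (if (is.matrix(default_cor)) default_cor else {
      m <- matrix(default_cor, p, p); diag(m) <- 1; m
    })
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("correlation matrix for group '", g$label,
                              "' is not positive semi-definite",
                              call. = FALSE)
    Sigma <- diag(g$sd) %*% R %*% diag(g$sd)
    draws <- MASS::mvrnorm(g$n, mu = g$mean, Sigma = Sigma)
    draws <- matrix(pmax(0, draws), nrow = g$n,
                    dimnames = list(NULL, vars))
    df <- data.frame(subject_id = sprintf("s%04d", sid + seq_len(g$n)),
                     group = g$label)
    sid <- sid + g$n
    rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(draws))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled reference group parameters for CCM endpoints
#'
#' Representative group means and standard deviations of the five CCM
#' endpoints for healthy controls, four diabetic neuropathy severity bands
#' (by Neuropathy Disability Score) and sarcoidosis-associated small fiber
#' neuropathy, on the HRT III scale, with typical clinical sample sizes.
#' Used as default parameters for [generate_cohort()].
#'
#' @return Named list of group specifications.
#' @export
ccm_reference_groups <- function() {
  v <- c("nfd", "nbd", "nfl", "nfa_wxl", "nfa_fiji")
  mk <- function(label, n, mean, sd) {
    list(label = label, n = n, mean = setNames(mean, v),
         sd = setNames(sd, v))
  }
  list(
    control = mk("control", 48L,
                 c(28.8, 36.5, 17.1, 52331, 30931),
                 c(4.8, 14.4, 3.2, 9344, 8735)),
    nds_0_2 = mk("nds_0_2", 21L,
                 c(21.5, 21.6, 12.8, 39385, 20966),
                 c(7.3, 11.7, 3.4, 10626, 7718)),
    nds_3_5 = mk("nds_3_5", 21L,
                 c(20.5, 28.2, 12.7, 39843, 22122),
                 c(9.5, 17.3, 5.0, 14474, 10740)),
    nds_6_8 = mk("nds_6_8", 19L,
                 c(15.2, 17.2, 9.6, 30340, 16414),
                 c(8.7, 13.2, 4.3, 12571, 7594)),
    nds_9_10 = mk("nds_9_10", 20L,
                  c(10.3, 10.8, 7.3, 28827, 12516),
                  c(8.5, 10.7, 4.7, 13603, 7773)),
    sarcoidosis = mk("sarcoidosis", 63L,
                     c(19.2, 25.5, 12.7, 46890, 19243),
                     c(5.4, 11.8, 2.9, 10737, 5407))
  )
}
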