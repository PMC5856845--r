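test_that("width histograms count and normalize correctly", {
  cal <- calibration()
  d <- width_histogram(rep(3L, 40), cal)
  expect_equal(d$frequency[3], 1)
  expect_equal(sum(d$frequency), 1)

  d2 <- width_histogram(c(2L, 2L, 3L, 3L, 3L, 4L), cal)
  expect_equal(d2$frequency[2:4], c(2, 3, 1) / 6)
  expect_equal(d2$bin_center_um, (1:8) * 400 / 384)

  expect_error(width_histogram(integer(0), cal), "empty")
})

test_that("histograms are invariant to skeleton pixel ordering and dedupe", {
  prof <- data.frame(edge_id = 1L, r = c(1, 2, 3, 3), c = c(1, 1, 1, 1),
                     width_px = c(2L, 2L, 3L, 3L), width_um = 0,
                     dl_um = 1)
  attr(prof, "calibration") <- calibration()
  class(prof) <- c("width_profile", "data.frame")
  d <- width_histogram(prof)
  # the duplicated (3,1) pixel counts once
  expect_equal(d$count[2:3], c(2, 1))
  shuffled <- prof[c(3, 1, 4, 2), ]
  attr(shuffled, "calibration") <- calibration()
  class(shuffled) <- c("width_profile", "data.frame")
  expect_equal(width_histogram(shuffled)$frequency, d$frequency)
})

test_that("group averaging preserves normalization", {
  cal <- calibration()
  set.seed(8)
  dists <- lapply(1:6, function(i)
    width_histogram(sample(1:8, 50, replace = TRUE,
                           prob = dnorm(1:8, 3, 1.2)), cal))
  avg <- average_width_distributions(dists)
  expect_equal(sum(avg$frequency), 1, tolerance = 1e-9)
  expect_true(all(avg$sem >= 0))
})

test_that("gaussian fits recover noiseless parameters", {
  cal <- calibration()
  x <- (1:8) * cal$pixel_pitch_um
  y <- 0.4 * exp(-(x - 3.2)^2 / (2 * 0.8^2))
  d <- data.frame(bin_px = 1:8, bin_center_um = x, count = 0, frequency = y)
  attr(d, "calibration") <- cal
  class(d) <- c("width_distribution", "data.frame")
  fit <- fit_width_model(d, "gaussian")
  expect_true(fit$converged)
  expect_equal(fit$location, 3.2, tolerance = 1e-6)
  expect_equal(fit$scale, 0.8, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.4, tolerance = 1e-6)
})

test_that("gaussian and lognormal fit measured control-like data
           comparably", {
  dists <- lapply(1:10, function(s) {
    ph <- generate_plexus(random_plexus_spec(n_fibers = 7,
                                             seed = 7000 + s))
    analyze_image(ph$image)$width_distribution
  })
  avg <- average_width_distributions(dists)
  fg <- fit_width_model(avg, "gaussian")
  fl <- fit_width_model(avg, "lognormal")
  expect_true(fg$converged && fl$converged)
  rat <- max(fg$rss, fl$rss) / min(fg$rss, fl$rss)
  expect_lt(rat, 2)
  # measured control-like peak sits near the healthy-subject ~3.1-3.2 um
  expect_equal(fg$location, 3.15, tolerance = 0.15)
})

test_that("fits demand at least four non-zero bins", {
  cal <- calibration()
  d <- width_histogram(c(2L, 3L, 3L, 4L), cal)   # 3 non-zero bins
  expect_error(fit_width_model(d), "4 non-zero")
})

test_that("mid-width dropout ratios behave on constructed fixtures", {
  cal <- calibration()
  ref <- width_histogram(rep(1:8, c(2, 10, 30, 20, 8, 4, 2, 1)), cal)
  expect_equal(midwidth_dropout(ref, ref), 1)

  # halve the in-band mass (bins 3 and 4 at default pitch), renormalize
  f <- ref$frequency
  inband <- ref$bin_center_um >= 2.8 & ref$bin_center_um < 4.0
  f2 <- f; f2[inband] <- f[inband] / 2
  f2 <- f2 / sum(f2)
  d <- ref; d$frequency <- f2
  expected <- sum(f2[inband]) / sum(f[inband])
  expect_equal(midwidth_dropout(d, ref), expected, tolerance = 1e-12)

  empty_band <- ref
  empty_band$frequency <- c(0.5, 0.5, 0, 0, 0, 0, 0, 0)
  expect_error(midwidth_dropout(ref, empty_band), "no mass")
})
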