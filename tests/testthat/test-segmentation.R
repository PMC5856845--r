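test_that("tubularity map is zero on flat images and peaks on ridges", {
  expect_equal(tubularity_map(matrix(7, 50, 50)), matrix(0, 50, 50))

  img <- matrix(0, 64, 64)
  img[31:33, ] <- 200                          # bright horizontal bar
  tub <- tubularity_map(img, scales = c(1, 2, 3))
  center <- median(tub[32, 10:54])
  off <- max(tub[c(1:20, 44:64), 10:54])
  expect_gt(center, 0)
  expect_lt(off, 0.1 * center)
})

test_that("tubularity is symmetric under 90-degree rotation", {
  img <- matrix(0, 64, 64)
  img[31:33, 10:54] <- 200
  tub_h <- tubularity_map(img)
  tub_v <- tubularity_map(t(img))
  expect_equal(tub_v, t(tub_h), tolerance = 1e-8)
})

test_that("an all-dark image segments to an empty mask", {
  img <- ccm_image(matrix(0L, 384, 384), calibration())
  m <- segment_nerves(img)
  expect_s3_class(m, "nerve_mask")
  expect_equal(sum(m$mask), 0)
})

test_that("a single spanning fiber yields one component near 3x384 px", {
  ph <- bar_phantom(3, seed = 2)
  m <- segment_nerves(ph$image)
  lab <- ccmorph:::cc_label(m$mask)
  expect_equal(max(lab), 1)
  expect_lt(abs(sum(m$mask) / (3 * 384) - 1), 0.2)
})

test_that("a linear background ramp barely changes the mask", {
  ph_flat <- bar_phantom(3, seed = 5)
  ph_ramp <- bar_phantom(3, seed = 5, gradient = c(76, 0))  # 30% of range
  m1 <- segment_nerves(ph_flat$image)$mask
  m2 <- segment_nerves(ph_ramp$image)$mask
  disagreement <- sum(m1 != m2) / max(sum(m1), sum(m2))
  expect_lt(disagreement, 0.05)
})

test_that("segmentation is deterministic", {
  ph <- bar_phantom(3, seed = 9)
  m1 <- segment_nerves(ph$image)
  m2 <- segment_nerves(ph$image)
  expect_identical(m1$mask, m2$mask)
})

test_that("pixel-counting NFA follows the area contract", {
  cal <- calibration()
  expect_equal(compute_nfa_fiji(nerve_mask(matrix(0L, 384, 384), cal)), 0)
  expect_equal(compute_nfa_fiji(nerve_mask(matrix(1L, 384, 384), cal)),
               1e6)
  m <- matrix(0L, 384, 384); m[sample.int(384^2, 1000)] <- 1L
  nfa <- compute_nfa_fiji(nerve_mask(m, cal))
  expect_equal(nfa, 1000 * (400 / 384)^2 / 0.16, tolerance = 1e-12)
  expect_equal(round(nfa), 6782)
})

test_that("NFA is invariant under rotation and mirroring of the mask", {
  set.seed(4)
  m <- matrix(rbinom(96^2, 1, 0.1), 96, 96)
  cal <- calibration(400 / 384, 96, 96)
  ref <- compute_nfa_fiji(nerve_mask(m, cal))
  for (tr in list(t(m), m[nrow(m):1, ], m[, ncol(m):1])) {
    expect_equal(compute_nfa_fiji(nerve_mask(tr, cal)), ref)
  }
  # pixel-count conservation: invert the normalization exactly
  expect_equal(ref * cal$field_area_mm2 / cal$pixel_pitch_um^2, sum(m))
})

test_that("NFA grows with phantom fiber width at fixed length", {
  nfas <- vapply(c(2, 4, 6), function(w) {
    ph <- bar_phantom(w, seed = 11)
    compute_nfa_fiji(segment_nerves(ph$image))
  }, numeric(1))
  expect_true(all(diff(nfas) > 0))
})
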