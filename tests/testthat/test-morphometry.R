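test_that("empty masks give empty graphs and zero variables", {
  cal <- calibration(1, 64, 64)
  mask <- nerve_mask(matrix(0L, 64, 64), cal)
  g <- skeletonize_mask(mask)
  expect_length(g$edges, 0)
  v <- compute_variables(classify_fibers(g), measure_widths(mask, g), mask)
  expect_true(all(unlist(v) == 0))
})

test_that("a solid 3x100 bar skeletonizes to one edge of the bar's length", {
  cal <- calibration(1, 120, 120)
  m <- matrix(0L, 120, 120)
  m[60:62, 11:110] <- 1L
  g <- skeletonize_mask(nerve_mask(m, cal))
  expect_length(g$edges, 1)
  types <- vapply(g$nodes, function(n) n$type, character(1))
  expect_equal(sum(types == "endpoint"), 2)
  # thinning erodes up to 2 px from each rounded bar end
  expect_lt(abs(g$edges[[1]]$length_um - 99), 4.5)
})

test_that("a T-shaped mask yields one junction, three endpoints, three edges", {
  cal <- calibration(1, 80, 80)
  m <- matrix(0L, 80, 80)
  m[40:42, 11:70] <- 1L        # horizontal bar
  m[11:40, 39:41] <- 1L        # vertical stem
  g <- skeletonize_mask(nerve_mask(m, cal), prune_um = 2)
  types <- vapply(g$nodes, function(n) n$type, character(1))
  expect_equal(sum(types == "junction"), 1)
  expect_equal(sum(types == "endpoint"), 3)
  expect_length(g$edges, 3)
})

test_that("a single long edge is one main fiber with no branches", {
  cal <- calibration(1, 120, 120)
  m <- matrix(0L, 120, 120); m[60:62, 11:110] <- 1L
  g <- skeletonize_mask(nerve_mask(m, cal))
  fib <- classify_fibers(g)
  expect_equal(fib$n_main, 1)
  expect_equal(fib$n_branch, 0)
})

test_that("a main fiber with two stubs classifies as 1 main + 2 branches", {
  cal <- calibration()
  m <- matrix(0L, 384, 384)
  m[191:193, 3:382] <- 1L                       # 380 px main
  m[151:190, 100:102] <- 1L                     # 40 px stub up
  m[194:233, 250:252] <- 1L                     # 40 px stub down
  g <- skeletonize_mask(nerve_mask(m, cal))
  fib <- classify_fibers(g)
  expect_equal(fib$n_main, 1)
  expect_equal(fib$n_branch, 2)
})

test_that("an X crossing of two long fibers is two mains, no branches", {
  cal <- calibration(1, 200, 200)
  m <- matrix(0L, 200, 200)
  for (i in 10:190) {
    m[max(1, i - 1):min(200, i + 1), i] <- 1L          # diagonal 1
    m[max(1, 200 - i):min(200, 202 - i), i] <- 1L      # diagonal 2
  }
  g <- skeletonize_mask(nerve_mask(m, cal))
  fib <- classify_fibers(g, main_min_length_um = 50)
  expect_equal(fib$n_main, 2)
  expect_equal(fib$n_branch, 0)
})

test_that("distance-transform widths match bar geometry and saturate", {
  cal <- calibration(1, 200, 80)
  line <- matrix(0L, 80, 200); line[40, 11:190] <- 1L
  g <- skeletonize_mask(nerve_mask(line, cal))
  w <- measure_widths(nerve_mask(line, cal), g)
  expect_true(all(w$width_px == 1))

  bar5 <- matrix(0L, 80, 200); bar5[38:42, 11:190] <- 1L
  g5 <- skeletonize_mask(nerve_mask(bar5, cal))
  w5 <- measure_widths(nerve_mask(bar5, cal), g5)
  interior <- w5$c > 30 & w5$c < 170
  expect_true(all(w5$width_px[interior] == 5))

  bar20 <- matrix(0L, 80, 200); bar20[31:50, 11:190] <- 1L
  g20 <- skeletonize_mask(nerve_mask(bar20, cal))
  w20 <- measure_widths(nerve_mask(bar20, cal), g20)
  interior <- w20$c > 40 & w20$c < 160
  expect_true(all(w20$width_px[interior] == 8))   # clamped at 8 px
})

test_that("distance-transform and ray-cast widths agree on straight bars", {
  cal <- calibration(1, 200, 80)
  for (h in c(3, 5)) {
    m <- matrix(0L, 80, 200)
    m[40:(40 + h - 1), 11:190] <- 1L
    mask <- nerve_mask(m, cal)
    g <- skeletonize_mask(mask)
    w <- measure_widths(mask, g)
    mid <- which(w$c == 100)[1]
    rc <- ccmorph:::width_raycast(mask, w$r[mid], w$c[mid], c(0, 1))
    expect_lt(abs(w$width_px[mid] - rc), 1 + 1e-9)
  }
})

test_that("variables match hand arithmetic for a full-span 3 px fiber", {
  cal <- calibration()
  m <- matrix(0L, 384, 384)
  m[191:193, ] <- 1L
  mask <- nerve_mask(m, cal)
  g <- skeletonize_mask(mask)
  fib <- classify_fibers(g)
  w <- measure_widths(mask, g)
  v <- compute_variables(fib, w, mask)
  expect_equal(v$nfd, 6.25)
  expect_equal(v$nfl, 2.5, tolerance = 0.02)
  expect_equal(v$nfa_wxl, 7812.5, tolerance = 0.02)
  # the length-weighted identity holds by construction
  expect_equal(v$nfa_wxl, 1000 * v$nfl * v$mean_width_um,
               tolerance = 1e-10)
})

test_that("NFL is additive over disjoint masks", {
  cal <- calibration(1, 128, 128)
  m1 <- matrix(0L, 128, 128); m1[30:32, 11:118] <- 1L
  m2 <- matrix(0L, 128, 128); m2[90:92, 11:118] <- 1L
  nfl_of <- function(m) {
    mask <- nerve_mask(m, cal)
    g <- skeletonize_mask(mask)
    compute_variables(classify_fibers(g), measure_widths(mask, g), mask)$nfl
  }
  expect_equal(nfl_of(m1 + m2), nfl_of(m1) + nfl_of(m2),
               tolerance = 1e-10)
})

test_that("variables are invariant under image mirroring", {
  ph <- bar_phantom(3, seed = 21)
  cfg <- study_config()
  v1 <- analyze_image(ph$image, cfg)$variables
  mirrored <- ccm_image(ph$image$intensities[, 384:1], calibration())
  v2 <- analyze_image(mirrored, cfg)$variables
  for (nm in c("nfd", "nbd", "nfa_fiji")) {
    expect_equal(v1[[nm]], v2[[nm]], tolerance = 1e-10)
  }
  expect_equal(v1$nfl, v2$nfl, tolerance = 0.02)
  expect_equal(v1$mean_width_um, v2$mean_width_um, tolerance = 0.05)
})

test_that("mismatched calibrations are rejected", {
  cal <- calibration(1, 64, 64)
  m <- matrix(0L, 64, 64); m[30:32, 10:50] <- 1L
  mask <- nerve_mask(m, cal)
  g <- skeletonize_mask(mask)
  w <- measure_widths(mask, g)
  other <- nerve_mask(m, calibration(2, 64, 64))
  expect_error(compute_variables(classify_fibers(g), w, other),
               "calibration")
})
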