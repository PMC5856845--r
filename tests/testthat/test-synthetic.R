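test_that("an empty spec renders pure background with all-zero truth", {
  spec <- plexus_spec(list(), seed = 3)
  ph <- generate_plexus(spec)
  expect_equal(ph$truth$nfd, 0)
  expect_equal(ph$truth$nfl, 0)
  expect_equal(sum(ph$truth$mask), 0)
  expect_true(abs(mean(ph$image$intensities) - 40) < 2)
})

test_that("a field-spanning fiber has the hand-computed truth densities", {
  cal <- calibration()
  f <- list(x = c(1.6, 384 - 0.6), y = c(192, 192),
            width_um = 3 * cal$pixel_pitch_um, branches = list())
  ph <- generate_plexus(plexus_spec(list(f), calibration = cal, seed = 1))
  expect_equal(ph$truth$nfd, 6.25)
  expect_equal(ph$truth$nfl, 2.5, tolerance = 0.01)   # 0.4 mm / 0.16 mm^2
})

test_that("branches count into NBD truth", {
  spec <- random_plexus_spec(n_fibers = 2, branches_range = c(1L, 1L),
                             seed = 6)
  ph <- generate_plexus(spec)
  expect_equal(ph$truth$nbd, 2 / 0.16)
})

test_that("generation is seed-deterministic", {
  spec <- random_plexus_spec(n_fibers = 4, seed = 17)
  a <- generate_plexus(spec)
  b <- generate_plexus(spec)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth, b$truth)
})

test_that("fibers outside the field are rejected", {
  f <- list(x = c(-20, 100), y = c(50, 50), width_um = 3,
            branches = list())
  expect_error(generate_plexus(plexus_spec(list(f), seed = 1)),
               "outside")
})

test_that("severity 0 leaves the spec unchanged", {
  spec <- random_plexus_spec(n_fibers = 5, seed = 2)
  expect_identical(apply_neuropathy(spec, 0), spec)
})

test_that("dropout prefers the mid-width band over thick fibers", {
  kept_band <- kept_thick <- n_band <- n_thick <- 0
  for (s in 1:40) {
    spec <- random_plexus_spec(n_fibers = 8, seed = 300 + s)
    w0 <- vapply(spec$fibers, function(f) mean(f$width_um), numeric(1))
    sp1 <- apply_neuropathy(spec, 1, swelling = 0)
    w1 <- vapply(sp1$fibers, function(f) mean(f$width_um), numeric(1))
    band0 <- w0 >= 2.7 & w0 <= 4.0
    n_band <- n_band + sum(band0); n_thick <- n_thick + sum(w0 > 4.0)
    kept_band <- kept_band + sum(w1 >= 2.7 & w1 <= 4.0)
    kept_thick <- kept_thick + sum(w1 > 4.0)
  }
  expect_lt(kept_band / n_band, kept_thick / n_thick)
})

test_that("cohorts reproduce group moments and correlations", {
  g <- list(list(label = "g0", n = 5,
                 mean = c(nfd = 20, nfl = 10), sd = c(nfd = 0, nfl = 0)))
  tab0 <- generate_cohort(g, seed = 1)
  expect_true(all(tab0$nfd == 20) && all(tab0$nfl == 10))

  ctrl <- ccm_reference_groups()$control
  ctrl$n <- 10000L
  tab <- generate_cohort(list(ctrl), seed = 5)
  expect_equal(mean(tab$nfd), 28.8, tolerance = 0.15)
  expect_equal(cor(tab$nfl, tab$nfa_fiji), 0.85, tolerance = 0.05)

  bad <- ctrl
  bad$cor <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  bad$mean <- bad$mean[1:3]; bad$sd <- bad$sd[1:3]
  expect_error(generate_cohort(list(bad), seed = 1), "positive semi")
})

test_that("truth width distributions peak where the generator puts them", {
  specs <- lapply(1:20, function(s)
    random_plexus_spec(n_fibers = 8, seed = 500 + s))
  avg <- average_width_distributions(lapply(specs,
                                            truth_width_distribution))
  mode_bin <- which.max(avg$frequency)
  expect_equal(mode_bin, 3)           # ~3.1 um at HRT III pitch
  expect_equal(avg$bin_center_um[3], 3.125)
})
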