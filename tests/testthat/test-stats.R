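test_that("ROC handles separation, the 4-point example, and errors", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "lower")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r4 <- roc_analysis(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE), "lower")
  expect_equal(r4$auc, 0.75)

  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("AUC equals brute-force pairwise concordance on random data", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    v <- round(rnorm(n), 1)            # ties likely
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    r <- roc_analysis(v, lab, "lower")
    expect_equal(r$auc, auc_oracle(v, lab), tolerance = 1e-12)
  }
})

test_that("trapezoid area under the empirical curve equals the AUC", {
  set.seed(7)
  v <- round(rnorm(40), 1)
  lab <- rep(c(TRUE, FALSE), 20)
  r <- roc_analysis(v, lab, "lower")
  x <- c(0, r$curve$fpr, 1); y <- c(0, r$curve$sensitivity, 1)
  o <- order(x, y); x <- x[o]; y <- y[o]
  trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("the cut point maximizes TP+TN with ties towards sensitivity", {
  v <- c(1, 2, 3, 4, 5, 6)
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r <- roc_analysis(v, lab, "lower")
  correct <- sapply(sort(unique(v)), function(t)
    sum(v[lab] <= t) + sum(v[!lab] > t))
  expect_equal(sum(v[lab] <= r$cutpoint) + sum(v[!lab] > r$cutpoint),
               max(correct))
})

test_that("identical endpoints compare with z = 0, p = 1", {
  v <- rnorm(30); lab <- rep(c(TRUE, FALSE), 15)
  r1 <- roc_analysis(v, lab, "lower")
  cc <- compare_auc(r1, r1, paired = TRUE)
  expect_equal(cc$z, 0)
  expect_equal(cc$p, 1)
})

test_that("unpaired comparison reduces to the independent-SE z-test", {
  v1 <- c(1, 2, 3, 4); lab1 <- c(TRUE, FALSE, TRUE, FALSE)   # A = 0.75
  v2 <- c(1, 2, 3, 4, 5, 6)
  lab2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)           # A = 1
  r1 <- roc_analysis(v1, lab1, "lower")
  r2 <- roc_analysis(v2, lab2, "lower")
  # Hanley-McNeil SE by hand: Q1 = A/(2-A), Q2 = 2A^2/(1+A)
  se_hand <- function(A, m, n) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    sqrt((A * (1 - A) + (m - 1) * (q1 - A^2) + (n - 1) * (q2 - A^2)) /
           (m * n))
  }
  z_hand <- (0.75 - 1) / sqrt(se_hand(0.75, 2, 2)^2 + se_hand(1, 3, 3)^2)
  cc <- compare_auc(r1, r2, paired = FALSE)
  expect_equal(cc$z, z_hand, tolerance = 1e-12)
})

test_that("swapping comparison inputs negates z", {
  set.seed(5)
  lab <- rep(c(TRUE, FALSE), each = 15)
  z <- rnorm(30)
  s1 <- z + rnorm(30, 0, 0.5) - lab
  s2 <- z + rnorm(30, 0, 0.5) - 1.3 * lab
  r1 <- roc_analysis(s1, lab, "lower")
  r2 <- roc_analysis(s2, lab, "lower")
  a <- compare_auc(r1, r2, paired = TRUE)
  b <- compare_auc(r2, r1, paired = TRUE)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_error(compare_auc(r1, roc_analysis(s2[1:20], lab[1:20], "lower"),
                           paired = TRUE), "same subjects")
})

test_that("paired comparison tracks an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- rep(c(1, 0), each = 20)
  z <- rnorm(40)
  s1 <- z + rnorm(40, 0, 0.6) - lab
  s2 <- z + rnorm(40, 0, 0.6) - 1.2 * lab
  mine <- compare_auc(roc_analysis(s1, lab == 1, "lower"),
                      roc_analysis(s2, lab == 1, "lower"), paired = TRUE)
  ref <- pROC::roc.test(
    pROC::roc(lab, s1, direction = ">", quiet = TRUE),
    pROC::roc(lab, s2, direction = ">", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 0.05)
})

test_that("Passing-Bablok recovers exact linear relations", {
  f <- passing_bablok(1:10, 1:10)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_true(f$ci_slope[1] <= f$slope && f$slope <= f$ci_slope[2])
  expect_error(passing_bablok(rep(2, 8), rnorm(8)), "identical")
  expect_error(passing_bablok(1:2, 1:2), "at least 3")
})

test_that("Passing-Bablok equals the brute-force shifted median", {
  x5 <- c(1, 2.2, 3.1, 4.7, 6)
  y5 <- c(1.3, 2.1, 3.8, 4.9, 6.4)
  f <- passing_bablok(x5, y5)
  o <- pb_oracle(x5, y5)
  expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-12)

  set.seed(33)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    x <- rnorm(n, 10, 3)
    y <- 0.8 * x + rnorm(n, 0, 0.5)
    f <- passing_bablok(x, y)
    o <- pb_oracle(x, y)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-12)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-12)
  }
})

test_that("Passing-Bablok is equivariant under affine y-maps and
           axis swap", {
  set.seed(12)
  for (i in 1:20) {
    x <- cumsum(runif(12, 1, 3))
    y <- 1.4 * x + rnorm(12, 0, 0.1)   # all pairwise slopes positive
    f <- passing_bablok(x, y)
    g <- passing_bablok(x, 2 * y + 3)
    expect_equal(g$slope, 2 * f$slope, tolerance = 1e-12)
    expect_equal(g$intercept, 2 * f$intercept + 3, tolerance = 1e-12)
    s <- passing_bablok(y, x)
    expect_equal(s$slope, 1 / f$slope, tolerance = 0.1)
  }
})

test_that("quadratic fits recover the generating curve and degenerate to
           linear", {
  x <- seq(200, 4000, length.out = 48)
  y <- 2.78e-4 * x^2 + 0.72 * x + 471
  q <- fit_quadratic(x, y)
  expect_equal(q$a, 2.78e-4, tolerance = 1e-9)
  expect_equal(q$b, 0.72, tolerance = 1e-9)
  expect_equal(q$c, 471, tolerance = 1e-9)
  expect_equal(predict(q, 1000), 2.78e-4 * 1e6 + 720 + 471,
               tolerance = 1e-6)

  set.seed(2)
  xl <- runif(60, 0, 10); yl <- 2 * xl + 1 + rnorm(60, 0, 0.1)
  ql <- fit_quadratic(xl, yl)
  expect_lt(abs(ql$a), 0.02)
  expect_error(fit_quadratic(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("cross-validation r2 is high for on-curve data", {
  x <- seq(200, 4000, length.out = 48)
  q <- fit_quadratic(x, 2.78e-4 * x^2 + 0.72 * x + 471)
  set.seed(4)
  x2 <- runif(48, 200, 4000)
  y2 <- predict(q, x2) * (1 + rnorm(48, 0, 0.05))
  expect_gt(crossval_r2(q, x2, y2), 0.9)
})

test_that("minimum detectable change follows the closed form", {
  expect_equal(mdc(0), 0)
  expect_equal(mdc(1), 1.96 * sqrt(2))
  expect_equal(mdc(1), 2.771859, tolerance = 1e-6)
  s <- c(0.1, 2, 37)
  expect_equal(mdc(3 * s), 3 * mdc(s))
  expect_error(mdc(-1), "non-negative")
  # sarcoidosis NFL: sd 2.9 over n = 63 -> SEM 0.365 -> MDC ~1.01,
  # matching the reported 1.03 to the rounding of the table sd
  expect_equal(mdc(2.9 / sqrt(63)), 1.03, tolerance = 0.025)
})

test_that("square-root normalization transforms and diagnoses", {
  nv <- normalize_variable(c(0, 1, 4, 9))
  expect_equal(nv$values, c(0, 1, 2, 3))
  expect_error(normalize_variable(c(-1, 2)), "non-negative")
  deg <- normalize_variable(rep(4, 10))
  expect_true(is.na(deg$shapiro_before$W))
})

test_that("sqrt transform improves normality of squared-Gaussian data", {
  set.seed(77)
  better <- replicate(100, {
    x <- rnorm(60, 1.5, 1)^2          # markedly right-skewed, area-like
    nv <- normalize_variable(x)
    nv$shapiro_after$W > nv$shapiro_before$W
  })
  expect_gte(mean(better), 0.95)
})

test_that("ANCOVA matches the normal-equations solution on a fixture", {
  base <- c(10, 12, 9, 14, 11, 13, 10, 15, 12, 11)
  fu <- c(11, 13, 10, 15, 13, 17, 13, 19, 16, 14)
  arm <- rep(c("placebo", "active"), each = 5)
  a <- ancova_change(base, fu, factor(arm, levels = c("placebo",
                                                      "active")))
  X <- cbind(1, base, as.numeric(arm == "active"))
  beta <- solve(t(X) %*% X, t(X) %*% fu)
  expect_equal(unname(a$effect), beta[3], tolerance = 1e-10)

  same <- ancova_change(base, base, arm)
  expect_equal(unname(same$effect), 0, tolerance = 1e-10)
  expect_error(ancova_change(base, fu, rep("a", 10)), "two")
})

test_that("group summaries match hand arithmetic and flag tiny groups", {
  tab <- data.frame(group = rep(c("control", "case"), c(4, 3)),
                    nfl = c(10, 12, 14, 16, 6, 8, 10),
                    nfd = c(20, 22, 24, 26, 12, 14, 16))
  s <- summarize_groups(tab, "control", c("nfl", "nfd"))
  ctrl <- s$summary[s$summary$group == "control" &
                      s$summary$variable == "nfl", ]
  expect_equal(ctrl$mean, 13)
  expect_equal(ctrl$sd, sd(c(10, 12, 14, 16)))
  expect_equal(ctrl$sem, ctrl$sd / 2)
  expect_equal(ctrl$percent_of_control, 100)
  case <- s$summary[s$summary$group == "case" &
                      s$summary$variable == "nfl", ]
  expect_equal(case$percent_of_control, 100 * 8 / 13)
  # perfectly collinear variables give off-diagonal r = 1
  expect_equal(s$correlations$control["nfl", "nfd"], 1)
  expect_true(all(c("contrast", "p_adj") %in% names(s$tukey$nfl)))

  tiny <- data.frame(group = c("control", "control", "case"),
                     nfl = c(1, 2, 3))
  s2 <- summarize_groups(tiny, "control", "nfl")
  expect_true(is.na(s2$summary$sd[s2$summary$group == "case"]))
  expect_error(summarize_groups(tab, "nope"), "not present")
})
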