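#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods with
#' errors in both variables. The slope is the shifted median of all
#' pairwise slopes `S_ij = (y_j - y_i) / (x_j - x_i)` (pairs with equal x
#' and slopes exactly -1 excluded; the median index is shifted by K, the
#' number of slopes below -1), the intercept is `median(y - slope * x)`, and
#' confidence bounds come from the binomial rank limits on the ordered
#' slopes.
#'
#' @param x,y Paired measurements from the two methods.
#' @param conf.level Confidence level for the bounds.
#' @return A `pb_fit`: `slope`, `intercept`, `ci_slope`, `ci_intercept`,
#'   `n`, `n_slopes`, `K`.
#' @examples
#' f <- passing_bablok(1:10, 1:10)
#' c(f$slope, f$intercept)   # 1, 0
#' @export
passing_bablok <- function(x, y, conf.level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L) stop("all x values identical", call. = FALSE)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  S <- dy[ok] / dx[ok]
  S <- S[S != -1]
  N <- length(S)
  if (N == 0L) stop("no valid pairwise slopes", call. = FALSE)
  S <- sort(S)
  K <- sum(S < -1)
  idx_med <- function(i) S[min(N, max(1L, i))]
  slope <- if (N %% 2L == 1L) {
    idx_med((N + 1L) %/% 2L + K)
  } else {
    (idx_med(N %/% 2L + K) + idx_med(N %/% 2L + 1L + K)) / 2
  }
  w <- qnorm(1 - (1 - conf.level) / 2) *
    sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1L
  ci_slope <- c(idx_med(M1 + K), idx_med(M2 + K))
  intercept <- median(y - slope * x)
  ci_intercept <- c(median(y - ci_slope[2] * x),
                    median(y - ci_slope[1] * x))
  structure(list(slope = slope, intercept = intercept,
                 ci_slope = ci_slope, ci_intercept = ci_intercept,
                 n = n, n_slopes = N, K = K, conf.level = conf.level),
            class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok fit (n = %d): slope %.4f [%.4f, %.4f], intercept %.4f [%.4f, %.4f]\n",
    x$n, x$slope, x$ci_slope[1], x$ci_slope[2],
    x$intercept, x$ci_intercept[1], x$ci_intercept[2]))
  invisible(x)
}

#' Quadratic model of the length-area relationship
#'
#' Ordinary least-squares fit of `y = a x^2 + b x + c`, used to model how
#' the pixel-counting nerve fiber area grows faster than linearly with
#' nerve fiber length as the plexus approaches normal abundance.
#'
#' @param x,y Numeric vectors (e.g. NFL and NFA in pixel units).
#' @return A `quad_fit`: coefficients `a`, `b`, `c`, the fit `r2`, and the
#'   underlying `lm` object (for `confint` etc.).
#' @export
fit_quadratic <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (length(unique(x)) <= 2L) stop("degenerate design: <= 2 distinct x",
                                    call. = FALSE)
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  r2 <- summary(fit)$r.squared
  structure(list(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
                 r2 = r2, model = fit),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("Quadratic fit: y = %.4g x^2 + %.4g x + %.4g (r^2 = %.3f)\n",
              x$a, x$b, x$c, x$r2))
  invisible(x)
}

#' @export
predict.quad_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$a * x^2 + object$b * x + object$c
}

#' Coefficient of determination of a quadratic model on new data
#'
#' Squared Pearson correlation between observed values and the model's
#' predictions; used to cross-validate a fitted length-area curve on an
#' independent cohort.
#'
#' @param fit A [fit_quadratic()] result.
#' @param x,y New data.
#' @return Scalar r^2.
#' @export
crossval_r2 <- function(fit, x, y) {
  cor(predict(fit, x), y)^2
}
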