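# ROC/AUC machinery: Mann-Whitney areas, Hanley-McNeil standard errors,
# accuracy-maximizing cut points, and correlated-AUC comparison.

# Case-likeness scores: higher score = more case-like.
roc_scores <- function(values, direction) {
  if (direction == "lower") -values else values
}

# Mann-Whitney AUC (ties count 1/2) via ranks.
mw_auc <- function(scores, is_case) {
  m <- sum(is_case); n <- sum(!is_case)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_case]) - m * (m + 1) / 2) / (m * n)
}

# Hanley-McNeil closed-form SE of an AUC with m cases and n controls.
hanley_mcneil_se <- function(A, m, n) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (m - 1) * (Q1 - A^2) + (n - 1) * (Q2 - A^2)) /
         (m * n))
}

#' ROC analysis of one CCM endpoint
#'
#' Computes the area under the ROC curve as the Mann-Whitney concordance
#' probability (ties count one half), its Hanley-McNeil standard error, the
#' empirical ROC curve over observed thresholds, and the cut point that
#' maximizes the number of true positives plus true negatives (accuracy
#' criterion; ties broken towards higher sensitivity). The Youden-maximal
#' cut point is also reported.
#'
#' @param values Endpoint values for all subjects.
#' @param is_case Logical vector, `TRUE` for cases.
#' @param direction `"lower"` if lower values indicate disease (the usual
#'   situation for nerve fiber endpoints), `"higher"` otherwise.
#' @return A `ccm_roc` object: `auc`, `se_auc`, `curve` (data.frame of
#'   threshold, sensitivity, specificity, fpr), `cutpoint`, `sensitivity`,
#'   `specificity`, `cutpoint_youden`, `n_pos`, `n_neg`, plus the inputs
#'   (needed by [compare_auc()] for paired comparisons).
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))$auc  # 0.75
#' @export
roc_analysis <- function(values, is_case, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(is_case), is.logical(is_case))
  keep <- !is.na(values) & !is.na(is_case)
  values <- values[keep]; is_case <- is_case[keep]
  m <- sum(is_case); n <- sum(!is_case)
  if (m == 0L || n == 0L) stop("both classes must be non-empty",
                               call. = FALSE)
  scores <- roc_scores(values, direction)
  A <- mw_auc(scores, is_case)

  thr <- sort(unique(values))
  sens <- vapply(thr, function(t) {
    if (direction == "lower") mean(values[is_case] <= t)
    else mean(values[is_case] >= t)
  }, numeric(1))
  spec <- vapply(thr, function(t) {
    if (direction == "lower") mean(values[!is_case] > t)
    else mean(values[!is_case] < t)
  }, numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, fpr = 1 - spec)

  correct <- m * sens + n * spec
  best <- which(correct == max(correct))
  best <- best[which.max(sens[best])]
  youden <- which.max(sens + spec - 1)

  structure(list(auc = A, se_auc = hanley_mcneil_se(A, m, n),
                 curve = curve,
                 cutpoint = thr[best], sensitivity = sens[best],
                 specificity = spec[best],
                 cutpoint_youden = thr[youden],
                 n_pos = m, n_neg = n, direction = direction,
                 values = values, is_case = is_case),
            class = "ccm_roc")
}

#' @export
print.ccm_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (SE %.3f), cut point %.4g (sens %.2f, spec %.2f), %d cases / %d controls\n",
    x$auc, x$se_auc, x$cutpoint, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.ccm_roc <- function(x, ...) {
  plot(c(0, x$curve$fpr, 1), c(0, x$curve$sensitivity, 1), type = "s",
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

# Mann-Whitney structural components: per-case and per-control means of the
# pairwise concordance kernel. Their empirical covariances give the
# covariance of two AUCs computed on the same subjects.
auc_components <- function(scores, is_case) {
  sc <- scores[is_case]; sn <- scores[!is_case]
  H <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(H), v01 = colMeans(H))
}

#' Compare two correlated (or independent) AUCs
#'
#' Hanley-McNeil z-test for the difference of two ROC areas:
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)`, with the SEs from
#' the closed-form expressions. For paired designs (both endpoints measured
#' on the same subjects, supplied in the same order) the correlation `r`
#' between the two areas is estimated from the empirical covariance of the
#' Mann-Whitney structural components (`r_method = "components"`), or, as
#' the classic approximation, from the average of the within-case and
#' within-control Pearson correlations of the two scores
#' (`r_method = "score"`). Unpaired comparisons use `r = 0`.
#'
#' @param r1,r2 [roc_analysis()] results. For `paired = TRUE` they must
#'   come from the same subjects in the same order.
#' @param paired Were both endpoints measured on the same subjects?
#' @param r_method Correlation estimator for paired comparisons.
#' @param r Optional: override the correlation with a known value.
#' @return List with `z`, `p` (two-sided), `auc1`, `auc2`, `r`.
#' @export
compare_auc <- function(r1, r2, paired = TRUE,
                        r_method = c("components", "score"), r = NULL) {
  r_method <- match.arg(r_method)
  stopifnot(inherits(r1, "ccm_roc"), inherits(r2, "ccm_roc"))
  if (paired) {
    if (r1$n_pos != r2$n_pos || r1$n_neg != r2$n_neg) {
      stop("paired comparison requires the same subjects underlying both",
           call. = FALSE)
    }
    if (!identical(r1$is_case, r2$is_case)) {
      stop("paired comparison requires identical case labels in the same order",
           call. = FALSE)
    }
  }
  se1 <- r1$se_auc; se2 <- r2$se_auc
  if (is.null(r)) {
    if (!paired) {
      r <- 0
    } else if (r_method == "components") {
      s1 <- roc_scores(r1$values, r1$direction)
      s2 <- roc_scores(r2$values, r2$direction)
      cp1 <- auc_components(s1, r1$is_case)
      cp2 <- auc_components(s2, r2$is_case)
      m <- r1$n_pos; n <- r1$n_neg
      cov12 <- cov_safe(cp1$v10, cp2$v10) / m + cov_safe(cp1$v01, cp2$v01) / n
      var1 <- var_safe(cp1$v10) / m + var_safe(cp1$v01) / n
      var2 <- var_safe(cp2$v10) / m + var_safe(cp2$v01) / n
      r <- if (var1 > 0 && var2 > 0) cov12 / sqrt(var1 * var2) else 0
      r <- min(1, max(-1, r))
    } else {
      s1 <- roc_scores(r1$values, r1$direction)
      s2 <- roc_scores(r2$values, r2$direction)
      rc <- cor_safe(s1[r1$is_case], s2[r2$is_case])
      rn <- cor_safe(s1[!r1$is_case], s2[!r2$is_case])
      r <- mean(c(rc, rn), na.rm = TRUE)
      if (!is.finite(r)) r <- 0
    }
  }
  d <- r1$auc - r2$auc
  denom2 <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (d == 0) {
    z <- 0
  } else if (denom2 <= 0) {
    z <- sign(d) * Inf
  } else {
    z <- d / sqrt(denom2)
  }
  list(z = z, p = 2 * pnorm(-abs(z)), auc1 = r1$auc, auc2 = r2$auc, r = r)
}

cov_safe <- function(a, b) if (length(a) > 1L) cov(a, b) else 0
var_safe <- function(a) if (length(a) > 1L) var(a) else 0
cor_safe <- function(a, b) {
  if (length(a) > 1L && sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
}

#' Bootstrap comparison of two paired AUCs
#'
#' Stratified bootstrap (cases and controls resampled separately, pairing
#' preserved) of the AUC difference; the two-sided p-value uses the normal
#' approximation with the bootstrap standard error. Serves as a
#' resampling cross-check of [compare_auc()].
#'
#' @param values1,values2 Paired endpoint values on the same subjects.
#' @param is_case Logical case labels.
#' @param direction As in [roc_analysis()].
#' @param B Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @return List with `z`, `p`, `d` (AUC difference), `sd_boot`.
#' @export
compare_auc_boot <- function(values1, values2, is_case,
                             direction = c("lower", "higher"),
                             B = 500L, seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  s1 <- roc_scores(values1, direction)
  s2 <- roc_scores(values2, direction)
  ic <- which(is_case); nc <- which(!is_case)
  d0 <- mw_auc(s1, is_case) - mw_auc(s2, is_case)
  ds <- vapply(seq_len(B), function(b) {
    i <- sample(ic, replace = TRUE)
    j <- sample(nc, replace = TRUE)
    idx <- c(i, j)
    lab <- c(rep(TRUE, length(i)), rep(FALSE, length(j)))
    mw_auc(s1[idx], lab) - mw_auc(s2[idx], lab)
  }, numeric(1))
  sdb <- sd(ds)
  z <- if (sdb > 0) d0 / sdb else 0
  list(z = z, p = 2 * pnorm(-abs(z)), d = d0, sd_boot = sdb)
}
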