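#' Minimum detectable change
#'
#' The smallest change in an endpoint exceeding measurement noise at 95%
#' confidence for a test-retest design: `MDC = SEM * 1.96 * sqrt(2)`, where
#' SEM is the standard error of measurement of the endpoint.
#'
#' @param sem Standard error(s) of measurement, non-negative.
#' @return MDC on the same scale as `sem`.
#' @examples
#' mdc(1)   # 2.771859
#' @export
mdc <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) {
    stop("sem must be finite and non-negative", call. = FALSE)
  }
  sem * 1.96 * sqrt(2)
}

#' Square-root normalization with Shapiro-Wilk diagnostics
#'
#' Area-like endpoints are right-skewed; the square-root transform brings
#' them close to normal. Returns the transformed values together with the
#' Shapiro-Wilk W statistic and p-value before and after the transform
#' (flagged `NA` for degenerate samples where the test is undefined).
#'
#' @param values Non-negative numeric vector.
#' @return List of class `ccm_normalization`: `values` (transformed),
#'   `transform`, `shapiro_before`, `shapiro_after` (each `list(W, p)`).
#' @export
normalize_variable <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("square-root transform requires non-negative values",
         call. = FALSE)
  }
  sw <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(v) > 5000L || sd(v) == 0) {
      return(list(W = NA_real_, p = NA_real_))
    }
    t <- shapiro.test(v)
    list(W = unname(t$statistic), p = t$p.value)
  }
  out <- list(values = sqrt(values), transform = "sqrt",
              shapiro_before = sw(values),
              shapiro_after = sw(sqrt(values)))
  class(out) <- "ccm_normalization"
  out
}

#' @export
print.ccm_normalization <- function(x, ...) {
  cat(sprintf("sqrt transform: W %.4f -> %.4f (p %.3g -> %.3g)\n",
              x$shapiro_before$W, x$shapiro_after$W,
              x$shapiro_before$p, x$shapiro_after$p))
  invisible(x)
}

#' Baseline-adjusted treatment effect (ANCOVA)
#'
#' Linear model `followup ~ baseline + arm`: the arm coefficient is the
#' between-arm difference in follow-up values adjusted for baseline (the
#' adjusted net change), appropriate when longitudinal change depends on the
#' baseline value.
#'
#' @param baseline,followup Per-subject endpoint values (same order).
#' @param arm Two-level factor or character; the first level is the
#'   reference (e.g. placebo), and the reported effect is for the second
#'   level relative to it.
#' @return List: `effect`, `se`, `p`, `arm_levels`, `n`, and the `lm` fit.
#' @export
ancova_change <- function(baseline, followup, arm) {
  stopifnot(length(baseline) == length(followup),
            length(arm) == length(baseline))
  keep <- is.finite(baseline) & is.finite(followup) & !is.na(arm)
  baseline <- baseline[keep]; followup <- followup[keep]
  arm <- factor(arm[keep])
  if (nlevels(arm) != 2L) {
    stop("exactly two non-empty arms required", call. = FALSE)
  }
  fit <- lm(followup ~ baseline + arm)
  sm <- summary(fit)$coefficients
  row <- grep("^arm", rownames(sm))
  list(effect = sm[row, 1], se = sm[row, 2], p = sm[row, 4],
       arm_levels = levels(arm), n = length(baseline), model = fit)
}

#' Group descriptive statistics, correlations and Tukey comparisons
#'
#' For each group and endpoint: n, mean, sd, sem, median, iqr, min, max and
#' the mean as a percent of the control-group mean. Also returns the Pearson
#' correlation matrix between endpoints within each group, and Tukey HSD
#' pairwise group comparisons per endpoint (on `aov(value ~ group)`).
#'
#' @param table Data.frame with a `group` column and endpoint columns.
#' @param control_label Label of the control group (for percent-of-control).
#' @param variables Endpoint columns to summarize.
#' @return A `ccm_group_summary`: `summary` (long data.frame),
#'   `correlations` (named list of matrices), `tukey` (named list of
#'   data.frames).
#' @export
summarize_groups <- function(table, control_label = "control",
                             variables = intersect(ccm_variable_names(),
                                                   names(table))) {
  stopifnot(is.data.frame(table), "group" %in% names(table),
            length(variables) >= 1L)
  if (!control_label %in% table$group) {
    stop("control group '", control_label, "' not present", call. = FALSE)
  }
  groups <- unique(table$group)
  rows <- list()
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    for (v in variables) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      nv <- length(vals)
      ctrl_mean <- mean(table[[v]][table$group == control_label],
                        na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = nv,
        mean = mean(vals),
        sd = if (nv >= 2L) sd(vals) else NA_real_,
        sem = if (nv >= 2L) sd(vals) / sqrt(nv) else NA_real_,
        median = median(vals),
        iqr = unname(diff(quantile(vals, c(0.25, 0.75)))),
        min = min(vals), max = max(vals),
        percent_of_control = 100 * mean(vals) / ctrl_mean)
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  correlations <- lapply(setNames(groups, groups), function(g) {
    sub <- table[table$group == g, variables, drop = FALSE]
    if (nrow(sub) >= 3L) cor(sub, use = "pairwise.complete.obs") else NULL
  })

  tukey <- NULL
  if (length(groups) >= 2L && all(table(table$group) >= 2L)) {
    tukey <- lapply(setNames(variables, variables), function(v) {
      fit <- aov(table[[v]] ~ factor(table$group))
      th <- TukeyHSD(fit)[[1]]
      data.frame(contrast = rownames(th), diff = th[, "diff"],
                 lwr = th[, "lwr"], upr = th[, "upr"],
                 p_adj = th[, "p adj"], row.names = NULL)
    })
  }

  structure(list(summary = summary_df, correlations = correlations,
                 tukey = tukey, control_label = control_label),
            class = "ccm_group_summary")
}

#' @export
print.ccm_group_summary <- function(x, ...) {
  cat("Group summaries (control: ", x$control_label, ")\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
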