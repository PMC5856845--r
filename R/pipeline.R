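# End-to-end orchestration: per-image analysis, the cross-sectional
# diagnostic design (group summaries, ROC, cut points, AUC comparisons,
# length-area model, width distributions) and the longitudinal
# intervention design (ANCOVA, MDC gating).

#' Analysis configuration for a CCM study
#'
#' Bundles every tunable of the image pipeline and study analyses so runs
#' are reproducible from the recorded configuration.
#'
#' @param calibration A [calibration()].
#' @param seg A [seg_params()].
#' @param main_min_length_um,branch_min_length_um,max_turn_deg Fiber
#'   classification parameters ([classify_fibers()]).
#' @param prune_um Skeleton spur pruning ([skeletonize_mask()]).
#' @param aggregation Per-subject averaging mode ([aggregate_subject()]).
#' @param control_label Control group label.
#' @param seed Seed recorded (and used) by randomized analyses.
#' @return A `study_config`.
#' @export
study_config <- function(calibration = ccmorph::calibration(),
                         seg = seg_params(),
                         main_min_length_um = 50,
                         branch_min_length_um = 10,
                         max_turn_deg = 75,
                         prune_um = 5,
                         aggregation = "both_eyes",
                         control_label = "control",
                         seed = 1L) {
  structure(list(calibration = calibration, seg = seg,
                 main_min_length_um = main_min_length_um,
                 branch_min_length_um = branch_min_length_um,
                 max_turn_deg = max_turn_deg, prune_um = prune_um,
                 aggregation = aggregation, control_label = control_label,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Analyze one CCM image end to end
#'
#' Segmentation, skeletonization, fiber classification and width
#' measurement composed into a single per-image record. Deterministic: the
#' same image and configuration always give the same record.
#'
#' @param image A [ccm_image()].
#' @param config A [study_config()].
#' @param keep_intermediates Also return the mask, graph, fiber set and
#'   width profile.
#' @return List: `variables` (a `ccm_variables` row), `width_distribution`
#'   (or NULL for an empty mask), and intermediates when requested.
#' @export
analyze_image <- function(image, config = study_config(),
                          keep_intermediates = FALSE) {
  stopifnot(inherits(image, "ccm_image"), inherits(config, "study_config"))
  mask <- segment_nerves(image, config$seg)
  graph <- skeletonize_mask(mask, prune_um = config$prune_um)
  fibers <- classify_fibers(graph,
                            main_min_length_um = config$main_min_length_um,
                            branch_min_length_um = config$branch_min_length_um,
                            max_turn_deg = config$max_turn_deg)
  widths <- measure_widths(mask, graph)
  vars <- compute_variables(fibers, widths, mask)
  wd <- if (nrow(widths)) width_histogram(widths) else NULL
  out <- list(variables = vars, width_distribution = wd,
              meta = image$meta)
  if (keep_intermediates) {
    out$mask <- mask; out$graph <- graph
    out$fibers <- fibers; out$widths <- widths
  }
  out
}

roc_summary <- function(r) {
  list(auc = r$auc, se_auc = r$se_auc, cutpoint = r$cutpoint,
       sensitivity = r$sensitivity, specificity = r$specificity,
       n_pos = r$n_pos, n_neg = r$n_neg)
}

#' Cross-sectional diagnostic study
#'
#' Given a per-subject endpoint table with a control group and one or more
#' case groups, computes per endpoint: group descriptive statistics and
#' percent-of-control, case-vs-control ROC curves with Hanley-McNeil
#' standard errors and accuracy-maximizing cut points, pairwise
#' correlated-AUC comparisons across endpoints within each case group,
#' within-group endpoint correlation matrices, and the quadratic
#' length-area model. Endpoints failing Shapiro-Wilk normality (p < 0.05)
#' are square-root transformed for the mean comparisons and correlations
#' (rank-based ROC analyses are unaffected); raw-scale summaries are always
#' reported alongside.
#'
#' @param table Data.frame with `subject_id`, `group` and endpoint columns.
#' @param config A [study_config()] (supplies the control label).
#' @param variables Endpoint columns to analyze.
#' @param width_dists Optional named list (by group label) of lists of
#'   per-subject [width_histogram()]s; adds group-averaged width
#'   distributions and mid-width dropout ratios versus control.
#' @return A `ccm_report` list.
#' @export
run_diagnostic_study <- function(table, config = study_config(),
                                 variables = intersect(ccm_variable_names(),
                                                       names(table)),
                                 width_dists = NULL) {
  control <- config$control_label
  if (!control %in% table$group) stop("control group missing",
                                      call. = FALSE)
  case_groups <- setdiff(unique(table$group), control)
  if (!length(case_groups)) stop("need at least one case group",
                                 call. = FALSE)

  normality <- lapply(setNames(variables, variables), function(v) {
    vals <- table[[v]]
    if (any(vals < 0, na.rm = TRUE)) return(NULL)
    nv <- normalize_variable(vals)
    list(W_raw = nv$shapiro_before$W, p_raw = nv$shapiro_before$p,
         W_sqrt = nv$shapiro_after$W, p_sqrt = nv$shapiro_after$p,
         transformed = is.finite(nv$shapiro_before$p) &&
           nv$shapiro_before$p < 0.05)
  })
  table_t <- table
  for (v in variables) {
    if (isTRUE(normality[[v]]$transformed)) {
      table_t[[v]] <- sqrt(table[[v]])
    }
  }

  summaries <- summarize_groups(table, control, variables)
  summaries_t <- summarize_groups(table_t, control, variables)

  roc <- list(); auc_cmp <- list()
  for (g in case_groups) {
    sub <- table[table$group %in% c(g, control), , drop = FALSE]
    is_case <- sub$group == g
    rocs <- lapply(setNames(variables, variables), function(v)
      roc_analysis(sub[[v]], is_case, direction = "lower"))
    roc[[g]] <- lapply(rocs, roc_summary)
    cmp <- list()
    for (i in seq_along(variables)[-length(variables)]) {
      for (j in (i + 1L):length(variables)) {
        key <- paste(variables[i], variables[j], sep = "_vs_")
        cc <- compare_auc(rocs[[i]], rocs[[j]], paired = TRUE)
        cmp[[key]] <- list(z = cc$z, p = cc$p, auc1 = cc$auc1,
                           auc2 = cc$auc2, r = cc$r)
      }
    }
    auc_cmp[[g]] <- cmp
  }

  quad <- NULL
  if (all(c("nfl", "nfa_fiji") %in% variables)) {
    qf <- fit_quadratic(table$nfl, table$nfa_fiji)
    quad <- list(a = qf$a, b = qf$b, c = qf$c, r2 = qf$r2)
  }

  widths <- NULL
  if (!is.null(width_dists)) {
    avg <- lapply(width_dists, average_width_distributions)
    dropout <- NULL
    if (control %in% names(avg)) {
      dropout <- lapply(avg[setdiff(names(avg), control)], function(d)
        midwidth_dropout(d, avg[[control]]))
    }
    widths <- list(group_averages = avg, dropout_vs_control = dropout)
  }

  structure(list(design = "diagnostic",
                 control = control, case_groups = case_groups,
                 variables = variables, seed = config$seed,
                 normality = normality,
                 summary = summaries$summary,
                 summary_transformed = summaries_t$summary,
                 correlations = summaries_t$correlations,
                 tukey = summaries_t$tukey,
                 roc = roc, auc_comparisons = auc_cmp,
                 quadratic_nfl_nfa = quad,
                 width_distributions = widths),
            class = "ccm_report")
}

#' Longitudinal intervention study
#'
#' Matches subjects across baseline and follow-up visits (error listing any
#' unmatched ids), then per endpoint reports the mean change and its SE per
#' arm, the baseline-adjusted ANCOVA treatment effect with SE and p, the
#' minimum detectable change derived from the baseline SEM (sd of baseline
#' values over sqrt(n)), and whether the net change exceeds it.
#'
#' @param baseline Data.frame: `subject_id`, `arm`, endpoint columns.
#' @param followup Data.frame: `subject_id`, endpoint columns.
#' @param config A [study_config()].
#' @param variables Endpoint columns to analyze.
#' @param reference_arm Arm treated as reference (e.g. `"placebo"`); the
#'   reported effect and net change are for the other arm relative to it.
#'   Defaults to the first factor level of `arm`.
#' @return A `ccm_report` list.
#' @export
run_longitudinal_study <- function(baseline, followup,
                                   config = study_config(),
                                   variables = intersect(ccm_variable_names(),
                                                         names(baseline)),
                                   reference_arm = NULL) {
  stopifnot("arm" %in% names(baseline))
  unmatched <- c(setdiff(baseline$subject_id, followup$subject_id),
                 setdiff(followup$subject_id, baseline$subject_id))
  if (length(unmatched)) {
    stop("unmatched subjects across visits: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  followup <- followup[match(baseline$subject_id, followup$subject_id), ,
                       drop = FALSE]
  arm <- factor(baseline$arm)
  if (!is.null(reference_arm)) {
    stopifnot(reference_arm %in% levels(arm))
    arm <- stats::relevel(arm, ref = reference_arm)
  }
  if (nlevels(arm) != 2L) stop("exactly two arms required", call. = FALSE)

  per_var <- lapply(setNames(variables, variables), function(v) {
    b <- baseline[[v]]; f <- followup[[v]]
    ch <- f - b
    by_arm <- lapply(setNames(levels(arm), levels(arm)), function(a) {
      x <- ch[arm == a]
      list(n = length(x), mean_change = mean(x),
           se_change = sd(x) / sqrt(length(x)))
    })
    an <- ancova_change(b, f, arm)
    sem <- sd(b) / sqrt(length(b))
    m <- mdc(sem)
    net <- by_arm[[2]]$mean_change - by_arm[[1]]$mean_change
    list(arms = by_arm,
         ancova = list(effect = an$effect, se = an$se, p = an$p),
         baseline_sem = sem, mdc = m, net_change = net,
         exceeds_mdc = abs(net) > m)
  })

  structure(list(design = "longitudinal", variables = variables,
                 arms = levels(arm), seed = config$seed,
                 n_subjects = nrow(baseline), results = per_var),
            class = "ccm_report")
}

#' Serialize a study report to JSON
#'
#' Reports are plain nested lists of scalars, vectors and data frames, so
#' they round-trip losslessly through JSON.
#'
#' @param report A `ccm_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.ccm_report <- function(x, ...) {
  cat("CCM study report (", x$design, " design)\n", sep = "")
  if (x$design == "diagnostic") {
    cat("  groups:", paste(c(x$control, x$case_groups), collapse = ", "),
        "\n")
    for (g in names(x$roc)) {
      aucs <- vapply(x$roc[[g]], function(r) r$auc, numeric(1))
      cat(sprintf("  %s vs %s AUC: %s\n", g, x$control,
                  paste(sprintf("%s %.2f", names(aucs), aucs),
                        collapse = ", ")))
    }
  } else {
    for (v in names(x$results)) {
      r <- x$results[[v]]
      cat(sprintf(
        "  %s: net change %.3g (MDC %.3g%s), ANCOVA p = %.3g\n",
        v, r$net_change, r$mdc,
        if (r$exceeds_mdc) ", exceeded" else "", r$ancova$p))
    }
  }
  invisible(x)
}
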