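#' Variable columns of a per-image morphometry table
#' @keywords internal
ccm_variable_names <- function() {
  c("nfd", "nbd", "nfl", "nfa_wxl", "nfa_fiji", "mean_width_um")
}

#' Read a subject metadata table
#'
#' Expects a CSV with header columns `subject_id, group, nds, eye, visit,
#' image_path` (extra columns are kept). `nds`, when present, must lie in
#' 0..10 (the Neuropathy Disability Score scale).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_subject_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("subject table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("nds" %in% names(tab)) {
    bad <- !is.na(tab$nds) & (tab$nds < 0 | tab$nds > 10)
    if (any(bad)) stop("nds values outside 0-10", call. = FALSE)
  }
  tab
}

#' Aggregate per-image endpoints to one record per subject
#'
#' Per-image CCM endpoints are averaged to a single record per subject.
#' In `"single_eye"` mode all images of a subject are averaged directly.
#' In `"both_eyes"` mode images are first averaged within each eye and the
#' subject value is the mean of the two eye means (so eyes with unequal image
#' counts carry equal weight); a subject with only one eye available falls
#' back to that eye and is flagged. A `"pooled"` mode that ignores the eye
#' grouping is provided for sensitivity analyses.
#'
#' @param records Data.frame with columns `subject_id`, `eye` (needed for
#'   `both_eyes`), and one or more numeric endpoint columns (by default the
#'   standard set, see [compute_variables()]; other numeric columns named in
#'   `variables` work equally).
#' @param mode `"single_eye"`, `"both_eyes"` or `"pooled"`.
#' @param variables Character vector of columns to average.
#' @return Data.frame with one row per subject, the averaged variables, and
#'   for `both_eyes` the columns `n_eyes` and `missing_eye` flag.
#' @examples
#' recs <- data.frame(subject_id = "s1", eye = c("L", "L", "R"),
#'                    nfl = c(10, 20, 30))
#' aggregate_subject(recs, "both_eyes", variables = "nfl")$nfl  # 22.5
#' @export
aggregate_subject <- function(records,
                              mode = c("single_eye", "both_eyes", "pooled"),
                              variables = intersect(ccm_variable_names(),
                                                    names(records))) {
  mode <- match.arg(mode)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  if (!length(variables)) stop("no endpoint columns to aggregate",
                               call. = FALSE)
  if (!"subject_id" %in% names(records)) stop("missing subject_id column",
                                              call. = FALSE)
  subjects <- unique(records$subject_id)
  rows <- lapply(subjects, function(sid) {
    sub <- records[records$subject_id == sid, , drop = FALSE]
    if (mode %in% c("single_eye", "pooled")) {
      vals <- vapply(variables, function(v) mean(sub[[v]]), numeric(1))
      data.frame(subject_id = sid, t(vals), n_images = nrow(sub),
                 check.names = FALSE)
    } else {
      if (!"eye" %in% names(sub)) stop("both_eyes mode needs an eye column",
                                       call. = FALSE)
      eyes <- unique(sub$eye)
      eye_means <- t(vapply(eyes, function(e) {
        vapply(variables, function(v) mean(sub[[v]][sub$eye == e]),
               numeric(1))
      }, numeric(length(variables))))
      vals <- colMeans(matrix(eye_means, ncol = length(variables),
                              dimnames = list(NULL, variables)))
      data.frame(subject_id = sid, t(vals), n_images = nrow(sub),
                 n_eyes = length(eyes), missing_eye = length(eyes) < 2L,
                 check.names = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (mode == "both_eyes" && any(out$missing_eye)) {
    warning(sum(out$missing_eye),
            " subject(s) had images from only one eye; the available eye ",
            "mean was used", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
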