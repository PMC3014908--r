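#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random case outscores a random control, with half
#' credit for ties (the Mann-Whitney convention):
#' `(#pairs case > control + 0.5 * #ties) / (n_case * n_control)`.
#'
#' @param case_scores,control_scores Numeric score vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(3, 1), c(2, 0, 1))  # 0.75
auc <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores))
    stop("both score vectors must be non-empty")
  n1 <- as.numeric(length(case_scores))
  n0 <- as.numeric(length(control_scores))
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full ROC curve
#'
#' False- and true-positive rates at every observed threshold (classifying
#' `score >= threshold` as positive), from the all-positive to the
#' all-negative operating point.
#'
#' @inheritParams auc
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores))
    stop("both score vectors must be non-empty")
  th <- sort(unique(c(case_scores, control_scores)))
  tpr <- vapply(th, function(t) mean(case_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(control_scores >= t), numeric(1))
  data.frame(threshold = c(-Inf, th, Inf),
             fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
}

#' Subgroup ROC areas of patient strata against a common control group
#'
#' Scores patients and controls with a fitted conditional model and computes
#' the AUC of each patient subgroup (by stage and by histology) against ALL
#' controls of the data set. Subgroups with fewer than 3 patients are
#' flagged `low_n`; empty subgroups give an `NA` row.
#'
#' @param fit An [`aa_clogit`][fit_conditional] fit.
#' @param patients Cohort `data.frame` of patients annotated with `stage`
#'   and `histology`.
#' @param controls Cohort `data.frame` of controls.
#' @param by Annotation columns to stratify on (default stage and
#'   histology).
#' @return `data.frame` with columns `variable`, `level`, `n`, `auc`,
#'   `low_n`, plus a first row `overall`.
#' @export
subgroup_auc <- function(fit, patients, controls,
                         by = c("stage", "histology")) {
  s_case <- discriminant_score(fit, patients)
  s_ctrl <- discriminant_score(fit, controls)
  rows <- list(data.frame(variable = "overall", level = "all",
                          n = length(s_case),
                          auc = auc(s_case, s_ctrl), low_n = FALSE))
  for (v in by) {
    levels_v <- if (v == "stage") c("I", "II", "III", "IV")
                else sort(unique(stats::na.omit(patients[[v]])))
    for (lv in levels_v) {
      in_sub <- which(!is.na(patients[[v]]) & patients[[v]] == lv)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lv, n = length(in_sub),
        auc = if (length(in_sub)) auc(s_case[in_sub], s_ctrl) else NA_real_,
        low_n = length(in_sub) < 3L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
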