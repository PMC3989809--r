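# Empirical ROC curves, tie-corrected AUC, and Youden-index optimal
# cut-point selection for dichotomizing continuous predictors.

.check_two_classes <- function(outcome) {
  if (any(is.na(outcome)) || !all(outcome %in% c(0, 1)))
    stop("outcome must be 0/1 with no missing values", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("degenerate input: outcome has a single class", call. = FALSE)
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity of the rule "positive when value >=
#' threshold" at every distinct observed value, plus the two trivial
#' endpoints (threshold -Inf: sens 1 / spec 0; threshold +Inf: sens 0 /
#' spec 1). Candidate thresholds are the observed values themselves, not
#' midpoints, so a selected cut-off is always an attainable data value.
#'
#' @param values Numeric predictor vector.
#' @param outcome 0/1 outcome vector of the same length; both classes
#'   must be present.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, ordered by increasing threshold; sensitivity is
#'   non-increasing and specificity non-decreasing along it.
#' @export
roc_curve <- function(values, outcome) {
  .check_two_classes(outcome)
  stopifnot(length(values) == length(outcome), !any(is.na(values)))
  thr <- sort(unique(values))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  f <- factor(values, levels = thr)
  at1 <- tabulate(f[outcome == 1], nbins = length(thr))
  at0 <- tabulate(f[outcome == 0], nbins = length(thr))
  # cases at or above each threshold; controls strictly below it
  sens <- rev(cumsum(rev(at1))) / n1
  spec <- (cumsum(at0) - at0) / n0
  data.frame(threshold = c(-Inf, thr, Inf),
             sensitivity = c(1, sens, 0),
             specificity = c(0, spec, 1))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal area under the empirical ROC polygon, which equals the
#' tie-corrected Mann-Whitney statistic
#' \eqn{(\#wins + \#ties/2) / (n_1 n_0)} on the same data.
#'
#' @param roc ROC data frame from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  fpr <- rev(1 - roc$specificity)  # increasing FPR
  tpr <- rev(roc$sensitivity)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Mann-Whitney AUC directly from values
#'
#' Rank-based computation of the probability that a random case outranks
#' a random control, counting ties as one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(values, outcome) {
  .check_two_classes(outcome)
  r <- rank(values)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index optimal cut-point
#'
#' Selects the threshold maximizing J = sensitivity + specificity - 1
#' over the distinct observed values. The risk direction is either fixed
#' by the caller or chosen as the one whose AUC is at least 0.5
#' (`ge_is_risk` when high values predict the outcome, `lt_is_risk` when
#' low values do, as for body-mass index). Ties in J are broken towards
#' the smaller cut-off in the risk direction, for determinism.
#'
#' @inheritParams roc_curve
#' @param variable Name carried into the result, for reporting.
#' @param direction `"ge_is_risk"`, `"lt_is_risk"`, or `NULL` to choose
#'   by AUC.
#' @return Object of class `cutpoint`: a list with `variable`, `cutoff`
#'   (an observed data value), `direction`, `youden_j`, `sensitivity`,
#'   `specificity`, `auc` (in the chosen direction) and `p_value` (AUC
#'   versus 0.5, from [auc_pvalue()]).
#' @export
youden_cutpoint <- function(values, outcome, variable = "x",
                            direction = NULL) {
  .check_two_classes(outcome)
  if (!is.null(direction))
    direction <- match.arg(direction, c("ge_is_risk", "lt_is_risk"))
  else {
    a <- auc_mann_whitney(values, outcome)
    direction <- if (a >= 0.5) "ge_is_risk" else "lt_is_risk"
  }
  # J on the exact integer scale J * n1 * n0, so equal-J ties are broken
  # deterministically (towards the smaller cut-off) without float noise.
  # J of the rule "risk when value >= t"; the strict rule "risk when
  # value < t" on the same threshold grid has J_lt(t) = -J_ge(t).
  thr <- sort(unique(values))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  f <- factor(values, levels = thr)
  at1 <- tabulate(f[outcome == 1], nbins = length(thr))
  at0 <- tabulate(f[outcome == 0], nbins = length(thr))
  cases_ge <- rev(cumsum(rev(at1)))
  ctrl_lt <- cumsum(at0) - at0
  j_int <- cases_ge * n0 + ctrl_lt * n1 - n1 * n0
  if (direction == "lt_is_risk") j_int <- -j_int
  best <- which.max(j_int)  # thresholds ascend: ties keep the smaller
  sens <- if (direction == "ge_is_risk") cases_ge[best] / n1
          else 1 - cases_ge[best] / n1
  spec <- if (direction == "ge_is_risk") ctrl_lt[best] / n0
          else 1 - ctrl_lt[best] / n0
  a_dir <- auc_mann_whitney(
    if (direction == "ge_is_risk") values else -values, outcome)
  structure(list(variable = variable, cutoff = thr[best],
                 direction = direction, youden_j = j_int[best] / (n1 * n0),
                 sensitivity = sens, specificity = spec,
                 auc = a_dir,
                 p_value = auc_pvalue(a_dir, sum(outcome == 1),
                                      sum(outcome == 0))),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  op <- if (x$direction == "ge_is_risk") ">=" else "<"
  cat(sprintf(
    "Youden cut-point for %s: risk when %s %s %g (J = %.3f, AUC = %.3f, p = %.3g)\n",
    x$variable, x$variable, op, x$cutoff, x$youden_j, x$auc, x$p_value))
  invisible(x)
}

#' Two-sided p-value for AUC against 0.5
#'
#' Normal approximation to the null distribution of the Mann-Whitney
#' statistic (no ties): under H0 the AUC has mean 1/2 and variance
#' \eqn{(n_1 + n_0 + 1) / (12 n_1 n_0)}. A continuity correction of
#' half an AUC step, \eqn{1 / (2 n_1 n_0)}, keeps the approximation
#' close to the exact permutation null in small samples.
#'
#' @param auc Observed AUC.
#' @param n_pos,n_neg Numbers of cases and controls.
#' @return Two-sided p-value in \[0, 1\]; equals 1 when `auc` is 0.5.
#' @export
auc_pvalue <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  se0 <- sqrt((n_pos + n_neg + 1) / (12 * n_pos * n_neg))
  dev <- max(0, abs(auc - 0.5) - 1 / (2 * n_pos * n_neg))
  min(1, 2 * stats::pnorm(-dev / se0))
}

#' Youden cut-points for a set of cohort variables
#'
#' Applies [youden_cutpoint()] to each named continuous column of a
#' cohort against the stenosis outcome, with the score's fixed direction
#' conventions (BMI: low is risk; all others: high is risk).
#'
#' @param cohort Cohort data frame with an `ras_significant` column.
#' @param variables Continuous columns to dichotomize.
#' @param directions Named character vector overriding the default
#'   direction per variable.
#' @return Named list of `cutpoint` objects.
#' @export
select_cutpoints <- function(cohort,
                             variables = c("age", "bmi", "cimt",
                                           "total_chol", "hdl_chol",
                                           "triglyceride"),
                             directions = c(bmi = "lt_is_risk")) {
  out <- lapply(variables, function(v) {
    dir <- if (v %in% names(directions)) directions[[v]] else "ge_is_risk"
    youden_cutpoint(cohort[[v]], cohort$ras_significant,
                    variable = v, direction = dir)
  })
  stats::setNames(out, variables)
}
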