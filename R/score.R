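# Integer risk-score derivation from logistic coefficients, score
# calibration, and evaluation of a score on grouped (score, n, events)
# data: AUC with confidence interval, classification metrics,
# Hosmer-Lemeshow goodness of fit, and paired AUC comparison.

# round-half-away-from-zero, the "closest integer" rule used for points
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive integer points from model coefficients
#'
#' Each retained predictor is assigned the integer closest to the ratio
#' of its coefficient to the smallest retained coefficient, so the
#' weakest predictor carries 1 point. Halves round away from zero. The
#' maximum attainable total treats mutually exclusive indicator groups
#' (the levels of a categorical predictor, e.g. unilateral vs bilateral
#' plaque) as contributing only their largest value.
#'
#' @param x A fitted `ras_logit` (its non-intercept coefficients are
#'   used, and categorical blocks define the exclusive groups), or a
#'   named numeric coefficient vector.
#' @param exclusive When `x` is a plain vector: list of character
#'   vectors naming mutually exclusive indicators. Defaults to the
#'   plaque-extent pair when both its indicators are present.
#' @return Object of class `score_system`: list with `points` (named
#'   integer vector, all >= 1), `max_score`, `exclusive`, and a `NULL`
#'   `calibration` slot filled by [calibrate_score()].
#' @export
derive_scores <- function(x, exclusive = NULL) {
  if (inherits(x, "ras_logit")) {
    beta <- x$coefficients[setdiff(names(x$coefficients),
                                   "(Intercept)")]
    if (is.null(exclusive)) {
      multi <- x$blocks[vapply(x$blocks, length, 1L) > 1L]
      exclusive <- unname(multi)
    }
  } else {
    beta <- x
    if (is.null(exclusive)) {
      cap <- intersect(c("cap_unilateral", "cap_bilateral"), names(beta))
      exclusive <- if (length(cap) == 2L) list(cap) else list()
    }
  }
  if (length(beta) == 0L) stop("no coefficients to score", call. = FALSE)
  if (any(beta <= 0))
    stop("all retained coefficients must be positive; recode ",
         paste(sQuote(names(beta)[beta <= 0]), collapse = ", "),
         " so that the indicator marks the risk direction",
         call. = FALSE)
  points <- as.integer(.round_half_away(beta / min(beta)))
  names(points) <- names(beta)
  grouped <- unlist(exclusive)
  max_score <- sum(points[setdiff(names(points), grouped)]) +
    sum(vapply(exclusive, function(g) max(points[g]), numeric(1)))
  structure(list(points = points, max_score = as.integer(max_score),
                 exclusive = exclusive, calibration = NULL),
            class = "score_system")
}

#' @export
print.score_system <- function(x, ...) {
  cat("Integer risk score (max", x$max_score, "points):\n")
  print(x$points)
  if (!is.null(x$calibration))
    cat(sprintf(
      "Calibration: logit(p) = %.4f + %.4f * score\n",
      x$calibration[["intercept"]], x$calibration[["slope"]]))
  invisible(x)
}

#' Total score of each record
#'
#' Sum of the points of the indicators present in each record.
#'
#' @param records Derived cohort data frame with every indicator column
#'   the system scores.
#' @param sys A [derive_scores()] system.
#' @return Integer vector of totals in `[0, max_score]`.
#' @export
total_score <- function(records, sys) {
  miss <- setdiff(names(sys$points), names(records))
  if (length(miss) > 0L)
    stop("records lack scored indicator(s): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  M <- as.matrix(records[, names(sys$points), drop = FALSE])
  as.integer(M %*% sys$points)
}

#' Calibrate the score-to-probability mapping
#'
#' Fits the score-only logistic model `logit(p) = a + b * score` by
#' maximum likelihood and attaches `(a, b)` to the score system, along
#' with the model-predicted event frequency at each observed score
#' (`n_s * p(s)`, the "predicted frequency" column of a grouped table).
#'
#' @param data A [grouped_scores()] table, or a derived cohort (then
#'   `sys` must be given so totals can be computed against its
#'   `ras_significant` outcome).
#' @param sys Optional [derive_scores()] system to update.
#' @return The updated `score_system` (or, when `sys` is `NULL`, a bare
#'   list) with `calibration = c(intercept, slope)` and a
#'   `predicted` data frame (`score`, `n`, `observed_events`,
#'   `predicted_events`).
#' @export
calibrate_score <- function(data, sys = NULL) {
  if (inherits(data, "grouped_scores")) {
    subjects <- expand_score_table(data)
  } else {
    stopifnot(!is.null(sys))
    subjects <- data.frame(score = total_score(data, sys),
                           outcome = data$ras_significant)
  }
  if (length(unique(subjects$score)) < 2L)
    stop("degenerate score distribution: need >= 2 distinct scores",
         call. = FALSE)
  fit <- fit_logistic(design_spec(terms = "score", outcome = "outcome"),
                      subjects)
  cal <- c(intercept = unname(fit$coefficients["(Intercept)"]),
           slope = unname(fit$coefficients["score"]))
  agg <- stats::aggregate(outcome ~ score, subjects,
                          FUN = function(x) c(n = length(x),
                                              ev = sum(x)))
  pred <- data.frame(
    score = agg$score,
    n = agg$outcome[, "n"],
    observed_events = agg$outcome[, "ev"])
  pred$predicted_events <- pred$n *
    stats::plogis(cal[["intercept"]] + cal[["slope"]] * pred$score)
  out <- if (is.null(sys))
    structure(list(points = NULL, max_score = NA_integer_,
                   exclusive = list(), calibration = NULL),
              class = "score_system")
  else sys
  out$calibration <- cal
  out$predicted <- pred
  out$calibration_fit <- fit
  out
}

#' Probability of the outcome at a given score
#'
#' @param sys A calibrated `score_system`.
#' @param score Integer score value(s).
#' @return `1 / (1 + exp(-(a + b * score)))`.
#' @export
score_probability <- function(sys, score) {
  if (is.null(sys$calibration))
    stop("score system is not calibrated; run calibrate_score()",
         call. = FALSE)
  stats::plogis(sys$calibration[["intercept"]] +
                  sys$calibration[["slope"]] * score)
}

# per-row placement counts for grouped data:
# for cases at score s, the fraction of controls ranked below them
# (strictly below + half at s); symmetric for controls.
.grouped_placements <- function(table) {
  ctrl <- table$n - table$events
  n1 <- sum(table$events); n0 <- sum(ctrl)
  below_ctrl <- cumsum(ctrl) - ctrl
  above_case <- rev(cumsum(rev(table$events))) - table$events
  list(n1 = n1, n0 = n0,
       v10 = (below_ctrl + 0.5 * ctrl) / n0,        # one per case row
       v01 = (above_case + 0.5 * table$events) / n1, # one per control row
       w1 = table$events, w0 = ctrl)
}

#' AUC of a score from grouped counts
#'
#' Tie-corrected Mann-Whitney AUC computed directly from a grouped
#' table: over all case-control pairs, the fraction of pairs the case
#' outranks plus half the ties. The confidence interval uses the DeLong
#' placement-value variance on the logit scale, so it respects \[0, 1\].
#'
#' @param table A [grouped_scores()] table.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci` (length-2 vector), `n1`, `n0`.
#' @export
grouped_auc <- function(table, conf_level = 0.95) {
  pl <- .grouped_placements(table)
  if (pl$n1 == 0 || pl$n0 == 0)
    stop("degenerate table: need both events and non-events",
         call. = FALSE)
  auc <- sum(pl$w1 * pl$v10) / pl$n1
  # weighted sample variances of the placement values
  vvar <- function(v, w, m) {
    n <- sum(w)
    if (n < 2) return(0)
    sum(w * (v - m)^2) / (n - 1)
  }
  s10 <- vvar(pl$v10, pl$w1, auc)
  s01 <- vvar(pl$v01, pl$w0, sum(pl$w0 * pl$v01) / pl$n0)
  se <- sqrt(s10 / pl$n1 + s01 / pl$n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (auc <= 0 || auc >= 1 || se == 0) c(auc, auc) else {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
  }
  list(auc = auc, se = se, ci = ci, n1 = pl$n1, n0 = pl$n0)
}

#' Classification metrics of a score cut-off
#'
#' Test-positive means score >= cutoff. Sensitivity and specificity come
#' from the grouped counts; predictive values are reported both from the
#' raw counts and, when a prevalence is supplied, re-weighted by Bayes'
#' formulas at that prevalence.
#'
#' @param table A [grouped_scores()] table.
#' @param cutoff Integer cut-off within the score range.
#' @param prevalence Optional outcome prevalence for adjusted predictive
#'   values.
#' @return List with `sensitivity`, `specificity`, `ppv_raw`,
#'   `npv_raw`, and (when `prevalence` is given) `ppv_adjusted`,
#'   `npv_adjusted`.
#' @export
classification_metrics <- function(table, cutoff, prevalence = NULL) {
  pos <- table$score >= cutoff
  ctrl <- table$n - table$events
  E <- sum(table$events); C <- sum(ctrl)
  tp <- sum(table$events[pos]); fp <- sum(ctrl[pos])
  fn <- E - tp; tn <- C - fp
  sens <- tp / E; spec <- tn / C
  out <- list(sensitivity = sens, specificity = spec,
              ppv_raw = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
              npv_raw = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  if (!is.null(prevalence)) {
    stopifnot(prevalence > 0, prevalence < 1)
    out$ppv_adjusted <- sens * prevalence /
      (sens * prevalence + (1 - spec) * (1 - prevalence))
    out$npv_adjusted <- spec * (1 - prevalence) /
      (spec * (1 - prevalence) + (1 - sens) * prevalence)
  }
  out
}

#' Hosmer-Lemeshow goodness of fit on score groups
#'
#' Chi-square comparison of observed and calibration-predicted event
#' counts across the observed score values (not deciles of risk, since
#' grouped score data arrives already banded by score). Groups whose
#' expected event or non-event count is zero are merged into their upper
#' neighbour and noted in the result.
#'
#' @param table A [grouped_scores()] table.
#' @param calibration Numeric `c(intercept, slope)` of the score-only
#'   logistic model (see [calibrate_score()]).
#' @param df_adjust Degrees-of-freedom reduction: `df = groups -
#'   df_adjust` (default 2, for the two fitted calibration parameters).
#' @return List with `chisq`, `df`, `p`, `groups` (data frame of
#'   observed/expected per group), `merged` (character note, possibly
#'   empty).
#' @export
hosmer_lemeshow <- function(table, calibration, df_adjust = 2L) {
  tab <- as.data.frame(table)[table$n > 0, ]
  if (nrow(tab) < 3L)
    stop("need >= 3 non-empty score groups", call. = FALSE)
  p <- stats::plogis(calibration[[1]] + calibration[[2]] * tab$score)
  e <- tab$n * p
  merged <- character()
  i <- 1L
  while (i <= nrow(tab)) {
    if (e[i] <= 0 || e[i] >= tab$n[i]) {
      j <- if (i < nrow(tab)) i + 1L else i - 1L
      merged <- c(merged,
                  sprintf("merged score group %d into %d",
                          tab$score[i], tab$score[j]))
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$events[j] <- tab$events[j] + tab$events[i]
      e[j] <- e[j] + e[i]
      tab <- tab[-i, ]; e <- e[-i]
    } else i <- i + 1L
  }
  o <- tab$events
  chisq <- sum((o - e)^2 / e + ((tab$n - o) - (tab$n - e))^2 /
                 (tab$n - e))
  df <- nrow(tab) - df_adjust
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       groups = data.frame(score = tab$score, n = tab$n, observed = o,
                           expected = e),
       merged = merged)
}

#' Paired AUC comparison by the DeLong method
#'
#' Compares the AUCs of two prediction vectors on the same subjects
#' using the nonparametric placement-value covariance estimator; the
#' difference is rank-based, so any strictly monotone transform of a
#' predictor leaves it unchanged.
#'
#' @param predictions_a,predictions_b Numeric prediction vectors over
#'   the same subjects.
#' @param outcome 0/1 outcome vector; both classes must be present.
#' @return List with `auc_a`, `auc_b`, `delta` (a minus b), `se`, `z`,
#'   `p` (two-sided).
#' @export
delong_compare <- function(predictions_a, predictions_b, outcome) {
  .check_two_classes(outcome)
  stopifnot(length(predictions_a) == length(outcome),
            length(predictions_b) == length(outcome))
  case <- outcome == 1
  n1 <- sum(case); n0 <- sum(!case)
  placements <- function(x) {
    xc <- x[case]; xn <- x[!case]
    v10 <- vapply(xc, function(v)
      (sum(xn < v) + 0.5 * sum(xn == v)) / n0, numeric(1))
    v01 <- vapply(xn, function(v)
      (sum(xc > v) + 0.5 * sum(xc == v)) / n1, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(predictions_a); pb <- placements(predictions_b)
  delta <- pa$auc - pb$auc
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = se,
       z = z, p = min(1, p))
}

#' Coefficient of determination between observed and predicted
#' frequencies
#'
#' R-squared of the ordinary least-squares regression of observed on
#' predicted per-score frequencies; 1 when they coincide.
#'
#' @param observed,predicted Numeric vectors of per-score frequencies
#'   (>= 3 points).
#' @return R-squared, or `NA` (with a warning) when the predicted
#'   frequencies have zero variance.
#' @export
fit_goodness_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            length(observed) >= 3L)
  if (stats::var(predicted) == 0) {
    warning("predicted frequencies have zero variance; R2 undefined")
    return(NA_real_)
  }
  fit <- stats::lm(observed ~ predicted)
  1 - sum(stats::residuals(fit)^2) /
    sum((observed - mean(observed))^2)
}

#' Evaluate a scoring system on grouped data
#'
#' One-stop evaluation of a score from its grouped development table:
#' discrimination (AUC with confidence interval), the Youden-optimal
#' score cut-off with its classification metrics (raw and
#' prevalence-adjusted predictive values), score calibration with
#' predicted frequencies, Hosmer-Lemeshow goodness of fit, and the
#' observed-vs-predicted R-squared.
#'
#' @param table A [grouped_scores()] table.
#' @param cutoff Score cut-off; `NULL` selects the Youden-optimal one.
#' @param prevalence Prevalence for adjusted predictive values; `NULL`
#'   uses the table's own event fraction.
#' @param df_adjust Passed to [hosmer_lemeshow()].
#' @return Object of class `score_evaluation`.
#' @export
evaluate_score_table <- function(table, cutoff = NULL,
                                 prevalence = NULL, df_adjust = 2L) {
  subjects <- expand_score_table(table)
  if (is.null(cutoff))
    cutoff <- youden_cutpoint(subjects$score, subjects$outcome,
                              variable = "score",
                              direction = "ge_is_risk")$cutoff
  if (is.null(prevalence))
    prevalence <- sum(table$events) / sum(table$n)
  cal <- calibrate_score(table)
  structure(list(
    auc = grouped_auc(table),
    cutoff = cutoff,
    metrics = classification_metrics(table, cutoff, prevalence),
    prevalence = prevalence,
    calibration = cal$calibration,
    predicted = cal$predicted,
    hosmer_lemeshow = hosmer_lemeshow(table, cal$calibration,
                                      df_adjust),
    r2 = fit_goodness_r2(cal$predicted$observed_events,
                         cal$predicted$predicted_events)),
    class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("Score AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc$auc, x$auc$ci[1], x$auc$ci[2]))
  m <- x$metrics
  cat(sprintf(
    "At cut-off >= %d: sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    x$cutoff, 100 * m$sensitivity, 100 * m$specificity,
    100 * m$ppv_raw, 100 * m$npv_raw))
  cat(sprintf("Hosmer-Lemeshow chi2 %.2f on %d df, p = %.3f; R2 = %.3f\n",
              x$hosmer_lemeshow$chisq, x$hosmer_lemeshow$df,
              x$hosmer_lemeshow$p, x$r2))
  invisible(x)
}

#' Serialize a score system to JSON
#'
#' Writes the points map, maximum score, exclusive groups and (if
#' present) the calibration intercept/slope.
#'
#' @param sys A `score_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_system <- function(sys, path) {
  obj <- list(points = as.list(sys$points),
              max_score = sys$max_score,
              exclusive = sys$exclusive)
  if (!is.null(sys$calibration))
    obj$calibration <- as.list(sys$calibration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a score system from JSON
#'
#' @param path Path written by [write_score_system()].
#' @return A `score_system`.
#' @export
read_score_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    points = stats::setNames(as.integer(unlist(obj$points)),
                             names(obj$points)),
    max_score = as.integer(obj$max_score),
    exclusive = lapply(obj$exclusive, as.character),
    calibration = if (!is.null(obj$calibration))
      unlist(obj$calibration) else NULL),
    class = "score_system")
}
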