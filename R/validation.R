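# The end-to-end modelling pipeline and its bootstrap internal
# validation: per-resample cut-point re-derivation, backward selection,
# optimism-corrected AUC, and calibration curves.

#' Candidate predictors of the stenosis model
#'
#' The full design the backward elimination starts from: every binary
#' covariate, the dichotomized continuous covariates, and plaque extent
#' as a 3-category variable.
#'
#' @return A [design_spec()].
#' @export
full_design <- function() {
  design_spec(
    terms = c("cad_significant", "ckd_stage_ge3", "ahm_ge4",
              "age_ge_cut", "bmi_lt_cut", "cimt_ge_cut",
              "chol_ge_cut", "hdl_ge_cut", "tg_ge_cut",
              "hypertension", "diabetes", "smoking", "male",
              "proteinuria"),
    categorical = list(cap_extent = cap_levels()),
    outcome = "ras_significant")
}

#' Fit the full modelling pipeline on a cohort
#'
#' Reproduces the whole model-development procedure from raw records:
#' Youden-index cut-points are derived for each continuous covariate on
#' this data, the covariates are dichotomized at them, and backward Wald
#' elimination (exclusion at p >= `p_exit`) reduces the full candidate
#' design to the final model. Because the cut-points belong to the
#' fitted object, the pipeline can be re-run per bootstrap resample and
#' its predictions evaluated on any cohort.
#'
#' @param data Raw cohort data frame (see [validate_cohort()]).
#' @param p_exit Backward-elimination exclusion threshold (default
#'   0.10).
#' @param design Candidate design (default [full_design()]).
#' @param directions Per-variable risk directions for cut-point
#'   selection (default: low body-mass index is risk, high everything
#'   else).
#' @return Object of class `ras_pipeline`: `cutpoints` (list of
#'   `cutpoint` objects), `cutoffs` (named vector), `fit` (final
#'   `ras_logit`), `trace`, `log`.
#' @export
ras_pipeline <- function(data, p_exit = 0.10, design = full_design(),
                         directions = c(bmi = "lt_is_risk")) {
  cps <- select_cutpoints(data, directions = directions)
  cutoffs <- vapply(cps, `[[`, numeric(1), "cutoff")
  derived <- derive_record(data, cutoffs = cutoffs)
  bw <- backward_select(design, derived, p_exit = p_exit)
  structure(list(cutpoints = cps, cutoffs = cutoffs, fit = bw$model,
                 trace = bw$trace, log = bw$log),
            class = "ras_pipeline")
}

#' @export
predict.ras_pipeline <- function(object, newdata, ...) {
  derived <- derive_record(newdata, cutoffs = object$cutoffs)
  predict(object$fit, derived)
}

#' @export
print.ras_pipeline <- function(x, ...) {
  cat("Cut-points:",
      paste(sprintf("%s %g", names(x$cutoffs), x$cutoffs),
            collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Bootstrap internal validation with optimism correction
#'
#' For each of `m` resamples of size n drawn with replacement, the
#' entire pipeline (cut-point selection, dichotomization, backward
#' elimination, fitting) is re-run on the resample; the resample model's
#' AUC on its own resample (`C_boot`) and on the original data
#' (`C_orig`) are recorded, and the optimism estimate is
#' `mean(C_boot - C_orig)` over the resamples that converged. The
#' bias-corrected AUC is the apparent AUC minus the optimism. Resamples
#' on which the pipeline fails are skipped and counted; more than 20%
#' failures raises a validity note in the report. The Efron 0.632
#' estimate (`0.632 * mean out-of-bag AUC + 0.368 * apparent`) is
#' reported alongside for comparison.
#'
#' @param data Raw cohort data frame with the `ras_significant` outcome.
#' @param fit_fun Pipeline: a function of a cohort returning an object
#'   with a `predict(object, newdata)` method (default [ras_pipeline()]).
#' @param m Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param span Smoother span for the calibration curve of the original
#'   fit.
#' @param ... Passed to `fit_fun`.
#' @return Object of class `validation_report`: `m_requested`,
#'   `m_converged`, `apparent_auc`, `optimism`, `bias_corrected_auc`,
#'   `auc_632`, `calibration` (see [calibration_curve()]),
#'   `mean_abs_error`, `q90_abs_error`, `resamples` (per-resample log),
#'   `validity` (character, possibly empty).
#' @export
bootstrap_validate <- function(data, fit_fun = ras_pipeline, m = 1000L,
                               seed = 1L, span = 0.75, ...) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  y <- data$ras_significant
  orig <- fit_fun(data, ...)
  # a pipeline may return a plain prediction function of new data
  pred <- function(fit, nd) if (is.function(fit)) fit(nd)
                            else stats::predict(fit, nd)
  p_orig <- pred(orig, data)
  apparent <- auc_mann_whitney(p_orig, y)
  # calibration is only meaningful for probability-scale predictions
  cal <- if (all(p_orig >= 0 & p_orig <= 1))
    calibration_curve(p_orig, y, span = span)
  else list(curve = NULL, mean_abs_error = NA_real_,
            q90_abs_error = NA_real_, span = span)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- nrow(data)
  log <- data.frame(resample = seq_len(m), converged = FALSE,
                    c_boot = NA_real_, c_orig = NA_real_,
                    c_oob = NA_real_)
  for (b in seq_len(m)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    fit <- tryCatch(fit_fun(boot, ...), error = function(e) NULL)
    if (is.null(fit)) next
    ok <- tryCatch({
      log$c_boot[b] <- auc_mann_whitney(pred(fit, boot), y[idx])
      log$c_orig[b] <- auc_mann_whitney(pred(fit, data), y)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(y[oob])) == 2L)
        log$c_oob[b] <- auc_mann_whitney(
          pred(fit, data[oob, , drop = FALSE]), y[oob])
      TRUE
    }, error = function(e) FALSE)
    log$converged[b] <- isTRUE(ok)
  }
  conv <- log[log$converged, ]
  if (nrow(conv) == 0L)
    stop("no bootstrap resample converged", call. = FALSE)
  optimism <- mean(conv$c_boot - conv$c_orig)
  validity <- character()
  if (nrow(conv) < 0.8 * m)
    validity <- sprintf(
      "only %d of %d resamples converged (> 20%% failures)",
      nrow(conv), m)
  structure(list(
    m_requested = m, m_converged = nrow(conv),
    apparent_auc = apparent, optimism = optimism,
    bias_corrected_auc = apparent - optimism,
    auc_632 = 0.632 * mean(conv$c_oob, na.rm = TRUE) +
      0.368 * apparent,
    calibration = cal,
    mean_abs_error = cal$mean_abs_error,
    q90_abs_error = cal$q90_abs_error,
    resamples = log, validity = validity),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Bootstrap validation: %d/%d resamples converged\n",
    x$m_converged, x$m_requested))
  cat(sprintf(
    "Apparent AUC %.3f, optimism %.3f, bias-corrected AUC %.3f (0.632 estimate %.3f)\n",
    x$apparent_auc, x$optimism, x$bias_corrected_auc, x$auc_632))
  cat(sprintf(
    "Calibration: mean |error| %.3f, 0.9-quantile |error| %.3f\n",
    x$mean_abs_error, x$q90_abs_error))
  if (length(x$validity) > 0L) cat("NOTE:", x$validity, "\n")
  invisible(x)
}

#' Calibration curve of predicted probabilities
#'
#' Locally weighted scatterplot smoothing (tricube-weighted local linear
#' regression, no robustness iterations since the response is 0/1) of
#' the observed outcome against the predicted probability. The smoothed
#' value at each subject's prediction estimates the observed event
#' probability there; its absolute distance to the prediction summarises
#' miscalibration.
#'
#' @param predicted Predicted probabilities in \[0, 1\].
#' @param observed 0/1 outcomes of the same length.
#' @param span Smoother span, a fraction in (0, 1\] (default 0.75).
#' @return List with `curve` (data frame `predicted`,
#'   `observed_smoothed`, one row per subject, sorted by prediction),
#'   `mean_abs_error`, `q90_abs_error`, `span`.
#' @export
calibration_curve <- function(predicted, observed, span = 0.75) {
  stopifnot(length(predicted) == length(observed))
  if (!(span > 0 && span <= 1))
    stop("span must be in (0, 1]", call. = FALSE)
  if (any(predicted < 0 | predicted > 1))
    stop("predicted must be probabilities in [0, 1]", call. = FALSE)
  sm <- stats::lowess(predicted, observed, f = span, iter = 0)
  at <- stats::approx(sm$x, sm$y, xout = predicted, rule = 2,
                      ties = "ordered")$y
  at <- pmin(1, pmax(0, at))
  err <- abs(at - predicted)
  ord <- order(predicted)
  list(curve = data.frame(predicted = predicted[ord],
                          observed_smoothed = at[ord]),
       mean_abs_error = mean(err),
       q90_abs_error = unname(stats::quantile(err, 0.9)),
       span = span)
}
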