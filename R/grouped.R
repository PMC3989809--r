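# Grouped score data: per-score counts of patients with and without the
# outcome, the shape in which a published scoring system's development
# data is reported.

#' Grouped score table
#'
#' Container for per-score counts: for each integer score value, the
#' number of patients and the number with the outcome.
#'
#' @param score Strictly increasing integer score values.
#' @param n Number of patients at each score.
#' @param events Number of patients with the outcome at each score.
#' @return Data frame of class `grouped_scores` with columns `score`,
#'   `n`, `events` and attributes `N` (total patients) and `E` (total
#'   events).
#' @export
grouped_scores <- function(score, n, events) {
  stopifnot(length(score) == length(n), length(n) == length(events))
  if (any(diff(score) <= 0))
    stop("scores must be strictly increasing", call. = FALSE)
  if (any(n < 0) || any(events < 0) || any(events > n))
    stop("need 0 <= events <= n in every row", call. = FALSE)
  structure(data.frame(score = as.integer(score), n = as.integer(n),
                       events = as.integer(events)),
            N = sum(n), E = sum(events),
            class = c("grouped_scores", "data.frame"))
}

#' Read a grouped score table from CSV
#'
#' Expects columns `score`, `n`, `events`.
#'
#' @param path CSV path.
#' @return A [grouped_scores()] table.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  miss <- setdiff(c("score", "n", "events"), names(d))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(sQuote(miss), collapse = ", "),
         call. = FALSE)
  grouped_scores(d$score, d$n, d$events)
}

#' Write a grouped score table to CSV
#' @param table A [grouped_scores()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("score", "n", "events")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a grouped score table to per-subject records
#'
#' @param table A [grouped_scores()] table.
#' @return Data frame with one row per patient: columns `score` and
#'   `outcome` (0/1).
#' @export
expand_score_table <- function(table) {
  data.frame(
    score = rep(table$score, times = table$n),
    outcome = unlist(lapply(seq_len(nrow(table)), function(i)
      rep(c(1L, 0L), c(table$events[i], table$n[i] - table$events[i]))))
  )
}

#' Reference coefficients of the published stenosis model
#'
#' Log odds ratios of the final multivariable model from the development
#' cohort of the renal-artery-stenosis score (641 patients undergoing
#' coronary angiography, 60 with >=50% stenosis): significant coronary
#' artery disease, unilateral and bilateral carotid plaque, chronic
#' kidney disease stage >= 3, four or more anti-hypertensive
#' medications, carotid intima-media thickness >= 1.0 mm, age >= 67
#' years, and body-mass index < 22 kg/m2.
#'
#' @return Named numeric vector of coefficients on the derived indicator
#'   columns of [derive_record()].
#' @export
reference_coefficients <- function() {
  c(cad_significant = 1.724,
    cap_unilateral = 0.958,
    cap_bilateral = 1.584,
    ckd_stage_ge3 = 1.566,
    ahm_ge4 = 1.563,
    cimt_ge_cut = 0.849,
    age_ge_cut = 0.831,
    bmi_lt_cut = 0.872)
}

#' Reference grouped score data of the published stenosis score
#'
#' Observed frequencies of significant renal artery stenosis at each
#' total score in the score's development cohort: 641 patients, 60
#' events, scores 0 through 8 observed (the attainable maximum is 11).
#'
#' @return A [grouped_scores()] table.
#' @export
reference_score_table <- function() {
  grouped_scores(score = 0:8,
                 n = c(156, 145, 106, 77, 56, 45, 28, 21, 7),
                 events = c(1, 1, 2, 6, 8, 11, 14, 12, 5))
}
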