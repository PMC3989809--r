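# Patient-level cohort handling: canonical columns, validation, derived
# clinical variables (eGFR, CKD stage, proteinuria), and CSV I/O.

#' Canonical cohort columns
#'
#' Column names and types expected of a patient-level cohort data frame.
#' `upcr` (urine protein/creatinine ratio) is the only column that may be
#' missing per row; every other value must be present.
#'
#' @return Named character vector mapping column name to type
#'   (`"numeric"`, `"integer"`, `"flag"`, `"category"`, `"character"`).
#' @export
cohort_columns <- function() {
  c(id = "character",
    age = "numeric", male = "flag", bmi = "numeric",
    hypertension = "flag", n_ahm = "integer",
    diabetes = "flag", smoking = "flag",
    total_chol = "numeric", hdl_chol = "numeric", triglyceride = "numeric",
    creatinine = "numeric", upcr = "numeric", cimt = "numeric",
    cap_extent = "category", cad_significant = "flag",
    ras_significant = "flag")
}

#' Levels of carotid-plaque extent
#' @return `c("none", "unilateral", "bilateral")`
#' @export
cap_levels <- function() c("none", "unilateral", "bilateral")

# truthy/falsy tokens accepted for flag columns (case-insensitive)
.flag_true  <- c("1", "true", "yes", "y", "t")
.flag_false <- c("0", "false", "no", "n", "f")

.parse_flag <- function(x, column) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% .flag_true] <- 1L
  out[lx %in% .flag_false] <- 0L
  bad <- which(is.na(out) & !is.na(x) & nzchar(lx))
  if (length(bad) > 0L)
    stop(sprintf("column '%s': unparseable flag value '%s' in row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  as.integer(out)
}

#' Validate a patient-level cohort
#'
#' Checks the invariants every record must satisfy: positive age, BMI and
#' CIMT, non-negative laboratory values and medication counts, and a
#' carotid-plaque extent equal to exactly one of the three categories.
#'
#' @param cohort Data frame with the columns of [cohort_columns()].
#' @return The cohort, invisibly, with `cap_extent` as a factor over
#'   [cap_levels()]. Errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(names(cohort_columns()), names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  chk <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L)
      stop(sprintf("invalid record (row %d): %s", bad[1], what),
           call. = FALSE)
  }
  chk(!is.na(cohort$age) & cohort$age > 0, "age must be > 0")
  chk(!is.na(cohort$bmi) & cohort$bmi > 0, "bmi must be > 0")
  chk(!is.na(cohort$cimt) & cohort$cimt > 0, "cimt must be > 0")
  chk(!is.na(cohort$creatinine) & cohort$creatinine > 0,
      "creatinine must be > 0")
  chk(!is.na(cohort$n_ahm) & cohort$n_ahm >= 0 &
        cohort$n_ahm == round(cohort$n_ahm),
      "n_ahm must be a non-negative integer")
  for (v in c("total_chol", "hdl_chol", "triglyceride"))
    chk(!is.na(cohort[[v]]) & cohort[[v]] >= 0,
        paste(v, "must be >= 0"))
  chk(is.na(cohort$upcr) | cohort$upcr >= 0, "upcr must be >= 0")
  cap <- as.character(cohort$cap_extent)
  chk(!is.na(cap) & cap %in% cap_levels(),
      "cap_extent must be one of none/unilateral/bilateral")
  cohort$cap_extent <- factor(cap, levels = cap_levels())
  for (v in names(cohort_columns())[cohort_columns() == "flag"])
    chk(cohort[[v]] %in% c(0L, 1L), paste(v, "must be 0/1"))
  invisible(cohort)
}

#' Read a patient-level cohort from CSV
#'
#' Reads a header CSV with one row per patient. A schema maps file column
#' names (and category spellings) onto the canonical columns; flags accept
#' 0/1, true/false, yes/no case-insensitively.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param schema Optional schema, as returned by [cohort_schema()] or a
#'   path to a YAML file with `columns:` and optional `cap_aliases:`
#'   entries. By default columns are expected under their canonical names.
#' @return A validated cohort data frame (see [validate_cohort()]).
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema)) schema <- cohort_schema(yaml_path = schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  want <- names(cohort_columns())
  src <- schema$columns[want]
  absent <- want[!(unlist(src) %in% names(raw))]
  if (length(absent) > 0L)
    stop("missing mandatory column(s): ",
         paste(sQuote(absent), collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  types <- cohort_columns()
  for (col in want) {
    x <- raw[[src[[col]]]]
    x[!nzchar(trimws(x))] <- NA
    out[[col]] <- switch(types[[col]],
      character = as.character(x),
      numeric = .parse_numeric(x, col),
      integer = as.integer(.parse_numeric(x, col)),
      flag = .parse_flag(x, col),
      category = .parse_cap(x, schema$cap_aliases))
  }
  validate_cohort(out)
  out$cap_extent <- factor(out$cap_extent, levels = cap_levels())
  out
}

.parse_numeric <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L)
    stop(sprintf("column '%s': unparseable value '%s' in row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  out
}

.parse_cap <- function(x, aliases) {
  lx <- tolower(trimws(as.character(x)))
  for (lev in names(aliases)) lx[lx %in% tolower(aliases[[lev]])] <- lev
  bad <- which(!is.na(lx) & !(lx %in% cap_levels()))
  if (length(bad) > 0L)
    stop(sprintf(
      "column 'cap_extent': value '%s' (row %d) is not one of %s",
      x[bad[1]], bad[1], paste(cap_levels(), collapse = "/")),
      call. = FALSE)
  lx
}

#' Cohort CSV schema
#'
#' @param columns Named list mapping canonical column names to the column
#'   names used in the file; defaults to identity.
#' @param cap_aliases Named list mapping each plaque-extent level to
#'   alternative spellings accepted in the file (case-insensitive).
#' @param yaml_path Optionally, read both mappings from a YAML file with
#'   top-level keys `columns` and `cap_aliases`.
#' @return A list with elements `columns` and `cap_aliases`.
#' @export
cohort_schema <- function(columns = list(), cap_aliases = list(),
                          yaml_path = NULL) {
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    columns <- utils::modifyList(columns, as.list(y$columns %||% list()))
    cap_aliases <- utils::modifyList(cap_aliases,
                                     as.list(y$cap_aliases %||% list()))
  }
  base <- as.list(stats::setNames(names(cohort_columns()),
                                  names(cohort_columns())))
  list(columns = utils::modifyList(base, columns),
       cap_aliases = cap_aliases)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] under canonical column names: writing then
#' reading preserves every field value and the row order.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, names(cohort_columns())]
  out$cap_extent <- as.character(out$cap_extent)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Estimated glomerular filtration rate (MDRD)
#'
#' Four-variable IDMS-traceable MDRD equation,
#' \deqn{eGFR = 175 \cdot Scr^{-1.154} \cdot age^{-0.203} \cdot 0.742^{[female]}}
#' in ml/min/1.73 m2. The race factor is omitted (not collected in the
#' intended cohorts); the leading constant is overridable.
#'
#' @param creatinine Serum creatinine, mg/dl (> 0).
#' @param age Age in years (> 0).
#' @param male Logical or 0/1 flag.
#' @param constant Leading constant of the equation (default 175).
#' @return eGFR in ml/min/1.73 m2, strictly decreasing in creatinine and
#'   in age.
#' @export
compute_egfr <- function(creatinine, age, male, constant = 175) {
  if (any(is.na(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be > 0", call. = FALSE)
  if (any(is.na(age)) || any(age <= 0))
    stop("age must be > 0", call. = FALSE)
  constant * creatinine^-1.154 * age^-0.203 *
    ifelse(as.logical(male), 1, 0.742)
}

#' Default dichotomization cut-offs of the published score
#'
#' The cut-points used by the reference renal-artery-stenosis score:
#' age >= 67 years, BMI < 22 kg/m2, CIMT >= 1.0 mm, total cholesterol
#' >= 158 mg/dl, HDL cholesterol >= 47 mg/dl, triglyceride >= 119 mg/dl.
#'
#' @return Named numeric vector of cut-offs.
#' @export
reference_cutoffs <- function() {
  c(age = 67, bmi = 22, cimt = 1.0,
    total_chol = 158, hdl_chol = 47, triglyceride = 119)
}

#' Derive modelling variables from raw patient records
#'
#' Adds eGFR (MDRD), the chronic-kidney-disease stage >= 3 flag
#' (eGFR < 60, strict), the proteinuria flag (urine protein/creatinine
#' > 300 mg/g, strict), and the dichotomized risk indicators. Threshold
#' directions are fixed conventions of the score: age, CIMT, cholesterol,
#' HDL and triglyceride are risk when at or above their cut-off, BMI is
#' risk when below, and the medication-count indicator is `n_ahm >= 4`.
#' Plaque extent contributes two dummy indicators against the `none`
#' reference.
#'
#' Rows with a missing urine protein/creatinine ratio get `proteinuria =
#' 0` and are counted in the `n_missing_upcr` attribute of the result.
#'
#' @param cohort A validated cohort data frame.
#' @param cutoffs Named vector of cut-offs for the continuous variables,
#'   with names among `age`, `bmi`, `cimt`, `total_chol`, `hdl_chol`,
#'   `triglyceride` (default [reference_cutoffs()]).
#' @param ahm_threshold Medication-count threshold (default 4).
#' @param egfr_constant Passed to [compute_egfr()].
#' @return The cohort with columns `egfr`, `ckd_stage_ge3`, `proteinuria`,
#'   `ahm_ge4`, `cap_unilateral`, `cap_bilateral` and, for each supplied
#'   cut-off, an indicator column (`age_ge_cut`, `bmi_lt_cut`,
#'   `cimt_ge_cut`, `chol_ge_cut`, `hdl_ge_cut`, `tg_ge_cut`).
#' @export
derive_record <- function(cohort, cutoffs = reference_cutoffs(),
                          ahm_threshold = 4, egfr_constant = 175) {
  validate_cohort(cohort)
  d <- cohort
  d$egfr <- compute_egfr(d$creatinine, d$age, d$male,
                         constant = egfr_constant)
  d$ckd_stage_ge3 <- as.integer(d$egfr < 60)
  d$proteinuria <- as.integer(!is.na(d$upcr) & d$upcr > 300)
  d$ahm_ge4 <- as.integer(d$n_ahm >= ahm_threshold)
  cap <- as.character(d$cap_extent)
  d$cap_unilateral <- as.integer(cap == "unilateral")
  d$cap_bilateral <- as.integer(cap == "bilateral")
  ind <- c(age = "age_ge_cut", bmi = "bmi_lt_cut", cimt = "cimt_ge_cut",
           total_chol = "chol_ge_cut", hdl_chol = "hdl_ge_cut",
           triglyceride = "tg_ge_cut")
  for (v in names(cutoffs)) {
    if (!(v %in% names(ind)))
      stop("no dichotomization rule for variable ", sQuote(v),
           call. = FALSE)
    d[[ind[[v]]]] <- if (v == "bmi") as.integer(d[[v]] < cutoffs[[v]])
                     else as.integer(d[[v]] >= cutoffs[[v]])
  }
  attr(d, "n_missing_upcr") <- sum(is.na(cohort$upcr))
  attr(d, "cutoffs") <- cutoffs
  d
}
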