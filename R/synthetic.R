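# Synthetic cohort generation: covariate marginals matched to the
# development setting, outcome drawn from an indicator-based logistic
# model with the intercept solved to hit a target prevalence.

#' Default covariate marginals
#'
#' One entry per raw covariate, each a list with a `dist` tag and its
#' parameters. Continuous lab values with skewed summaries (HDL,
#' triglyceride, creatinine, urine protein/creatinine, CIMT) are
#' log-normal, matched to the printed median/IQR or mean/SD; roughly
#' symmetric ones (age, BMI, total cholesterol) are truncated normal.
#' Plaque extent is a 3-category multinomial with overall prevalence
#' 42%, split evenly between unilateral and bilateral involvement (the
#' split is configurable; only the overall prevalence is pinned down).
#'
#' @return Named list of marginal specifications, in sampling order.
#' @export
default_marginals <- function() {
  list(
    age = list(dist = "truncnorm", mean = 61.2, sd = 12.5,
               lower = 18, upper = 100),
    male = list(dist = "bernoulli", p = 0.49),
    bmi = list(dist = "truncnorm", mean = 25.4, sd = 3.5,
               lower = 13, upper = 50),
    hypertension = list(dist = "bernoulli", p = 0.61),
    n_ahm = list(dist = "poisson", lambda = 1.6),
    diabetes = list(dist = "bernoulli", p = 0.278),
    smoking = list(dist = "bernoulli", p = 0.27),
    total_chol = list(dist = "truncnorm", mean = 175.8, sd = 41.1,
                      lower = 50, upper = 400),
    hdl_chol = list(dist = "lognormal", meanlog = log(46),
                    sdlog = 0.255),
    triglyceride = list(dist = "lognormal", meanlog = log(121),
                        sdlog = 0.497),
    creatinine = list(dist = "lognormal", meanlog = -0.2225,
                      sdlog = 0.4078),
    upcr = list(dist = "lognormal", meanlog = log(100), sdlog = 1.026),
    cimt = list(dist = "lognormal", meanlog = log(0.85), sdlog = 0.229),
    cap_extent = list(dist = "categorical", levels = cap_levels(),
                      p = c(0.58, 0.21, 0.21)),
    cad_significant = list(dist = "bernoulli", p = 0.26)
  )
}

#' Generator configuration
#'
#' @param n Cohort size (default 641).
#' @param target_prevalence Outcome prevalence the intercept is solved
#'   for (default 0.094).
#' @param coefficients Named log-odds-ratio vector on the derived
#'   indicator columns; defaults to [reference_coefficients()].
#' @param marginals Covariate marginals (see [default_marginals()]).
#' @param cutoffs Cut-offs used to form the outcome-model indicators
#'   (default [reference_cutoffs()]).
#' @param copula_corr Optional correlation matrix (Gaussian copula) over
#'   the covariates in marginal order, for collinearity stress tests;
#'   `NULL` draws covariates independently.
#' @param seed Integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n = 641, target_prevalence = 0.094,
                             coefficients = reference_coefficients(),
                             marginals = default_marginals(),
                             cutoffs = reference_cutoffs(),
                             copula_corr = NULL, seed = 1L) {
  stopifnot(n >= 1, target_prevalence > 0, target_prevalence < 1)
  if (!is.null(copula_corr))
    stopifnot(is.matrix(copula_corr),
              nrow(copula_corr) == length(marginals),
              isSymmetric(copula_corr))
  structure(list(n = n, target_prevalence = target_prevalence,
                 coefficients = coefficients, marginals = marginals,
                 cutoffs = cutoffs, copula_corr = copula_corr,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# quantile function of one marginal, applied to uniforms
.marginal_quantile <- function(m, u) {
  switch(m$dist,
    truncnorm = {
      plo <- stats::pnorm(m$lower, m$mean, m$sd)
      phi <- stats::pnorm(m$upper, m$mean, m$sd)
      stats::qnorm(plo + u * (phi - plo), m$mean, m$sd)
    },
    lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
    bernoulli = as.integer(u < m$p),
    poisson = stats::qpois(u, m$lambda),
    categorical = m$levels[1L + findInterval(u, cumsum(m$p) / sum(m$p))],
    stop("unknown marginal distribution: ", m$dist, call. = FALSE))
}

# Draw n covariate vectors; independent by default, or through a
# Gaussian copula when a correlation matrix is supplied.
.sample_covariates <- function(n, marginals, copula_corr = NULL) {
  k <- length(marginals)
  if (is.null(copula_corr)) {
    U <- matrix(stats::runif(n * k), n, k)
  } else {
    L <- chol(copula_corr)
    Z <- matrix(stats::rnorm(n * k), n, k) %*% L
    U <- stats::pnorm(Z)
  }
  out <- data.frame(id = sprintf("S%05d", seq_len(n)))
  for (j in seq_len(k))
    out[[names(marginals)[j]]] <- .marginal_quantile(marginals[[j]],
                                                     U[, j])
  out$cap_extent <- factor(out$cap_extent, levels = cap_levels())
  out
}

# indicator matrix of the outcome model for a raw covariate draw
.outcome_indicators <- function(raw, cutoffs) {
  raw$ras_significant <- 0L  # placeholder for validation only
  d <- derive_record(raw, cutoffs = cutoffs)
  d
}

#' Solve the outcome-model intercept for a target prevalence
#'
#' The marginal outcome probability `E[1 / (1 + exp(-(a + b'x)))]` is
#' strictly increasing in the intercept `a`, so the value hitting a
#' target prevalence is found by monotone bisection over a Monte-Carlo
#' sample of covariate vectors.
#'
#' @param coefficients Named vector of log odds ratios on indicator
#'   columns.
#' @param covariate_sampler Function of one argument `n` returning a
#'   data frame containing those columns.
#' @param target_prevalence Desired mean outcome probability.
#' @param n_mc Monte-Carlo sample size (default 200000).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param tol Bisection tolerance on the achieved mean probability.
#' @return The intercept, a single number in \[-20, 20\].
#' @export
solve_intercept <- function(coefficients, covariate_sampler,
                            target_prevalence, n_mc = 200000L,
                            seed = 1L, tol = 5e-4) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  X <- covariate_sampler(n_mc)
  lp <- .linear_predictor(coefficients, X)
  f <- function(a) mean(stats::plogis(a + lp)) - target_prevalence
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence not attainable with intercept in [-20, 20]",
         call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid
}

.linear_predictor <- function(coefficients, data) {
  lp <- numeric(nrow(data))
  for (nm in names(coefficients)) {
    if (is.null(data[[nm]]))
      stop("coefficient refers to unknown indicator: ", sQuote(nm),
           call. = FALSE)
    lp <- lp + coefficients[[nm]] * as.numeric(data[[nm]])
  }
  lp
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort
#'
#' Draws raw covariates from the configured marginals, forms the
#' outcome-model indicators at the configured cut-offs, solves the
#' intercept for the target prevalence, and draws the stenosis outcome
#' from the logistic model. Two runs with the same configuration are
#' identical.
#'
#' @param cfg A [generator_config()].
#' @return A validated cohort data frame of raw patient records, with
#'   attributes `intercept` (the solved value) and `config`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  sampler <- function(n) {
    raw <- .sample_covariates(n, cfg$marginals, cfg$copula_corr)
    .outcome_indicators(raw, cfg$cutoffs)
  }
  alpha <- solve_intercept(cfg$coefficients, sampler,
                           cfg$target_prevalence,
                           seed = cfg$seed + 10000L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  raw <- .sample_covariates(cfg$n, cfg$marginals, cfg$copula_corr)
  ind <- .outcome_indicators(raw, cfg$cutoffs)
  lp <- alpha + .linear_predictor(cfg$coefficients, ind)
  raw$ras_significant <- stats::rbinom(cfg$n, 1L, stats::plogis(lp))
  cohort <- validate_cohort(raw)
  attr(cohort, "intercept") <- alpha
  attr(cohort, "config") <- cfg
  cohort
}
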