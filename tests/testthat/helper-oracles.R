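# Independent brute-force oracles used to check the fast implementations.

# AUC as an explicit double loop over all case-control pairs
oracle_auc_pairs <- function(values, outcome) {
  cases <- values[outcome == 1]
  controls <- values[outcome == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# Exhaustive Youden search over every observed threshold in a fixed
# direction ("risk when value >= t", or strictly "< t"); ties keep the
# smallest cut-off.
oracle_youden <- function(values, outcome, dir = "ge_is_risk") {
  best <- list(j = -Inf, cutoff = NA)
  for (t in sort(unique(values))) {
    pos <- if (dir == "ge_is_risk") values >= t else values < t
    sens <- sum(pos & outcome == 1) / sum(outcome == 1)
    spec <- sum(!pos & outcome == 0) / sum(outcome == 0)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, cutoff = t)
  }
  best
}

# Maximized Bernoulli log-likelihood by generic numeric optimizers
# (quasi-Newton from several starts, then nlm), independent of the IRLS
# path. The solution is also returned so fixtures can screen out
# quasi-separated draws, where the supremum is a plateau at infinity.
oracle_loglik_max <- function(X, y) {
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    -drop(crossprod(X, y - stats::plogis(eta)))
  }
  best <- -Inf; best_b <- numeric(ncol(X))
  for (start in list(numeric(ncol(X)),
                     rep(0.3, ncol(X)), rep(-0.3, ncol(X)))) {
    fit <- stats::optim(start, negll, grad, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-16))
    if (-fit$value > best) { best <- -fit$value; best_b <- fit$par }
  }
  nll <- function(b) {
    r <- negll(b); attr(r, "gradient") <- grad(b); r
  }
  nf <- suppressWarnings(stats::nlm(nll, best_b, gradtol = 1e-12,
                                    iterlim = 1000))
  structure(max(best, -nf$minimum),
            coef = if (-nf$minimum >= best) nf$estimate else best_b)
}

# Random toy logistic data set with a guaranteed mix of outcomes and a
# finite interior maximum (quasi-separated draws are regenerated)
toy_logit_data <- function(n, k) {
  repeat {
    X <- cbind(1, matrix(rbinom(n * k, 1, 0.5), n, k))
    eta <- drop(X %*% c(-0.5, stats::runif(k, -1, 1)))
    y <- rbinom(n, 1, stats::plogis(eta))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    sol <- oracle_loglik_max(X, y)
    if (max(abs(attr(sol, "coef"))) < 8)
      return(list(X = X, y = y, loglik = as.numeric(sol)))
  }
}

# Small raw cohort with hand-set values, valid under validate_cohort()
make_cohort <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("P%02d", seq_len(n)),
    age = round(runif(n, 40, 85), 1),
    male = rbinom(n, 1, 0.5),
    bmi = round(runif(n, 18, 32), 1),
    hypertension = rbinom(n, 1, 0.6),
    n_ahm = rpois(n, 1.5),
    diabetes = rbinom(n, 1, 0.3),
    smoking = rbinom(n, 1, 0.3),
    total_chol = round(runif(n, 120, 240), 1),
    hdl_chol = round(runif(n, 30, 70), 1),
    triglyceride = round(runif(n, 60, 300), 1),
    creatinine = round(runif(n, 0.5, 2.0), 2),
    upcr = round(runif(n, 20, 500), 1),
    cimt = round(runif(n, 0.6, 1.4), 2),
    cap_extent = sample(cap_levels(), n, replace = TRUE),
    cad_significant = rbinom(n, 1, 0.3),
    ras_significant = rbinom(n, 1, 0.5)
  )
}

# Random small grouped score table with both classes present
random_score_table <- function(max_rows = 6) {
  k <- sample(2:max_rows, 1)
  n <- sample(1:30, k, replace = TRUE)
  ev <- vapply(n, function(m) sample(0:m, 1), integer(1))
  if (sum(ev) == 0) ev[sample(k, 1)] <- 1L
  if (sum(ev) == sum(n)) { i <- which(n > 0)[1]; ev[i] <- ev[i] - 1L }
  grouped_scores(sort(sample(0:20, k)), n, ev)
}
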