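# Maximum-likelihood logistic regression by iteratively reweighted least
# squares, block-wise Wald inference, backward elimination, and variance
# inflation factors.

#' Model design specification
#'
#' Describes the terms of a logistic model on a derived cohort: plain
#' numeric/indicator columns, and categorical variables expanded to dummy
#' indicators against their first (reference) level. A categorical
#' variable forms one multi-column block that is tested and eliminated as
#' a whole.
#'
#' @param terms Character vector of numeric or 0/1 indicator columns.
#' @param categorical Named list: variable name -> character vector of
#'   levels, the first being the reference (e.g. `list(cap_extent =
#'   c("none", "unilateral", "bilateral"))`).
#' @param outcome Name of the 0/1 outcome column.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(terms = character(), categorical = list(),
                        outcome = "ras_significant") {
  stopifnot(!anyDuplicated(terms), is.list(categorical))
  structure(list(terms = terms, categorical = categorical,
                 outcome = outcome),
            class = "design_spec")
}

# Build the model matrix (with intercept) and the block structure:
# a named list mapping each term/categorical variable to its columns.
.build_design <- function(design, data) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  blocks <- list()
  for (v in design$terms) {
    if (is.null(data[[v]]))
      stop("design column not found: ", sQuote(v), call. = FALSE)
    cols[[v]] <- as.numeric(data[[v]])
    blocks[[v]] <- v
  }
  for (v in names(design$categorical)) {
    levs <- design$categorical[[v]]
    x <- as.character(data[[v]])
    bad <- setdiff(unique(x), levs)
    if (length(bad) > 0L)
      stop("unknown level(s) of ", sQuote(v), ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    nm <- paste(v, levs[-1], sep = ".")
    for (i in seq_along(nm)) cols[[nm[i]]] <- as.numeric(x == levs[-1][i])
    blocks[[v]] <- nm
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, blocks = blocks)
}

#' Fit a logistic regression model
#'
#' Maximizes the Bernoulli log-likelihood by iteratively reweighted least
#' squares. Convergence is declared when the maximum absolute score
#' (gradient) component falls below `tol_score` or the relative change in
#' log-likelihood falls below `tol_ll`; at a converged solution the score
#' equations force the fitted probabilities to sum to the event count.
#' Complete or quasi-complete separation is detected as a coefficient
#' diverging past `beta_max` while its score component does not vanish,
#' and reported as an error naming the offending term.
#'
#' @param design A [design_spec()].
#' @param data Derived cohort data frame containing every design column
#'   and the outcome.
#' @param max_iter,tol_score,tol_ll,beta_max IRLS controls.
#' @return Object of class `ras_logit` with elements `coefficients`,
#'   `vcov`, `blocks`, `wald` (per-block chi-square, df, p), `or_ci`
#'   (odds ratios with 90% and 95% Wald intervals), `log_lik`,
#'   `fitted`, `apparent_auc`, `converged`, `n_used`, `design`.
#' @export
fit_logistic <- function(design, data, max_iter = 50L,
                         tol_score = 1e-8, tol_ll = 1e-10,
                         beta_max = 15) {
  y <- as.numeric(data[[design$outcome]])
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("outcome must be 0/1 with no missing values", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event", call. = FALSE)
  bd <- .build_design(design, data)
  X <- bd$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design: rank-deficient in ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    ll <- sum(y * eta - log1p(exp(eta)))
    big <- which(abs(beta) > beta_max)
    big <- big[big > 1L]
    if (length(big) > 0L && any(abs(score[big]) > 1e-4)) {
      term <- .owning_block(bd$blocks, colnames(X)[big[1]])
      stop(structure(class = c("rascore_separation", "error",
                               "condition"),
                     list(message = paste0(
                            "separation detected for term '", term, "'"),
                          call = NULL, term = term)))
    }
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) <=
           tol_ll * (abs(ll_old) + tol_ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  model <- structure(list(
    coefficients = beta, vcov = vcov, blocks = bd$blocks,
    log_lik = sum(y * eta - log1p(exp(eta))),
    fitted = mu, linear_predictor = eta,
    apparent_auc = auc_mann_whitney(mu, y),
    converged = converged, n_used = length(y), n_events = sum(y),
    design = design), class = "ras_logit")
  model$wald <- .wald_all(model)
  model$or_ci <- .or_ci(model)
  model
}

.owning_block <- function(blocks, column) {
  for (b in names(blocks)) if (column %in% blocks[[b]]) return(b)
  column
}

.wald_all <- function(model) {
  do.call(rbind, lapply(names(model$blocks), function(b) {
    w <- wald_test(model, b)
    data.frame(term = b, chisq = w$chisq, df = w$df, p = w$p)
  }))
}

.or_ci <- function(model) {
  idx <- unlist(model$blocks)
  b <- model$coefficients[idx]
  se <- sqrt(diag(model$vcov))[idx]
  z90 <- stats::qnorm(0.95); z95 <- stats::qnorm(0.975)
  data.frame(term = idx, beta = b, se = se, or = exp(b),
             lo90 = exp(b - z90 * se), hi90 = exp(b + z90 * se),
             lo95 = exp(b - z95 * se), hi95 = exp(b + z95 * se),
             row.names = NULL)
}

#' Wald test for a model term
#'
#' Single-column terms use the 1-df chi-square `(beta/se)^2`; categorical
#' blocks use the multi-df quadratic form `b' V^{-1} b` over the block's
#' coefficients. P-values come from the upper chi-square tail with
#' matching degrees of freedom.
#'
#' @param model A fitted `ras_logit`.
#' @param term Block name (a design term or categorical variable).
#' @return List with `chisq`, `df`, `p`.
#' @export
wald_test <- function(model, term) {
  if (!(term %in% names(model$blocks)))
    stop("term not in model: ", sQuote(term), call. = FALSE)
  idx <- model$blocks[[term]]
  b <- model$coefficients[idx]
  V <- model$vcov[idx, idx, drop = FALSE]
  chisq <- drop(t(b) %*% solve(V, b))
  df <- length(idx)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Backward elimination by Wald statistics
#'
#' Starting from the full design, repeatedly refits the model and removes
#' the term with the largest Wald p-value among those at or above
#' `p_exit`, until all remaining terms fall below it. Categorical blocks
#' enter and leave as a whole. Terms that are constant in the data are
#' dropped up front, and a term causing separation mid-path is removed
#' with a logged warning, so that bootstrap resamples with degenerate
#' draws still yield a model.
#'
#' @param design A [design_spec()].
#' @param data Derived cohort data frame.
#' @param p_exit Exclusion threshold; a term is removed when its Wald
#'   p-value is `>= p_exit` (default 0.10).
#' @param ... Passed to [fit_logistic()].
#' @return List of class `backward_fit`: `model` (the final `ras_logit`),
#'   `trace` (data frame of removals with their p-values), and `log`
#'   (character notes on constant or separating terms).
#' @export
backward_select <- function(design, data, p_exit = 0.10, ...) {
  stopifnot(p_exit > 0, p_exit <= 1)
  log <- character()
  # drop terms with no variation in this sample
  keep_t <- design$terms[vapply(design$terms, function(v)
    length(unique(data[[v]])) > 1L, logical(1))]
  dropped <- setdiff(design$terms, keep_t)
  cat_keep <- design$categorical
  for (v in names(design$categorical)) {
    obs <- unique(as.character(data[[v]]))
    if (length(obs) < 2L) {
      cat_keep[[v]] <- NULL
      dropped <- c(dropped, v)
    } else if (!all(design$categorical[[v]] %in% c(obs, design$categorical[[v]][1]))) {
      # unobserved non-reference level: collapse to observed levels
      levs <- design$categorical[[v]]
      cat_keep[[v]] <- c(levs[1], intersect(levs[-1], obs))
      log <- c(log, paste0("collapsed unobserved level(s) of '", v, "'"))
    }
  }
  if (length(dropped) > 0L)
    log <- c(log, paste0("dropped constant term(s): ",
                         paste(dropped, collapse = ", ")))
  cur <- design_spec(keep_t, cat_keep, design$outcome)
  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric())
  step <- 0L
  repeat {
    model <- tryCatch(fit_logistic(cur, data, ...),
                      rascore_separation = function(e) e)
    if (inherits(model, "rascore_separation")) {
      term <- model$term
      log <- c(log, paste0("removed separating term '", term, "'"))
      cur <- .drop_term(cur, term)
      if (length(cur$terms) + length(cur$categorical) == 0L)
        stop("all terms removed by separation handling", call. = FALSE)
      next
    }
    w <- model$wald
    if (is.null(w) || nrow(w) == 0L) break  # intercept-only endpoint
    worst <- which.max(w$p)
    if (w$p[worst] < p_exit) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = w$term[worst],
                                     p = w$p[worst]))
    cur <- .drop_term(cur, w$term[worst])
  }
  structure(list(model = if (inherits(model, "ras_logit")) model else NULL,
                 trace = trace, log = log, design = cur),
            class = "backward_fit")
}

.drop_term <- function(design, term) {
  design$terms <- setdiff(design$terms, term)
  design$categorical[[term]] <- NULL
  design
}

#' Variance inflation factors of a design
#'
#' For each non-intercept column of the design matrix, `VIF = 1 / (1 -
#' R^2)` where `R^2` comes from the least-squares regression of that
#' column on all the others (with intercept). An exactly collinear
#' column is reported as `Inf`.
#'
#' @inheritParams fit_logistic
#' @return Named numeric vector of VIFs, all `>= 1`.
#' @export
vif <- function(design, data) {
  X <- .build_design(design, data)$X
  Z <- X[, -1, drop = FALSE]
  vapply(seq_len(ncol(Z)), function(k) {
    yk <- Z[, k]
    Xk <- cbind(1, Z[, -k, drop = FALSE])
    fit <- stats::lm.fit(Xk, yk)
    sst <- sum((yk - mean(yk))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(Z))
}

#' @export
print.ras_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic model: %d records, %d events, log-likelihood %.3f, apparent AUC %.3f\n",
    x$n_used, x$n_events, x$log_lik, x$apparent_auc))
  tab <- merge(x$or_ci, x$wald, by = "term", all.x = TRUE, sort = FALSE)
  print(tab[, c("term", "beta", "or", "lo95", "hi95", "p")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Predict probabilities from a fitted logistic model
#'
#' @param object A `ras_logit`.
#' @param newdata Derived cohort data frame with the design's columns.
#' @param ... Unused.
#' @return Vector of predicted outcome probabilities.
#' @export
predict.ras_logit <- function(object, newdata, ...) {
  X <- .build_design(object$design, newdata)$X
  drop(stats::plogis(X %*% object$coefficients[colnames(X)]))
}
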