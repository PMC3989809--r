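test_that("points follow the coefficient-ratio rounding rule", {
  sys <- derive_scores(reference_coefficients())
  expect_equal(sys$points,
               c(cad_significant = 2L, cap_unilateral = 1L,
                 cap_bilateral = 2L, ckd_stage_ge3 = 2L, ahm_ge4 = 2L,
                 cimt_ge_cut = 1L, age_ge_cut = 1L, bmi_lt_cut = 1L))
  expect_equal(sys$max_score, 11L)
  # equal coefficients all score 1
  expect_equal(unname(derive_scores(c(a = 0.7, b = 0.7, c = 0.7))$points),
               rep(1L, 3))
  # ratio 1.26/0.5 = 2.52 rounds to 3
  expect_equal(unname(derive_scores(c(a = 0.5, b = 1.26))$points),
               c(1L, 3L))
  # half-away-from-zero at an exact .5 ratio
  expect_equal(unname(derive_scores(c(a = 1, b = 1.5))$points),
               c(1L, 2L))
})

test_that("point derivation is scale-invariant", {
  set.seed(51)
  for (i in 1:20) {
    beta <- setNames(runif(5, 0.2, 3), letters[1:5])
    s1 <- derive_scores(beta)
    s2 <- derive_scores(beta * runif(1, 0.01, 50))
    expect_identical(s1$points, s2$points)
    expect_identical(s1$max_score, s2$max_score)
  }
})

test_that("non-positive coefficients are refused with recoding advice", {
  expect_error(derive_scores(c(a = 1.2, b = -0.3)), "recode.*'b'")
})

test_that("total scores add the points of present indicators", {
  sys <- derive_scores(reference_coefficients())
  rec <- as.data.frame(as.list(setNames(rep(0L, 8),
                                        names(sys$points))))
  expect_equal(total_score(rec, sys), 0L)
  # everything present at the maximal (bilateral) plaque level
  full <- rec
  full[] <- 1L
  full$cap_unilateral <- 0L
  expect_equal(total_score(full, sys), 11L)
  # coronary disease + bilateral plaque only
  two <- rec
  two$cad_significant <- 1L; two$cap_bilateral <- 1L
  expect_equal(total_score(two, sys), 4L)
  expect_error(total_score(rec[, -1], sys), "cad_significant")
})

test_that("adding a risk indicator never lowers the total", {
  sys <- derive_scores(reference_coefficients())
  set.seed(52)
  for (i in 1:20) {
    rec <- as.data.frame(as.list(setNames(rbinom(8, 1, 0.4),
                                          names(sys$points))))
    if (rec$cap_unilateral + rec$cap_bilateral == 2)
      rec$cap_unilateral <- 0L
    base <- total_score(rec, sys)
    off <- names(sys$points)[unlist(rec) == 0]
    # adding an absent indicator (respecting plaque-level exclusivity)
    # raises the total by exactly its points
    for (v in off) {
      if (v == "cap_unilateral" && rec$cap_bilateral == 1) next
      if (v == "cap_bilateral" && rec$cap_unilateral == 1) next
      rec2 <- rec; rec2[[v]] <- 1L
      expect_equal(total_score(rec2, sys), base + sys$points[[v]])
    }
    expect_lte(base, sys$max_score)
  }
})

test_that("score calibration recovers known grouped-logistic parameters", {
  set.seed(53)
  a <- -4.2; b <- 0.75
  score <- 0:9
  n <- rep(2000, 10)
  ev <- rbinom(10, n, plogis(a + b * score))
  cal <- calibrate_score(grouped_scores(score, n, ev))
  expect_equal(unname(cal$calibration["intercept"]), a, tolerance = 0.05)
  expect_equal(unname(cal$calibration["slope"]), b, tolerance = 0.05)
  expect_error(calibrate_score(grouped_scores(3, 50, 10)),
               "degenerate")
})

test_that("predicted frequencies from the reference table match print", {
  cal <- calibrate_score(reference_score_table())
  at5 <- cal$predicted$predicted_events[cal$predicted$score == 5]
  expect_equal(at5, 11.32, tolerance = 0.05)
  # ML fit forces predicted events to sum to the observed total
  expect_equal(sum(cal$predicted$predicted_events), 60, tolerance = 0.01)
  expect_equal(score_probability(cal, 5) * 45, at5)
})

test_that("grouped AUC equals the expanded per-subject computation", {
  set.seed(54)
  for (i in 1:50) {
    tab <- random_score_table()
    s <- expand_score_table(tab)
    expect_equal(grouped_auc(tab)$auc,
                 auc_mann_whitney(s$score, s$outcome),
                 tolerance = 1e-12)
  }
  # all events above all non-events
  top <- grouped_scores(0:1, c(30, 10), c(0, 10))
  expect_equal(grouped_auc(top)$auc, 1.0)
  expect_error(grouped_auc(grouped_scores(0:1, c(5, 5), c(0, 0))),
               "degenerate")
})

test_that("grouped AUC variance matches the subject-level DeLong value", {
  skip_if_not_installed("pROC")
  tab <- reference_score_table()
  s <- expand_score_table(tab)
  r <- pROC::roc(s$outcome, s$score, quiet = TRUE)
  ci <- pROC::ci.auc(r, method = "delong")
  g <- grouped_auc(tab)
  se_proc <- (ci[3] - ci[1]) / (2 * qnorm(0.975))
  expect_equal(g$se, se_proc, tolerance = 1e-6)
})

test_that("classification metrics match confusion-matrix enumeration", {
  tab <- grouped_scores(0:3, c(10, 20, 15, 5), c(1, 3, 6, 4))
  s <- expand_score_table(tab)
  for (cut in 0:4) {
    m <- classification_metrics(tab, cut)
    pos <- s$score >= cut
    expect_equal(m$sensitivity, sum(pos & s$outcome == 1) /
                   sum(s$outcome == 1))
    expect_equal(m$specificity, sum(!pos & s$outcome == 0) /
                   sum(s$outcome == 0))
    if (any(pos))
      expect_equal(m$ppv_raw, mean(s$outcome[pos]))
    if (any(!pos))
      expect_equal(m$npv_raw, 1 - mean(s$outcome[!pos]))
  }
  m0 <- classification_metrics(tab, 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
})

test_that("prevalence-matched adjustment reproduces raw predictive values", {
  tab <- reference_score_table()
  prev <- sum(tab$events) / sum(tab$n)
  m <- classification_metrics(tab, 4, prevalence = prev)
  expect_equal(m$ppv_adjusted, m$ppv_raw, tolerance = 1e-4)
  expect_equal(m$npv_adjusted, m$npv_raw, tolerance = 1e-4)
})

test_that("Hosmer-Lemeshow statistic matches hand computation", {
  # groups where observed equals expected exactly: chi2 = 0, p = 1
  tab <- grouped_scores(0:3, c(10, 10, 10, 10), c(5, 5, 5, 5))
  hl0 <- hosmer_lemeshow(tab, c(0, 0))  # p = 1/2 everywhere -> E = 5
  expect_equal(hl0$chisq, 0)
  expect_equal(hl0$p, 1)
  # 4-group toy, term-by-term arithmetic
  tab2 <- grouped_scores(0:3, c(20, 20, 20, 20), c(2, 5, 9, 15))
  cal <- c(-2, 1)
  p <- plogis(-2 + 1 * (0:3))
  e <- 20 * p
  o <- c(2, 5, 9, 15)
  chi_hand <- sum((o - e)^2 / e + ((20 - o) - (20 - e))^2 / (20 - e))
  hl <- hosmer_lemeshow(tab2, cal)
  expect_equal(hl$chisq, chi_hand, tolerance = 1e-12)
  expect_equal(hl$df, 2)
  expect_equal(hl$p, pchisq(chi_hand, 2, lower.tail = FALSE))
})

test_that("reference-table goodness of fit brackets the published p", {
  cal <- calibrate_score(reference_score_table())
  hl <- hosmer_lemeshow(reference_score_table(), cal$calibration)
  expect_gt(hl$p, 0.8)
  expect_lt(hl$p, 0.95)
})

test_that("DeLong comparison is null for self and monotone transforms", {
  set.seed(55)
  x <- rnorm(80); y <- c(0, 1, rbinom(78, 1, 0.4))
  self <- delong_compare(x, x, y)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
  mono <- delong_compare(x, exp(2 * x) + 5, y)
  expect_equal(mono$delta, 0)  # rank invariance, exact
  expect_equal(mono$p, 1)
  expect_error(delong_compare(x, x, rep(1, 80)), "single class")
})

test_that("DeLong test holds its size on independent noise predictors", {
  set.seed(56)
  rejections <- replicate(200, {
    y <- rbinom(200, 1, 0.3)
    if (length(unique(y)) < 2) return(NA)
    d <- delong_compare(rnorm(200), rnorm(200), y)
    d$p < 0.05
  })
  rate <- mean(rejections, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("R2 of observed on predicted frequencies is OLS", {
  expect_equal(fit_goodness_r2(c(1, 4, 9), c(1, 4, 9)), 1.0)
  obs <- c(2, 5, 9, 14); pred <- c(1.5, 6, 8.5, 15)
  fit <- lm(obs ~ pred)
  r2_hand <- 1 - sum(residuals(fit)^2) / sum((obs - mean(obs))^2)
  expect_equal(fit_goodness_r2(obs, pred), r2_hand)
  expect_warning(r <- fit_goodness_r2(c(1, 2, 3), c(2, 2, 2)),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("score systems round-trip through JSON", {
  sys <- derive_scores(reference_coefficients())
  sys <- calibrate_score(reference_score_table(), sys)
  path <- withr::local_tempfile(fileext = ".json")
  write_score_system(sys, path)
  back <- read_score_system(path)
  expect_identical(back$points, sys$points)
  expect_identical(back$max_score, sys$max_score)
  expect_equal(back$calibration, sys$calibration, tolerance = 1e-12)
})

test_that("full grouped evaluation reproduces the development numbers", {
  ev <- evaluate_score_table(reference_score_table(),
                             prevalence = 0.094)
  expect_equal(ev$cutoff, 4)  # Youden-optimal score threshold
  expect_equal(ev$auc$auc, 0.896, tolerance = 5e-4)
  expect_equal(ev$metrics$sensitivity, 0.833, tolerance = 5e-4)
  expect_equal(ev$metrics$specificity, 0.816, tolerance = 5e-4)
  expect_gte(ev$r2, 0.95)
})
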