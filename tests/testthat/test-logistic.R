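test_that("single binary predictor reproduces the 2x2 closed form", {
  # cells: x=1 (a events, b non), x=0 (c events, d non)
  a <- 12; b <- 7; c <- 5; d <- 20
  dat <- data.frame(
    x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
  f <- fit_logistic(design_spec("x", outcome = "y"), dat)
  expect_equal(unname(f$coefficients["x"]), log(a * d / (b * c)),
               tolerance = 1e-8)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(c / d),
               tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("converged fits satisfy the score equations", {
  set.seed(21)
  for (i in 1:20) {
    td <- toy_logit_data(n = sample(30:80, 1), k = sample(1:3, 1))
    dat <- as.data.frame(td$X[, -1, drop = FALSE])
    names(dat) <- paste0("x", seq_len(ncol(dat)))
    dat$y <- td$y
    f <- fit_logistic(design_spec(names(dat)[-ncol(dat)], outcome = "y"),
                      dat)
    # X'(y - p) = 0, hence fitted probabilities sum to the event count
    expect_lt(abs(sum(f$fitted) - sum(td$y)), 1e-6)
    resid <- drop(crossprod(td$X, td$y - f$fitted))
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("IRLS log-likelihood matches a numeric-optimizer oracle", {
  set.seed(22)
  for (i in 1:30) {
    td <- toy_logit_data(n = 25, k = 2)
    dat <- data.frame(x1 = td$X[, 2], x2 = td$X[, 3], y = td$y)
    f <- fit_logistic(design_spec(c("x1", "x2"), outcome = "y"), dat)
    expect_equal(f$log_lik, td$loglik, tolerance = 1e-6)
  }
})

test_that("IRLS agrees with glm on a moderate fit", {
  co <- generate_cohort(generator_config(n = 2000, seed = 31))
  d <- derive_record(co)
  des <- design_spec(c("cad_significant", "ckd_stage_ge3", "ahm_ge4",
                       "cimt_ge_cut"),
                     categorical = list(cap_extent = cap_levels()))
  f <- fit_logistic(des, d)
  g <- glm(ras_significant ~ cad_significant + ckd_stage_ge3 + ahm_ge4 +
             cimt_ge_cut + cap_extent, binomial, d)
  expect_equal(unname(f$coefficients["cad_significant"]),
               unname(coef(g)["cad_significant"]), tolerance = 1e-6)
  expect_equal(unname(f$coefficients["cap_extent.bilateral"]),
               unname(coef(g)["cap_extentbilateral"]), tolerance = 1e-6)
  expect_equal(f$log_lik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("Wald p-values obey the normal-quantile identity", {
  co <- generate_cohort(generator_config(n = 3000, seed = 32))
  d <- derive_record(co)
  f <- fit_logistic(design_spec(c("cad_significant", "ckd_stage_ge3")),
                    d)
  b <- f$coefficients["cad_significant"]
  se <- sqrt(f$vcov["cad_significant", "cad_significant"])
  w <- wald_test(f, "cad_significant")
  expect_equal(w$chisq, unname((b / se)^2), tolerance = 1e-10)
  expect_equal(w$p, unname(2 * pnorm(-abs(b / se))), tolerance = 1e-10)
  # beta/se = 1.96 would give p ~= 0.05 under the same identity
  expect_equal(pchisq(1.96^2, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
})

test_that("multi-df Wald block test tracks the likelihood-ratio test", {
  co <- generate_cohort(generator_config(n = 2000, seed = 33))
  d <- derive_record(co)
  des <- design_spec("cad_significant",
                     categorical = list(cap_extent = cap_levels()))
  f <- fit_logistic(des, d)
  w <- wald_test(f, "cap_extent")
  expect_equal(w$df, 2)
  f0 <- fit_logistic(design_spec("cad_significant"), d)
  lrt_p <- pchisq(2 * (f$log_lik - f0$log_lik), 2, lower.tail = FALSE)
  expect_equal(w$p, lrt_p, tolerance = 0.02)
})

test_that("odds-ratio confidence bounds equal exp(beta +/- z se)", {
  co <- generate_cohort(generator_config(n = 1500, seed = 34))
  d <- derive_record(co)
  f <- fit_logistic(design_spec(c("cad_significant", "ahm_ge4")), d)
  oc <- f$or_ci
  expect_equal(oc$or, exp(oc$beta))
  expect_equal(oc$lo95, exp(oc$beta - qnorm(0.975) * oc$se))
  expect_equal(oc$hi90, exp(oc$beta + qnorm(0.95) * oc$se))
})

test_that("separation is detected and the offending term is named", {
  set.seed(35)
  dat <- data.frame(x = rep(c(0, 1), each = 25),
                    z = rbinom(50, 1, 0.5))
  dat$y <- dat$x  # x separates y completely
  expect_error(fit_logistic(design_spec(c("x", "z"), outcome = "y"), dat),
               class = "rascore_separation")
  err <- tryCatch(fit_logistic(design_spec(c("x", "z"), outcome = "y"),
                               dat),
                  rascore_separation = function(e) e)
  expect_equal(err$term, "x")
  # backward elimination drops it and still returns a model
  bw <- backward_select(design_spec(c("x", "z"), outcome = "y"), dat)
  expect_true(any(grepl("separating term 'x'", bw$log)))
  expect_s3_class(bw$model, "ras_logit")
})

test_that("rank-deficient designs raise a collinearity error", {
  dat <- data.frame(x = rbinom(40, 1, 0.5))
  dat$w <- dat$x
  dat$y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(design_spec(c("x", "w"), outcome = "y"), dat),
               "collinear")
})

test_that("backward elimination keeps strong terms and sheds noise", {
  set.seed(36)
  co <- generate_cohort(generator_config(n = 5000, seed = 36))
  d <- derive_record(co)
  d$noise <- rbinom(nrow(d), 1, 0.5)
  des <- design_spec(c("cad_significant", "ckd_stage_ge3", "ahm_ge4",
                       "cimt_ge_cut", "age_ge_cut", "bmi_lt_cut",
                       "noise"),
                     categorical = list(cap_extent = cap_levels()))
  removed <- replicate(20, {
    d$noise <- rbinom(nrow(d), 1, 0.5)
    bw <- backward_select(des, d)
    "noise" %in% bw$trace$removed
  })
  expect_gte(mean(removed), 0.85)
  # the strong true predictors survive every time at this n
  bw <- backward_select(des, d)
  expect_true(all(c("cad_significant", "ckd_stage_ge3", "ahm_ge4") %in%
                    names(bw$model$blocks)))
  expect_true(all(bw$model$wald$p < 0.10))
})

test_that("elimination trace records removals in threshold order", {
  co <- generate_cohort(generator_config(n = 641, seed = 37))
  d <- derive_record(co)
  des <- full_design()
  bw <- backward_select(des, d)
  if (nrow(bw$trace) > 0) {
    expect_true(all(bw$trace$p >= 0.10))
    expect_equal(bw$trace$step, seq_len(nrow(bw$trace)))
  }
  # retained terms all below the exit threshold
  expect_true(all(bw$model$wald$p < 0.10))
})

test_that("variance inflation factors match a least-squares oracle", {
  set.seed(38)
  # orthogonal balanced design: all VIFs 1
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  dat <- g[rep(seq_len(8), 10), ]
  dat$y <- rep(c(0, 1), 40)
  v <- vif(design_spec(c("a", "b", "c"), outcome = "y"), dat)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)
  # correlated columns: compare against explicit R^2 computation
  dat$d <- ifelse(runif(80) < 0.8, dat$a, 1 - dat$a)
  v2 <- vif(design_spec(c("a", "b", "d"), outcome = "y"), dat)
  r2 <- summary(lm(a ~ b + d, dat))$r.squared
  expect_equal(unname(v2["a"]), 1 / (1 - r2), tolerance = 1e-8)
  # duplicated column: infinite, reported as such
  dat$e <- dat$a
  v3 <- vif(design_spec(c("a", "e"), outcome = "y"), dat)
  expect_true(all(is.infinite(v3)))
})
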