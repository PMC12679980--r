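make_children <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age_months = runif(n, 6, 36),
    poverty_pct = runif(n, 0, 90),
    quarter = sample(paste0("Q", 1:4), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    year = sample(2015:2016, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("IRLS matches the reference ML fit with equal weights and unit clusters", {
  ch <- make_children(100, seed = 2)
  eta <- 0.4 + 0.9 * log(ch$age_months) - 0.03 * ch$poverty_pct
  set.seed(3)
  consumer <- rbinom(100, 1, plogis(eta))
  e4rz <- ifelse(consumer == 1, pmin((rnorm(100, 5, 1.5))^2, 100), 0)
  d <- srs_design(100)

  fit <- fit_two_part(ch, e4rz, d)

  # independent oracle: stats::glm / lm on the same data
  gb <- glm(consumer ~ log(age_months) + poverty_pct, binomial(), data = ch)
  expect_equal(unname(fit$binomial$coef), unname(coef(gb)),
               tolerance = 1e-7)

  keep <- e4rz > 0
  gl <- lm(sqrt(e4rz[keep]) ~ age_months + log(age_months) +
             I(quarter == "Q2") + I(quarter == "Q3") + I(quarter == "Q4"),
           data = ch[keep, ])
  expect_equal(unname(fit$normal$coef), unname(coef(gl)), tolerance = 1e-9)
})

test_that("intercept-only binomial with half consumers recovers logit(0.5) = 0", {
  n <- 40
  ch <- make_children(n)
  e4rz <- rep(c(0, 25), n / 2)
  d <- srs_design(n)
  fit <- fit_two_part(ch, e4rz, d,
                      model_spec(binomial_terms = character(0),
                                 normal_terms = character(0)))
  expect_equal(unname(fit$binomial$coef), 0, tolerance = 1e-8)
  expect_equal(unname(fit$normal$coef), 5)  # mean sqrt(25)
})

test_that("weights shift the fit and separation fails loudly", {
  n <- 60
  ch <- make_children(n, seed = 5)
  e4rz <- rep(c(0, 25, 25), n / 3)
  w <- ifelse(e4rz > 0, 1, 4)
  fit <- fit_two_part(ch, e4rz, srs_design(n, w),
                      model_spec(binomial_terms = character(0),
                                 normal_terms = character(0)))
  # weighted consumer share = (2/3) / (2/3 + 4/3) = 1/3
  expect_equal(unname(plogis(fit$binomial$coef)), 1 / 3, tolerance = 1e-8)

  # perfectly separated consumer indicator
  sep <- ifelse(ch$age_months > 20, 25, 0)
  expect_error(
    fit_two_part(ch, sep, srs_design(n),
                 model_spec(binomial_terms = "age",
                            normal_terms = character(0))),
    class = "upfsurvey_error")
})

test_that("degenerate consumer indicators skip components with warnings", {
  ch <- make_children(20)
  w <- capture_warnings(fit <- fit_two_part(ch, rep(0, 20), srs_design(20)))
  expect_match(w, "no consumers", all = FALSE)
  expect_match(w, "degenerate consumer indicator", all = FALSE)
  expect_null(fit$normal)
  expect_null(fit$binomial)
})

test_that("sandwich SEs track model-based SEs under independence", {
  n <- 2000
  ch <- make_children(n, seed = 8)
  eta <- 10.9 + 0.14 * ch$age_months - 3.1 * log(ch$age_months)
  set.seed(9)
  y <- (pmax(rnorm(n, eta, 1.8), 0.1))^2
  fit <- suppressWarnings(   # every child a consumer: binomial skipped
    fit_two_part(ch, y, srs_design(n),
                 model_spec(normal_terms = c("age", "log_age"))))
  gl <- lm(sqrt(y) ~ age_months + log(age_months), data = ch)
  ratio <- fit$normal$se / sqrt(diag(vcov(gl)))
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("scenario predictions follow the printed-coefficient arithmetic", {
  # hand-build a fit carrying the published Total coefficients
  bterms <- c("(Intercept)", "log_age", "poverty")
  nterms <- c("(Intercept)", "age", "log_age",
              "quarterQ2", "quarterQ3", "quarterQ4")
  fit <- structure(list(
    binomial = list(terms = bterms,
                    coef = setNames(c(0.377, 0.943, -0.036), bterms),
                    se = setNames(rep(0.1, 3), bterms),
                    vcov = diag(0, 3), n = 2887, df = 100),
    normal = list(terms = nterms,
                  coef = setNames(c(10.917, 0.145, -3.088,
                                    0.614, 0.296, 0.284), nterms),
                  se = setNames(rep(0.1, 6), nterms),
                  vcov = diag(0, 6), n = 2531, df = 100),
    spec = model_spec()), class = "two_part_fit")

  prof <- data.frame(age_months = 21, poverty_pct = 30, quarter = "Q3")
  pred <- predict_scenario(fit, prof)

  eta_n <- 10.917 + 0.145 * 21 - 3.088 * log(21) + 0.296
  expect_equal(eta_n, 4.8565, tolerance = 1e-3)       # sqrt-scale ~ 4.86
  expect_equal(pred$mrat, eta_n^2)                    # ~ 23.6 %
  expect_equal(round(pred$mrat, 1), 23.6)
  eta_b <- 0.377 + 0.943 * log(21) - 0.036 * 30
  expect_equal(pred$poct, 100 * plogis(eta_b))

  # zero vcov: bands collapse onto the point curve
  expect_equal(pred$mrat_low, pred$mrat)
  expect_equal(pred$poct_high, pred$poct)

  expect_error(predict_scenario(fit, data.frame(age_months = 21)),
               class = "upf_model_error")
})

test_that("bands contain the point curve and respect monotone transforms", {
  ch <- make_children(400, seed = 12)
  eta <- 0.4 + 0.9 * log(ch$age_months) - 0.03 * ch$poverty_pct
  set.seed(13)
  consumer <- rbinom(400, 1, plogis(eta))
  e4rz <- ifelse(consumer == 1, pmin((rnorm(400, 5, 1.5))^2, 100), 0)
  fit <- fit_two_part(ch, e4rz, srs_design(400))
  prof <- data.frame(age_months = seq(6, 35, by = 1), poverty_pct = 30,
                     quarter = "Q3")
  pred <- predict_scenario(fit, prof)
  expect_true(all(pred$poct_low <= pred$poct & pred$poct <= pred$poct_high))
  expect_true(all(pred$mrat_low <= pred$mrat & pred$mrat <= pred$mrat_high))
  expect_true(all(pred$poct >= 0 & pred$poct_high <= 100))
  expect_true(all(pred$mrat_low >= 0))
})

test_that("a binomial intercept of 0 gives a flat 50% consumer curve", {
  bterms <- "(Intercept)"
  fit <- structure(list(
    binomial = list(terms = bterms, coef = setNames(0, bterms),
                    se = setNames(0.1, bterms), vcov = diag(0, 1),
                    n = 10, df = 5),
    normal = NULL, spec = model_spec()), class = "two_part_fit")
  pred <- predict_scenario(fit, data.frame(age_months = c(6, 21, 35),
                                           poverty_pct = 0, quarter = "Q1"))
  expect_equal(pred$poct, rep(50, 3))
})
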