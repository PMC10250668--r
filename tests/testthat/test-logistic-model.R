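test_that("saturated 2x2 logistic slope equals the closed-form log odds ratio", {
  d <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(39, 22, 2, 9)),
    y = rep(c(1, 0, 1, 0), c(39, 22, 2, 9))
  )
  fit <- fit_logistic(d, "y", "x")
  slope <- tidy(fit)$estimate[tidy(fit)$term == "x"]
  expect_equal(slope, log(351 / 44), tolerance = 1e-7)
})

test_that("null data give near-zero coefficients", {
  withr::with_seed(4, {
    d <- tibble::tibble(x = stats::rnorm(400),
                        y = rep(c(0, 1), 200))
    fit <- fit_logistic(d, "y", "x")
    expect_lt(abs(tidy(fit)$estimate[2]), 0.25)
    expect_lt(abs(tidy(fit)$estimate[1]), 0.25)
    g <- glance(fit)
    expect_lt(g$model_chi2, 6)
  })
})

test_that("odds-ratio arithmetic: exp(B) and Wald interval", {
  or <- wald_or_ci(0.886, 0.334)
  expect_equal(round(or$odds_ratio, 3), 2.425)
  expect_equal(round(or$ci_low, 3), 1.260)
  # the upper bound recomputed from 3-decimal inputs lands at 4.6676,
  # within one unit in the last printed digit of 4.667
  expect_equal(or$ci_high, 4.667, tolerance = 1e-3)

  # fit columns use the same arithmetic
  d <- tibble::tibble(x = c(0, 0, 1, 1, 0, 1, 1, 0, 1, 0),
                      y = c(0, 1, 1, 0, 0, 1, 1, 0, 0, 1))
  co <- tidy(fit_logistic(d, "y", "x"))
  expect_equal(co$odds_ratio, exp(co$estimate))
  expect_equal(co$or_ci_low, exp(co$estimate - 1.96 * co$std_error))
  expect_true(all(co$or_ci_low <= co$odds_ratio &
                    co$odds_ratio <= co$or_ci_high))
})

test_that("score equations vanish at convergence", {
  withr::with_seed(15, {
    for (rep in 1:5) {
      n <- 300
      d <- tibble::tibble(
        x1 = stats::rnorm(n),
        x2 = stats::rbinom(n, 1, 0.4)
      )
      eta <- -0.5 + 0.8 * d$x1 + 1.1 * d$x2
      d$y <- stats::rbinom(n, 1, stats::plogis(eta))
      fit <- fit_logistic(d, "y", c("x1", "x2"))
      resid <- fit$y - fit$fitted
      expect_lt(max(abs(crossprod(fit$design, resid))), 1e-6)
    }
  })
})

test_that("coefficients agree with the reference IRLS fit on random fixtures", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      n <- sample(80:200, 1)
      d <- tibble::tibble(
        x1 = stats::rnorm(n),
        x2 = stats::runif(n, 0, 4)
      )
      eta <- stats::rnorm(1, 0, 0.5) + 0.7 * d$x1 - 0.4 * d$x2
      d$y <- stats::rbinom(n, 1, stats::plogis(eta))
      if (length(unique(d$y)) < 2) next
      fit <- fit_logistic(d, "y", c("x1", "x2"))
      ref <- stats::glm(y ~ x1 + x2, data = d, family = stats::binomial())
      expect_equal(tidy(fit)$estimate, unname(stats::coef(ref)),
                   tolerance = 1e-6)
      # glm stops on a looser deviance criterion, so its SEs carry more
      # numerical slack than the coefficients
      expect_equal(tidy(fit)$std_error,
                   unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
      expect_equal(fit$log_lik, as.numeric(stats::logLik(ref)),
                   tolerance = 1e-8)
    }
  })
})

test_that("separation and singular designs raise typed errors", {
  sep <- tibble::tibble(x = c(1:5, 6:10), y = rep(c(0, 1), each = 5))
  expect_error(fit_logistic(sep, "y", "x"),
               class = "nptpredict_separation_error")
  sing <- tibble::tibble(x1 = 1:20, x2 = 2 * (1:20),
                         y = rep(c(0, 1), 10))
  expect_error(fit_logistic(sing, "y", c("x1", "x2")),
               class = "nptpredict_singular_error")
  expect_error(fit_logistic(tibble::tibble(x = 1:4, y = c(1, 1, 1, 1)),
                            "y", "x"),
               class = "nptpredict_input_error")
})

test_that("Nagelkerke R2 and model chi-squared match hand-computed likelihoods", {
  # 6-row fixture, likelihoods evaluable by hand from the fitted probabilities
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), y = c(0, 0, 1, 0, 1, 1))
  fit <- fit_logistic(d, "y", "x")
  mu <- fit$fitted
  ll1 <- sum(d$y * log(mu) + (1 - d$y) * log(1 - mu))
  ll0 <- 3 * log(0.5) + 3 * log(0.5)
  expect_equal(fit$log_lik, ll1, tolerance = 1e-10)
  expect_equal(fit$null_log_lik, ll0, tolerance = 1e-10)
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / 6)
  expect_equal(nagelkerke_r2(fit), r2_cs / (1 - exp(2 * ll0 / 6)),
               tolerance = 1e-10)
  expect_equal(model_chi2(fit)$chi2, -2 * (ll0 - ll1), tolerance = 1e-10)

  # intercept-only model explains nothing
  null_fit <- fit_logistic(tibble::tibble(z = rep(0, 8),
                                          y = rep(c(0, 1), 4)),
                           "y", character(0))
  expect_equal(nagelkerke_r2(null_fit), 0, tolerance = 1e-10)
  expect_equal(model_chi2(null_fit)$chi2, 0, tolerance = 1e-10)
})

test_that("adding an informative predictor never decreases the model chi-squared", {
  withr::with_seed(50, {
    n <- 250
    d <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
    d$y <- stats::rbinom(n, 1, stats::plogis(-0.3 + 1.2 * d$x2))
    small <- fit_logistic(d, "y", "x1")
    big <- fit_logistic(d, "y", c("x1", "x2"))
    expect_gte(model_chi2(big)$chi2, model_chi2(small)$chi2)
  })
})

test_that("classification accuracy at 0.5 equals a brute-force recount", {
  d <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(39, 22, 2, 9)),
    y = rep(c(1, 0, 1, 0), c(39, 22, 2, 9))
  )
  fit <- fit_logistic(d, "y", "x")
  brute <- 100 * mean((fit$fitted >= 0.5) == (d$y == 1))
  expect_equal(accuracy_at_half(fit), round_half_up(brute, 1))

  # an uninformative model predicts the majority class everywhere:
  # accuracy equals the prevalence (61/72 -> 84.7%)
  flat <- tibble::tibble(z = rep(0, 72), y = rep(c(1, 0), c(61, 11)))
  expect_equal(accuracy_at_half(fit_logistic(flat, "y", character(0))), 84.7)
})

test_that("predicted probabilities follow the inverse logit of the coefficients", {
  expect_equal(predict_probability(c(`(Intercept)` = 0), numeric(0)), 0.5)
  p <- predict_probability(
    c(`(Intercept)` = -5.300, vas = 0.886, activity = 0.209),
    c(vas = 7, activity = 7.25)
  )
  expect_equal(p, stats::plogis(-5.300 + 0.886 * 7 + 0.209 * 7.25))
  expect_equal(round(p, 4), 0.9181)

  grid <- tibble::tibble(vas = 0:10, activity = 5)
  probs <- predict_probability(
    c(`(Intercept)` = -5.3, vas = 0.886, activity = 0.209), grid
  )
  expect_true(all(diff(probs) > 0))
  expect_error(
    predict_probability(c(`(Intercept)` = 0, vas = 1), c(wrong = 2)),
    class = "nptpredict_input_error"
  )
})

test_that("Box-Tidwell flags a quadratic logit but not a linear one", {
  withr::with_seed(61, {
    n <- 2000
    # linear logit: augmentation term should rarely be significant
    null_hits <- 0
    for (s in 1:30) {
      x <- stats::runif(n, 0.5, 6)
      y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.6 * x))
      bt <- box_tidwell(tibble::tibble(x = x, y = y), "y", "x")
      null_hits <- null_hits + (bt$p_value < 0.05)
    }
    expect_lte(null_hits, 5)  # ~5% nominal level over 30 draws

    # quadratic logit: high power
    alt_hits <- 0
    for (s in 1:10) {
      x <- stats::runif(n, 0.5, 6)
      y <- stats::rbinom(n, 1, stats::plogis(-2 + 0.9 * (x - 3)^2))
      bt <- box_tidwell(tibble::tibble(x = x, y = y), "y", "x")
      alt_hits <- alt_hits + (bt$p_value < 0.05)
    }
    expect_gte(alt_hits, 9)
  })
})

test_that("single-predictor Box-Tidwell equals fitting the augmented model directly", {
  withr::with_seed(62, {
    x <- stats::runif(150, 0.2, 5)
    y <- stats::rbinom(150, 1, stats::plogis(-0.5 + 0.4 * x))
    bt <- box_tidwell(tibble::tibble(x = x, y = y), "y", "x")
    direct <- fit_logistic(
      tibble::tibble(x = x, xlx = x * log(x), y = y), "y", c("x", "xlx")
    )
    expect_equal(bt$estimate,
                 tidy(direct)$estimate[tidy(direct)$term == "xlx"],
                 tolerance = 1e-8)
    expect_equal(bt$p_value,
                 tidy(direct)$p_value[tidy(direct)$term == "xlx"],
                 tolerance = 1e-8)
  })
})

test_that("zero-containing predictors are shifted before the log transform", {
  withr::with_seed(63, {
    x <- sample(0:10, 300, replace = TRUE)
    y <- stats::rbinom(300, 1, stats::plogis(-1 + 0.3 * x))
    bt <- box_tidwell(tibble::tibble(x = x, y = y), "y", "x")
    expect_true(is.finite(bt$p_value))
  })
  expect_error(
    box_tidwell(tibble::tibble(x = c(-1, 2, 3), y = c(0, 1, 0)), "y", "x"),
    class = "nptpredict_input_error"
  )
})
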