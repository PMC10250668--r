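test_that("candidate cutoffs are midpoints plus sentinels", {
  expect_equal(candidate_cutoffs(c(6.0, 6.5, 9.0)), c(5.0, 6.25, 7.75, 10.0))
  expect_equal(candidate_cutoffs(c(1, 2)), c(0, 1.5, 3))
  expect_equal(candidate_cutoffs(c(5, 5, 5)), c(4, 6))
  expect_error(candidate_cutoffs(numeric()), class = "nptpredict_input_error")
})

test_that("AUC: separation, null behaviour, and input checks", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  withr::with_seed(5, {
    null_auc <- roc_auc(stats::rnorm(4000), rep(c(0, 1), 2000))
    expect_lt(abs(null_auc - 0.5), 0.03)
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "nptpredict_input_error")
})

test_that("AUC equals the pair-counting oracle on 200 random datasets", {
  withr::with_seed(14, {
    for (rep in 1:200) {
      n <- sample(4:50, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      s <- sample(0:12, n, replace = TRUE)  # many ties
      expect_identical(roc_auc(s, y), oracle_auc(s, y))
    }
  })
})

test_that("AUC respects direction and increasing-transform invariance", {
  withr::with_seed(3, {
    s <- stats::rnorm(60)
    y <- c(rep(1, 30), rep(0, 30))
    a <- roc_auc(s, y)
    expect_equal(roc_auc(-s, y, direction = "lower"), a)
    expect_equal(roc_auc(-s, y) + a, 1)           # tie-free complement
    expect_equal(roc_auc(exp(2 * s), y), a)        # monotone transform
  })
})

test_that("Hanley-McNeil AUC inference behaves", {
  expect_equal(auc_test(0.5, 20, 20)$p_value, 1)
  strong <- auc_test(0.82, 61, 11)
  expect_lt(strong$p_value, 0.01)
  # SE shrinks as the negative class grows
  ses <- vapply(c(5, 11, 50, 200),
                function(n0) auc_test(0.82, 61, n0)$se, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_error(auc_test(0.8, 0, 5), class = "nptpredict_input_error")
})

test_that("Youden cutoff equals exhaustive maximization (100 random datasets)", {
  withr::with_seed(27, {
    for (rep in 1:100) {
      n <- sample(6:40, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.6))
      s <- round(stats::rnorm(n, mean = 2 * y), 1)
      bc <- best_cutoff(s, y)
      expect_equal(bc$youden_j, oracle_best_j(s, y), tolerance = 1e-12)
    }
  })
})

test_that("perfect separation puts the Youden cutoff at the class midpoint", {
  bc <- best_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(bc$cutoff, 6.5)
  expect_equal(bc$youden_j, 1)
  expect_equal(bc$sens, 100)
  expect_equal(bc$spec, 100)
})

test_that("cutoff metrics recompute exactly from the implied confusion matrix", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- sample(15:60, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.7))
      s <- round(stats::rnorm(n, mean = 1.5 * y), 1)
      bc <- best_cutoff(s, y)
      cm <- confusion_matrix(
        tp = sum(s >= bc$cutoff & y == 1), fn = sum(s < bc$cutoff & y == 1),
        fp = sum(s >= bc$cutoff & y == 0), tn = sum(s < bc$cutoff & y == 0)
      )
      expect_equal(confusion_metrics(cm)[, c("sens", "spec", "ppv", "npv")],
                   bc[, c("sens", "spec", "ppv", "npv")])
    }
  })
})

test_that("roc_summary: label-as-predictor, direction symmetry, degeneracy flag", {
  y <- c(rep(1, 8), rep(0, 5))
  expect_equal(roc_summary(y, y)$auc, 1)

  withr::with_seed(9, {
    s <- stats::rnorm(40)
    yy <- stats::rbinom(40, 1, 0.5)
    yy[1:2] <- c(0, 1)
    up <- roc_summary(s, yy)
    down <- roc_summary(-s, yy, direction = "lower")
    expect_equal(down$auc, up$auc)
    expect_equal(down$sens, up$sens)
    expect_equal(down$spec, up$spec)
    expect_equal(down$cutoff, -up$cutoff)
  })

  flat <- roc_summary(rep(2, 10), c(rep(1, 6), rep(0, 4)))
  expect_true(flat$degenerate)
})

test_that("roc_table produces one calibrated row per predictor", {
  cohort <- generate_cohort(cohort_config(n_patients = 60, seed = 19))
  act <- build_activity_table(cohort)
  d <- dplyr::left_join(cohort, act, by = "patient_id")
  preds <- c("spt_timothy", "sige_phl_p_5", "activity_phl_p_5_cyn_d_1",
             "vas_severity_retro")
  tab <- roc_table(d, preds)
  expect_equal(tab$predictor, preds)
  for (i in seq_along(preds)) {
    expect_equal(tab$auc[i], oracle_auc(d[[preds[i]]], d$npt_positive))
  }
  expect_error(roc_table(d, "no_such_column"),
               class = "nptpredict_input_error")
})

test_that("ROC curve coordinates span both ends and plot cleanly", {
  withr::with_seed(2, {
    s <- stats::rnorm(30)
    y <- c(0, 1, stats::rbinom(28, 1, 0.5))
    pts <- roc_curve_points(s, y)
    expect_true(any(pts$sens == 1 & pts$spec == 0))
    expect_true(any(pts$sens == 0 & pts$spec == 1))
    p <- autoplot(pts)
    expect_s3_class(p, "ggplot")
  })
})
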