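test_that("degenerate cohort sizes behave: empty cohort, forced prevalence", {
  empty <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("patient_id", "total_ige", "sige_phl_p_5") %in%
                    names(empty)))

  all_pos <- generate_cohort(
    cohort_config(n_patients = 50, prevalence_positive = 1, seed = 2)
  )
  expect_equal(sum(all_pos$npt_positive), 50L)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(prevalence_positive = 1.2),
               class = "nptpredict_config_error")
  expect_error(cohort_config(n_patients = -1),
               class = "nptpredict_config_error")
  expect_error(cohort_config(assay_floor = 100, assay_cap = 0.1),
               class = "nptpredict_config_error")
  bad_panel <- default_analyte_panel()
  bad_panel$median_pos[1] <- -5
  expect_error(cohort_config(analytes = bad_panel),
               class = "nptpredict_config_error")
})

test_that("generation is reproducible and respects field ranges", {
  cfg <- cohort_config(n_patients = 120, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_true(all(a$total_ige > 0))
  sige <- as.matrix(dplyr::select(a, dplyr::starts_with("sige_")))
  expect_true(all(sige >= 0.1 - 1e-9))
  expect_true(all(sige <= 100 + 1e-9))
  expect_true(all(sige <= a$total_ige + 1e-9))
  expect_true(all(a$vas_severity_retro %in% 0:10))
  expect_true(all(a$vas_drug_efficacy %in% 0:10))
  expect_true(all(a$spt_timothy >= 0))
})

test_that("NPT prevalence and sensitization rates are calibrated at n = 10000", {
  cfg <- cohort_config(n_patients = 10000, seed = 31)
  cohort <- generate_cohort(cfg)

  prev <- mean(cohort$npt_positive)
  se <- sqrt(0.847 * 0.153 / 10000)
  expect_lt(abs(prev - 0.847), 3 * se)

  # per-group sensitization frequency of each analyte vs its configured rate
  for (i in seq_len(nrow(cfg$analytes))) {
    row <- cfg$analytes[i, ]
    v <- cohort[[paste0("sige_", row$analyte)]]
    for (grp in c(1L, 0L)) {
      rate <- if (grp == 1L) row$rate_pos else row$rate_neg
      obs <- is_sensitized(v[cohort$npt_positive == grp])
      n_g <- length(obs)
      se_g <- sqrt(rate * (1 - rate) / n_g)
      expect_lt(abs(mean(obs) - rate), 3 * se_g + 1e-12)
    }
  }
})

test_that("pollen series: determinism, cap, zero peak, bad n_days", {
  a <- generate_pollen_series(n_days = 60, seed = 5)
  b <- generate_pollen_series(n_days = 60, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$grains_m3 >= 0))
  expect_true(all(a$grains_m3 <= 199))

  z <- generate_pollen_series(n_days = 30, peak_height = 0, seed = 1)
  expect_true(all(z$grains_m3 == 0))

  expect_error(generate_pollen_series(n_days = 0),
               class = "nptpredict_config_error")
})

test_that("diaries stay in range and track pollen and NPT group by construction", {
  cfg <- cohort_config(n_patients = 50, seed = 8)
  cohort <- generate_cohort(cfg)
  pollen <- generate_pollen_series(n_days = 100, seed = 8)
  diary <- generate_diary(cohort, pollen, seed = 8)

  expect_equal(nrow(diary), 50 * 100)
  expect_true(all(diary$rtss %in% 0:18))
  expect_true(all(diary$csms >= 0 & diary$csms <= 6))
  expect_true(all(diary$vas %in% 0:10))

  # >= 5000 patient-days: positive group mean VAS exceeds negative group
  merged <- dplyr::left_join(diary,
                             cohort[, c("patient_id", "npt_positive")],
                             by = "patient_id")
  means <- tapply(merged$vas, merged$npt_positive, mean)
  expect_gt(means[["1"]], means[["0"]])
})

test_that("noise-free, exposure-free diaries are constant per patient", {
  cfg <- cohort_config(n_patients = 4, seed = 3)
  cohort <- generate_cohort(cfg)
  pollen <- generate_pollen_series(n_days = 10, seed = 3)
  diary <- generate_diary(cohort, pollen, exposure_coef = 0, noise_sd = 0,
                          latent_sd = 0, seed = 3)
  per_patient_sd <- tapply(diary$vas, diary$patient_id, stats::sd)
  expect_true(all(per_patient_sd == 0))
})

test_that("stronger Phl p 5 separation never lowers the combined-activity AUC", {
  auc_for <- function(rate_pos, seed) {
    panel <- default_analyte_panel()
    panel$rate_pos[panel$analyte == "phl_p_5"] <- rate_pos
    cohort <- generate_cohort(
      cohort_config(n_patients = 5000, analytes = panel, seed = seed)
    )
    act <- build_activity_table(cohort)
    roc_auc(act$activity_phl_p_5_cyn_d_1, cohort$npt_positive)
  }
  for (seed in 1:10) {
    expect_gte(auc_for(0.85, seed), auc_for(0.640, seed))
  }
})

test_that("cohort, diary and pollen CSV writers round-trip through readr", {
  tmp <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_config(n_patients = 6, seed = 4))
  p <- write_cohort_csv(cohort, file.path(tmp, "c.csv"))
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})
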