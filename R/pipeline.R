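#' Pipeline configuration
#'
#' Assembles and validates the options for [run_pipeline()]: either
#' simulate a cohort (via [cohort_config()]) or load the three CSV inputs,
#' then set the season windowing, high-day threshold, predictor list and
#' combined decision rule.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param cohort_path,diary_path,pollen_path CSV paths (load mode).
#' @param cohort A [cohort_config()] (simulate mode).
#' @param pollen_args List of arguments for [generate_pollen_series()]
#'   (simulate mode).
#' @param diary_args List of extra arguments for [generate_diary()]
#'   (simulate mode).
#' @param season_args List of arguments for [detect_season()] (thresholds,
#'   run length, fixed-window overrides).
#' @param high_day_threshold High-pollen-day threshold, grains/m^3 (> 0).
#' @param predictors Character vector of predictor columns for the ROC
#'   table; `NULL` for the default set.
#' @param rule An [rule_spec()].
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL` to
#'   keep everything in memory.
#' @param seed Integer seed for the simulate mode.
#' @return A list of class `npt_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            cohort_path = NULL, diary_path = NULL,
                            pollen_path = NULL,
                            cohort = cohort_config(seed = seed),
                            pollen_args = list(),
                            diary_args = list(),
                            season_args = list(),
                            high_day_threshold = 30,
                            predictors = NULL,
                            rule = rule_spec(),
                            out_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (high_day_threshold <= 0) {
    abort_npt("`high_day_threshold` must be positive.",
              "nptpredict_config_error")
  }
  if (mode == "load") {
    paths <- c(cohort_path, diary_path, pollen_path)
    if (length(paths) != 3L || !all(file.exists(paths))) {
      abort_npt("Load mode needs existing cohort, diary and pollen CSVs.",
                "nptpredict_config_error")
    }
  }
  structure(
    list(mode = mode, cohort_path = cohort_path, diary_path = diary_path,
         pollen_path = pollen_path, cohort = cohort,
         pollen_args = pollen_args, diary_args = diary_args,
         season_args = season_args,
         high_day_threshold = high_day_threshold,
         predictors = predictors, rule = rule, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "npt_pipeline_config"
  )
}

#' Load and validate the cohort, diary and pollen CSVs
#'
#' Reads the three documented CSV schemas and validates them: required
#' columns, non-negative IgE and pollen values, score ranges, and unique
#' (patient, date) diary rows. Violations raise errors naming the
#' offending rows.
#'
#' @param cohort_path,diary_path,pollen_path CSV file paths.
#' @return List with tibbles `cohort`, `diary`, `pollen`.
#' @export
load_cohort <- function(cohort_path, diary_path, pollen_path) {
  cohort <- readr::read_csv(cohort_path, show_col_types = FALSE)
  need <- c("patient_id", "npt_positive", "total_ige")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    abort_npt(sprintf("Cohort CSV lacks column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "nptpredict_input_error")
  }
  sige_cols <- grep("^sige_", names(cohort), value = TRUE)
  for (col in c("total_ige", sige_cols)) {
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      abort_npt(sprintf("Cohort column `%s` must be numeric.", col),
                "nptpredict_input_error")
    }
    bad <- which(v < 0)
    if (length(bad) > 0L) {
      abort_npt(sprintf("Negative IgE in `%s`, row(s) %s.", col,
                        paste(utils::head(bad, 5), collapse = ", ")),
                "nptpredict_input_error")
    }
  }
  diary <- readr::read_csv(diary_path, show_col_types = FALSE)
  if (!all(c("patient_id", "date") %in% names(diary))) {
    abort_npt("Diary CSV needs `patient_id` and `date` columns.",
              "nptpredict_input_error")
  }
  dup <- duplicated(diary[, c("patient_id", "date")])
  if (any(dup)) {
    abort_npt(sprintf("Duplicate (patient, date) diary row(s): %s.",
                      paste(utils::head(which(dup), 5), collapse = ", ")),
              "nptpredict_input_error")
  }
  for (col in intersect(c("rtss", "csms", "vas"), names(diary))) {
    hi <- c(rtss = 18, csms = 6, vas = 10)[[col]]
    bad <- which(diary[[col]] < 0 | diary[[col]] > hi)
    if (length(bad) > 0L) {
      abort_npt(sprintf("`%s` out of range in diary row(s) %s.", col,
                        paste(utils::head(bad, 5), collapse = ", ")),
                "nptpredict_input_error")
    }
  }
  pollen <- readr::read_csv(pollen_path, show_col_types = FALSE)
  if (!all(c("date", "grains_m3") %in% names(pollen))) {
    abort_npt("Pollen CSV needs `date` and `grains_m3` columns.",
              "nptpredict_input_error")
  }
  if (any(pollen$grains_m3 < 0)) {
    abort_npt("Negative pollen concentrations in pollen CSV.",
              "nptpredict_input_error")
  }
  list(cohort = cohort, diary = diary, pollen = pollen)
}

#' Two-group comparison table by NPT outcome
#'
#' For each variable: medians and IQRs (linear-interpolation quantiles)
#' per NPT group and a two-group test. Continuous variables use the
#' Mann-Whitney U test; binary (0/1) variables a 2x2 test (Fisher exact
#' when any expected cell is below 5, else Yates-corrected chi-squared).
#' Constant variables are reported with a note instead of a test.
#'
#' @param data Cohort-level tibble.
#' @param variables Character vector of columns to compare.
#' @param label_col 0/1 outcome column.
#' @return Tibble: `variable`, `median_neg`, `q1_neg`, `q3_neg`,
#'   `median_pos`, `q1_pos`, `q3_pos`, `p_value`, `method`, `note`.
#' @export
group_compare <- function(data, variables, label_col = "npt_positive") {
  missing_cols <- setdiff(c(variables, label_col), names(data))
  if (length(missing_cols) > 0L) {
    abort_npt(sprintf("Missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "nptpredict_input_error")
  }
  y <- as.integer(data[[label_col]])
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    neg <- x[y == 0L & !is.na(x)]
    pos <- x[y == 1L & !is.na(x)]
    qs <- function(z) {
      if (length(z) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      stats::quantile(z, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    }
    qn <- qs(neg); qp <- qs(pos)
    base <- tibble::tibble(
      variable = v,
      median_neg = qn[1], q1_neg = qn[2], q3_neg = qn[3],
      median_pos = qp[1], q1_pos = qp[2], q3_pos = qp[3]
    )
    all_vals <- c(neg, pos)
    if (length(unique(all_vals)) < 2L) {
      return(dplyr::mutate(base, p_value = NA_real_, method = NA_character_,
                           note = "constant variable; test skipped"))
    }
    if (all(all_vals %in% c(0, 1))) {
      res <- compare_2x2(sum(pos == 1), sum(pos == 0),
                         sum(neg == 1), sum(neg == 0))
    } else {
      res <- mann_whitney(pos, neg)
    }
    dplyr::mutate(base, p_value = res$p_value, method = res$method,
                  note = NA_character_)
  })
}

#' Run the full NPT-prediction pipeline
#'
#' Orchestrates every stage: obtain cohort, diary and pollen data
#' (simulated or loaded), derive season windows and the high-day mask,
#' summarize diaries, build the activity table, compare groups, compute
#' the ROC table, fit the logistic model on the combined activity and
#' retrospective VAS, and evaluate the combined decision rule.
#' Deterministic given the seed; optionally writes all artifacts under
#' `config$out_dir`.
#'
#' @param config An [pipeline_config()] object.
#' @return A list of class `npt_report`: `cohort`, `activity`,
#'   `diary_summary`, `season`, `group_table`, `roc`, `logistic` (or a
#'   condition object if separation occurred), `rule_eval`, `provenance`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep$rule_eval$metrics
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "npt_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_npt(sprintf("Stage `%s` failed: %s", name,
                        conditionMessage(e)),
                "nptpredict_stage_error")
    })
  }

  if (config$mode == "simulate") {
    cohort <- stage("simulate_cohort", generate_cohort(config$cohort))
    pollen <- stage("simulate_pollen", do.call(
      generate_pollen_series,
      utils::modifyList(list(seed = config$seed), config$pollen_args)
    ))
    diary <- stage("simulate_diary", do.call(
      generate_diary,
      utils::modifyList(list(cohort = cohort, pollen = pollen,
                             seed = config$seed), config$diary_args)
    ))
  } else {
    loaded <- stage("load", load_cohort(config$cohort_path,
                                        config$diary_path,
                                        config$pollen_path))
    cohort <- loaded$cohort
    diary <- loaded$diary
    pollen <- loaded$pollen
    pollen$date <- as.Date(pollen$date)
    diary$date <- as.Date(diary$date)
  }

  season <- stage("season", do.call(
    detect_season, c(list(series = pollen), config$season_args)
  ))
  mask_window <- season$peak_season
  mask <- stage("high_days", high_day_mask(
    pollen, window = mask_window, threshold = config$high_day_threshold
  ))
  diary_summary <- stage("diary_summary", summarize_diaries(diary, mask))
  activity <- stage("activity", build_activity_table(cohort))

  analysis <- dplyr::left_join(cohort, activity, by = "patient_id")
  analysis <- dplyr::left_join(analysis, diary_summary, by = "patient_id")

  compare_vars <- intersect(
    c("spt_timothy", "spt_bermuda", "total_ige",
      grep("^sige_", names(cohort), value = TRUE),
      grep("^activity_", names(activity), value = TRUE),
      "vas_severity_retro", "vas_drug_efficacy",
      "rtss_max", "rtss_cv", "csms_max", "csms_cv", "vas_max", "vas_cv"),
    names(analysis)
  )
  group_table <- stage("group_compare",
                       group_compare(analysis, compare_vars))

  predictors <- config$predictors
  if (is.null(predictors)) {
    predictors <- intersect(
      c("spt_timothy", "spt_bermuda",
        grep("^(sige_|activity_)", names(analysis), value = TRUE),
        "vas_severity_retro", "vas_max", "vas_cv"),
      names(analysis)
    )
  }
  roc <- stage("roc", roc_table(analysis, predictors))

  logistic <- tryCatch(
    fit_logistic(analysis, "npt_positive",
                 c("vas_severity_retro", "activity_phl_p_5_cyn_d_1")),
    nptpredict_separation_error = function(e) e
  )

  rule_eval <- stage("rule", evaluate_rule(
    analysis, "activity_phl_p_5_cyn_d_1", "vas_severity_retro",
    "npt_positive", config$rule
  ))

  report <- structure(
    list(
      cohort = cohort, diary = diary, pollen = pollen,
      activity = activity, diary_summary = diary_summary,
      season = season, group_table = group_table, roc = roc,
      logistic = logistic, rule_eval = rule_eval,
      provenance = list(
        seed = config$seed, mode = config$mode,
        high_day_threshold = config$high_day_threshold,
        rule = unclass(config$rule),
        package_version = as.character(utils::packageVersion("nptpredict")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "npt_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.npt_report <- function(x, ...) {
  cat("NPT prediction report\n")
  cat(sprintf("  cohort: %d patients (%d NPT-positive)\n",
              nrow(x$cohort), sum(x$cohort$npt_positive)))
  cat(sprintf("  high pollen days in mask window: %d\n",
              sum(x$season$day_class$class == "high")))
  cat(sprintf("  ROC predictors: %d\n", nrow(x$roc)))
  m <- x$rule_eval$metrics
  cat(sprintf(
    "  combined rule: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    m$sens, m$spec, m$ppv, m$npv))
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' @param report An `npt_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
  write_diary_csv(report$diary, file.path(dir, "diary.csv"))
  write_pollen_csv(report$pollen, file.path(dir, "pollen.csv"))
  write_activity_csv(report$activity, file.path(dir, "activity.csv"))
  write_diary_summary_csv(report$diary_summary,
                          file.path(dir, "diary_summary.csv"))
  readr::write_csv(report$group_table, file.path(dir, "group_table.csv"))
  write_roc_csv(report$roc, file.path(dir, "roc_table.csv"))
  if (inherits(report$logistic, "npt_logit")) {
    write_logistic_csv(report$logistic, file.path(dir, "logistic.csv"))
  }
  season_windows_json(report$season, file.path(dir, "season.json"))
  jsonlite::write_json(
    list(
      rule = report$rule_eval$rule |> unclass(),
      confusion = unclass(report$rule_eval$confusion),
      metrics = as.list(report$rule_eval$metrics),
      provenance = report$provenance
    ),
    file.path(dir, "rule_and_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
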