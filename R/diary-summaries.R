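#' Coefficient of variation in percent
#'
#' `100 * SD / mean` with the sample SD (n - 1 denominator). An all-zero
#' sample returns 0 (the 0/0 convention: no dispersion). Fewer than two
#' non-missing values give `NA`: a CV is not defined for a single diary
#' entry.
#'
#' @param values Numeric vector of non-negative scores.
#' @param min_n Minimum number of non-missing values required (default 2).
#' @return CV in percent, or `NA_real_`.
#' @examples
#' cv_percent(c(2, 4, 6))
#' @export
cv_percent <- function(values, min_n = 2L) {
  values <- values[!is.na(values)]
  if (any(values < 0)) {
    abort_npt("Scores must be non-negative.", "nptpredict_input_error")
  }
  if (length(values) < min_n) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(0)
  100 * stats::sd(values) / m
}

#' Maximum observed score
#'
#' Maximum of the non-missing values; `NA` when nothing was observed.
#'
#' @param values Numeric vector.
#' @return Scalar maximum or `NA_real_`.
#' @export
max_score <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  max(values)
}

#' Summarize e-diary scores over high-pollen days
#'
#' Restricts each patient's diary to the dates flagged high in the mask
#' (typically concentration > 30 grains/m^3 within the peak season) and
#' summarizes each score (RTSS, CSMS, VAS) as its maximum and its
#' coefficient of variation. Missing diary days are dropped, not imputed;
#' patients with fewer than two observed high days get an `NA` CV and
#' patients with no observed high days get `NA` throughout.
#'
#' @param diary Long diary tibble: `patient_id`, `date`, plus score
#'   columns.
#' @param mask Tibble `date`, `high` from [high_day_mask()].
#' @param scores Character vector of score columns to summarize.
#' @return Tibble, one row per patient: `patient_id`, `n_days` (observed
#'   high days) and `<score>_max`, `<score>_cv` columns.
#' @examples
#' diary <- tibble::tibble(
#'   patient_id = "P1", date = as.Date("2016-06-01") + 0:2,
#'   vas = c(2, 4, 6)
#' )
#' mask <- tibble::tibble(date = diary$date, high = TRUE)
#' summarize_diaries(diary, mask, scores = "vas")
#' @export
summarize_diaries <- function(diary, mask,
                              scores = c("rtss", "csms", "vas")) {
  stopifnot(all(c("patient_id", "date") %in% names(diary)),
            all(c("date", "high") %in% names(mask)))
  missing_scores <- setdiff(scores, names(diary))
  if (length(missing_scores) > 0L) {
    abort_npt(sprintf("Diary lacks score column(s): %s.",
                      paste(missing_scores, collapse = ", ")),
              "nptpredict_input_error")
  }
  high_dates <- mask$date[mask$high]
  patients <- unique(diary$patient_id)
  on_high <- diary[diary$date %in% high_dates, , drop = FALSE]

  summarize_one <- function(pid) {
    rows <- on_high[on_high$patient_id == pid, , drop = FALSE]
    out <- tibble::tibble(patient_id = pid, n_days = nrow(rows))
    for (sc in scores) {
      v <- rows[[sc]]
      out[[paste0(sc, "_max")]] <- max_score(v)
      out[[paste0(sc, "_cv")]] <- cv_percent(v)
    }
    out
  }
  purrr::map_dfr(patients, summarize_one)
}

#' @rdname cohort_io
#' @param summary Diary summary tibble from [summarize_diaries()].
#' @export
write_diary_summary_csv <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}
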