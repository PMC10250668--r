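#' Sensitization call from a specific IgE level
#'
#' A specific IgE result is positive (sensitized) when it is strictly
#' greater than the assay positivity threshold of 0.35 kU/L.
#'
#' @param sige Specific IgE, kU/L (non-negative).
#' @param threshold Positivity threshold, kU/L.
#' @return Logical vector.
#' @examples
#' is_sensitized(c(0.35, 0.36))
#' @export
is_sensitized <- function(sige, threshold = 0.35) {
  if (any(sige < 0, na.rm = TRUE)) {
    abort_npt("Specific IgE must be non-negative.", "nptpredict_input_error")
  }
  sige > threshold
}

#' IgE-specific activity
#'
#' The specific activity of an IgE antibody is its concentration expressed
#' as a percentage of total IgE: `100 * sige / total_ige`.
#'
#' @param sige Specific IgE, kU/L; must not exceed `total_ige`.
#' @param total_ige Total IgE, kU/L; strictly positive.
#' @return Activity in percent, in `[0, 100]`.
#' @examples
#' specific_activity(17.4, 402.8)
#' @export
specific_activity <- function(sige, total_ige) {
  if (any(total_ige <= 0, na.rm = TRUE)) {
    abort_npt("`total_ige` must be strictly positive.",
              "nptpredict_input_error")
  }
  if (any(sige < 0, na.rm = TRUE)) {
    abort_npt("`sige` must be non-negative.", "nptpredict_input_error")
  }
  if (any(sige > total_ige, na.rm = TRUE)) {
    abort_npt("Specific IgE exceeds total IgE: inconsistent record.",
              "nptpredict_input_error")
  }
  100 * sige / total_ige
}

#' Combined IgE-specific activity of several analytes
#'
#' The combined activity of a set of analytes is the specific activity of
#' the summed specific IgE: `100 * sum(sige) / total_ige`. It therefore
#' equals the sum of the component activities.
#'
#' @param sige_values Numeric vector of specific IgE levels, kU/L; their
#'   sum must not exceed `total_ige`.
#' @param total_ige Total IgE, kU/L (scalar, strictly positive).
#' @return Combined activity in percent.
#' @examples
#' combined_activity(c(17.4, 37.0), 402.8)
#' @export
combined_activity <- function(sige_values, total_ige) {
  specific_activity(sum(sige_values), total_ige)
}

#' Per-patient activity table
#'
#' Computes the IgE-specific activity for each requested analyte and each
#' named combination (sum of component IgE over total IgE) for every
#' patient in a cohort. The default predictor set covers the two grass
#' extracts, their sum, the major species-specific molecules and the
#' combined Phl p 5 + Cyn d 1 index.
#'
#' Specific IgE columns are expected as `sige_<analyte>`. Values below the
#' assay floor should already be coded at the floor (0.1 kU/L by
#' convention); set `floor_as_zero = TRUE` to enter them as zero instead.
#'
#' @param cohort Cohort tibble with `patient_id`, `total_ige` and
#'   `sige_<analyte>` columns.
#' @param analyte_sets Named list; each element is a character vector of
#'   analyte names whose IgE levels are summed before dividing by total
#'   IgE. Single-analyte sets give plain specific activities.
#' @param floor_as_zero Recode values at `floor` to zero before computing
#'   activities.
#' @param floor Assay floor used by `floor_as_zero`, kU/L.
#' @return Tibble: `patient_id` plus one `activity_<set>` column per set,
#'   in percent.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4, seed = 7))
#' build_activity_table(cohort)
#' @export
build_activity_table <- function(cohort,
                                 analyte_sets = default_analyte_sets(),
                                 floor_as_zero = FALSE,
                                 floor = 0.1) {
  need <- unique(unlist(analyte_sets))
  missing_cols <- setdiff(paste0("sige_", need), names(cohort))
  if (length(missing_cols) > 0L) {
    abort_npt(
      sprintf("Cohort is missing analyte column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "nptpredict_input_error"
    )
  }
  out <- tibble::tibble(patient_id = cohort$patient_id)
  for (set_name in names(analyte_sets)) {
    cols <- paste0("sige_", analyte_sets[[set_name]])
    mat <- as.matrix(cohort[, cols, drop = FALSE])
    if (floor_as_zero) mat[mat <= floor] <- 0
    out[[paste0("activity_", set_name)]] <-
      specific_activity(rowSums(mat), cohort$total_ige)
  }
  out
}

#' Default activity predictor sets
#'
#' @return Named list of analyte vectors: each extract and molecule alone,
#'   plus the timothy + Bermuda and Phl p 5 + Cyn d 1 combinations.
#' @export
default_analyte_sets <- function() {
  list(
    timothy = "timothy",
    bermuda = "bermuda",
    timothy_bermuda = c("timothy", "bermuda"),
    phl_p_1 = "phl_p_1",
    phl_p_5 = "phl_p_5",
    cyn_d_1 = "cyn_d_1",
    phl_p_5_cyn_d_1 = c("phl_p_5", "cyn_d_1")
  )
}

#' Write an activity table to CSV
#'
#' Activities are written rounded to 2 decimals (reporting convention);
#' full precision is retained in memory.
#'
#' @param activity Tibble from [build_activity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  rounded <- dplyr::mutate(
    activity,
    dplyr::across(dplyr::starts_with("activity_"), ~ round_half_up(.x, 2))
  )
  readr::write_csv(rounded, path)
  invisible(path)
}
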