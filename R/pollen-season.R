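#' Classify pollen days by concentration
#'
#' Aerobiological day classes for grass pollen: `low` below 10 grains/m^3,
#' `medium` from 10 to 30 inclusive, `high` strictly above 30.
#'
#' @param concentration Numeric vector of daily concentrations, grains/m^3.
#' @param thresholds Length-2 numeric `(low_upper, medium_upper)`; the
#'   medium class is the closed interval between them.
#' @return Factor vector with levels `low`, `medium`, `high`.
#' @examples
#' classify_pollen_day(c(5, 10, 30, 31))
#' @export
classify_pollen_day <- function(concentration, thresholds = c(10, 30)) {
  if (any(concentration < 0, na.rm = TRUE)) {
    abort_npt("Pollen concentrations must be non-negative.",
              "nptpredict_input_error")
  }
  cls <- ifelse(concentration < thresholds[1], "low",
                ifelse(concentration > thresholds[2], "high", "medium"))
  factor(cls, levels = c("low", "medium", "high"))
}

# first/last day of the first/last run of >= run_length consecutive TRUEs;
# returns NULL when no qualifying run exists
run_window <- function(flag, run_length) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= run_length)
  if (length(ok) == 0L) return(NULL)
  c(start = starts[ok[1]], end = ends[ok[length(ok)]])
}

#' Derive whole-season and peak-season windows from a pollen series
#'
#' A season starts on the first day of the first run of `run_length`
#' consecutive days at or above the threshold, and ends on the last day of
#' the last such run. The whole season uses `start_threshold` (default
#' 10 grains/m^3) and the peak season `peak_threshold` (default 30); both
#' run lengths and thresholds are configurable, mirroring threshold-based
#' adaptations of the EAACI season criteria. Alternatively, fixed window
#' overrides reproduce externally published season dates verbatim.
#'
#' Daily concentrations are also classified via [classify_pollen_day()].
#'
#' @param series Tibble with `date` and `grains_m3` columns; dates must be
#'   strictly increasing.
#' @param start_threshold Whole-season threshold, grains/m^3.
#' @param peak_threshold Peak-season threshold, grains/m^3.
#' @param run_length Consecutive qualifying days required (default 3).
#' @param whole_override,peak_override Optional length-2 `Date` (or
#'   coercible) vectors; when given, returned verbatim instead of detected.
#' @return A list of class `npt_season_windows`: `whole_season` and
#'   `peak_season` (each a length-2 Date vector or `NULL` when no
#'   qualifying run exists) and `day_class`, a tibble `date`,
#'   `grains_m3`, `class`.
#' @examples
#' s <- tibble::tibble(
#'   date = as.Date("2016-05-01") + 0:10,
#'   grains_m3 = c(0, 0, 12, 15, 20, 5, 40, 50, 60, 5, 0)
#' )
#' detect_season(s)
#' @export
detect_season <- function(series,
                          start_threshold = 10,
                          peak_threshold = 30,
                          run_length = 3L,
                          whole_override = NULL,
                          peak_override = NULL) {
  if (nrow(series) == 0L) {
    abort_npt("Pollen series is empty.", "nptpredict_input_error")
  }
  if (is.unsorted(series$date, strictly = TRUE)) {
    abort_npt("Pollen series dates must be strictly increasing.",
              "nptpredict_input_error")
  }
  as_window <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.Date(x)
    stopifnot(length(x) == 2L, x[1] <= x[2])
    x
  }
  whole <- as_window(whole_override)
  peak <- as_window(peak_override)
  if (is.null(whole)) {
    w <- run_window(series$grains_m3 >= start_threshold, run_length)
    if (!is.null(w)) whole <- c(series$date[w["start"]], series$date[w["end"]])
  }
  if (is.null(peak)) {
    w <- run_window(series$grains_m3 >= peak_threshold, run_length)
    if (!is.null(w)) peak <- c(series$date[w["start"]], series$date[w["end"]])
  }
  day_class <- tibble::tibble(
    date = series$date,
    grains_m3 = series$grains_m3,
    class = classify_pollen_day(series$grains_m3)
  )
  structure(
    list(whole_season = whole, peak_season = peak, day_class = day_class),
    class = "npt_season_windows"
  )
}

#' @export
print.npt_season_windows <- function(x, ...) {
  fmt <- function(w) {
    if (is.null(w)) "none" else paste(format(w[1]), "to", format(w[2]))
  }
  cat("Pollen season windows\n")
  cat("  whole season:", fmt(x$whole_season), "\n")
  cat("  peak season: ", fmt(x$peak_season), "\n")
  cat("  days classified:", nrow(x$day_class), "\n")
  invisible(x)
}

#' High-pollen-day mask over a window
#'
#' Flags the dates, within a window, on which the concentration strictly
#' exceeds the high-day threshold (default 30 grains/m^3).
#'
#' @param series Tibble with `date`, `grains_m3`.
#' @param window Length-2 Date vector (inclusive), or `NULL` for the full
#'   series. A zero-length window yields an empty mask.
#' @param threshold High-day threshold, grains/m^3; strict `>` comparison.
#' @return Tibble `date`, `high` (logical), one row per series date inside
#'   the window.
#' @examples
#' s <- tibble::tibble(date = as.Date("2016-06-01") + 0:2,
#'                     grains_m3 = c(31, 30, 35))
#' high_day_mask(s)
#' @export
high_day_mask <- function(series, window = NULL, threshold = 30) {
  if (is.null(window)) {
    keep <- rep(TRUE, nrow(series))
  } else {
    window <- as.Date(window)
    if (length(window) == 0L) {
      return(tibble::tibble(date = as.Date(character()), high = logical()))
    }
    stopifnot(length(window) == 2L)
    if (window[1] < min(series$date) || window[2] > max(series$date)) {
      abort_npt("`window` extends outside the pollen series.",
                "nptpredict_input_error")
    }
    keep <- series$date >= window[1] & series$date <= window[2]
  }
  tibble::tibble(
    date = series$date[keep],
    high = series$grains_m3[keep] > threshold
  )
}

#' Plot a daily pollen series with the day-class thresholds
#'
#' @param object An `npt_pollen_series` tibble (`date`, `grains_m3`).
#' @param ... Unused.
#' @return A ggplot object with the 10 and 30 grains/m^3 class thresholds.
#' @export
autoplot.npt_pollen_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date,
                                       y = .data$grains_m3)) +
    ggplot2::geom_col(width = 1, fill = "darkolivegreen4") +
    ggplot2::geom_hline(yintercept = c(10, 30), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "grains/m³") +
    ggplot2::theme_minimal()
}

#' Serialize season windows to JSON
#'
#' @param windows An `npt_season_windows` object.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
season_windows_json <- function(windows, path = NULL) {
  payload <- list(
    whole_season = if (is.null(windows$whole_season)) NULL else
      format(windows$whole_season),
    peak_season = if (is.null(windows$peak_season)) NULL else
      format(windows$peak_season),
    n_days = nrow(windows$day_class),
    n_high_days = sum(windows$day_class$class == "high")
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
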