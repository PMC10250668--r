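#' Confusion matrix constructor
#'
#' @param tp,fn,fp,tn Non-negative counts: true positives, false
#'   negatives, false positives, true negatives.
#' @return A named list of class `npt_confusion`.
#' @examples
#' confusion_matrix(43, 18, 1, 10)
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) {
    abort_npt("Confusion counts must be non-negative.",
              "nptpredict_input_error")
  }
  structure(as.list(counts), class = "npt_confusion")
}

#' @export
print.npt_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("truth +", "truth -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Reconstruct a confusion matrix from reported sensitivity/specificity
#'
#' Given the class sizes and sensitivity/specificity in percent, recovers
#' the integer confusion matrix: `tp = round(sens/100 * n_pos)` and
#' `tn = round(spec/100 * n_neg)` with halves rounded up, complements for
#' `fn` and `fp`. This is the algebra needed to recover PPV and NPV from a
#' published ROC-table row.
#'
#' @param n_pos,n_neg Positive and negative class sizes (>= 1).
#' @param sens,spec Sensitivity and specificity, percent.
#' @return An `npt_confusion` object.
#' @examples
#' confusion_from_rates(61, 11, 70.5, 90.9)
#' @export
confusion_from_rates <- function(n_pos, n_neg, sens, spec) {
  if (n_pos < 1 || n_neg < 1) {
    abort_npt("Class sizes must be at least 1.", "nptpredict_input_error")
  }
  if (any(c(sens, spec) < 0) || any(c(sens, spec) > 100)) {
    abort_npt("Rates must be percentages in [0, 100].",
              "nptpredict_input_error")
  }
  tp <- round_half_up(sens / 100 * n_pos)
  tn <- round_half_up(spec / 100 * n_neg)
  if (tp > n_pos) { warning("tp clamped to n_pos"); tp <- n_pos }
  if (tn > n_neg) { warning("tn clamped to n_neg"); tn <- n_neg }
  confusion_matrix(tp, n_pos - tp, n_neg - tn, tn)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy in percent, rounded half-up to one decimal. Ratios with a zero
#' denominator are reported as `NA`.
#'
#' @param cm An `npt_confusion` object.
#' @param digits Decimal places (half-up); use `Inf` for unrounded values.
#' @return One-row tibble: `sens`, `spec`, `ppv`, `npv`, `accuracy`.
#' @examples
#' confusion_metrics(confusion_matrix(43, 18, 1, 10))
#' @export
confusion_metrics <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "npt_confusion"))
  tot <- cm$tp + cm$fn + cm$fp + cm$tn
  if (tot == 0) {
    abort_npt("All-zero confusion matrix.", "nptpredict_input_error")
  }
  if (cm$tp + cm$fn < 1 || cm$fp + cm$tn < 1) {
    abort_npt("Both classes must be represented.", "nptpredict_input_error")
  }
  rate <- function(num, den) {
    if (den == 0) return(NA_real_)
    v <- 100 * num / den
    if (is.finite(digits)) round_half_up(v, digits) else v
  }
  tibble::tibble(
    sens = rate(cm$tp, cm$tp + cm$fn),
    spec = rate(cm$tn, cm$tn + cm$fp),
    ppv = rate(cm$tp, cm$tp + cm$fp),
    npv = rate(cm$tn, cm$tn + cm$fn),
    accuracy = rate(cm$tp + cm$tn, tot)
  )
}

#' Combined diagnostic rule specification
#'
#' The decision rule that combines the molecular sensitization index with
#' the retrospective severity score: by default, call NPT-positive when
#' the combined Phl p 5 + Cyn d 1 IgE-specific activity is at least 7.25%
#' OR the past-season severity VAS is at least 7. Both comparisons are
#' inclusive.
#'
#' @param activity_cutoff Activity threshold, percent (0-100).
#' @param vas_cutoff VAS threshold, 0-10.
#' @param combinator `"OR"` (either criterion suffices) or `"AND"` (both
#'   required).
#' @return A list of class `npt_rule`.
#' @examples
#' rule_spec()
#' @export
rule_spec <- function(activity_cutoff = 7.25, vas_cutoff = 7,
                      combinator = c("OR", "AND")) {
  combinator <- match.arg(combinator)
  if (activity_cutoff < 0 || activity_cutoff > 100) {
    abort_npt("`activity_cutoff` must lie in [0, 100].",
              "nptpredict_config_error")
  }
  if (vas_cutoff < 0 || vas_cutoff > 10) {
    abort_npt("`vas_cutoff` must lie in [0, 10].",
              "nptpredict_config_error")
  }
  structure(list(activity_cutoff = activity_cutoff,
                 vas_cutoff = vas_cutoff, combinator = combinator),
            class = "npt_rule")
}

#' Apply the combined rule to activity and VAS values
#'
#' Vectorized prediction: positive iff `activity >= activity_cutoff`
#' OR/AND `vas >= vas_cutoff`. When one input is missing the decision
#' falls back on the observed criterion (for OR; for AND a missing input
#' makes the prediction missing unless the observed one already decides);
#' when both are missing the prediction is missing.
#'
#' @param activity Combined IgE-specific activity, percent.
#' @param vas Severity VAS, 0-10.
#' @param rule An [rule_spec()] object.
#' @return Integer vector of 0/1 predictions (NA where undecidable).
#' @examples
#' rule_predict(c(7.25, 0, 7.24), c(0, 7, 6))
#' @export
rule_predict <- function(activity, vas, rule = rule_spec()) {
  stopifnot(inherits(rule, "npt_rule"))
  a_hit <- activity >= rule$activity_cutoff
  v_hit <- vas >= rule$vas_cutoff
  pred <- if (rule$combinator == "OR") a_hit | v_hit else a_hit & v_hit
  # exactly one criterion observed: decide on it alone
  one_obs <- xor(is.na(a_hit), is.na(v_hit))
  obs <- ifelse(is.na(a_hit), v_hit, a_hit)
  pred[one_obs] <- obs[one_obs]
  as.integer(pred)
}

#' Evaluate the combined rule on a cohort
#'
#' Applies [rule_predict()] per patient and aggregates the confusion
#' matrix and its diagnostic metrics against the NPT outcome labels.
#' Patients with undecidable predictions are dropped (and counted).
#'
#' @param data Tibble with the activity, VAS and label columns.
#' @param activity_col,vas_col,label_col Column names.
#' @param rule An [rule_spec()] object.
#' @return List with `confusion` (an `npt_confusion`), `metrics` (tibble
#'   from [confusion_metrics()]), `rule`, and `n_dropped`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 30, seed = 5))
#' act <- build_activity_table(cohort)
#' d <- dplyr::left_join(cohort, act, by = "patient_id")
#' evaluate_rule(d, "activity_phl_p_5_cyn_d_1", "vas_severity_retro")
#' @export
evaluate_rule <- function(data,
                          activity_col = "activity_phl_p_5_cyn_d_1",
                          vas_col = "vas_severity_retro",
                          label_col = "npt_positive",
                          rule = rule_spec()) {
  if (nrow(data) == 0L) {
    abort_npt("Empty cohort.", "nptpredict_input_error")
  }
  missing_cols <- setdiff(c(activity_col, vas_col, label_col), names(data))
  if (length(missing_cols) > 0L) {
    abort_npt(sprintf("Missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "nptpredict_input_error")
  }
  pred <- rule_predict(data[[activity_col]], data[[vas_col]], rule)
  y <- as.integer(data[[label_col]])
  keep <- !is.na(pred) & !is.na(y)
  cm <- confusion_matrix(
    tp = sum(pred[keep] == 1L & y[keep] == 1L),
    fn = sum(pred[keep] == 0L & y[keep] == 1L),
    fp = sum(pred[keep] == 1L & y[keep] == 0L),
    tn = sum(pred[keep] == 0L & y[keep] == 0L)
  )
  list(confusion = cm, metrics = confusion_metrics(cm), rule = rule,
       n_dropped = sum(!keep))
}
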