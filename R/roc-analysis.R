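#' Candidate cutoffs for a continuous predictor
#'
#' Midpoints between consecutive distinct sorted score values, plus one
#' sentinel cutoff below the minimum (every case called positive under the
#' "positive if score >= cutoff" rule) and one above the maximum (every
#' case called negative), so both ends of the ROC curve are reachable.
#'
#' @param scores Numeric vector.
#' @return Increasing numeric vector of cutoffs. A constant predictor
#'   yields only the two sentinels.
#' @examples
#' candidate_cutoffs(c(6.0, 6.5, 9.0))
#' @export
candidate_cutoffs <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) {
    abort_npt("No scores supplied.", "nptpredict_input_error")
  }
  v <- sort(unique(scores))
  mids <- if (length(v) >= 2L) (v[-1] + v[-length(v)]) / 2 else numeric()
  c(v[1] - 1, mids, v[length(v)] + 1)
}

#' Empirical area under the ROC curve
#'
#' The probability that a randomly chosen positive case scores above a
#' randomly chosen negative case, ties counted 0.5 — identical to the
#' trapezoidal area under the empirical ROC curve. Computed via the
#' rank-sum identity.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1 or logical); both classes required.
#' @param direction `"higher"` when large scores indicate the positive
#'   class, `"lower"` for the reverse.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_npt("Both outcome classes must be present.",
              "nptpredict_input_error")
  }
  if (direction == "lower") scores <- -scores
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil test of an AUC against 0.5
#'
#' Standard error of a nonparametric AUC by the Hanley-McNeil exponential
#' approximation and the two-sided normal p-value for the null AUC = 0.5.
#'
#' @param auc Observed AUC.
#' @param n_pos,n_neg Class sizes.
#' @return One-row tibble: `auc`, `se`, `z`, `p_value`.
#' @examples
#' auc_test(0.82, 61, 11)
#' @export
auc_test <- function(auc, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) {
    abort_npt("Class counts must be at least 1.", "nptpredict_input_error")
  }
  if (auc < 0 || auc > 1) {
    abort_npt("`auc` must lie in [0, 1].", "nptpredict_input_error")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(max(v, 0))
  z <- if (se == 0) Inf * sign(auc - 0.5) else (auc - 0.5) / se
  if (auc == 0.5) z <- 0
  tibble::tibble(auc = auc, se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

# confusion counts under "positive if score >= cutoff"
cutoff_confusion <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  c(tp = sum(pred & labels == 1L), fn = sum(!pred & labels == 1L),
    fp = sum(pred & labels == 0L), tn = sum(!pred & labels == 0L))
}

#' Optimal cutoff by the Youden index
#'
#' Evaluates every candidate cutoff (midpoints plus sentinels) under the
#' rule "positive if score >= cutoff" (direction-aware) and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1. Ties are
#' broken in favour of higher specificity, then the lower cutoff. The
#' accuracy-maximizing cutoff is reported alongside for transparency.
#'
#' @inheritParams roc_auc
#' @param criterion Cutoff selection criterion: Youden's J (default) or
#'   overall accuracy.
#' @return One-row tibble: `cutoff`, `sens`, `spec`, `ppv`, `npv`
#'   (percent, half-up to 1 decimal), `youden_j`, `accuracy_cutoff`.
#' @examples
#' best_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' @export
best_cutoff <- function(scores, labels,
                        direction = c("higher", "lower"),
                        criterion = c("youden", "accuracy")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_npt("Both outcome classes must be present.",
              "nptpredict_input_error")
  }
  s <- if (direction == "lower") -scores else scores
  cands <- candidate_cutoffs(s)
  eval_one <- function(ct) {
    cm <- cutoff_confusion(s, labels, ct)
    sens <- cm["tp"] / n_pos
    spec <- cm["tn"] / n_neg
    acc <- (cm["tp"] + cm["tn"]) / (n_pos + n_neg)
    c(cutoff = ct, sens = unname(sens), spec = unname(spec),
      j = unname(sens + spec - 1), acc = unname(acc))
  }
  grid <- do.call(rbind, lapply(cands, eval_one))
  key <- if (criterion == "youden") grid[, "j"] else grid[, "acc"]
  # max criterion, then higher specificity, then lower cutoff
  ord <- order(-key, -grid[, "spec"], grid[, "cutoff"])
  pick <- grid[ord[1], ]
  cm <- cutoff_confusion(s, labels, pick["cutoff"])
  m <- confusion_metrics(confusion_matrix(cm["tp"], cm["fn"],
                                          cm["fp"], cm["tn"]))
  acc_ord <- order(-grid[, "acc"], -grid[, "spec"], grid[, "cutoff"])
  cut_out <- unname(pick["cutoff"])
  acc_cut <- unname(grid[acc_ord[1], "cutoff"])
  if (direction == "lower") {
    cut_out <- -cut_out
    acc_cut <- -acc_cut
  }
  tibble::tibble(
    cutoff = cut_out, sens = m$sens, spec = m$spec,
    ppv = m$ppv, npv = m$npv,
    youden_j = unname(pick["j"]),
    accuracy_cutoff = acc_cut
  )
}

#' ROC summary for one predictor
#'
#' AUC with Hanley-McNeil inference plus the Youden-optimal cutoff and its
#' diagnostic metrics, in the layout of a ROC results table row.
#'
#' @inheritParams roc_auc
#' @param predictor Label for the predictor.
#' @return One-row tibble: `predictor`, `auc`, `auc_se`, `auc_p`,
#'   `cutoff`, `sens`, `spec`, `ppv`, `npv`, `youden_j`, `direction`,
#'   `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_summary <- function(scores, labels, predictor = "score",
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  s <- scores[keep]; y <- as.integer(labels[keep])
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  degenerate <- length(unique(s)) < 2L
  a <- roc_auc(s, y, direction)
  at <- auc_test(a, n_pos, n_neg)
  bc <- best_cutoff(s, y, direction)
  tibble::tibble(
    predictor = predictor,
    auc = a, auc_se = at$se, auc_p = at$p_value,
    cutoff = bc$cutoff, sens = bc$sens, spec = bc$spec,
    ppv = bc$ppv, npv = bc$npv, youden_j = bc$youden_j,
    direction = direction, n_pos = n_pos, n_neg = n_neg,
    degenerate = degenerate
  )
}

#' ROC table over a set of predictors
#'
#' Computes one ROC summary row per predictor column against a common
#' binary outcome, the layout used for sensitization and symptom-score
#' predictor comparisons.
#'
#' @param data Tibble holding predictor columns and the outcome.
#' @param predictors Character vector of predictor column names; defaults
#'   to every `activity_`, `sige_`, `spt_` and VAS-derived column present.
#' @param label_col Name of the 0/1 outcome column.
#' @return Tibble with one [roc_summary()] row per predictor.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 40, seed = 2))
#' roc_table(cohort, c("spt_timothy", "sige_phl_p_5"), "npt_positive")
#' @export
roc_table <- function(data, predictors = NULL, label_col = "npt_positive") {
  if (is.null(predictors)) {
    predictors <- grep("^(activity_|sige_|spt_|vas_)|_max$|_cv$",
                       names(data), value = TRUE)
  }
  missing_cols <- setdiff(c(predictors, label_col), names(data))
  if (length(missing_cols) > 0L) {
    abort_npt(sprintf("Missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "nptpredict_input_error")
  }
  purrr::map_dfr(
    predictors,
    function(p) roc_summary(data[[p]], data[[label_col]], predictor = p)
  )
}

#' Empirical ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return Tibble of class `npt_roc_curve`: `cutoff`, `sens`, `spec`,
#'   `fpr` (1 - specificity), ordered along the curve.
#' @export
roc_curve_points <- function(scores, labels,
                             direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  s <- if (direction == "lower") -scores else scores
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  cands <- candidate_cutoffs(s)
  rows <- purrr::map_dfr(cands, function(ct) {
    cm <- cutoff_confusion(s, labels, ct)
    tibble::tibble(cutoff = if (direction == "lower") -ct else ct,
                   sens = cm[["tp"]] / n_pos,
                   spec = cm[["tn"]] / n_neg)
  })
  rows$fpr <- 1 - rows$spec
  out <- dplyr::arrange(rows, .data$fpr, .data$sens)
  class(out) <- c("npt_roc_curve", class(out))
  out
}

#' Plot an empirical ROC curve
#'
#' @param object An `npt_roc_curve` tibble from [roc_curve_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.npt_roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$sens)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname cohort_io
#' @param roc ROC table tibble from [roc_table()].
#' @export
write_roc_csv <- function(roc, path) {
  readr::write_csv(roc, path)
  invisible(path)
}
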