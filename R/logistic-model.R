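#' Binary logistic regression with Wald inference
#'
#' Maximum-likelihood fit of a binary logistic model by Newton-Raphson on
#' the log-likelihood (the "enter" method: all listed predictors enter
#' simultaneously). Standard errors come from the inverse observed
#' information; per-term Wald chi-squared statistics are `(B/SE)^2` with
#' 1 df, and odds-ratio confidence intervals are `exp(B +/- 1.96 SE)`.
#'
#' Convergence requires the maximum absolute score below `score_tol` or a
#' maximum parameter change below `step_tol` within `max_iter` iterations.
#' Quasi-complete separation is reported as an error (class
#' `nptpredict_separation_error`) when the fit fails to converge or any
#' coefficient diverges beyond `separation_bound`.
#'
#' @param data Tibble holding the outcome and predictor columns.
#' @param outcome Name of the 0/1 outcome column.
#' @param predictors Character vector of predictor column names.
#' @param max_iter,score_tol,step_tol Newton-Raphson controls.
#' @param separation_bound Absolute coefficient value treated as evidence
#'   of separation (log-odds units).
#' @return An object of class `npt_logit`: coefficient table, fitted
#'   probabilities, log-likelihoods, convergence info.
#' @examples
#' d <- tibble::tibble(x = c(0, 0, 1, 1, 0, 1, 1, 0),
#'                     y = c(0, 0, 1, 0, 1, 1, 1, 0))
#' fit <- fit_logistic(d, "y", "x")
#' tidy(fit)
#' @export
fit_logistic <- function(data, outcome, predictors,
                         max_iter = 25L, score_tol = 1e-8,
                         step_tol = 1e-10, separation_bound = 15) {
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols) > 0L) {
    abort_npt(sprintf("Missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")),
              "nptpredict_input_error")
  }
  keep <- stats::complete.cases(data[, c(outcome, predictors)])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) {
    abort_npt("Outcome must be coded 0/1.", "nptpredict_input_error")
  }
  if (length(unique(y)) < 2L) {
    abort_npt("Outcome must contain both classes.",
              "nptpredict_input_error")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    abort_npt("More parameters than observations.",
              "nptpredict_input_error")
  }

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    if (max(abs(score)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      abort_npt("Singular information matrix: collinear design.",
                "nptpredict_singular_error")
    }
    beta <- beta + step
    if (max(abs(step)) < step_tol) { converged <- TRUE; break }
  }
  if (!converged || any(abs(beta) > separation_bound)) {
    abort_npt(
      "Logistic fit did not converge (likely complete or quasi-complete separation).",
      "nptpredict_separation_error"
    )
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  vcov_mat <- solve(info)
  se <- sqrt(diag(vcov_mat))
  wald <- (beta / se)^2
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  pbar <- mean(y)
  ll0 <- sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar)

  coef_tbl <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    wald = unname(wald),
    df = 1L,
    p_value = stats::pchisq(unname(wald), df = 1, lower.tail = FALSE),
    odds_ratio = exp(unname(beta)),
    or_ci_low = exp(unname(beta) - 1.96 * unname(se)),
    or_ci_high = exp(unname(beta) + 1.96 * unname(se))
  )
  structure(
    list(
      coefficients = coef_tbl,
      vcov = vcov_mat,
      fitted = mu,
      y = y,
      design = X,
      outcome = outcome,
      predictors = predictors,
      log_lik = ll,
      null_log_lik = ll0,
      n = n,
      converged = converged,
      n_iter = iter
    ),
    class = "npt_logit"
  )
}

#' @export
print.npt_logit <- function(x, ...) {
  cat(sprintf("Logistic regression: %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("n = %d, log-likelihood = %.4f (null %.4f), %d iterations\n",
              x$n, x$log_lik, x$null_log_lik, x$n_iter))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient table of a logistic fit
#'
#' @param x An `npt_logit` object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std_error`, `wald`, `df`,
#'   `p_value`, `odds_ratio`, `or_ci_low`, `or_ci_high`.
#' @export
tidy.npt_logit <- function(x, ...) {
  x$coefficients
}

#' Model-level summary of a logistic fit
#'
#' @param x An `npt_logit` object.
#' @param ... Unused.
#' @return One-row tibble: log-likelihoods, likelihood-ratio chi-squared
#'   with df and p, Nagelkerke R-squared, classification accuracy at the
#'   0.5 threshold, `n`, convergence info.
#' @export
glance.npt_logit <- function(x, ...) {
  chi2 <- model_chi2(x)
  tibble::tibble(
    log_lik = x$log_lik,
    null_log_lik = x$null_log_lik,
    model_chi2 = chi2$chi2,
    df = chi2$df,
    p_value = chi2$p_value,
    nagelkerke_r2 = nagelkerke_r2(x),
    accuracy = accuracy_at_half(x),
    n = x$n,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Nagelkerke's R-squared
#'
#' Cox-Snell `R2_CS = 1 - exp(2 (LL0 - LL1) / n)` rescaled by its maximum
#' attainable value, `R2_N = R2_CS / (1 - exp(2 LL0 / n))`.
#'
#' @param fit An `npt_logit` object.
#' @return Proportion in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "npt_logit"))
  if (fit$log_lik < fit$null_log_lik - 1e-8) {
    abort_npt("Fitted log-likelihood below the null: optimizer failure.",
              "nptpredict_fit_error")
  }
  r2_cs <- 1 - exp(2 * (fit$null_log_lik - fit$log_lik) / fit$n)
  r2_max <- 1 - exp(2 * fit$null_log_lik / fit$n)
  min(1, max(0, r2_cs / r2_max))
}

#' Likelihood-ratio chi-squared of a logistic model
#'
#' `-2 (LL0 - LL1)` against the intercept-only model, with one degree of
#' freedom per non-intercept predictor.
#'
#' @param fit An `npt_logit` object.
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
model_chi2 <- function(fit) {
  stopifnot(inherits(fit, "npt_logit"))
  chi2 <- max(0, -2 * (fit$null_log_lik - fit$log_lik))
  df <- length(fit$predictors)
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Classification accuracy at the 0.5 probability threshold
#'
#' Percent of cases whose fitted probability, dichotomized at 0.5
#' (`>= 0.5` predicts the positive class), matches the observed outcome.
#' Half-up rounding to one decimal.
#'
#' @param fit An `npt_logit` object.
#' @param digits Decimal places; `Inf` for unrounded.
#' @return Accuracy in percent.
#' @export
accuracy_at_half <- function(fit, digits = 1) {
  stopifnot(inherits(fit, "npt_logit"))
  acc <- 100 * mean((fit$fitted >= 0.5) == (fit$y == 1))
  if (is.finite(digits)) round_half_up(acc, digits) else acc
}

#' Predicted probability from coefficients
#'
#' Inverse-logit of the linear predictor built from a named coefficient
#' vector (the intercept named `(Intercept)`) and matching predictor
#' values.
#'
#' @param coefficients Named numeric vector of log-odds coefficients.
#' @param values Named numeric vector, or a data frame with one column per
#'   non-intercept coefficient.
#' @return Probability vector.
#' @examples
#' predict_probability(
#'   c(`(Intercept)` = -5.300, vas = 0.886, activity = 0.209),
#'   c(vas = 7, activity = 7.25)
#' )
#' @export
predict_probability <- function(coefficients, values) {
  terms <- setdiff(names(coefficients), "(Intercept)")
  if (is.data.frame(values)) {
    if (!all(terms %in% names(values))) {
      abort_npt("`values` lacks columns for some coefficients.",
                "nptpredict_input_error")
    }
    lin <- as.matrix(values[, terms, drop = FALSE]) %*%
      coefficients[terms]
  } else {
    if (!all(terms %in% names(values))) {
      abort_npt("`values` must be named to match the coefficients.",
                "nptpredict_input_error")
    }
    lin <- sum(coefficients[terms] * values[terms])
  }
  intercept <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else {
    0
  }
  stats::plogis(drop(lin) + intercept)
}

#' Odds ratio with Wald confidence interval from a coefficient
#'
#' `exp(B)` with the 95% Wald interval `exp(B +/- 1.96 SE)`, the
#' arithmetic used to report logistic coefficients as odds ratios.
#'
#' @param estimate Log-odds coefficient B.
#' @param std_error Its standard error.
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return One-row tibble: `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' wald_or_ci(0.886, 0.334)
#' @export
wald_or_ci <- function(estimate, std_error, z = 1.96) {
  if (any(std_error < 0)) {
    abort_npt("`std_error` must be non-negative.", "nptpredict_input_error")
  }
  tibble::tibble(
    odds_ratio = exp(estimate),
    ci_low = exp(estimate - z * std_error),
    ci_high = exp(estimate + z * std_error)
  )
}

#' Box-Tidwell check of linearity in the logit
#'
#' Augments the logistic model with `x * ln(x)` terms for each continuous
#' predictor (all at once, the standard construction) and reports the Wald
#' p-value of each augmentation term: a small p-value flags departure from
#' linearity of that predictor's effect on the logit scale.
#'
#' Continuous predictors must be strictly positive; where zeros occur a
#' constant `shift` is added before taking logs.
#'
#' @inheritParams fit_logistic
#' @param continuous Character vector of continuous predictors to check
#'   (default: all `predictors`).
#' @param shift Added to a predictor containing zeros (default 0.5, half
#'   of the smallest score increment on the integer scales used here).
#' @return Tibble: `term`, `estimate`, `std_error`, `wald`, `p_value` for
#'   the augmentation terms only, plus the full augmented fit as
#'   attribute `"fit"`.
#' @export
box_tidwell <- function(data, outcome, predictors,
                        continuous = predictors, shift = 0.5) {
  stopifnot(all(continuous %in% predictors))
  aug <- data
  aug_terms <- character()
  for (v in continuous) {
    x <- aug[[v]]
    if (any(x < 0, na.rm = TRUE)) {
      abort_npt(sprintf("`%s` must be non-negative for Box-Tidwell.", v),
                "nptpredict_input_error")
    }
    if (any(x == 0, na.rm = TRUE)) x <- x + shift
    if (any(x <= 0, na.rm = TRUE)) {
      abort_npt(sprintf("`%s` not strictly positive after shift.", v),
                "nptpredict_input_error")
    }
    term <- paste0(v, "_xlogx")
    aug[[term]] <- x * log(x)
    aug[[v]] <- x
    aug_terms <- c(aug_terms, term)
  }
  fit <- fit_logistic(aug, outcome, c(predictors, aug_terms))
  out <- fit$coefficients[fit$coefficients$term %in% aug_terms,
                          c("term", "estimate", "std_error", "wald",
                            "p_value")]
  attr(out, "fit") <- fit
  out
}

#' @rdname cohort_io
#' @param fit An `npt_logit` object; written as a coefficient-table CSV
#'   (B, SE, Wald, df, p, odds ratio, CI bounds).
#' @export
write_logistic_csv <- function(fit, path) {
  readr::write_csv(tidy(fit), path)
  invisible(path)
}
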