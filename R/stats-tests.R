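# Exact null distribution of the Mann-Whitney U statistic (no ties):
# counts[u + 1] = number of choices of n1 ranks out of n1 + n2 whose U
# equals u. Recursion on the largest pooled observation: it is either an
# x (beats all j y's: subproblem (i-1, j), U shifted by j) or a y
# (subproblem (i, j-1), U unchanged).
mw_null_counts <- function(n1, n2) {
  f <- rep(list(1), n2 + 1)  # (0, j): point mass at U = 0
  for (i in seq_len(n1)) {
    newf <- vector("list", n2 + 1)
    newf[[1]] <- 1           # (i, 0): U = 0
    for (j in seq_len(n2)) {
      len <- i * j + 1
      a <- numeric(len); b <- numeric(len)
      prev <- f[[j + 1]]      # (i - 1, j), shifted by j
      a[seq_along(prev) + j] <- prev
      side <- newf[[j]]       # (i, j - 1)
      b[seq_along(side)] <- side
      newf[[j + 1]] <- a + b
    }
    f <- newf
  }
  f[[n2 + 1]]
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic counts pairs where an `x` observation exceeds a `y`
#' observation, with ties counted 0.5. For small tie-free samples
#' (`n1 + n2 <= exact_limit`) the p-value is exact, from the full
#' permutation null distribution of U; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_limit Largest combined sample size for the exact path.
#' @return One-row tibble: `method`, `statistic` (U for the first sample),
#'   `p_value`, `n1`, `n2`, `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort_npt("Both samples must be non-empty.", "nptpredict_input_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks for ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))

  if (!ties && n <= exact_limit) {
    counts <- mw_null_counts(n1, n2)
    total <- sum(counts)
    lower <- sum(counts[seq_len(u + 1)]) / total        # P(U <= u)
    upper <- sum(counts[(u + 1):length(counts)]) / total # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
      if (abs(u - mu) <= 0.5) z <- 0
      p <- 2 * stats::pnorm(-abs(z))
    }
    exact <- FALSE
  }
  tbl_row(method = "Mann-Whitney U", statistic = u, p_value = p,
          n1 = n1, n2 = n2, exact = exact)
}

# log hypergeometric pmf for cell `a` given margins (r1, r2, c1)
lhyper_pmf <- function(a, r1, r2, c1) {
  lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum, over all
#' tables with the observed margins, of hypergeometric probabilities no
#' larger than that of the observed table (with a small relative tolerance
#' against floating-point noise). Also returns the sample odds ratio
#' `a*d / (b*c)`.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return One-row tibble: `method`, `statistic` (odds ratio), `p_value`,
#'   `a`, `b`, `c`, `d`.
#' @examples
#' fisher_exact_2x2(39, 22, 2, 9)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_npt("Cell counts must be non-negative integers.",
              "nptpredict_input_error")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("Degenerate 2x2 table (zero margin); p = 1.")
    return(tbl_row(method = "Fisher exact", statistic = or, p_value = 1,
                   a = a, b = b, c = c, d = d))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- lhyper_pmf(support, r1, r2, c1)
  lp_obs <- lhyper_pmf(a, r1, r2, c1)
  p <- sum(exp(lp)[lp <= lp_obs + 1e-7])
  p <- min(1, p)
  tbl_row(method = "Fisher exact", statistic = or, p_value = p,
          a = a, b = b, c = c, d = d)
}

#' Yates continuity-corrected chi-squared test for a 2x2 table
#'
#' Pearson chi-squared with each `|O - E|` reduced by 0.5 (floored at
#' zero), 1 degree of freedom, upper-tail p-value.
#'
#' @inheritParams fisher_exact_2x2
#' @return One-row tibble: `method`, `statistic` (chi-squared), `p_value`,
#'   `df`, `a`, `b`, `c`, `d`.
#' @examples
#' chi2_yates_2x2(39, 22, 2, 9)
#' @export
chi2_yates_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_npt("Cell counts must be non-negative integers.",
              "nptpredict_input_error")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    abort_npt("Degenerate 2x2 table (zero margin).",
              "nptpredict_input_error")
  }
  expected <- outer(c(r1, r2), c(c1, c2)) / n
  observed <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  dev <- pmax(abs(observed - expected) - 0.5, 0)
  stat <- sum(dev^2 / expected)
  tbl_row(method = "Chi-squared (Yates)", statistic = stat,
          p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
          df = 1L, a = a, b = b, c = c, d = d)
}

#' Choose the 2x2 test the way applied reports do
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the Yates-corrected chi-squared test.
#'
#' @inheritParams fisher_exact_2x2
#' @return One-row tibble as returned by the chosen test.
#' @export
compare_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) {
    abort_npt("Empty 2x2 table.", "nptpredict_input_error")
  }
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(expected < 5)) fisher_exact_2x2(a, b, c, d)
  else chi2_yates_2x2(a, b, c, d)
}
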