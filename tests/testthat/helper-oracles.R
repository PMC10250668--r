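# Independent brute-force oracles used across the suite. These never call
# package internals for the quantity they check.

# AUC by explicit positive x negative pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# two-sided Fisher p by enumeration with stats::dhyper
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration of all label assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  lower <- mean(all_u <= u_obs + 1e-9)
  upper <- mean(all_u >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Youden-best cutoff by exhaustive search over midpoint candidates
oracle_best_j <- function(scores, labels) {
  v <- sort(unique(scores))
  cands <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  js <- vapply(cands, function(ct) {
    sens <- mean(scores[labels == 1] >= ct)
    spec <- mean(scores[labels == 0] < ct)
    sens + spec - 1
  }, numeric(1))
  max(js)
}

# tiny deterministic diary fixture: one patient per row of `vas_by_day`
make_diary <- function(vas_by_day, start = as.Date("2016-06-01")) {
  purrr::imap_dfr(vas_by_day, function(v, pid) {
    tibble::tibble(
      patient_id = pid,
      date = start + seq_along(v) - 1L,
      rtss = pmin(18L, as.integer(v) * 2L),
      csms = pmin(6, v / 2),
      vas = v
    )
  })
}
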