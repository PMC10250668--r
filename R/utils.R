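#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (2.5 -> 3),
#' the convention used throughout the reported tables, rather than the
#' IEEE banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), digits = 0)
#' round_half_up(97.727, digits = 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Run `expr` under a deterministic RNG substream derived from (seed, stage),
# restoring the caller's RNG state afterwards. Stages get well-separated
# substreams so each generator can be re-run independently.
with_substream <- function(seed, stage, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # fold the stage label into the seed; keep within 32-bit integer range
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  set.seed((as.integer(seed) %% 1000003L) * 2039L + (h %% 104729L))
  force(expr)
}

# fast one-row tibble constructor for hot paths (test statistics are
# computed in tight loops by the property suites)
tbl_row <- function(...) {
  tibble::new_tibble(list(...), nrow = 1L)
}

abort_npt <- function(msg, class) {
  rlang::abort(msg, class = c(class, "nptpredict_error"))
}

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_npt(sprintf("`%s` must be a probability in [0, 1].", name),
              "nptpredict_config_error")
  }
  invisible(x)
}
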