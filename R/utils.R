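# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; screening reports in this field
#' round half away from zero (2.375 -> 2.38). Used for every printed
#' percentage in the package.
#'
#' @param x numeric vector.
#' @param dp number of decimal places (non-negative integer).
#' @return `x` rounded to `dp` decimals, ties going away from zero.
#' @examples
#' round_half_up(2.375, 2)   # 2.38, where round() gives 2.38 or 2.37
#' round_half_up(12.5, 0)    # 13
#' @export
round_half_up <- function(x, dp = 0) {
  stopifnot(is.numeric(x), dp >= 0, dp == as.integer(dp))
  # nudge by a relative epsilon so values that are exactly representable
  # halves (12.5) round up, but float dust (4.7999999...) is untouched
  sign(x) * floor(abs(x) * 10^dp + 0.5 + 1e-9) / 10^dp
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's .Random.seed afterwards so simulation helpers do not
# perturb user code. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix for input-validation failures, so the
# CLI can map them to exit code 1.
abort_invalid <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("hdrscreen_invalid", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
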