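# Descriptive screening statistics: minimum integration rates, rounded
# proportions, exact binomial tests and Clopper-Pearson intervals.

#' Minimum integration rate of a knock-in construct
#'
#' In a pooled G0 screen the integration rate is bounded from below by
#' the number of positive pools over the number of surviving injected
#' (G0) individuals, times 100. It is a *minimum* because a single
#' positive pool may hide several independent integration events: one
#' fluorescent G1 is enough to mark the whole pool positive. At high
#' integration frequencies (every pool positive) the downward bias is
#' substantial; see [expected_minimum_rate()] for the closed-form bias.
#'
#' @param k number of positive pools (successes), `0 <= k <= n`.
#' @param n number of surviving G0 individuals (trials), `n > 0`.
#' @param dp decimal places for the reported percentage (default 2).
#' @param level confidence level for the exact Clopper-Pearson interval
#'   on the underlying proportion.
#' @return An object of class `rate_estimate`: a list with `k`, `n`,
#'   `pct` (percentage, rounded half away from zero to `dp` decimals),
#'   `ci_low`, `ci_high` (exact bounds on the proportion, not in
#'   percent), `dp`, `level`, and `lower_bound = TRUE` flagging that the
#'   estimate is a lower bound on the per-individual rate.
#' @examples
#' minimum_integration_rate(13, 271)  # 4.80%
#' minimum_integration_rate(1, 178)   # 0.56%
#' @seealso [proportion_pct()], [clopper_pearson_ci()]
#' @export
minimum_integration_rate <- function(k, n, dp = 2, level = 0.95) {
  if (!is_count(k) || !is_count(n, min = 1L) || k > n) {
    abort_invalid("need counts 0 <= k <= n with n > 0; got k = ", k, ", n = ", n)
  }
  ci <- clopper_pearson_ci(k, n, level = level)
  structure(
    list(
      k = as.integer(k), n = as.integer(n),
      pct = round_half_up(100 * k / n, dp),
      ci_low = ci[[1L]], ci_high = ci[[2L]],
      dp = as.integer(dp), level = level,
      lower_bound = TRUE
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Minimum integration rate: %s%% (%d/%d; exact %d%% CI on proportion: %.4f-%.4f)\n",
    format(x$pct, nsmall = x$dp), x$k, x$n, round(100 * x$level),
    x$ci_low, x$ci_high
  ))
  cat("Lower bound: one positive pool may contain multiple independent events.\n")
  invisible(x)
}

#' Rounded percentage of a count pair
#'
#' `100 * k / n` rounded half away from zero, as printed in screening
#' reports (canonical-integration proportions, flight-assay outcomes).
#'
#' @param k successes.
#' @param n trials, `n > 0`.
#' @param dp decimal places.
#' @return A single number, the percentage.
#' @examples
#' proportion_pct(13, 22, 0)  # 59
#' proportion_pct(1, 266, 1)  # 0.4
#' @export
proportion_pct <- function(k, n, dp = 0) {
  if (!is_count(k) || !is_count(n, min = 1L) || k > n) {
    abort_invalid("need counts 0 <= k <= n with n > 0; got k = ", k, ", n = ", n)
  }
  round_half_up(100 * k / n, dp)
}

#' Exact binomial test
#'
#' Exact test of `k` successes in `n` trials against a null proportion
#' `p0`. One-sided p-values are exact binomial tail sums. The two-sided
#' p-value uses, by default, the minimum-likelihood ("minlike")
#' definition: the sum of `P(X = j | n, p0)` over all outcomes `j` no
#' more probable than the observed `k` (with a small relative tolerance
#' for floating-point ties). This is the convention used when screening
#' reports quote "two-sided binomial test" p-values against a
#' comparator's point estimate. A "central" (doubled one-sided,
#' capped at 1) definition is available as an option.
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n trials.
#' @param p0 null proportion in `[0, 1]`.
#' @param alternative one of `"two_sided"`, `"less"`, `"greater"`.
#' @param two_sided one of `"minlike"` (default) or `"central"`;
#'   ignored for one-sided alternatives.
#' @param rel_tol relative tolerance used to treat binomial point masses
#'   as tied with `P(X = k)` in the minlike enumeration.
#' @return An object of class `binom_test_result`: list with `k`, `n`,
#'   `p0`, `alternative`, `two_sided`, and `p_value`.
#' @examples
#' exact_binomial_test(3, 184, 13 / 271)$p_value   # ~0.04
#' exact_binomial_test(0, 3, 13 / 22)$p_value      # ~0.07
#' @export
exact_binomial_test <- function(k, n, p0,
                                alternative = c("two_sided", "less", "greater"),
                                two_sided = c("minlike", "central"),
                                rel_tol = 1e-7) {
  alternative <- match.arg(alternative)
  two_sided <- match.arg(two_sided)
  if (!is_count(k) || !is_count(n, min = 1L) || k > n) {
    abort_invalid("need counts 0 <= k <= n; got k = ", k, ", n = ", n)
  }
  if (!is_prob(p0)) abort_invalid("p0 must be a probability in [0, 1]")

  p_less <- stats::pbinom(k, n, p0)
  p_greater <- 1 - stats::pbinom(k - 1, n, p0)
  p_value <- switch(alternative,
    less = p_less,
    greater = p_greater,
    two_sided = {
      if (p0 == 0) {
        # degenerate null: only k = 0 is possible
        if (k == 0) 1 else 0
      } else if (p0 == 1) {
        if (k == n) 1 else 0
      } else if (two_sided == "central") {
        min(1, 2 * min(p_less, p_greater))
      } else {
        d <- stats::dbinom(0:n, n, p0)
        sum(d[d <= d[k + 1L] * (1 + rel_tol)])
      }
    }
  )
  structure(
    list(
      k = as.integer(k), n = as.integer(n), p0 = p0,
      alternative = alternative,
      two_sided = if (alternative == "two_sided") two_sided else NA_character_,
      p_value = min(1, p_value)
    ),
    class = "binom_test_result"
  )
}

#' @export
print.binom_test_result <- function(x, ...) {
  side <- if (x$alternative == "two_sided") {
    sprintf("two-sided (%s)", x$two_sided)
  } else {
    x$alternative
  }
  cat(sprintf(
    "Exact binomial test: %d/%d vs p0 = %.4g, %s, p = %.4g\n",
    x$k, x$n, x$p0, side, x$p_value
  ))
  invisible(x)
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' Central exact interval via the beta-quantile identity; coverage is at
#' least `level` by construction for every true proportion.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' clopper_pearson_ci(2, 174)
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (!is_count(k) || !is_count(n, min = 1L) || k > n) {
    abort_invalid("need counts 0 <= k <= n with n >= 1")
  }
  if (!is_prob(level) || level <= 0 || level >= 1) {
    abort_invalid("level must be in (0, 1)")
  }
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Compare construct positivity against a reference construct
#'
#' Aggregates a pool-level experiment table per construct (positive
#' pools `k`, surviving G0 `n`) and tests every non-reference construct
#' against the reference's point estimate `k_ref / n_ref` with the exact
#' two-sided binomial test. This mirrors the screening convention of
#' taking the best-performing construct as the comparator.
#'
#' Per-construct count pairs can also be supplied directly as a data
#' frame with columns `construct`, `k`, `n` (one row per construct),
#' which is what the canonical-integration comparisons use.
#'
#' @param table an experiment table as returned by
#'   [read_experiment_table()] or [simulate_experiment()] (pool-level,
#'   columns `construct`, `pool_id`, `positive`, `g0_survivors_total`),
#'   or a per-construct data frame with columns `construct`, `k`, `n`.
#' @param reference construct id used as the comparator.
#' @param dp decimal places for the reported percentage column.
#' @param two_sided two-sided convention passed to
#'   [exact_binomial_test()].
#' @return A data frame with one row per non-reference construct:
#'   `construct`, `k`, `n`, `pct`, `ci_low`, `ci_high`, `p0`, `p_value`.
#'   The null proportion `p0` is the reference's `k/n`.
#' @examples
#' counts <- data.frame(
#'   construct = c("A", "B"), k = c(13, 3), n = c(271, 184)
#' )
#' compare_constructs(counts, reference = "A")
#' @export
compare_constructs <- function(table, reference, dp = 2,
                               two_sided = c("minlike", "central")) {
  two_sided <- match.arg(two_sided)
  counts <- if (all(c("k", "n") %in% names(table))) {
    if (anyDuplicated(table$construct)) {
      abort_invalid("per-construct count table must have one row per construct")
    }
    table[, c("construct", "k", "n")]
  } else {
    aggregate_experiment(table)[, c("construct", "k", "n")]
  }
  if (!reference %in% counts$construct) {
    abort_invalid("reference construct '", reference, "' not present in table")
  }
  ref <- counts[counts$construct == reference, ]
  p0 <- ref$k / ref$n
  if (ref$k == 0) {
    warning("reference construct has k = 0: all tests are degenerate (p0 = 0)",
            call. = FALSE)
  }
  others <- counts[counts$construct != reference, , drop = FALSE]
  rows <- lapply(seq_len(nrow(others)), function(i) {
    k <- others$k[i]; n <- others$n[i]
    tst <- exact_binomial_test(k, n, p0, "two_sided", two_sided = two_sided)
    ci <- clopper_pearson_ci(k, n)
    data.frame(
      construct = others$construct[i], k = k, n = n,
      pct = round_half_up(100 * k / n, dp),
      ci_low = ci[[1L]], ci_high = ci[[2L]],
      p0 = p0, p_value = tst$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-construct summary of a pool-level experiment table
#'
#' @param table pool-level experiment table (see
#'   [read_experiment_table()] for the column contract).
#' @param dp decimal places for the minimum-rate percentage.
#' @param level confidence level for the exact interval.
#' @return Data frame, one row per construct: `construct`, `donor_type`,
#'   `n_pools`, `k` (positive pools), `n` (G0 survivors), `pct`
#'   (minimum integration rate), `ci_low`, `ci_high`.
#' @export
aggregate_experiment <- function(table, dp = 2, level = 0.95) {
  validate_experiment_table(table)
  split_rows <- split(table, table$construct)
  rows <- lapply(split_rows, function(df) {
    n_surv <- unique(df$g0_survivors_total)
    if (length(n_surv) != 1L) {
      abort_invalid("construct '", df$construct[1L],
                    "': g0_survivors_total must be constant within construct")
    }
    k <- sum(df$positive)
    est <- minimum_integration_rate(k, n_surv, dp = dp, level = level)
    data.frame(
      construct = df$construct[1L],
      donor_type = if ("donor_type" %in% names(df)) df$donor_type[1L] else NA_character_,
      n_pools = nrow(df), k = k, n = as.integer(n_surv),
      pct = est$pct, ci_low = est$ci_low, ci_high = est$ci_high,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # preserve first-appearance order of constructs
  out <- out[match(unique(table$construct), out$construct), , drop = FALSE]
  rownames(out) <- NULL
  out
}
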