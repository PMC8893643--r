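test_that("pool positivity probability has the closed form and is monotone", {
  expect_equal(pool_positive_prob(0, 20), 0)
  expect_equal(pool_positive_prob(1, 20), 1)
  expect_equal(pool_positive_prob(0.05, 20), 1 - 0.95^20, tolerance = 1e-12)
  # strict monotonicity checked below saturation (near p = 1 the value
  # is 1 to double precision)
  p <- seq(0.001, 0.6, by = 0.001)
  expect_true(all(diff(pool_positive_prob(p, 20)) > 0))
  q10 <- pool_positive_prob(p, 10); q30 <- pool_positive_prob(p, 30)
  expect_true(all(q30 > q10))
  # detection thins the per-founder rate
  expect_equal(pool_positive_prob(0.1, 20, d = 0.5),
               pool_positive_prob(0.05, 20), tolerance = 1e-12)
})

test_that("pool log-likelihood matches the binomial pmf for equal pools", {
  pools <- equal_pools(k = 5, K = 12, n = 20)
  for (p in c(0.005, 0.02, 0.08)) {
    q <- pool_positive_prob(p, 20)
    expect_equal(
      pool_loglik(p, pools),
      dbinom(5, 12, q, log = TRUE) - log(choose(12, 5)),
      tolerance = 1e-9
    )
  }
  # certainty: all pools negative at p = 0 has log-likelihood 0
  expect_equal(pool_loglik(0, equal_pools(0, 10)), 0)
  # an observed positive pool is impossible at p = 0
  expect_equal(pool_loglik(0, equal_pools(3, 10)), -Inf)
  # 13 positive pools are vastly less likely at p = 1e-4 than at 0.05
  pools13 <- equal_pools(13, 13)
  expect_lt(pool_loglik(1e-4, pools13), pool_loglik(0.05, pools13))
})

test_that("MLE agrees with the closed-form inversion and the grid max", {
  for (cfg in list(c(3, 9), c(8, 16), c(8, 17))) {
    pools <- equal_pools(cfg[1], cfg[2], n = 20)
    fit <- estimate_individual_rate(pools)
    expect_equal(fit$p_mle, 1 - (1 - cfg[1] / cfg[2])^(1 / 20), tolerance = 1e-12)
    # grid maximum sits within one grid step of the closed form
    expect_lt(abs(fit$p_grid[which.max(fit$loglik)] - fit$p_mle), 2e-4)
  }
  # heterogeneous pools: compare to an independent 1-d optimisation
  pools <- data.frame(
    n_founders = c(20L, 20L, 14L, 25L, 18L),
    positive = c(TRUE, FALSE, TRUE, FALSE, FALSE)
  )
  fit <- suppressWarnings(estimate_individual_rate(pools))
  direct <- optimize(function(p) pool_loglik(p, pools), c(0, 0.5),
                     maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(fit$p_mle, direct, tolerance = 1e-6)
})

test_that("boundary data yield one-sided intervals with sensible bounds", {
  all_pos <- estimate_individual_rate(equal_pools(13, 13, n = 20))
  expect_equal(all_pos$p_mle, 1)
  expect_equal(all_pos$one_sided, "lower")
  expect_equal(all_pos$interval[2], 1)
  expect_gt(all_pos$interval[1], 0.048)
  # every reported construction puts the lower bound above 0.048
  expect_true(all(all_pos$intervals$lower > 0.048))

  none <- lapply(c(5, 10, 20), function(K) {
    estimate_individual_rate(equal_pools(0, K, n = 20))
  })
  expect_true(all(sapply(none, function(f) f$p_mle) == 0))
  expect_true(all(sapply(none, function(f) f$one_sided) == "upper"))
  uppers <- sapply(none, function(f) f$interval[2])
  expect_true(all(diff(uppers) < 0))  # more negative pools tighten the bound
})

test_that("interval construction is consistent across methods", {
  pools <- equal_pools(8, 17, n = 20)
  fit <- estimate_individual_rate(pools)
  iv <- fit$intervals
  # exact Clopper-Pearson inversion is the widest, mid-p sits inside it
  exact <- iv[iv$method == "exact", ]
  midp <- iv[iv$method == "midp", ]
  expect_lte(exact$lower, midp$lower)
  expect_gte(exact$upper, midp$upper)
  # all intervals contain the MLE
  expect_true(all(iv$lower <= fit$p_mle & fit$p_mle <= iv$upper))
})

test_that("compatibility intervals recover a true simulated rate", {
  # deterministic check via enumeration over the number of positive
  # pools (the sufficient statistic for equal pools), plus a small
  # simulation round-trip through simulate_experiment
  p_true <- 0.05; K <- 15L; n <- 20L
  q <- pool_positive_prob(p_true, n)
  cover <- sapply(0:K, function(x) {
    f <- estimate_individual_rate(equal_pools(x, K, n))
    f$interval[1] <= p_true && p_true <= f$interval[2]
  })
  exact_coverage <- sum(dbinom(0:K, K, q) * cover)
  expect_gt(exact_coverage, 0.92)

  des <- sim_design(n_constructs = 100, pools_per_construct = K,
                    founders_per_pool = n, p_individual = p_true, seed = 91)
  tab <- simulate_experiment(des)
  hits <- sapply(split(tab, tab$construct), function(df) {
    f <- estimate_individual_rate(df)
    f$interval[1] <= p_true && p_true <= f$interval[2]
  })
  expect_gt(mean(hits), 0.85)
})

test_that("overlap assessment separates incompatible rates and not identical ones", {
  a <- estimate_individual_rate(equal_pools(3, 9, n = 20))
  a2 <- estimate_individual_rate(equal_pools(3, 9, n = 20))
  same <- overlap_assessment(a, a2)
  expect_true(same$intervals_overlap)
  expect_equal(same$overlap_interval, a$interval)

  b <- estimate_individual_rate(equal_pools(13, 13, n = 20))
  apart <- overlap_assessment(b, a)
  expect_false(apart$intervals_overlap)
  expect_lt(apart$max_prob_a_under_b, 0.01)

  # constructs simulated at one shared rate overlap in most replicates
  des <- sim_design(n_constructs = 60, pools_per_construct = 12,
                    p_individual = 0.04, seed = 7)
  tab <- simulate_experiment(des)
  fits <- lapply(split(tab, tab$construct), estimate_individual_rate)
  pairs <- matrix(sample(seq_along(fits)), ncol = 2)
  agree <- apply(pairs, 1, function(ij) {
    overlap_assessment(fits[[ij[1]]], fits[[ij[2]]])$intervals_overlap
  })
  expect_gt(mean(agree), 0.85)
})

test_that("expected minimum rate is conservative with ratio 1 at the origin", {
  des <- sim_design(founders_per_pool = 20L, p_individual = 0.1)
  expect_equal(expected_minimum_rate(0.10, des),
               100 * (1 - 0.9^20) / 20, tolerance = 1e-12)
  p <- seq(0.001, 1, by = 0.001)
  emr <- expected_minimum_rate(p, des)
  expect_true(all(emr <= 100 * p + 1e-12))
  small <- c(1e-6, 1e-5, 1e-4)
  ratio <- expected_minimum_rate(small, des) / (100 * small)
  expect_true(all(abs(ratio - 1) < 0.01))
  expect_true(all(diff(ratio) < 0))  # bias grows with p
})
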