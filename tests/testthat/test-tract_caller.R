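fixture_events <- function() {
  mapA <- read_snp_map(extdata("snp_map_190recoded_synthetic.tsv"))
  mapB <- read_snp_map(extdata("snp_map_234recoded_synthetic.tsv"))
  callsA <- read_conversion_calls(extdata("conversion_calls_190recoded_synthetic.tsv"))
  callsB <- read_conversion_calls(extdata("conversion_calls_234recoded_synthetic.tsv"))
  list(mapA = mapA, mapB = mapB, callsA = callsA, callsB = callsB,
       events = c(call_events(callsA, mapA), call_events(callsB, mapB)))
}

test_that("packaged fixture events classify with the reported directions and extents", {
  fx <- fixture_events()
  ev <- fx$events

  bi_small <- ev[["ev_bi_94_149"]]
  expect_equal(bi_small$direction, "bidirectional")
  expect_equal(bi_small$mechanism, "sdsa_two_ended_or_hj")
  expect_equal(bi_small$extent_5p_min, 94)
  expect_equal(bi_small$extent_3p_min, 149)

  bi_large <- ev[["ev_bi_725_16"]]
  expect_equal(bi_large$direction, "bidirectional")
  expect_equal(bi_large$extent_5p_min, 725)
  expect_equal(bi_large$extent_3p_min, 16)

  # a unidirectional tract whose end is censored between 220 and 319 bp
  uni <- ev[["ev_uni5_220"]]
  expect_equal(uni$direction, "uni_5p")
  expect_equal(uni$mechanism, "sdsa_one_ended")
  expect_equal(c(uni$extent_5p_min, uni$extent_5p_max), c(220, 319))
  expect_equal(c(uni$extent_3p_min, uni$extent_3p_max), c(0, 0))

  non <- ev[["ev_non_a"]]
  expect_equal(non$direction, "non_conversion")
  expect_equal(non$mechanism, "none")
  expect_equal(non$extent_5p_min + non$extent_3p_min, 0)

  expect_true(all(vapply(ev, `[[`, logical(1), "continuous")))
})

test_that("fixture aggregate is 60% unidirectional, 20% non, 20% bidirectional", {
  fx <- fixture_events()
  agg <- aggregate_events(fx$events)
  expect_equal(agg$n_events, 10L)
  d <- agg$by_direction
  expect_equal(d$pct[d$direction == "unidirectional_any"], 60)
  expect_equal(d$pct[d$direction == "non_conversion"], 20)
  expect_equal(d$pct[d$direction == "bidirectional"], 20)
  m <- agg$by_mechanism
  expect_equal(m$count[m$mechanism == "sdsa_one_ended"], 6L)
  expect_equal(m$count[m$mechanism == "sdsa_two_ended_or_hj"], 2L)
  expect_equal(agg$max_extent_5p, 725)
  expect_equal(agg$n_discontinuous, 0L)
})

test_that("classification matches the brute-force scanner on random instances", {
  set.seed(77)
  n_cases <- 2000L
  for (i in seq_len(n_cases)) {
    n5 <- sample(0:6, 1); n3 <- sample(0:6, 1)
    if (n5 + n3 == 0) n3 <- 1
    map <- generate_snp_map(snp_map_spec(n5, n3, guard_bp = 10,
                                         arm_len_bp = 400,
                                         seed = 10000 + i))
    calls <- data.frame(
      offset = map$offset,
      state = sample(c("donor", "wildtype", "unread"), nrow(map),
                     replace = TRUE, prob = c(0.4, 0.4, 0.2))
    )
    if (all(calls$state == "unread")) calls$state[1] <- "wildtype"
    got <- call_event(calls, map)
    want <- brute_force_call(calls, map)
    expect_equal(got$direction, want$direction, info = paste("case", i))
    expect_equal(
      c(got$extent_5p_min, got$extent_5p_max, got$extent_3p_min, got$extent_3p_max),
      c(want$extent_5p_min, want$extent_5p_max, want$extent_3p_min, want$extent_3p_max),
      info = paste("case", i)
    )
    expect_equal(got$continuous, want$continuous, info = paste("case", i))
  }
})

test_that("re-calling an event is idempotent and input errors are rejected", {
  fx <- fixture_events()
  one <- fx$callsA[fx$callsA$event_id == "ev_bi_725_16", ]
  expect_identical(call_event(one, fx$mapA), call_event(one, fx$mapA))
  # call referencing an offset missing from the map
  bad <- rbind(one, data.frame(event_id = "ev_bi_725_16", offset = 9999,
                               side = "three_prime", state = "donor"))
  expect_error(call_event(bad, fx$mapA), "absent from the SNP map")
  # fully unread event is indeterminate and refuses aggregation
  blank <- transform(one, state = "unread")
  ind <- call_event(blank, fx$mapA)
  expect_equal(ind$direction, "indeterminate")
  expect_error(aggregate_events(list(ind)), "indeterminate")
  expect_error(aggregate_events(list()), "no events")
})

test_that("unread SNPs widen censoring without breaking continuity", {
  map <- data.frame(
    offset = c(-300L, -200L, -100L, 100L, 200L),
    side = rep(c("five_prime", "three_prime"), c(3, 2)),
    ref_base = "A", donor_base = "T", stringsAsFactors = FALSE
  )
  # donor at -200 with the SNP between it and the cut unread: continuous
  calls <- data.frame(offset = c(-300, -200, -100, 100, 200),
                      state = c("wildtype", "donor", "unread", "wildtype", "wildtype"))
  ev <- call_event(calls, map)
  expect_equal(ev$direction, "uni_5p")
  expect_true(ev$continuous)
  expect_equal(ev$n_unread_internal, 1L)
  expect_equal(c(ev$extent_5p_min, ev$extent_5p_max), c(200, 300))
  # same geometry with the internal SNP wildtype: discontinuous, reported
  calls2 <- transform(calls, state = replace(state, 3, "wildtype"))
  ev2 <- call_event(calls2, map)
  expect_false(ev2$continuous)
  expect_equal(aggregate_events(list(ev2))$n_discontinuous, 1L)
  # unread beyond the outermost donor does not cap the interval
  calls3 <- data.frame(offset = c(-300, -200, -100, 100, 200),
                       state = c("unread", "donor", "donor", "wildtype", "wildtype"))
  ev3 <- call_event(calls3, map)
  expect_equal(ev3$extent_5p_max, 300)  # sequenced-span boundary, not -300
})

test_that("censoring intervals always contain the simulated tract end", {
  map <- generate_snp_map(snp_map_spec(12, 12, guard_bp = 50,
                                       arm_len_bp = 1000, seed = 3))
  model <- tract_model(mean_tract_bp = 200, arm_extent_bp = 1000,
                       p_unread = 0.15)
  sim <- simulate_conversion_events(400, model, map, seed = 8)
  span <- c(-model$arm_extent_bp, model$arm_extent_bp)
  events <- call_events(sim$calls, map, sequenced_span = span)
  keep <- !vapply(events, function(e) e$direction == "indeterminate", logical(1))
  rep_tab <- censoring_interval_report(events[keep], sim$calls, map)
  truth <- sim$truth[match(rep_tab$event_id, sim$truth$event_id), ]
  true_len <- ifelse(rep_tab$side == "five_prime", truth$len_5p, truth$len_3p)
  expect_true(all(rep_tab$extent_min <= true_len + 1e-9))
  expect_true(all(true_len <= rep_tab$extent_max + 1e-9))
  expect_true(all(rep_tab$extent_min <= rep_tab$extent_max))
})

test_that("simulated direction classes are recovered when tracts hit markers", {
  map <- generate_snp_map(snp_map_spec(20, 20, guard_bp = 50,
                                       arm_len_bp = 2000, seed = 21))
  model <- tract_model(mean_tract_bp = 300, arm_extent_bp = 2000)
  sim <- simulate_conversion_events(500, model, map, seed = 22)
  events <- call_events(sim$calls, map,
                        sequenced_span = c(-2000, 2000))
  innermost5 <- min(abs(map$offset[map$offset < 0]))
  innermost3 <- min(map$offset[map$offset > 0])
  hit <- with(sim$truth,
    (len_5p == 0 | len_5p >= innermost5) & (len_3p == 0 | len_3p >= innermost3))
  got <- vapply(events, `[[`, character(1), "direction")[hit]
  expect_identical(unname(got), sim$truth$class[hit])
})
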