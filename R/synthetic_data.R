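# Synthetic experiments with the statistical structure of a pooled
# knock-in screen: founders -> pools -> G1 positivity, plus donor SNP
# maps and SDSA-style gene conversion tracts over recoded homology arms.

#' Design of a simulated pooled G0 screen
#'
#' Encodes the experiment structure the downstream analysis assumes:
#' injected survivors (G0) are crossed in pools of ~20, a pool screens
#' positive iff at least one of its founders transmits a detectable
#' integration to G1.
#'
#' @param n_constructs number of constructs to simulate.
#' @param pools_per_construct pools per construct.
#' @param founders_per_pool G0 founders per pool (default 20, the usual
#'   cage size). A vector of per-pool counts (length
#'   `pools_per_construct`) is accepted for heterogeneous pools.
#' @param p_individual per-founder probability of producing at least one
#'   detectable transgenic G1 (the underlying individual integration
#'   rate).
#' @param detection_prob probability a transgenic founder is detected by
#'   screening (default 1: every transmitting founder is seen).
#' @param mean_events_per_carrier mean number of independent integration
#'   events per integrating founder (`1 + Poisson(mean - 1)` per
#'   carrier; default 1, i.e. exactly one event each). Pool positivity
#'   is unaffected; the count is carried through as truth for bias
#'   studies.
#' @param seed integer seed making the simulated experiment reproducible.
#' @return Object of class `sim_design` (a validated list).
#' @export
sim_design <- function(n_constructs = 1L, pools_per_construct = 15L,
                       founders_per_pool = 20L, p_individual = 0.05,
                       detection_prob = 1, mean_events_per_carrier = 1,
                       seed = NULL) {
  if (!is_count(n_constructs, 1L)) abort_invalid("n_constructs must be >= 1")
  if (!is_count(pools_per_construct, 1L)) abort_invalid("pools_per_construct must be >= 1")
  ok_fpp <- is.numeric(founders_per_pool) && all(founders_per_pool >= 1) &&
    all(founders_per_pool == as.integer(founders_per_pool)) &&
    length(founders_per_pool) %in% c(1L, pools_per_construct)
  if (!ok_fpp) abort_invalid("founders_per_pool must be counts >= 1 (length 1 or one per pool)")
  if (!is_prob(p_individual)) abort_invalid("p_individual must be in [0, 1]")
  if (!is_prob(detection_prob)) abort_invalid("detection_prob must be in [0, 1]")
  if (!is.numeric(mean_events_per_carrier) || mean_events_per_carrier < 1) {
    abort_invalid("mean_events_per_carrier must be >= 1")
  }
  structure(
    list(
      n_constructs = as.integer(n_constructs),
      pools_per_construct = as.integer(pools_per_construct),
      founders_per_pool = as.integer(founders_per_pool),
      p_individual = p_individual,
      detection_prob = detection_prob,
      mean_events_per_carrier = mean_events_per_carrier,
      seed = seed
    ),
    class = "sim_design"
  )
}

#' Simulate a pooled knock-in screening experiment
#'
#' Each founder integrates independently with `p_individual`; each
#' integrating founder is detected with `detection_prob`; a pool is
#' positive iff it contains at least one detected integrating founder.
#' The per-construct G0 survivor total is taken as the founders actually
#' pooled (`sum(founders_per_pool)`), the convention under which the
#' minimum-rate estimator's bias has the closed form in
#' [expected_minimum_rate()].
#'
#' @param design a [sim_design()] object.
#' @return A pool-level experiment table (data frame) with columns
#'   `construct`, `donor_type` (`"simulated"`), `pool_id`, `n_founders`,
#'   `positive` (logical), `g0_survivors_total`, plus truth columns
#'   `n_transgenic` (integrating founders) and `n_events` (independent
#'   integration events) used only for validation studies.
#' @examples
#' simulate_experiment(sim_design(pools_per_construct = 3, seed = 1))
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    fpp <- rep(design$founders_per_pool, length.out = design$pools_per_construct)
    total <- sum(fpp)
    n_pools <- design$pools_per_construct * design$n_constructs
    n_founders <- rep(fpp, times = design$n_constructs)
    integrated <- stats::rbinom(n_pools, n_founders, design$p_individual)
    detected <- stats::rbinom(n_pools, integrated, design$detection_prob)
    events <- integrated
    if (design$mean_events_per_carrier > 1) {
      # zero-truncated Poisson count of independent events per carrier
      lam <- design$mean_events_per_carrier - 1
      extra <- vapply(integrated, function(m) {
        if (m == 0L) 0L else sum(stats::rpois(m, lam))
      }, integer(1))
      events <- integrated + extra
    }
    construct <- rep(sprintf("sim-%02d", seq_len(design$n_constructs)),
                     each = design$pools_per_construct)
    out <- data.frame(
      construct = construct, donor_type = "simulated",
      pool_id = sprintf("%s-p%05d", construct,
                        rep(seq_len(design$pools_per_construct),
                            times = design$n_constructs)),
      n_founders = n_founders, positive = detected > 0L,
      g0_survivors_total = total,
      n_transgenic = integrated, n_events = as.integer(events),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Specification of a synthetic donor SNP map
#'
#' Recoded homology arms carry engineered SNPs whose signed offsets are
#' measured from the predicted double-strand break (DSB, offset 0;
#' negative = 5' of the cut). A window of `guard_bp` immediately
#' flanking the cut is kept SNP-free on both sides, mimicking arms with
#' ~50 bp of uninterrupted perfect homology next to the cut site.
#'
#' @param n_snps_5p,n_snps_3p number of SNPs on the 5' / 3' arm.
#' @param guard_bp SNP-free window adjacent to the DSB (default 50).
#' @param arm_len_bp homology-arm length per side (default 2000).
#' @param seed integer seed.
#' @return Object of class `snp_map_spec`.
#' @export
snp_map_spec <- function(n_snps_5p, n_snps_3p, guard_bp = 50L,
                         arm_len_bp = 2000L, seed = NULL) {
  if (!is_count(n_snps_5p) || !is_count(n_snps_3p)) {
    abort_invalid("SNP counts must be non-negative integers")
  }
  if (!is_count(guard_bp) || !is_count(arm_len_bp, 1L)) {
    abort_invalid("guard_bp and arm_len_bp must be counts")
  }
  if ((n_snps_5p > 0 || n_snps_3p > 0) && guard_bp >= arm_len_bp) {
    abort_invalid("guard_bp >= arm_len_bp leaves no placeable SNP positions")
  }
  n_slots <- arm_len_bp - max(guard_bp, 1L) + 1L
  if (n_snps_5p > n_slots || n_snps_3p > n_slots) {
    abort_invalid("more SNPs requested than positions available outside the guard window")
  }
  structure(
    list(
      n_snps_5p = as.integer(n_snps_5p), n_snps_3p = as.integer(n_snps_3p),
      guard_bp = as.integer(guard_bp), arm_len_bp = as.integer(arm_len_bp),
      seed = seed
    ),
    class = "snp_map_spec"
  )
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic donor SNP map
#'
#' Draws SNP offsets uniformly without replacement from the positions
#' outside the guard window on each arm, and assigns reference/donor
#' base pairs (always differing). Deterministic under a fixed seed.
#'
#' @param spec a [snp_map_spec()].
#' @return A SNP map: data frame with columns `offset` (signed bp, DSB
#'   = 0, 5' negative), `side` (`"five_prime"` / `"three_prime"`),
#'   `ref_base`, `donor_base`, sorted by offset.
#' @examples
#' generate_snp_map(snp_map_spec(25, 25, seed = 1))
#' @export
generate_snp_map <- function(spec) {
  stopifnot(inherits(spec, "snp_map_spec"))
  with_seed(spec$seed, {
    lo <- max(spec$guard_bp, 1L)
    slots <- seq.int(lo, spec$arm_len_bp)
    draw_side <- function(n, sign) {
      if (n == 0L) return(integer(0))
      sign * sort(sample(slots, n))
    }
    off5 <- draw_side(spec$n_snps_5p, -1L)
    off3 <- draw_side(spec$n_snps_3p, 1L)
    offsets <- c(sort(off5), off3)
    n <- length(offsets)
    ref <- sample(BASES, n, replace = TRUE)
    donor <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    map <- data.frame(
      offset = offsets,
      side = ifelse(offsets < 0, "five_prime", "three_prime"),
      ref_base = ref, donor_base = unname(donor),
      stringsAsFactors = FALSE
    )
    rownames(map) <- NULL
    validate_snp_map(map)
    map
  })
}

validate_snp_map <- function(map) {
  if (!is.data.frame(map)) abort_invalid("SNP map must be a data frame")
  need <- c("offset", "side", "ref_base", "donor_base")
  miss <- setdiff(need, names(map))
  if (length(miss)) abort_invalid("SNP map missing columns: ", paste(miss, collapse = ", "))
  if (nrow(map) == 0L) return(invisible(map))
  if (anyDuplicated(map$offset)) abort_invalid("SNP offsets must be unique")
  if (any(map$offset == 0)) abort_invalid("SNP offsets must be nonzero (0 is the DSB)")
  ok_side <- ifelse(map$offset < 0, map$side == "five_prime", map$side == "three_prime")
  if (!all(ok_side)) abort_invalid("side must be five_prime for negative offsets, three_prime for positive")
  if (is.unsorted(map$offset)) abort_invalid("SNP map must be sorted by offset")
  if (any(map$ref_base == map$donor_base)) abort_invalid("donor_base must differ from ref_base")
  invisible(map)
}

#' Gene conversion tract model
#'
#' Event classes (non-conversion, unidirectional 5'/3', bidirectional)
#' and per-side tract lengths for SDSA-style repair. A converted side's
#' tract is a continuous interval anchored at the DSB whose length is
#' `1 + Geometric(1/mean_tract_bp)` (memoryless per-base extension, mean
#' `mean_tract_bp`), truncated at `arm_extent_bp`.
#'
#' Defaults reflect a screen in which 60% of characterised events were
#' unidirectional, 20% non-conversions and 20% bidirectional, with
#' tracts mostly ending within a few hundred bp of the cut on ~2 kb
#' arms.
#'
#' @param p_bidirectional probability of a bidirectional event.
#' @param p_nonconversion probability of a non-conversion event.
#' @param p_uni_5p probability, given unidirectional, that the converted
#'   side is 5' (default 0.5: no side bias assumed).
#' @param mean_tract_bp mean tract length per converted side (bp).
#' @param arm_extent_bp maximum simulated extent per side (bp).
#' @param p_unread per-SNP probability of an unreadable call (Sanger
#'   coverage gap); default 0.
#' @return Object of class `tract_model`.
#' @export
tract_model <- function(p_bidirectional = 0.2, p_nonconversion = 0.2,
                        p_uni_5p = 0.5, mean_tract_bp = 150,
                        arm_extent_bp = 2000L, p_unread = 0) {
  for (p in list(p_bidirectional, p_nonconversion, p_uni_5p, p_unread)) {
    if (!is_prob(p)) abort_invalid("tract model probabilities must be in [0, 1]")
  }
  if (p_bidirectional + p_nonconversion > 1) {
    abort_invalid("p_bidirectional + p_nonconversion must be <= 1")
  }
  if (!is.numeric(mean_tract_bp) || mean_tract_bp < 1) {
    abort_invalid("mean_tract_bp must be >= 1")
  }
  if (!is_count(arm_extent_bp, 1L)) abort_invalid("arm_extent_bp must be a count >= 1")
  structure(
    list(
      p_bidirectional = p_bidirectional, p_nonconversion = p_nonconversion,
      p_uni_5p = p_uni_5p, mean_tract_bp = mean_tract_bp,
      arm_extent_bp = as.integer(arm_extent_bp), p_unread = p_unread
    ),
    class = "tract_model"
  )
}

#' Simulate gene conversion events over a donor SNP map
#'
#' Each event draws a direction class from the model, then a tract
#' length per converted side (geometric, continuous from the DSB). A
#' SNP is called `donor` iff it lies inside the tract on its side,
#' `wildtype` otherwise; each call is independently replaced by
#' `unread` with probability `p_unread`.
#'
#' @param n_events number of events.
#' @param model a [tract_model()].
#' @param map a SNP map (see [generate_snp_map()]).
#' @param seed integer seed.
#' @return Object of class `conversion_sim`: list with `calls` (long
#'   data frame: `event_id`, `offset`, `side`, `state`), `truth` (per
#'   event: `event_id`, `class`, `len_5p`, `len_3p`), `map`, `model`.
#'   Classes are `"non_conversion"`, `"uni_5p"`, `"uni_3p"`,
#'   `"bidirectional"`; lengths are 0 on unconverted sides.
#' @examples
#' map <- generate_snp_map(snp_map_spec(10, 10, seed = 2))
#' sim <- simulate_conversion_events(5, tract_model(), map, seed = 3)
#' @export
simulate_conversion_events <- function(n_events, model, map, seed = NULL) {
  stopifnot(inherits(model, "tract_model"))
  validate_snp_map(map)
  if (!is_count(n_events, 1L)) abort_invalid("n_events must be >= 1")
  with_seed(seed, {
    p_uni <- 1 - model$p_bidirectional - model$p_nonconversion
    classes <- sample(
      c("non_conversion", "uni_5p", "uni_3p", "bidirectional"),
      n_events, replace = TRUE,
      prob = c(model$p_nonconversion,
               p_uni * model$p_uni_5p, p_uni * (1 - model$p_uni_5p),
               model$p_bidirectional)
    )
    draw_len <- function(converted) {
      len <- integer(length(converted))
      n_conv <- sum(converted)
      if (n_conv > 0L) {
        raw <- stats::rgeom(n_conv, prob = 1 / model$mean_tract_bp) + 1L
        len[converted] <- pmin(raw, model$arm_extent_bp)
      }
      len
    }
    len5 <- draw_len(classes %in% c("uni_5p", "bidirectional"))
    len3 <- draw_len(classes %in% c("uni_3p", "bidirectional"))
    truth <- data.frame(
      event_id = sprintf("ev%05d", seq_len(n_events)),
      class = classes, len_5p = len5, len_3p = len3,
      stringsAsFactors = FALSE
    )
    n_snps <- nrow(map)
    ev_idx <- rep(seq_len(n_events), each = n_snps)
    off <- rep(map$offset, times = n_events)
    inside <- ifelse(off < 0, -off <= len5[ev_idx], off <= len3[ev_idx])
    state <- ifelse(inside, "donor", "wildtype")
    if (model$p_unread > 0) {
      state[stats::runif(length(state)) < model$p_unread] <- "unread"
    }
    calls <- data.frame(
      event_id = truth$event_id[ev_idx], offset = off,
      side = rep(map$side, times = n_events), state = state,
      stringsAsFactors = FALSE
    )
    rownames(calls) <- NULL
    structure(
      list(calls = calls, truth = truth, map = map, model = model),
      class = "conversion_sim"
    )
  })
}
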