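# Independent oracles and in-code fixtures shared across test files.

# Published screening counts used throughout: positive pools / surviving
# G0 per construct, and the printed minimum rates they correspond to.
screen_counts <- function() {
  data.frame(
    construct = c("190-perfect", "64+234-perfect", "234-recoded",
                  "190-recoded", "190-recoded-ss", "190-recoded-bd",
                  "190-recoded-bs"),
    k = c(13L, 8L, 8L, 3L, 2L, 2L, 1L),
    n = c(271L, 355L, 339L, 184L, 174L, 184L, 178L),
    pct = c(4.80, 2.25, 2.36, 1.63, 1.15, 1.09, 0.56),
    stringsAsFactors = FALSE
  )
}

extdata <- function(name) {
  system.file("extdata", name, package = "hdrscreen", mustWork = TRUE)
}

# Brute-force two-sided minlike binomial p-value for small n: enumerate
# all 2^n Bernoulli outcome sequences, accumulate the pmf by success
# count, then sum masses no larger than the observed one. Deliberately
# naive and independent of the package's tail-sum implementation.
brute_force_minlike <- function(k, n, p0, rel_tol = 1e-7) {
  pmf <- numeric(n + 1L)
  for (code in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    s <- sum(bits)
    pmf[s + 1L] <- pmf[s + 1L] + p0^s * (1 - p0)^(n - s)
  }
  sum(pmf[pmf <= pmf[k + 1L] * (1 + rel_tol)])
}

# Brute-force conversion-event classifier: scans every SNP exhaustively
# with plain loops; independent of call_event's vectorised bookkeeping.
brute_force_call <- function(calls, map, sequenced_span = range(map$offset)) {
  state <- rep("unread", nrow(map))
  for (i in seq_len(nrow(map))) {
    hit <- which(calls$offset == map$offset[i])
    if (length(hit) == 1L) state[i] <- calls$state[hit]
  }
  if (all(state == "unread")) return(list(direction = "indeterminate"))
  side_scan <- function(want_5p) {
    sel <- if (want_5p) map$offset < 0 else map$offset > 0
    off <- map$offset[sel]; st <- state[sel]
    ord <- order(abs(off))          # innermost first
    off <- off[ord]; st <- st[ord]
    ext_min <- 0; continuous <- TRUE
    for (i in seq_along(off)) {
      if (st[i] == "donor") {
        if (i > 1L && any(st[seq_len(i - 1L)] == "wildtype")) continuous <- FALSE
        ext_min <- abs(off[i])
      }
    }
    ext_max <- if (ext_min == 0) 0 else {
      beyond <- which(abs(off) > ext_min & st == "wildtype")
      if (length(beyond)) min(abs(off[beyond])) else {
        abs(sequenced_span[if (want_5p) 1L else 2L])
      }
    }
    list(min = ext_min, max = ext_max, continuous = continuous)
  }
  s5 <- side_scan(TRUE); s3 <- side_scan(FALSE)
  direction <- if (s5$min > 0 && s3$min > 0) "bidirectional"
    else if (s5$min > 0) "uni_5p"
    else if (s3$min > 0) "uni_3p"
    else "non_conversion"
  list(
    direction = direction,
    extent_5p_min = s5$min, extent_5p_max = s5$max,
    extent_3p_min = s3$min, extent_3p_max = s3$max,
    continuous = s5$continuous && s3$continuous
  )
}

# Equal-pool experiment table builder: k positive pools out of K, n
# founders each, survivor total defaulting to pooled founders.
equal_pools <- function(k, K, n = 20L, survivors = K * n) {
  data.frame(
    construct = "c", donor_type = "plasmid",
    pool_id = sprintf("p%02d", seq_len(K)),
    n_founders = n, positive = seq_len(K) <= k,
    g0_survivors_total = survivors,
    stringsAsFactors = FALSE
  )
}
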