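# Classify canonical HDR events from donor-SNP conversion calls:
# direction, censored tract extents, continuity, and a repair-mechanism
# label, with aggregation across events.
#
# Coordinate convention (stated in every output header the package
# writes): offsets are signed bp anchored at the predicted DSB (blunt
# cut assumed 3 bp 5' of the PAM), negative = 5' of the cut; tract
# extents are magnitudes measured from the cut.

#' Classify one conversion event from its SNP calls
#'
#' Per side of the cut, the *observed* tract extent is censored: the
#' true tract end lies somewhere between the outermost donor-state SNP
#' (`extent_min`) and the innermost wildtype-state SNP beyond it
#' (`extent_max`), or the end of the sequenced span when no such SNP
#' exists. Unread SNPs are non-informative: they neither break
#' continuity nor bound the tract (they widen the censoring interval);
#' they are counted and reported. A side with no donor calls has both
#' extents 0. Direction follows from which sides carry donor calls; the
#' mechanism label is a pure function of direction: unidirectional
#' conversion indicates SDSA with one-ended strand invasion,
#' bidirectional conversion indicates two-ended SDSA or Holliday
#' junction formation with branch migration, and non-conversion is
#' unlabelled.
#'
#' @param calls data frame for one event with columns `offset` and
#'   `state` (`"donor"`, `"wildtype"`, `"unread"`); every offset must
#'   exist in `map`. An optional `event_id` column is carried through.
#' @param map SNP map (see [generate_snp_map()] for the contract).
#' @param sequenced_span length-2 numeric `(min_offset, max_offset)`
#'   actually covered by sequencing; defaults to the span of the map.
#'   Donor/wildtype calls outside the span are rejected.
#' @return Object of class `conversion_event`: list with `event_id`,
#'   `direction` (`"non_conversion"`, `"uni_5p"`, `"uni_3p"`,
#'   `"bidirectional"`, or `"indeterminate"` when every SNP is unread),
#'   `extent_5p_min`, `extent_5p_max`, `extent_3p_min`, `extent_3p_max`,
#'   `continuous`, `n_unread_internal` (unread SNPs inside an observed
#'   tract), and `mechanism` (`"sdsa_one_ended"`,
#'   `"sdsa_two_ended_or_hj"`, `"none"`, or `NA` if indeterminate).
#' @examples
#' map <- data.frame(
#'   offset = c(-220L, -94L, 149L, 319L),
#'   side = c("five_prime", "five_prime", "three_prime", "three_prime"),
#'   ref_base = "A", donor_base = "G"
#' )
#' calls <- data.frame(
#'   offset = c(-220, -94, 149, 319),
#'   state = c("wildtype", "donor", "donor", "wildtype")
#' )
#' call_event(calls, map)  # bidirectional, extents 94-220 and 149-319
#' @export
call_event <- function(calls, map, sequenced_span = NULL) {
  validate_snp_map(map)
  if (!is.data.frame(calls) || !all(c("offset", "state") %in% names(calls))) {
    abort_invalid("calls must be a data frame with columns offset and state")
  }
  if (!all(calls$state %in% c("donor", "wildtype", "unread"))) {
    abort_invalid("states must be donor, wildtype or unread")
  }
  missing_off <- setdiff(calls$offset, map$offset)
  if (length(missing_off)) {
    abort_invalid("calls reference offsets absent from the SNP map: ",
                  paste(missing_off, collapse = ", "))
  }
  if (anyDuplicated(calls$offset)) abort_invalid("duplicate calls for one offset")
  if (is.null(sequenced_span)) {
    sequenced_span <- range(map$offset)
  }
  if (length(sequenced_span) != 2L || sequenced_span[1L] > sequenced_span[2L]) {
    abort_invalid("sequenced_span must be (min_offset, max_offset)")
  }
  read <- calls$state != "unread"
  outside <- calls$offset < sequenced_span[1L] | calls$offset > sequenced_span[2L]
  if (any(read & outside)) {
    abort_invalid("donor/wildtype calls outside sequenced_span")
  }

  # map SNPs with no call row are treated as unread
  state <- stats::setNames(rep("unread", nrow(map)), map$offset)
  state[as.character(calls$offset)] <- calls$state

  event_id <- if ("event_id" %in% names(calls)) calls$event_id[1L] else NA_character_

  if (all(state == "unread")) {
    return(structure(
      list(event_id = event_id, direction = "indeterminate",
           extent_5p_min = NA_real_, extent_5p_max = NA_real_,
           extent_3p_min = NA_real_, extent_3p_max = NA_real_,
           continuous = NA, n_unread_internal = NA_integer_,
           mechanism = NA_character_, sequenced_span = sequenced_span),
      class = "conversion_event"
    ))
  }

  side_summary <- function(is_5p) {
    off <- map$offset[if (is_5p) map$offset < 0 else map$offset > 0]
    st <- state[as.character(off)]
    mag <- abs(off)
    boundary <- abs(sequenced_span[if (is_5p) 1L else 2L])
    donor_mag <- mag[st == "donor"]
    if (length(donor_mag) == 0L) {
      return(list(min = 0, max = 0, continuous = TRUE, unread_internal = 0L))
    }
    m <- max(donor_mag)
    wt_beyond <- mag[st == "wildtype" & mag > m]
    inner <- mag < m
    list(
      min = m,
      max = if (length(wt_beyond)) min(wt_beyond) else boundary,
      continuous = all(st[inner] != "wildtype"),
      unread_internal = sum(st[inner] == "unread")
    )
  }
  s5 <- side_summary(TRUE)
  s3 <- side_summary(FALSE)

  has5 <- s5$min > 0; has3 <- s3$min > 0
  direction <- if (!has5 && !has3) "non_conversion"
    else if (has5 && !has3) "uni_5p"
    else if (!has5 && has3) "uni_3p"
    else "bidirectional"
  mechanism <- switch(direction,
    non_conversion = "none",
    uni_5p = , uni_3p = "sdsa_one_ended",
    bidirectional = "sdsa_two_ended_or_hj"
  )
  structure(
    list(
      event_id = event_id, direction = direction,
      extent_5p_min = s5$min, extent_5p_max = s5$max,
      extent_3p_min = s3$min, extent_3p_max = s3$max,
      continuous = s5$continuous && s3$continuous,
      n_unread_internal = s5$unread_internal + s3$unread_internal,
      mechanism = mechanism, sequenced_span = sequenced_span
    ),
    class = "conversion_event"
  )
}

#' @export
print.conversion_event <- function(x, ...) {
  cat(sprintf("Conversion event %s: %s (%s)\n",
              if (is.na(x$event_id)) "<unnamed>" else x$event_id,
              x$direction,
              if (is.na(x$mechanism)) "mechanism indeterminate" else x$mechanism))
  if (x$direction != "indeterminate") {
    cat(sprintf("  5' extent: %g-%g bp; 3' extent: %g-%g bp; continuous: %s\n",
                x$extent_5p_min, x$extent_5p_max,
                x$extent_3p_min, x$extent_3p_max, x$continuous))
  }
  invisible(x)
}

#' Classify every event in a call table
#'
#' @param calls long data frame of calls with columns `event_id`,
#'   `offset`, `state` (as written by [write_conversion_calls()] or
#'   produced by [simulate_conversion_events()]).
#' @param map SNP map.
#' @param sequenced_span optional, passed to [call_event()].
#' @return List of `conversion_event` objects, one per `event_id`
#'   (first-appearance order).
#' @export
call_events <- function(calls, map, sequenced_span = NULL) {
  if (!"event_id" %in% names(calls)) abort_invalid("calls need an event_id column")
  ids <- unique(calls$event_id)
  chunks <- split(calls, factor(calls$event_id, levels = ids))
  lapply(chunks, function(chunk) {
    call_event(chunk, map, sequenced_span = sequenced_span)
  })
}

#' Aggregate classified conversion events
#'
#' Counts and percentages by direction class and mechanism, maximum
#' observed extents, and a flag for discontinuous events (tracts are
#' expected to be continuous under SDSA; discontinuity is reported, not
#' rejected).
#'
#' @param events list of `conversion_event` objects (none
#'   indeterminate).
#' @param dp decimal places for the percentage columns.
#' @return Object of class `tract_summary`: list with `n_events`,
#'   `by_direction` (data frame: direction, count, pct), `by_mechanism`,
#'   `max_extent_5p`, `max_extent_3p` (largest `extent_min` per side),
#'   `n_discontinuous`, `discontinuous_ids`.
#' @export
aggregate_events <- function(events, dp = 0) {
  if (length(events) == 0L) abort_invalid("no events to aggregate")
  if (!all(vapply(events, inherits, logical(1), "conversion_event"))) {
    abort_invalid("events must be conversion_event objects")
  }
  dirs <- vapply(events, `[[`, character(1), "direction")
  if (any(dirs == "indeterminate")) {
    abort_invalid("indeterminate events cannot be aggregated; drop or re-sequence them")
  }
  levels_dir <- c("non_conversion", "uni_5p", "uni_3p", "bidirectional")
  cnt <- table(factor(dirs, levels = levels_dir))
  n <- length(events)
  uni <- sum(cnt[c("uni_5p", "uni_3p")])
  by_direction <- data.frame(
    direction = c(levels_dir, "unidirectional_any"),
    count = c(as.integer(cnt), as.integer(uni)),
    pct = round_half_up(100 * c(as.integer(cnt), uni) / n, dp),
    stringsAsFactors = FALSE
  )
  mech <- vapply(events, `[[`, character(1), "mechanism")
  levels_mech <- c("none", "sdsa_one_ended", "sdsa_two_ended_or_hj")
  mcnt <- table(factor(mech, levels = levels_mech))
  by_mechanism <- data.frame(
    mechanism = levels_mech,
    count = as.integer(mcnt),
    pct = round_half_up(100 * as.integer(mcnt) / n, dp),
    stringsAsFactors = FALSE
  )
  disc <- vapply(events, function(e) isFALSE(e$continuous), logical(1))
  ids <- vapply(events, function(e) {
    if (is.na(e$event_id)) "<unnamed>" else e$event_id
  }, character(1))
  structure(
    list(
      n_events = n,
      by_direction = by_direction,
      by_mechanism = by_mechanism,
      max_extent_5p = max(vapply(events, `[[`, numeric(1), "extent_5p_min")),
      max_extent_3p = max(vapply(events, `[[`, numeric(1), "extent_3p_min")),
      n_discontinuous = sum(disc),
      discontinuous_ids = ids[disc]
    ),
    class = "tract_summary"
  )
}

#' @export
print.tract_summary <- function(x, ...) {
  cat(sprintf("Tract summary over %d events\n", x$n_events))
  d <- x$by_direction
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-20s %3d  (%s%%)\n", d$direction[i], d$count[i],
                format(d$pct[i])))
  }
  cat(sprintf("  max extent_min: %g bp (5'), %g bp (3')\n",
              x$max_extent_5p, x$max_extent_3p))
  cat(sprintf("  discontinuous events: %d\n", x$n_discontinuous))
  invisible(x)
}

#' Per-event, per-side censoring intervals for tract ends
#'
#' Makes the censoring explicit: on a converted side the true tract end
#' lies between the outermost converted SNP and the next unconverted
#' (wildtype) SNP beyond it, or the sequenced-span boundary; on an
#' unconverted side it lies between 0 and the innermost wildtype SNP
#' (any tract there was too short to reach a marker). Unread SNPs
#' widen the interval.
#'
#' @param events list of `conversion_event` objects, or a single one.
#' @param calls the call table the events were derived from (long
#'   format with `event_id`, `offset`, `state`); needed to locate the
#'   innermost informative SNP on unconverted sides.
#' @param map SNP map.
#' @return Data frame with one row per event and side: `event_id`,
#'   `side`, `converted`, `extent_min`, `extent_max`.
#' @export
censoring_interval_report <- function(events, calls, map) {
  if (inherits(events, "conversion_event")) events <- list(events)
  validate_snp_map(map)
  rows <- lapply(events, function(e) {
    ev_calls <- calls[calls$event_id %in% e$event_id, , drop = FALSE]
    state <- stats::setNames(rep("unread", nrow(map)), map$offset)
    state[as.character(ev_calls$offset)] <- ev_calls$state
    one_side <- function(side_label, is_5p, emin, emax) {
      off <- map$offset[if (is_5p) map$offset < 0 else map$offset > 0]
      mag <- abs(off)
      st <- state[as.character(off)]
      boundary <- abs(e$sequenced_span[if (is_5p) 1L else 2L])
      converted <- emin > 0
      if (!converted) {
        wt <- mag[st == "wildtype"]
        emin <- 0
        emax <- if (length(wt)) min(wt) else boundary
      }
      data.frame(
        event_id = e$event_id, side = side_label, converted = converted,
        extent_min = emin, extent_max = emax, stringsAsFactors = FALSE
      )
    }
    rbind(
      one_side("five_prime", TRUE, e$extent_5p_min, e$extent_5p_max),
      one_side("three_prime", FALSE, e$extent_3p_min, e$extent_3p_max)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
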