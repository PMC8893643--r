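# TSV readers/writers (tab, UTF-8, header row; TSV over CSV to avoid
# locale decimal trouble) and the JSON pipeline configuration.

HEADER_CONVENTION <- paste(
  "# coordinates: signed bp anchored at the predicted DSB (offset 0,",
  "blunt cut assumed 3 bp 5' of PAM); negative = 5' of cut"
)

#' Read a pool-level experiment table
#'
#' Expected TSV columns: `construct`, `donor_type`, `pool_id`,
#' `n_founders`, `positive` (0/1 or TRUE/FALSE), `g0_survivors_total`.
#' Validation is row-level: every failure message names the offending
#' rows. The pooled founders of a construct may total fewer than its
#' `g0_survivors_total` (not every survivor joins a pool), never more.
#'
#' @param path path to a TSV file.
#' @return Validated data frame (comment lines starting `#` ignored).
#' @export
read_experiment_table <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) abort_invalid("experiment table is empty: ", path)
  validate_experiment_table(tab)
  tab$positive <- as.logical(tab$positive)
  tab
}

validate_experiment_table <- function(tab) {
  need <- c("construct", "pool_id", "n_founders", "positive", "g0_survivors_total")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort_invalid("experiment table missing columns: ", paste(miss, collapse = ", "))
  }
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      abort_invalid(what, " in rows: ", paste(which(!ok), collapse = ", "))
    }
  }
  bad_rows(is.finite(tab$n_founders) & tab$n_founders >= 1 &
             tab$n_founders == as.integer(tab$n_founders),
           "n_founders must be integer >= 1")
  bad_rows(is.finite(tab$g0_survivors_total) & tab$g0_survivors_total >= 1,
           "g0_survivors_total must be >= 1")
  pos <- as.logical(tab$positive)
  bad_rows(!is.na(pos), "positive must be logical or 0/1")
  bad_rows(!duplicated(paste(tab$construct, tab$pool_id)),
           "duplicated (construct, pool_id)")
  for (cons in unique(tab$construct)) {
    sub <- tab[tab$construct == cons, ]
    if (sum(sub$n_founders) > sub$g0_survivors_total[1L]) {
      abort_invalid("construct '", cons,
                    "': pooled founders exceed g0_survivors_total")
    }
  }
  invisible(tab)
}

write_tsv <- function(x, path, header_lines = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(h, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pool-level experiment table as TSV
#'
#' @param table experiment table (pool-level data frame).
#' @param path output path.
#' @param seed optional seed to record in the file header.
#' @return The path, invisibly.
#' @export
write_experiment_table <- function(table, path, seed = NULL) {
  validate_experiment_table(table)
  hdr <- c(
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    sprintf("# written by hdrscreen %s",
            as.character(utils::packageVersion("hdrscreen")))
  )
  invisible(write_tsv(table, path, hdr))
}

#' Read / write a donor SNP map
#'
#' TSV columns: `offset` (signed bp, DSB = 0, 5' negative), `side`,
#' `ref_base`, `donor_base`.
#'
#' @param path file path.
#' @return `read_snp_map()`: validated SNP map data frame.
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  map <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_snp_map(map)
  map
}

#' @rdname read_snp_map
#' @param map SNP map data frame.
#' @param seed optional seed recorded in the header.
#' @export
write_snp_map <- function(map, path, seed = NULL) {
  validate_snp_map(map)
  hdr <- c(
    HEADER_CONVENTION,
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  invisible(write_tsv(map, path, hdr))
}

#' Read / write a per-event conversion call table
#'
#' Long TSV: one row per event x SNP with columns `event_id`, `offset`,
#' `side`, `state` (`donor` / `wildtype` / `unread`).
#'
#' @param path file path.
#' @return `read_conversion_calls()`: validated data frame.
#' @export
read_conversion_calls <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  calls <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("event_id", "offset", "state")
  miss <- setdiff(need, names(calls))
  if (length(miss)) abort_invalid("call table missing columns: ", paste(miss, collapse = ", "))
  if (!all(calls$state %in% c("donor", "wildtype", "unread"))) {
    abort_invalid("states must be donor, wildtype or unread")
  }
  calls
}

#' @rdname read_conversion_calls
#' @param calls call table data frame.
#' @param seed optional seed recorded in the header.
#' @export
write_conversion_calls <- function(calls, path, seed = NULL) {
  hdr <- c(
    HEADER_CONVENTION,
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  invisible(write_tsv(calls, path, hdr))
}

#' Read a pipeline configuration from JSON
#'
#' See [run_pipeline()] for the recognised fields. Referenced input
#' files must exist at read time.
#'
#' @param path JSON file.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_invalid("no such config file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  normalize_pipeline_config(cfg)
}

normalize_pipeline_config <- function(cfg) {
  defaults <- list(
    seed = 1L, level = 0.95, dp = 2L, founders_per_pool = 20L,
    interval = "midp", reference = NULL,
    experiment_table = NULL, snp_map = NULL, conversion_calls = NULL,
    simulate = NULL, out_dir = "."
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (f in c("experiment_table", "snp_map", "conversion_calls")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort_invalid("config references missing file ", f, ": ", cfg[[f]])
    }
  }
  cfg
}

#' Run the full screening pipeline
#'
#' Ties the stages together: (optionally) simulate an experiment, then
#' per-construct minimum rates, reference comparisons, pooled-rate
#' inference with a pairwise overlap matrix, and (when a SNP map and
#' call table are supplied) tract classification. Writes TSV tables and
#' one JSON summary carrying the package version, the seed, every
#' effective parameter, and the coordinate convention; two runs with the
#' same config and seed produce byte-identical summaries.
#'
#' @param config a config list (see [read_pipeline_config()]); fields:
#'   `seed`, `out_dir`, `level`, `dp`, `interval`, `reference`
#'   (construct id for comparisons; default: highest minimum rate),
#'   `experiment_table` (TSV path) *or* `simulate` (list of
#'   [sim_design()] arguments), optional `snp_map` + `conversion_calls`
#'   (TSV paths) for the tract stage.
#' @return Invisibly, a list with the per-stage results and the path of
#'   the JSON summary.
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  tab <- stage("input", {
    if (!is.null(cfg$experiment_table)) {
      read_experiment_table(cfg$experiment_table)
    } else if (!is.null(cfg$simulate)) {
      des <- do.call(sim_design, c(cfg$simulate, list(seed = cfg$seed)))
      simulate_experiment(des)
    } else {
      abort_invalid("config needs experiment_table or simulate")
    }
  })

  rates <- stage("rates", aggregate_experiment(tab, dp = cfg$dp, level = cfg$level))
  reference <- if (is.null(cfg$reference)) {
    rates$construct[which.max(rates$pct)]
  } else {
    cfg$reference
  }
  comparisons <- stage("rates", {
    if (nrow(rates) > 1L) compare_constructs(tab, reference, dp = cfg$dp) else NULL
  })

  inference <- stage("infer", {
    fits <- lapply(split(tab, tab$construct)[unique(tab$construct)], function(df) {
      estimate_individual_rate(df, level = cfg$level, interval = cfg$interval)
    })
    overlap <- NULL
    cs <- names(fits)
    if (length(cs) > 1L) {
      overlap <- matrix(NA, length(cs), length(cs), dimnames = list(cs, cs))
      for (i in seq_along(cs)) for (j in seq_along(cs)) {
        overlap[i, j] <- if (i == j) TRUE else {
          overlap_assessment(fits[[i]], fits[[j]])$intervals_overlap
        }
      }
    }
    list(fits = fits, overlap = overlap)
  })

  tracts <- NULL
  if (!is.null(cfg$snp_map) && !is.null(cfg$conversion_calls)) {
    tracts <- stage("tracts", {
      map <- read_snp_map(cfg$snp_map)
      calls <- read_conversion_calls(cfg$conversion_calls)
      events <- call_events(calls, map)
      list(
        events = events,
        summary = aggregate_events(events),
        censoring = censoring_interval_report(events, calls, map)
      )
    })
  }

  summary_path <- stage("report", {
    write_experiment_table(tab, file.path(cfg$out_dir, "experiment.tsv"),
                           seed = cfg$seed)
    rates_out <- rates
    if (!is.null(comparisons)) {
      rates_out <- merge(rates, comparisons[, c("construct", "p0", "p_value")],
                         by = "construct", all.x = TRUE, sort = FALSE)
      rates_out <- rates_out[match(rates$construct, rates_out$construct), ]
    }
    write_tsv(rates_out, file.path(cfg$out_dir, "rates.tsv"),
              sprintf("# reference construct for p-values: %s", reference))
    infer_tab <- do.call(rbind, lapply(names(inference$fits), function(cn) {
      f <- inference$fits[[cn]]
      data.frame(construct = cn, k_positive = f$k_positive,
                 n_pools = f$n_pools, p_mle = f$p_mle,
                 lower = f$interval[1L], upper = f$interval[2L],
                 method = f$interval_method, one_sided = f$one_sided,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(infer_tab, file.path(cfg$out_dir, "inference.tsv"),
              sprintf("# level: %g; founders per pool as recorded per row", cfg$level))
    if (!is.null(tracts)) {
      write_tsv(tracts$censoring, file.path(cfg$out_dir, "tract_censoring.tsv"),
                HEADER_CONVENTION)
    }
    summary <- list(
      package = "hdrscreen",
      version = as.character(utils::packageVersion("hdrscreen")),
      seed = cfg$seed,
      parameters = cfg[c("level", "dp", "interval", "founders_per_pool")],
      reference = reference,
      convention = sub("^# ", "", HEADER_CONVENTION),
      rates = rates_out,
      inference = infer_tab,
      overlap = if (!is.null(inference$overlap)) {
        as.data.frame(inference$overlap)
      },
      tracts = if (!is.null(tracts)) {
        list(
          by_direction = tracts$summary$by_direction,
          by_mechanism = tracts$summary$by_mechanism,
          n_discontinuous = tracts$summary$n_discontinuous
        )
      }
    )
    p <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  })

  invisible(list(
    table = tab, rates = rates, comparisons = comparisons,
    reference = reference, inference = inference, tracts = tracts,
    summary_json = summary_path
  ))
}
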