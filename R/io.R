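#' Read spike trains from CSV
#'
#' Expects columns `unit_id,timestamp_s`. Timestamps are sorted per unit
#' (with a warning if the input was unsorted) and duplicate timestamps are
#' removed with a warning.
#'
#' @param path CSV file.
#' @return named list: unit_id -> sorted numeric timestamps.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "timestamp_s") %in% names(df)))
    stop("spike CSV must have columns unit_id,timestamp_s")
  bad <- which(is.na(df$unit_id) | df$unit_id == "" |
                 is.na(suppressWarnings(as.numeric(df$timestamp_s))))
  if (length(bad))
    stop("malformed spike rows at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  df$timestamp_s <- as.numeric(df$timestamp_s)
  out <- split(df$timestamp_s, df$unit_id)
  out <- lapply(out, function(ts) {
    if (is.unsorted(ts)) {
      warning("unsorted timestamps; sorting")
      ts <- sort(ts)
    }
    if (anyDuplicated(ts)) {
      warning("duplicate timestamps removed")
      ts <- unique(ts)
    }
    ts
  })
  out[order(names(out))]
}

#' Write spike trains to CSV (`unit_id,timestamp_s`)
#' @param spikes named list of timestamp vectors.
#' @param path output CSV.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(names(spikes), lengths(spikes)),
    timestamp_s = sprintf("%.6f", unlist(spikes, use.names = FALSE)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event schedule from CSV
#'
#' Expects columns `session_id,context,trial_index,cs_onset_s,cs_offset_s`
#' and optionally `us_onset_s`.
#' @param path CSV file.
#' @return event schedule data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "context", "trial_index", "cs_onset_s", "cs_offset_s")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns ", paste(need, collapse = ","))
  if (!"us_onset_s" %in% names(df)) df$us_onset_s <- NA_real_
  if (any(df$cs_offset_s <= df$cs_onset_s))
    stop("cs_offset_s must exceed cs_onset_s")
  df
}

#' Write an event schedule to CSV
#' @param events event schedule data.frame.
#' @param path output CSV.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read freezing annotations (`subject_id,start_s,end_s`, optional context)
#' @param path CSV file.
#' @return data.frame.
#' @export
read_freezing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "start_s", "end_s") %in% names(df)))
    stop("freezing CSV must have columns subject_id,start_s,end_s")
  if (any(df$end_s <= df$start_s)) stop("freezing interval start must be < end")
  df
}

#' Read startle amplitudes (`trial_type,amplitude`)
#' @param path CSV file.
#' @return data.frame.
#' @export
read_startle <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trial_type", "amplitude") %in% names(df)))
    stop("startle CSV must have columns trial_type,amplitude")
  df
}

#' Run the full analysis pipeline
#'
#' Orchestrates classification (both 3-SD criteria on pooled trials),
#' per-unit context-modulation t-values over the thirty 1-s CS bins, the
#' direction chi-square over the configured population, paired window tests
#' (0-150 ms across short-latency units; 0-10 s and whole CS across PFUs),
#' population-average Z profiles per context, and optional behavioral
#' metrics. Deterministic given inputs; every exclusion is recorded with
#' its reason and `n_total = n_analyzed + n_excluded` always holds.
#'
#' @param spikes named list of spike trains (or path to a spikes CSV).
#' @param events event schedule data.frame (or path to an events CSV).
#' @param config a [pipeline_config()].
#' @param freezing optional freezing annotation data.frame with a `context`
#'   column; freezing is scored over the first CS presentation per context.
#' @param startle optional startle trial data.frame.
#' @param out_dir optional directory; writes units.csv, population.csv and
#'   summary.json there.
#' @return list of class "cdfd_report": `units`, `population`, `summary`,
#'   `window_tests`, `chisq`, `classification`, `modulation`.
#' @export
run_pipeline <- function(spikes, events, config = pipeline_config(),
                         freezing = NULL, startle = NULL, out_dir = NULL) {
  if (is.character(spikes)) spikes <- read_spikes(spikes)
  if (is.character(events)) events <- read_events(events)
  cls <- classify_population(spikes, events, config)
  mod <- modulation_table(spikes, events, config)
  units <- merge(cls$units,
                 mod[, c("unit_id", "t_value", "df", "p", "sum_d",
                         "significant", "direction", "degenerate")],
                 by = "unit_id", all.x = TRUE, sort = TRUE)
  units <- units[order(units$unit_id), ]
  rownames(units) <- NULL

  analyzable <- units[!units$excluded & !is.na(units$t_value), ]
  chisq_pop <- switch(config$chisq_population,
                      persistent = analyzable[analyzable$persistent, ],
                      analyzed = analyzable,
                      stop("unknown chisq_population"))
  chisq <- NULL
  if (nrow(chisq_pop) > 0) {
    n_pos <- sum(chisq_pop$significant & chisq_pop$direction == "positive")
    n_neg <- sum(chisq_pop$significant & chisq_pop$direction == "negative")
    chisq <- tryCatch(
      c(proportion_chisq(n_pos, n_neg, nrow(chisq_pop))[
          c("statistic", "df", "p")],
        list(n_pos = n_pos, n_neg = n_neg, n_total = nrow(chisq_pop))),
      error = function(e) list(statistic = NA_real_, note = conditionMessage(e),
                               n_pos = n_pos, n_neg = n_neg,
                               n_total = nrow(chisq_pop)))
  }

  profile_set <- function(ids, bw, win, bl) {
    per_unit <- lapply(ids, function(uid)
      context_zprofiles(spikes[[uid]], events, bw, win, bl,
                        baseline = config$context_baseline,
                        baseline_mode = config$baseline_mode))
    names(per_unit) <- ids
    lapply(c(A = "A", B = "B"), function(ctx) {
      ps <- lapply(per_unit, function(p) p[[ctx]])
      names(ps) <- ids
      ps
    })
  }
  window_tests <- list()
  sl_ids <- units$unit_id[units$short_latency & !units$excluded]
  if (length(sl_ids) >= 2L) {
    pf <- profile_set(sl_ids, config$bin_fast, config$window_fast,
                      config$baseline_fast)
    ok <- !vapply(pf$A, function(p) p$baseline$degenerate, logical(1)) &
          !vapply(pf$B, function(p) p$baseline$degenerate, logical(1))
    if (sum(ok) >= 2L)
      window_tests$short_latency_150ms <- window_mean_test(
        pf$A[ok], pf$B[ok], config$short_latency_window, config$alpha)
  }
  pfu_ids <- units$unit_id[units$persistent & !units$excluded]
  if (length(pfu_ids) >= 2L) {
    ps <- profile_set(pfu_ids, config$bin_slow, config$window_slow,
                      config$baseline_slow)
    ok <- !vapply(ps$A, function(p) p$baseline$degenerate, logical(1)) &
          !vapply(ps$B, function(p) p$baseline$degenerate, logical(1))
    if (sum(ok) >= 2L) {
      window_tests$sustained_10s <- window_mean_test(
        ps$A[ok], ps$B[ok], config$persistent_window, config$alpha)
      window_tests$sustained_cs <- window_mean_test(
        ps$A[ok], ps$B[ok], config$cs_window, config$alpha)
    }
  }

  an_ids <- units$unit_id[!units$excluded]
  population <- NULL
  if (length(an_ids) >= 1L) {
    slow <- profile_set(an_ids, config$bin_slow, config$window_slow,
                        config$baseline_slow)
    pop <- list()
    for (ctx in c("A", "B")) {
      prof <- slow[[ctx]]
      keep <- !vapply(prof, function(p) p$baseline$degenerate, logical(1))
      if (any(keep))
        pop[[ctx]] <- population_profile(prof[keep], context = ctx)
    }
    if (length(pop)) population <- do.call(rbind, pop)
  }

  behavior <- list()
  if (!is.null(freezing)) {
    first_cs <- events[!duplicated(events$context), ]
    behavior$freezing <- do.call(rbind, lapply(seq_len(nrow(first_cs)),
      function(i) {
        ctx <- first_cs$context[i]
        iv <- freezing[freezing$context == ctx, c("start_s", "end_s"),
                       drop = FALSE]
        data.frame(context = ctx,
                   freezing_pct = freezing_percentage(
                     iv, c(first_cs$cs_onset_s[i], first_cs$cs_offset_s[i])),
                   stringsAsFactors = FALSE)
      }))
  }
  if (!is.null(startle)) behavior$ppi <- ppi_from_trials(startle)

  n_sig_pos <- sum(analyzable$significant & analyzable$direction == "positive")
  n_sig_neg <- sum(analyzable$significant & analyzable$direction == "negative")
  summary <- c(cls$summary, list(
    n_modulation_analyzed = nrow(analyzable),
    n_significant_positive = n_sig_pos,
    n_significant_negative = n_sig_neg,
    chisq = chisq,
    window_tests = window_tests,
    behavior = behavior))
  report <- structure(list(units = units, population = population,
                           summary = summary, window_tests = window_tests,
                           chisq = chisq, classification = cls,
                           modulation = mod),
                      class = "cdfd_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `units.csv` (per-unit flags and statistics), `population.csv`
#' (per-context population Z profiles) and `summary.json`.
#'
#' @param report a "cdfd_report".
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$units, file.path(out_dir, "units.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$population))
    utils::write.csv(report$population, file.path(out_dir, "population.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
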