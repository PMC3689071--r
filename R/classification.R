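#' Short-latency CS-responsiveness criterion
#'
#' A unit is short-latency CS-responsive if the firing rate in at least one
#' of the first three post-CS 50-ms bins (the 0-150 ms window) exceeds the
#' pre-CS baseline by more than `threshold` SDs. "Over" is strict: a bin at
#' exactly the threshold does not qualify.
#'
#' @param zprofile a "cdfd_zprofile" at 50-ms resolution (1-s baseline).
#' @param threshold SD threshold (default 3).
#' @param window response window, s after CS onset (default 0-150 ms).
#' @return TRUE/FALSE; errors if the profile's baseline is degenerate.
#' @export
classify_short_latency <- function(zprofile, threshold = 3,
                                   window = c(0, 0.15)) {
  if (zprofile$baseline$degenerate)
    stop("degenerate baseline (SD = 0): unit must be excluded, not classified")
  idx <- bins_in_window(zprofile$window, zprofile$bin_width, window)
  if (length(idx) == 0L) stop("response window not covered by profile")
  max(zprofile$z[idx]) > threshold
}

#' Persistently firing unit (PFU) criterion
#'
#' A unit is a PFU if two or more of the first ten post-CS 1-s bins exceed
#' the 20-s pre-CS baseline by more than `threshold` SDs (strict).
#'
#' @param zprofile a "cdfd_zprofile" at 1-s resolution (20-s baseline).
#' @param threshold SD threshold (default 3).
#' @param window response window, s after CS onset (default 0-10 s).
#' @param min_bins minimum number of supra-threshold bins (default 2).
#' @return TRUE/FALSE; errors if the profile's baseline is degenerate.
#' @export
classify_persistent <- function(zprofile, threshold = 3, window = c(0, 10),
                                min_bins = 2L) {
  if (zprofile$baseline$degenerate)
    stop("degenerate baseline (SD = 0): unit must be excluded, not classified")
  idx <- bins_in_window(zprofile$window, zprofile$bin_width, window)
  if (length(idx) == 0L) stop("response window not covered by profile")
  sum(zprofile$z[idx] > threshold) >= min_bins
}

#' Classify a population of units
#'
#' Applies both responsiveness criteria to every unit, using trials pooled
#' across contexts (units are classified once, then contexts are compared
#' downstream) unless `config$classify_contexts = "per_context"`, in which
#' case a unit is responsive if it meets the criterion in either context.
#' Units with a zero-SD baseline at either resolution are excluded with
#' reason "degenerate_baseline"; units missing from `spikes` are excluded
#' with reason "missing_profile". Excluded units carry FALSE flags.
#'
#' @param spikes named list of spike trains (unit_id -> timestamps).
#' @param events event schedule data.frame.
#' @param config a [pipeline_config()].
#' @param unit_ids units to classify (default: names of `spikes`).
#' @return list: `units` (per-unit data.frame: unit_id, baseline_rate,
#'   short_latency, persistent, overlap, excluded, exclusion_reason) and
#'   `summary` (n_total, n_analyzed, n_excluded, n_short_latency,
#'   n_persistent, n_overlap and percentages of analyzed units).
#' @export
classify_population <- function(spikes, events, config = pipeline_config(),
                                unit_ids = names(spikes)) {
  if (length(unit_ids) == 0L) stop("no units to classify")
  pre_tone <- c(max(0, min(events$cs_onset_s) - 180), min(events$cs_onset_s))
  ctx_sets <- if (identical(config$classify_contexts, "per_context"))
    as.list(unique(events$context)) else list(NULL)
  rows <- lapply(unit_ids, function(uid) {
    row <- data.frame(unit_id = uid, baseline_rate = NA_real_,
                      short_latency = FALSE, persistent = FALSE,
                      overlap = FALSE, excluded = FALSE,
                      exclusion_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (is.null(spikes[[uid]])) {
      row$excluded <- TRUE; row$exclusion_reason <- "missing_profile"
      return(row)
    }
    train <- spikes[[uid]]
    row$baseline_rate <- spontaneous_rate(train, pre_tone)
    sl <- pf <- FALSE
    for (ctx in ctx_sets) {
      zf <- unit_zprofile(train, events, config$bin_fast, config$window_fast,
                          config$baseline_fast, contexts = ctx,
                          baseline_mode = config$baseline_mode)
      zs <- unit_zprofile(train, events, config$bin_slow, config$window_slow,
                          config$baseline_slow, contexts = ctx,
                          baseline_mode = config$baseline_mode)
      if (zf$baseline$degenerate || zs$baseline$degenerate) {
        row$excluded <- TRUE; row$exclusion_reason <- "degenerate_baseline"
        row$short_latency <- row$persistent <- row$overlap <- FALSE
        return(row)
      }
      sl <- sl || classify_short_latency(zf, config$sd_threshold,
                                         config$short_latency_window)
      pf <- pf || classify_persistent(zs, config$sd_threshold,
                                      config$persistent_window,
                                      config$persistent_min_bins)
    }
    row$short_latency <- sl; row$persistent <- pf; row$overlap <- sl && pf
    row
  })
  units <- do.call(rbind, rows)
  analyzed <- units[!units$excluded, , drop = FALSE]
  n_an <- nrow(analyzed)
  pct <- function(k) if (n_an > 0) 100 * k / n_an else 0
  summary <- list(
    n_total = nrow(units), n_analyzed = n_an,
    n_excluded = sum(units$excluded),
    n_short_latency = sum(analyzed$short_latency),
    n_persistent = sum(analyzed$persistent),
    n_overlap = sum(analyzed$overlap),
    pct_short_latency = pct(sum(analyzed$short_latency)),
    pct_persistent = pct(sum(analyzed$persistent)),
    pct_overlap = pct(sum(analyzed$overlap)))
  list(units = units, summary = summary)
}
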