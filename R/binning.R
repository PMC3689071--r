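#' Align a spike train to CS onsets
#'
#' Converts absolute spike times to times relative to each trial's CS onset
#' and keeps those inside `window` (half-open: a spike exactly at the window
#' end is excluded).
#'
#' @param train sorted numeric vector of spike timestamps (s).
#' @param schedule event schedule data.frame with columns `cs_onset_s`,
#'   `context`, `trial_index` (one row per trial).
#' @param window c(start, end) relative to CS onset, s; start < end.
#' @param contexts optional subset of context labels to keep.
#' @return list of class "cdfd_aligned": `trials` (list of relative-time
#'   vectors), `context` (label per trial), `window`.
#' @export
align_trials <- function(train, schedule, window, contexts = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (is.unsorted(train)) stop("spike train must be sorted")
  if (!is.null(contexts)) schedule <- schedule[schedule$context %in% contexts, ]
  trials <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    rel <- train - schedule$cs_onset_s[i]
    trials[[i]] <- rel[rel >= window[1] & rel < window[2]]
  }
  structure(list(trials = trials, context = schedule$context,
                 trial_index = schedule$trial_index, window = window),
            class = "cdfd_aligned")
}

#' Bin aligned trials into a peristimulus count matrix
#'
#' Bins are half-open intervals `[start + b*w, start + (b+1)*w)` on the
#' relative-time axis; `window` must be an integer multiple of `bin_width`.
#'
#' @param aligned result of [align_trials()].
#' @param bin_width bin width, s (0.05 and 1 are the analysis defaults).
#' @param window c(start, end) relative window to bin; defaults to the
#'   alignment window.
#' @return list of class "cdfd_binned": `counts` (trials x bins integer
#'   matrix), `bin_width`, `window`, `context`, `bin_start` (left edges).
#' @export
bin_counts <- function(aligned, bin_width, window = aligned$window) {
  n_bins <- n_bins_for(window, bin_width)
  counts <- matrix(0L, nrow = length(aligned$trials), ncol = n_bins)
  for (i in seq_along(aligned$trials)) {
    idx <- bin_index(aligned$trials[[i]], window[1], bin_width, n_bins)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = n_bins)
      counts[i, ] <- tab
    }
  }
  structure(list(counts = counts, bin_width = bin_width, window = window,
                 context = aligned$context,
                 bin_start = window[1] + (seq_len(n_bins) - 1L) * bin_width),
            class = "cdfd_binned")
}

#' Baseline-normalized Z-score profile
#'
#' Averages the count matrix across trials, then expresses each bin of the
#' trial-averaged profile in SD units of its pre-CS baseline bins: the
#' baseline mean and sample SD (divisor n-1) are computed over the baseline
#' bins of the trial-averaged profile (20 bins for both standard
#' configurations: 1 s of 50-ms bins, 20 s of 1-s bins). Units whose
#' baseline SD is zero are flagged `degenerate` and their Z values are NA;
#' downstream stages decide exclusion.
#'
#' @param binned result of [bin_counts()].
#' @param baseline_window c(start, end), s; must precede CS onset (end <= 0)
#'   and be covered by the binned window.
#' @param baseline_mode "averaged" (default): mean/SD over the baseline bins
#'   of the trial-averaged profile; "pooled": over all trials x baseline
#'   bins of the raw count matrix.
#' @return list of class "cdfd_zprofile": `z`, `avg` (trial-averaged
#'   counts/bin), `bin_width`, `window`, `bin_start`, `n_trials`, and
#'   `baseline` (mean, sd, n_bins, degenerate).
#' @export
zscore_profile <- function(binned, baseline_window,
                           baseline_mode = c("averaged", "pooled")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(length(baseline_window) == 2L,
            baseline_window[1] < baseline_window[2])
  if (baseline_window[2] > 1e-9)
    stop("baseline window must precede CS onset")
  idx <- bins_in_window(binned$window, binned$bin_width, baseline_window)
  n_expect <- n_bins_for(baseline_window, binned$bin_width)
  if (length(idx) != n_expect)
    stop("baseline window not covered by the binned window")
  avg <- colMeans(binned$counts)
  if (baseline_mode == "averaged") {
    m <- mean(avg[idx])
    s <- stats::sd(avg[idx])
  } else {
    pooled <- as.vector(binned$counts[, idx, drop = FALSE])
    m <- mean(pooled)
    s <- stats::sd(pooled)
  }
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(NA_real_, length(avg)) else (avg - m) / s
  structure(list(z = z, avg = avg, bin_width = binned$bin_width,
                 window = binned$window, bin_start = binned$bin_start,
                 n_trials = nrow(binned$counts),
                 baseline = list(mean = m, sd = if (degenerate) 0 else s,
                                 n_bins = length(idx),
                                 degenerate = degenerate)),
            class = "cdfd_zprofile")
}

#' One-call Z-profile for a unit
#'
#' Convenience wrapper: align, bin, and normalize in one step.
#'
#' @inheritParams align_trials
#' @inheritParams bin_counts
#' @param baseline_window passed to [zscore_profile()].
#' @param ... further arguments to [zscore_profile()].
#' @export
unit_zprofile <- function(train, schedule, bin_width, window,
                          baseline_window, contexts = NULL, ...) {
  al <- align_trials(train, schedule, window, contexts = contexts)
  zscore_profile(bin_counts(al, bin_width), baseline_window, ...)
}

#' Spontaneous firing rate over the pre-tone exposure period
#'
#' @param train sorted spike timestamps (s).
#' @param window c(t0, t1), s, absolute; typically the 180-s pre-tone
#'   exposure preceding the first CS.
#' @return rate in spikes/s.
#' @export
spontaneous_rate <- function(train, window) {
  dur <- window[2] - window[1]
  if (dur <= 0) stop("window must have positive duration")
  sum(train >= window[1] & train < window[2]) / dur
}
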