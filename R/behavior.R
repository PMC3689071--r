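#' Merge overlapping or touching intervals
#'
#' @param intervals two-column matrix or data.frame (start, end), s.
#' @return matrix of disjoint intervals sorted by start.
#' @export
merge_intervals <- function(intervals) {
  iv <- as.matrix(intervals)[, 1:2, drop = FALSE]
  if (nrow(iv) == 0L) return(iv)
  if (any(iv[, 1] >= iv[, 2])) stop("interval start must be < end")
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  unname(out)
}

#' Freezing percentage within an analysis window
#'
#' Freezing — immobility except for respiration — is quantified as the
#' percentage of the analysis window covered by annotated immobility
#' intervals: overlapping intervals are merged, intersected with the
#' window, and their total duration divided by the window length.
#' In the discrimination test this is computed over the first CS
#' presentation of each context.
#'
#' @param intervals two-column matrix/data.frame of (start, end) immobility
#'   times, s; may be empty.
#' @param window c(start, end) analysis window, s.
#' @return freezing percentage in \[0, 100\].
#' @export
freezing_percentage <- function(intervals, window) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("analysis window must have positive duration")
  iv <- as.matrix(intervals)
  if (nrow(iv) == 0L) return(0)
  iv <- merge_intervals(iv)
  lo <- pmax(iv[, 1], window[1])
  hi <- pmin(iv[, 2], window[2])
  covered <- sum(pmax(hi - lo, 0))
  100 * covered / (window[2] - window[1])
}

#' Prepulse inhibition percentage
#'
#' PPI (%) = 100 x (SS - PS) / SS, where SS is the mean startle amplitude
#' on startle-alone trials and PS the mean amplitude on prepulse-startle
#' trials (load-cell arbitrary units).
#'
#' @param ss mean startle-alone amplitude (> 0).
#' @param ps mean prepulse-startle amplitude.
#' @return PPI in percent.
#' @export
ppi_percent <- function(ss, ps) {
  if (!is.finite(ss) || ss <= 0) stop("SS must be positive for a defined PPI")
  100 * (ss - ps) / ss
}

#' PPI from a startle trial table
#'
#' @param trials data.frame with columns `trial_type` ("startle" /
#'   "prepulse_startle") and `amplitude`.
#' @return list: ppi_percent, ss, ps, n_ss, n_ps.
#' @export
ppi_from_trials <- function(trials) {
  ss_amp <- trials$amplitude[trials$trial_type == "startle"]
  ps_amp <- trials$amplitude[trials$trial_type == "prepulse_startle"]
  if (length(ss_amp) == 0L) stop("no startle-alone trials")
  ss <- mean(ss_amp); ps <- mean(ps_amp)
  list(ppi_percent = ppi_percent(ss, ps), ss = ss, ps = ps,
       n_ss = length(ss_amp), n_ps = length(ps_amp))
}
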