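#' Specify one synthetic unit
#'
#' A synthetic unit is an inhomogeneous Poisson process: a spontaneous
#' (baseline) rate modulated around CS onsets by a context-gated transient
#' component (first 150 ms) and a sustained component that decays linearly
#' back to baseline gain 1 at 10 s. Gains are dimensionless multipliers on
#' the baseline rate; gain 1 means no modulation in that context.
#'
#' @param unit_id character identifier.
#' @param baseline_rate spontaneous rate in spikes/s (>= 0; 0 is allowed and
#'   exercises the downstream zero-baseline exclusion path).
#' @param transient_gain_A,transient_gain_B multiplier applied during the
#'   first 150 ms after CS onset in context A / B.
#' @param sustained_gain_A,sustained_gain_B multiplier at CS onset decaying
#'   linearly to 1 at 10 s, in context A / B.
#' @return one-row data.frame (rows can be `rbind`-ed into a cohort).
#' @export
unit_spec <- function(unit_id, baseline_rate,
                      transient_gain_A = 1, transient_gain_B = 1,
                      sustained_gain_A = 1, sustained_gain_B = 1) {
  gains <- c(transient_gain_A, transient_gain_B,
             sustained_gain_A, sustained_gain_B)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (any(gains < 0)) stop("gains must be >= 0")
  data.frame(unit_id = as.character(unit_id),
             baseline_rate = baseline_rate,
             transient_gain_A = transient_gain_A,
             transient_gain_B = transient_gain_B,
             sustained_gain_A = sustained_gain_A,
             sustained_gain_B = sustained_gain_B,
             stringsAsFactors = FALSE)
}

#' Draw a cohort of synthetic units
#'
#' Baseline rates are drawn log-uniformly over `rate_range`, whose default
#' spans the spontaneous-rate range observed across prelimbic units in the
#' recording experiment this generator emulates (0.31-34.60 Hz).
#'
#' @param n number of units.
#' @param rate_range c(min, max) baseline rate in Hz; log-uniform draw.
#' @param transient_gain_A,transient_gain_B,sustained_gain_A,sustained_gain_B
#'   gains applied to every unit (scalar or length-n vector).
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param prefix unit-id prefix.
#' @return data.frame of unit specs.
#' @export
synthetic_cohort <- function(n, rate_range = c(0.31, 34.60),
                             transient_gain_A = 1, transient_gain_B = 1,
                             sustained_gain_A = 1, sustained_gain_B = 1,
                             seed = NULL, prefix = "u") {
  stopifnot(n >= 1, rate_range[1] > 0, rate_range[2] >= rate_range[1])
  rates <- with_seed(seed,
    exp(stats::runif(n, log(rate_range[1]), log(rate_range[2]))))
  out <- data.frame(
    unit_id = sprintf("%s%03d", prefix, seq_len(n)),
    baseline_rate = rates,
    transient_gain_A = rep_len(transient_gain_A, n),
    transient_gain_B = rep_len(transient_gain_B, n),
    sustained_gain_A = rep_len(sustained_gain_A, n),
    sustained_gain_B = rep_len(sustained_gain_B, n),
    stringsAsFactors = FALSE)
  if (any(out$transient_gain_A < 0 | out$transient_gain_B < 0 |
          out$sustained_gain_A < 0 | out$sustained_gain_B < 0))
    stop("gains must be >= 0")
  out
}

#' Specify a recording session schedule
#'
#' Defaults mirror the test-session structure of the discrimination
#' experiment: a 180-s pre-tone exposure, then 6 CS-only trials per context
#' with a 30-s tone CS and inter-trial intervals drawn uniformly from
#' 160-200 s (mean 180 s). Context sessions are laid end to end on one
#' continuous time base so that unit identities match across contexts.
#'
#' @param contexts ordered context labels (gains are defined for "A"/"B").
#' @param trials_per_context CS-only trials per context.
#' @param cs_duration CS length, s.
#' @param pre_tone_exposure baseline exposure before the first CS, s.
#' @param iti_range c(min, max) inter-trial interval, s.
#' @param transient_window duration of the transient response component, s.
#' @param sustained_window duration of the sustained response component, s.
#' @param combine how transient and sustained gains combine on the baseline
#'   rate: "multiplicative" (default) or "additive".
#' @param seed integer seed for schedule and spike generation.
#' @return list of class "cdfd_session_spec".
#' @export
session_spec <- function(contexts = c("A", "B"), trials_per_context = 6,
                         cs_duration = 30, pre_tone_exposure = 180,
                         iti_range = c(160, 200),
                         transient_window = 0.15, sustained_window = 10,
                         combine = c("multiplicative", "additive"),
                         seed = 1L) {
  combine <- match.arg(combine)
  stopifnot(cs_duration > 0, trials_per_context >= 1,
            iti_range[1] <= iti_range[2], iti_range[1] >= 0,
            pre_tone_exposure >= 0,
            transient_window > 0, sustained_window >= transient_window)
  structure(list(contexts = as.character(contexts),
                 trials_per_context = as.integer(trials_per_context),
                 cs_duration = cs_duration,
                 pre_tone_exposure = pre_tone_exposure,
                 iti_range = iti_range,
                 transient_window = transient_window,
                 sustained_window = sustained_window,
                 combine = combine,
                 seed = as.integer(seed)),
            class = "cdfd_session_spec")
}

# Context-dependent rate multiplier for one unit at relative times `rel`
# (s after the CS onset of a trial in context `ctx`).
unit_gain_factor <- function(unit, rel, ctx, spec) {
  tg <- ifelse(ctx == "A", unit$transient_gain_A,
        ifelse(ctx == "B", unit$transient_gain_B, 1))
  sg <- ifelse(ctx == "A", unit$sustained_gain_A,
        ifelse(ctx == "B", unit$sustained_gain_B, 1))
  tf <- ifelse(rel >= 0 & rel < spec$transient_window, tg, 1)
  sf <- ifelse(rel >= 0 & rel < spec$sustained_window,
               sg + (1 - sg) * rel / spec$sustained_window, 1)
  if (spec$combine == "multiplicative") pmax(tf * sf, 0)
  else pmax(1 + (tf - 1) + (sf - 1), 0)
}

# Build a vectorized rate function (spikes/s vs absolute time) for one unit
# over an event schedule, plus a sharp upper bound for thinning.
unit_rate_fn <- function(unit, schedule, spec) {
  base <- unit$baseline_rate
  onsets <- schedule$cs_onset_s
  ctxs <- schedule$context
  ord <- order(onsets)
  onsets <- onsets[ord]; ctxs <- ctxs[ord]
  fn <- function(tt) {
    r <- rep(base, length(tt))
    if (length(onsets) == 0L || base == 0) return(r)
    i <- findInterval(tt, onsets)
    hit <- i >= 1L
    if (any(hit)) {
      rel <- tt[hit] - onsets[i[hit]]
      r[hit] <- base * unit_gain_factor(unit, rel, ctxs[i[hit]], spec)
    }
    r
  }
  per_ctx_max <- function(tg, sg) {
    if (spec$combine == "multiplicative") max(1, tg, sg, tg * sg)
    else max(1, tg, sg, 1 + (tg - 1) + (sg - 1))
  }
  rate_max <- base * max(per_ctx_max(unit$transient_gain_A,
                                     unit$sustained_gain_A),
                         per_ctx_max(unit$transient_gain_B,
                                     unit$sustained_gain_B))
  list(fn = fn, rate_max = rate_max)
}

#' Simulate an inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at
#' `rate_max` over `span` and retained with probability
#' `rate_fn(t) / rate_max` (Lewis-Shedler thinning). Over any window the
#' retained count is Poisson with mean equal to the integral of the rate.
#'
#' @param rate_fn vectorized rate function (spikes/s), must satisfy
#'   0 <= rate_fn(t) <= rate_max on span.
#' @param span c(t0, t1), s.
#' @param rate_max finite upper bound on the rate over span.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return sorted, strictly increasing spike timestamps (s).
#' @export
generate_poisson_train <- function(rate_fn, span, rate_max, seed = NULL) {
  stopifnot(length(span) == 2L, span[2] >= span[1])
  if (!is.finite(rate_max) || rate_max < 0)
    stop("rate_max must be finite and >= 0")
  with_seed(seed, {
    dur <- span[2] - span[1]
    n <- stats::rpois(1L, rate_max * dur)
    if (n == 0L) return(numeric(0))
    tt <- sort(stats::runif(n, span[1], span[2]))
    rr <- rate_fn(tt)
    if (any(!is.finite(rr)) || any(rr < 0))
      stop("rate function must be finite and non-negative on span")
    if (any(rr > rate_max * (1 + 1e-9)))
      stop("rate function exceeds rate_max; thinning bound violated")
    keep <- stats::runif(n) * rate_max < rr
    enforce_increasing(tt[keep])
  })
}

#' Generate a full synthetic recording session
#'
#' Builds the event schedule (per-context pre-tone exposure followed by
#' CS-only trials separated by uniform ITIs), realizes each unit's
#' context-gated rate function as a spike train, and returns the dataset
#' together with the ground-truth unit specs for recovery tests.
#'
#' @param units data.frame of unit specs ([unit_spec()] / [synthetic_cohort()]).
#' @param spec a [session_spec()].
#' @return list of class "cdfd_dataset": `spikes` (named list, unit_id ->
#'   timestamps), `events` (one row per CS trial: session_id, context,
#'   trial_index, cs_onset_s, cs_offset_s, us_onset_s), `truth`, `spec`,
#'   `span`.
#' @export
generate_session <- function(units, spec = session_spec()) {
  if (!inherits(spec, "cdfd_session_spec")) stop("spec must be a session_spec")
  if (is.null(units) || nrow(units) == 0L) stop("at least one unit required")
  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in cohort")
  with_seed(spec$seed, {
    events <- list(); t0 <- 0
    for (ctx in spec$contexts) {
      itis <- stats::runif(spec$trials_per_context,
                           spec$iti_range[1], spec$iti_range[2])
      onset <- t0 + spec$pre_tone_exposure
      for (k in seq_len(spec$trials_per_context)) {
        events[[length(events) + 1L]] <- data.frame(
          session_id = ctx, context = ctx, trial_index = k,
          cs_onset_s = onset, cs_offset_s = onset + spec$cs_duration,
          us_onset_s = NA_real_, stringsAsFactors = FALSE)
        onset <- onset + spec$cs_duration + itis[k]
      }
      t0 <- onset  # session ends after the last trial's ITI
    }
    events <- do.call(rbind, events)
    span <- c(0, t0)
    spikes <- vector("list", nrow(units))
    names(spikes) <- units$unit_id
    for (i in seq_len(nrow(units))) {
      rf <- unit_rate_fn(units[i, ], events, spec)
      spikes[[i]] <- generate_poisson_train(rf$fn, span, rf$rate_max)
    }
    structure(list(spikes = spikes, events = events, truth = units,
                   spec = spec, span = span),
              class = "cdfd_dataset")
  })
}

#' Generate synthetic freezing annotations
#'
#' Emits immobility intervals inside each CS window such that the expected
#' freezing percentage per context equals the configured probability x 100:
#' the CS window is divided into `resolution`-s segments, each frozen
#' independently with the context's probability, and adjacent frozen
#' segments are merged.
#'
#' @param schedule event schedule data.frame (as in [generate_session()]).
#' @param freeze_prob_by_context named vector, e.g. c(A = 0.8, B = 0.2).
#' @param seed optional integer seed.
#' @param resolution segment length in s.
#' @param subject_id id recorded on each interval.
#' @return data.frame: subject_id, context, trial_index, start_s, end_s.
#' @export
generate_freezing <- function(schedule, freeze_prob_by_context, seed = NULL,
                              resolution = 1, subject_id = "synthetic") {
  p <- freeze_prob_by_context
  if (any(p < 0 | p > 1)) stop("freezing probabilities must be in [0, 1]")
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(schedule))) {
      ctx <- schedule$context[i]
      pc <- if (ctx %in% names(p)) p[[ctx]] else 0
      lo <- schedule$cs_onset_s[i]; hi <- schedule$cs_offset_s[i]
      edges <- seq(lo, hi, by = resolution)
      if (edges[length(edges)] < hi) edges <- c(edges, hi)
      n_seg <- length(edges) - 1L
      frozen <- stats::runif(n_seg) < pc
      if (!any(frozen)) next
      runs <- rle(frozen)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (j in which(runs$values)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject_id, context = ctx,
          trial_index = schedule$trial_index[i],
          start_s = edges[starts[j]], end_s = edges[ends[j] + 1L],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L)
      return(data.frame(subject_id = character(0), context = character(0),
                        trial_index = integer(0), start_s = numeric(0),
                        end_s = numeric(0), stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Generate synthetic startle amplitudes
#'
#' Log-normal amplitudes (load-cell arbitrary units) for startle-alone and
#' prepulse-startle trials, with the prepulse-startle mean scaled so the
#' true prepulse inhibition equals `ppi_true` percent.
#'
#' @param n_per_type trials per trial type.
#' @param ss_mean mean startle-alone amplitude.
#' @param ppi_true true PPI in percent (< 100).
#' @param cv coefficient of variation of amplitudes.
#' @param seed optional integer seed.
#' @return data.frame: trial_type ("startle"/"prepulse_startle"), amplitude.
#' @export
generate_startle <- function(n_per_type = 15, ss_mean = 200, ppi_true = 50,
                             cv = 0.2, seed = NULL) {
  stopifnot(ss_mean > 0, ppi_true < 100, cv > 0)
  ps_mean <- ss_mean * (1 - ppi_true / 100)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(m, n) {
    if (m <= 0) return(rep(0, n))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, data.frame(
    trial_type = rep(c("startle", "prepulse_startle"), each = n_per_type),
    amplitude = c(draw(ss_mean, n_per_type), draw(ps_mean, n_per_type)),
    stringsAsFactors = FALSE))
}
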