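#' Per-unit context-modulation t-value over matched bins
#'
#' Contrasts a unit's Z-score profile between the two contexts over matched
#' bins (the thirty 1-s CS bins in the standard analysis). The differences
#' d = zA - zB are summarized as a paired t-statistic, t = mean(d) /
#' (sd(d)/sqrt(n)), df = n - 1; the raw sum of differences is also reported.
#' Positive t means more CS-evoked activity in Context A (the fearful
#' context). Significance is two-tailed at `alpha`.
#'
#' @param zA,zB equal-length finite Z vectors (context A and B).
#' @param alpha two-tailed significance level.
#' @return list: t, df, p, sum_d, mean_d, significant, direction
#'   ("positive"/"negative"/"none"), degenerate (zero-variance differences
#'   with nonzero mean: direction is set but t is undefined).
#' @export
paired_bin_t <- function(zA, zB, alpha = 0.05) {
  if (length(zA) != length(zB)) stop("profiles must have equal length")
  n <- length(zA)
  if (n < 2L) stop("need at least 2 matched bins")
  if (any(!is.finite(zA)) || any(!is.finite(zB)))
    stop("profiles must be finite")
  d <- zA - zB
  s <- stats::sd(d)
  m <- mean(d)
  out <- list(t = NA_real_, df = n - 1L, p = NA_real_, sum_d = sum(d),
              mean_d = m, significant = FALSE, direction = "none",
              degenerate = FALSE)
  if (s == 0) {
    if (m == 0) {
      out$t <- 0; out$p <- 1
    } else {
      out$degenerate <- TRUE
      out$direction <- if (m > 0) "positive" else "negative"
    }
    return(out)
  }
  out$t <- m / (s / sqrt(n))
  out$p <- 2 * stats::pt(abs(out$t), df = n - 1L, lower.tail = FALSE)
  out$significant <- abs(out$t) > stats::qt(1 - alpha / 2, df = n - 1L)
  if (out$significant)
    out$direction <- if (out$t > 0) "positive" else "negative"
  out
}

#' Chi-square on modulation directions
#'
#' Pearson chi-square (no continuity correction, df = 1) comparing the
#' proportion of significantly positive against significantly negative
#' units, via the 2x2 table
#' `[[n_pos, n_total - n_pos], [n_neg, n_total - n_neg]]`.
#'
#' @param n_pos significantly positive units.
#' @param n_neg significantly negative units.
#' @param n_total units tested.
#' @return list: statistic, df, p, table, expected.
#' @export
proportion_chisq <- function(n_pos, n_neg, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_pos + n_neg > n_total) stop("n_pos + n_neg exceeds n_total")
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative")
  tab <- matrix(c(n_pos, n_total - n_pos, n_neg, n_total - n_neg),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("positive", "negative"),
                                c("significant", "not_significant")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: empty table margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       table = tab, expected = expected)
}

#' Paired window test across units
#'
#' For each unit, averages its Z profile over `window` in each context, then
#' tests the across-unit paired difference (Context A - Context B) with a
#' paired t-test (df = n_units - 1). Used for the 0-150 ms short-latency
#' comparison and the 0-10 s / whole-CS sustained comparisons.
#'
#' @param profiles_A,profiles_B named lists of "cdfd_zprofile" objects for
#'   the same units (names must match).
#' @param window c(start, end), s after CS onset.
#' @param alpha two-tailed significance level.
#' @return list: t, df, p, significant, mean_A, mean_B, n_units, degenerate.
#' @export
window_mean_test <- function(profiles_A, profiles_B, window, alpha = 0.05) {
  ids <- names(profiles_A)
  if (!setequal(ids, names(profiles_B)))
    stop("the same units are required in both contexts")
  if (length(ids) < 2L) stop("need at least 2 units")
  wm <- function(zp) {
    idx <- bins_in_window(zp$window, zp$bin_width, window)
    if (length(idx) == 0L) stop("window not covered by profile")
    mean(zp$z[idx])
  }
  a <- vapply(ids, function(u) wm(profiles_A[[u]]), numeric(1))
  b <- vapply(ids, function(u) wm(profiles_B[[u]]), numeric(1))
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  out <- list(t = NA_real_, df = n - 1L, p = NA_real_, significant = FALSE,
              mean_A = mean(a), mean_B = mean(b), n_units = n,
              degenerate = FALSE)
  if (s == 0) {
    if (mean(d) == 0) { out$t <- 0; out$p <- 1 } else out$degenerate <- TRUE
    return(out)
  }
  out$t <- mean(d) / (s / sqrt(n))
  out$p <- 2 * stats::pt(abs(out$t), df = n - 1L, lower.tail = FALSE)
  out$significant <- out$p < alpha
  out
}

#' Population-average Z profile
#'
#' Bin-wise mean and standard error of the Z profiles across units, per
#' context — the population-level summary in which Z-scores are calculated
#' for each unit and averaged.
#'
#' @param profiles named list of "cdfd_zprofile" objects (one per unit, all
#'   on the same bin grid).
#' @param context label recorded in the output.
#' @return data.frame: context, bin_start, mean_z, se_z, n_units.
#' @export
population_profile <- function(profiles, context = NA_character_) {
  if (length(profiles) == 0L) stop("need at least 1 unit")
  grids <- lapply(profiles, function(p) p$bin_start)
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1))))
    stop("profiles are on mismatched bin grids")
  zmat <- do.call(rbind, lapply(profiles, function(p) p$z))
  n <- nrow(zmat)
  se <- if (n > 1) apply(zmat, 2L, stats::sd) / sqrt(n) else rep(0, ncol(zmat))
  data.frame(context = context, bin_start = grids[[1]],
             mean_z = colMeans(zmat), se_z = se, n_units = n,
             stringsAsFactors = FALSE)
}

#' Two-within-factor repeated-measures ANOVA
#'
#' Full sum-of-squares decomposition for a design with one observation per
#' subject x factor-A x factor-B cell, subject as the random factor: each
#' within effect is tested against its own subject-interaction error term
#' (F_A = MS_A / MS_{A x S}, etc.). Used for the context x phase habituation
#' analysis and for group-level behavioral designs with two within factors.
#'
#' @param data data.frame with columns `subject`, `f1`, `f2`, `value`;
#'   exactly one row per subject x f1 x f2 combination.
#' @return list of class "cdfd_anova": per-effect rows (ss, df, ms, F, p,
#'   error ss/df/ms) for f1, f2 and f1:f2, plus ss_subject and ss_total.
#'   F is NA (flagged `degenerate`) when its error MS is zero.
#' @export
rm_anova_2within <- function(data) {
  need <- c("subject", "f1", "f2", "value")
  if (!all(need %in% names(data))) stop("columns subject, f1, f2, value required")
  s <- factor(data$subject); A <- factor(data$f1); B <- factor(data$f2)
  y <- data$value
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  if (nrow(data) != n * a * b || anyDuplicated(interaction(s, A, B)))
    stop("design must have exactly one observation per subject x f1 x f2 cell")
  if (n < 2L) stop("need at least 2 subjects")
  gm <- mean(y)
  cm <- function(...) tapply(y, list(...), mean)
  ss_total <- sum((y - gm)^2)
  ss_S <- a * b * sum((cm(s) - gm)^2)
  ss_A <- n * b * sum((cm(A) - gm)^2)
  ss_B <- n * a * sum((cm(B) - gm)^2)
  ss_AB <- n * sum((cm(A, B) - gm)^2) - ss_A - ss_B
  ss_AS <- b * sum((cm(A, s) - gm)^2) - ss_A - ss_S
  ss_BS <- a * sum((cm(B, s) - gm)^2) - ss_B - ss_S
  ss_ABS <- ss_total - ss_S - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  ss_ABS <- max(ss_ABS, 0)  # guard tiny negative rounding
  effect <- function(name, ss, df, ss_err, df_err) {
    ms <- ss / df; ms_err <- ss_err / df_err
    degenerate <- ms_err <= 0
    Fv <- if (degenerate) NA_real_ else ms / ms_err
    p <- if (degenerate) NA_real_ else
      stats::pf(Fv, df, df_err, lower.tail = FALSE)
    list(effect = name, ss = ss, df = df, ms = ms, F = Fv, p = p,
         ss_error = ss_err, df_error = df_err, ms_error = ms_err,
         degenerate = degenerate)
  }
  structure(list(
    f1 = effect("f1", ss_A, a - 1L, ss_AS, (a - 1L) * (n - 1L)),
    f2 = effect("f2", ss_B, b - 1L, ss_BS, (b - 1L) * (n - 1L)),
    f1_f2 = effect("f1:f2", ss_AB, (a - 1L) * (b - 1L),
                   ss_ABS, (a - 1L) * (b - 1L) * (n - 1L)),
    ss_subject = ss_S, ss_total = ss_total,
    n_subjects = n, a = a, b = b), class = "cdfd_anova")
}

#' Mixed-design (one between, one within) ANOVA
#'
#' Standard decomposition for group x within-factor designs (e.g. lesion
#' group x context): the between effect is tested against subjects within
#' groups, the within effect and interaction against the within x subject
#' error.
#'
#' @param data data.frame with columns `subject`, `group` (between), `f1`
#'   (within), `value`; one row per subject x f1 cell; each subject in one
#'   group.
#' @return list with `group`, `f1`, `group_f1` effect rows as in
#'   [rm_anova_2within()].
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "f1", "value")
  if (!all(need %in% names(data))) stop("columns subject, group, f1, value required")
  s <- factor(data$subject); g <- factor(data$group); A <- factor(data$f1)
  y <- data$value
  grp_of <- tapply(as.character(data$group), s, unique)
  if (any(lengths(grp_of) != 1))
    stop("each subject must belong to exactly one group")
  grp_of <- unlist(grp_of)  # named by subject level
  n <- nlevels(s); a <- nlevels(A); k <- nlevels(g)
  if (nrow(data) != n * a) stop("one observation per subject x f1 cell required")
  gm <- mean(y)
  cm <- function(...) tapply(y, list(...), mean)
  ss_total <- sum((y - gm)^2)
  m_s <- cm(s); m_g <- cm(g); m_a <- cm(A); m_ga <- cm(g, A)
  ng <- table(factor(grp_of, levels = levels(g)))  # subjects per group
  ss_G <- a * sum(ng * (m_g - gm)^2)
  ss_S_within_G <- a * sum((m_s - m_g[grp_of[names(m_s)]])^2)
  ss_A <- n * sum((m_a - gm)^2)
  dev <- sweep(sweep(m_ga, 1L, m_g), 2L, m_a) + gm
  ss_GA <- sum(as.numeric(ng) * rowSums(dev^2))
  ss_AS_within_G <- ss_total - ss_G - ss_S_within_G - ss_A - ss_GA
  ss_AS_within_G <- max(ss_AS_within_G, 0)
  effect <- function(name, ss, df, ss_err, df_err) {
    ms <- ss / df; ms_err <- ss_err / df_err
    degenerate <- ms_err <= 0
    Fv <- if (degenerate) NA_real_ else ms / ms_err
    p <- if (degenerate) NA_real_ else
      stats::pf(Fv, df, df_err, lower.tail = FALSE)
    list(effect = name, ss = ss, df = df, ms = ms, F = Fv, p = p,
         ss_error = ss_err, df_error = df_err, ms_error = ms_err,
         degenerate = degenerate)
  }
  list(group = effect("group", ss_G, k - 1L, ss_S_within_G, n - k),
       f1 = effect("f1", ss_A, a - 1L, ss_AS_within_G, (a - 1L) * (n - k)),
       group_f1 = effect("group:f1", ss_GA, (k - 1L) * (a - 1L),
                         ss_AS_within_G, (a - 1L) * (n - k)),
       ss_subject_within_group = ss_S_within_G, ss_total = ss_total)
}

#' Per-context Z profiles for one unit
#'
#' Computes one Z-score profile per context on a shared bin grid. With
#' `baseline = "common"` (default) both contexts' trial-averaged profiles
#' are normalized by the mean and SD of the pre-CS baseline bins pooled
#' across all trials of both contexts; baseline-estimation noise is then
#' common mode and cancels exactly in bin-wise context differences, which
#' keeps the paired-bin t statistic at its nominal null level. With
#' `baseline = "per_context"` each context is normalized to its own
#' baseline (its own pre-CS bins), which additionally removes any context
#' difference in spontaneous rate but leaves the contrast with an inflated
#' null level (the per-context baseline-mean error does not cancel).
#'
#' @param train sorted spike timestamps.
#' @param events event schedule.
#' @param bin_width,window,baseline_window bin geometry (s).
#' @param baseline "common" or "per_context".
#' @param baseline_mode passed to the baseline statistics ("averaged" or
#'   "pooled" across trials).
#' @param contexts the two context labels to contrast.
#' @return named list of "cdfd_zprofile" objects, one per context; all
#'   carry the same `degenerate` flag when `baseline = "common"`.
#' @export
context_zprofiles <- function(train, events, bin_width, window,
                              baseline_window,
                              baseline = c("common", "per_context"),
                              baseline_mode = "averaged",
                              contexts = c("A", "B")) {
  baseline <- match.arg(baseline)
  if (baseline == "per_context") {
    out <- lapply(contexts, function(ctx)
      unit_zprofile(train, events, bin_width, window, baseline_window,
                    contexts = ctx, baseline_mode = baseline_mode))
    names(out) <- contexts
    return(out)
  }
  ev <- events[events$context %in% contexts, ]
  al <- align_trials(train, ev, window)
  bc <- bin_counts(al, bin_width)
  pooled <- zscore_profile(bc, baseline_window, baseline_mode = baseline_mode)
  m <- pooled$baseline$mean; s <- pooled$baseline$sd
  out <- lapply(contexts, function(ctx) {
    rows <- bc$context == ctx
    avg <- colMeans(bc$counts[rows, , drop = FALSE])
    z <- if (pooled$baseline$degenerate) rep(NA_real_, length(avg))
         else (avg - m) / s
    structure(list(z = z, avg = avg, bin_width = bin_width, window = window,
                   bin_start = bc$bin_start, n_trials = sum(rows),
                   baseline = pooled$baseline),
              class = "cdfd_zprofile")
  })
  names(out) <- contexts
  out
}

#' Per-unit modulation table
#'
#' Computes each unit's per-context Z profile at 1-s resolution (20-s
#' baseline, computed within that context's trials) and the paired
#' modulation t-value over the thirty 1-s CS bins. Units with a degenerate
#' baseline in either context get NA statistics and an exclusion reason.
#'
#' @param spikes named list of spike trains.
#' @param events event schedule (contexts "A" and "B").
#' @param config a [pipeline_config()].
#' @param unit_ids units to analyze.
#' @return data.frame: unit_id, t_value, df, p, sum_d, significant,
#'   direction, degenerate, excluded, exclusion_reason.
#' @export
modulation_table <- function(spikes, events, config = pipeline_config(),
                             unit_ids = names(spikes)) {
  rows <- lapply(unit_ids, function(uid) {
    row <- data.frame(unit_id = uid, t_value = NA_real_, df = NA_integer_,
                      p = NA_real_, sum_d = NA_real_, significant = FALSE,
                      direction = "none", degenerate = FALSE,
                      excluded = FALSE, exclusion_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (is.null(spikes[[uid]])) {
      row$excluded <- TRUE; row$exclusion_reason <- "missing_profile"
      return(row)
    }
    zp <- context_zprofiles(spikes[[uid]], events, config$bin_slow,
                            config$window_slow, config$baseline_slow,
                            baseline = config$context_baseline,
                            baseline_mode = config$baseline_mode)
    if (any(vapply(zp, function(p) p$baseline$degenerate, logical(1)))) {
      row$excluded <- TRUE; row$exclusion_reason <- "degenerate_baseline"
      return(row)
    }
    idx <- bins_in_window(config$window_slow, config$bin_slow, config$cs_window)
    res <- paired_bin_t(zp[[1]]$z[idx], zp[[2]]$z[idx], alpha = config$alpha)
    row$t_value <- res$t; row$df <- res$df; row$p <- res$p
    row$sum_d <- res$sum_d; row$significant <- res$significant
    row$direction <- res$direction; row$degenerate <- res$degenerate
    row
  })
  do.call(rbind, rows)
}

#' Habituation analysis: context x phase split
#'
#' Splits each context's 6 test trials into an early phase (trials 1-3) and
#' a late phase (trials 4-6), recomputes each unit's Z-scores within each
#' context x phase cell (normalized to that phase's own pre-CS baseline
#' bins), averages Z over the response window, and runs the two-within
#' repeated-measures ANOVA (context, phase, context x phase) with unit as
#' the random factor.
#'
#' The "short_latency" variant uses 50-ms bins, the 1-s baseline and the
#' 0-150 ms response window; units that did not fire during the pre-CS
#' baseline throughout the early or the late trials (degenerate phase
#' baseline) are excluded. The "sustained" variant uses 1-s bins, the 20-s
#' baseline and the whole-CS window.
#'
#' @param spikes named list of spike trains.
#' @param events event schedule with >= 6 trials per context.
#' @param config a [pipeline_config()].
#' @param variant "short_latency" or "sustained".
#' @param unit_ids units to analyze.
#' @return list: `anova` ([rm_anova_2within()] result), `cells` (unit x
#'   context x phase mean Z), `excluded` (unit ids dropped, with reasons).
#' @export
habituation_split <- function(spikes, events, config = pipeline_config(),
                              variant = c("short_latency", "sustained"),
                              unit_ids = names(spikes)) {
  variant <- match.arg(variant)
  bw <- if (variant == "short_latency") config$bin_fast else config$bin_slow
  win <- if (variant == "short_latency") config$window_fast else config$window_slow
  bl <- if (variant == "short_latency") config$baseline_fast else config$baseline_slow
  resp <- if (variant == "short_latency") config$short_latency_window else
    config$cs_window
  contexts <- unique(events$context)
  for (ctx in contexts)
    if (sum(events$context == ctx) < 6L)
      stop("need at least 6 trials per context for the phase split")
  cells <- list(); excluded <- list()
  for (uid in unit_ids) {
    train <- spikes[[uid]]
    if (is.null(train)) {
      excluded[[uid]] <- "missing_profile"; next
    }
    vals <- list(); ok <- TRUE
    for (ctx in contexts) {
      ev <- events[events$context == ctx, ]
      ev <- ev[order(ev$trial_index), ]
      for (phase in c("early", "late")) {
        sel <- if (phase == "early") 1:3 else 4:6
        al <- align_trials(train, ev[sel, ], win)
        zp <- zscore_profile(bin_counts(al, bw), bl,
                             baseline_mode = config$baseline_mode)
        if (zp$baseline$degenerate) { ok <- FALSE; break }
        idx <- bins_in_window(win, bw, resp)
        vals[[paste(ctx, phase, sep = ".")]] <- mean(zp$z[idx])
      }
      if (!ok) break
    }
    if (!ok) { excluded[[uid]] <- "degenerate_baseline"; next }
    for (key in names(vals)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      cells[[length(cells) + 1L]] <- data.frame(
        subject = uid, f1 = parts[1], f2 = parts[2], value = vals[[key]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(cells) == 0L || length(unique(vapply(cells, function(x)
    x$subject, character(1)))) < 2L)
    stop("fewer than 2 analyzable units after exclusion")
  cells <- do.call(rbind, cells)
  list(anova = rm_anova_2within(cells), cells = cells,
       excluded = if (length(excluded))
         data.frame(unit_id = names(excluded),
                    reason = unlist(excluded), stringsAsFactors = FALSE,
                    row.names = NULL)
       else data.frame(unit_id = character(0), reason = character(0)))
}
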