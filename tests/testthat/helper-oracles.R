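# Independent oracles and small constructors used across the suite. These
# re-derive expected results from first principles (or via stats:: fits) so
# they stay independent of the package's own computation paths.

# Construct a binned-count container directly from a count matrix.
make_binned <- function(counts, bin_width, window, context = NULL) {
  n_bins <- ncol(counts)
  structure(list(counts = counts, bin_width = bin_width, window = window,
                 context = context %||% rep("A", nrow(counts)),
                 bin_start = window[1] + (seq_len(n_bins) - 1L) * bin_width),
            class = "cdfd_binned")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a Z-profile container directly from a z vector.
make_zprofile <- function(z, bin_width, window, degenerate = FALSE) {
  structure(list(z = z, avg = z, bin_width = bin_width, window = window,
                 bin_start = window[1] + (seq_along(z) - 1L) * bin_width,
                 n_trials = 1L,
                 baseline = list(mean = 0, sd = 1, n_bins = 20L,
                                 degenerate = degenerate)),
            class = "cdfd_zprofile")
}

# Brute-force evaluation of the printed responsiveness criteria straight
# from a raw count matrix: trial-average, baseline mean/SD over the first
# `n_base` bins, compare rates against mean + threshold * SD.
brute_short_latency <- function(counts, n_base = 20L, post = 1:3,
                                threshold = 3) {
  avg <- colMeans(counts)
  m <- mean(avg[seq_len(n_base)])
  s <- sd(avg[seq_len(n_base)])
  if (s == 0) return(NA)
  any(avg[n_base + post] > m + threshold * s)
}
brute_persistent <- function(counts, n_base = 20L, post = 1:10,
                             threshold = 3, min_bins = 2L) {
  avg <- colMeans(counts)
  m <- mean(avg[seq_len(n_base)])
  s <- sd(avg[seq_len(n_base)])
  if (s == 0) return(NA)
  sum(avg[n_base + post] > m + threshold * s) >= min_bins
}

# Pearson chi-square from explicit expected counts on the 2x2 table
# [[n_pos, n_total - n_pos], [n_neg, n_total - n_neg]].
oracle_chisq <- function(n_pos, n_neg, n_total) {
  o <- c(n_pos, n_total - n_pos, n_neg, n_total - n_neg)
  r1 <- n_total; r2 <- n_total
  c1 <- n_pos + n_neg; c2 <- 2 * n_total - c1
  e <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / (2 * n_total)
  sum((o - e)^2 / e)
}

# Inhomogeneous-Poisson simulation by time rescaling of a unit-rate
# process, for a step-rate function given by `breaks` (length k+1 edges)
# and `rates` (length k). Independent of the thinning generator.
sim_rescaled_step <- function(breaks, rates) {
  durs <- diff(breaks)
  Lam_edges <- c(0, cumsum(rates * durs))
  total <- Lam_edges[length(Lam_edges)]
  s <- 0; out <- numeric(0)
  repeat {
    s <- s + rexp(1)
    if (s > total) break
    k <- findInterval(s, Lam_edges, rightmost.closed = TRUE)
    out <- c(out, breaks[k] + (s - Lam_edges[k]) / rates[k])
  }
  out
}

# Repeated-measures ANOVA oracle via stats::aov with an Error stratum.
aov_2within_F <- function(data) {
  data$subject <- factor(data$subject)
  data$f1 <- factor(data$f1); data$f2 <- factor(data$f2)
  fit <- summary(aov(value ~ f1 * f2 + Error(subject / (f1 * f2)),
                     data = data))
  get_F <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(f1 = get_F("Error: subject:f1", "f1"),
    f2 = get_F("Error: subject:f2", "f2"),
    f1_f2 = get_F("Error: subject:f1:f2", "f1:f2"))
}

# Mixed-design oracle (one between, one within) via stats::aov.
aov_mixed_F <- function(data) {
  data$subject <- factor(data$subject)
  data$group <- factor(data$group); data$f1 <- factor(data$f1)
  fit <- summary(aov(value ~ group * f1 + Error(subject / f1), data = data))
  between <- fit[["Error: subject"]][[1]]
  within <- fit[["Error: subject:f1"]][[1]]
  c(group = between[trimws(rownames(between)) == "group", "F value"],
    f1 = within[trimws(rownames(within)) == "f1", "F value"],
    group_f1 = within[trimws(rownames(within)) == "group:f1", "F value"])
}

# Small two-context cohort + session used by several integration tests.
quick_session <- function(units, seed = 1, trials = 6) {
  generate_session(units, session_spec(trials_per_context = trials,
                                       seed = seed))
}
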