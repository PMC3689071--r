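test_that("zero-rate and invalid rate functions are handled", {
  expect_identical(
    generate_poisson_train(function(t) rep(0, length(t)), c(0, 100), 0,
                           seed = 1),
    numeric(0))
  expect_error(
    generate_poisson_train(function(t) rep(-1, length(t)), c(0, 10), 5,
                           seed = 1),
    "non-negative")
  expect_error(
    generate_poisson_train(function(t) rep(10, length(t)), c(0, 10), 5,
                           seed = 1),
    "rate_max")
  expect_error(generate_poisson_train(function(t) t, c(0, 10), Inf),
               "finite")
})

test_that("homogeneous thinning count matches the Poisson mean", {
  counts <- vapply(1:100, function(s)
    length(generate_poisson_train(function(t) rep(5, length(t)), c(0, 180),
                                  5, seed = s)),
    numeric(1))
  # mean of 100 Poisson(900) draws: SE = sqrt(900/100) = 3
  expect_lt(abs(mean(counts) - 900), 3 * 3)
})

test_that("thinning matches a time-rescaling oracle for a step rate", {
  breaks <- c(0, 30, 60); rates <- c(2, 10)
  rate_fn <- function(t) ifelse(t < 30, 2, 10)
  half_counts <- function(ts) c(sum(ts < 30), sum(ts >= 30))
  set.seed(42)
  thin <- t(vapply(1:200, function(s)
    half_counts(generate_poisson_train(rate_fn, c(0, 60), 10, seed = s)),
    numeric(2)))
  oracle <- t(replicate(200, half_counts(sim_rescaled_step(breaks, rates))))
  for (h in 1:2) {
    p <- suppressWarnings(ks.test(thin[, h], oracle[, h]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("identical seeds and specs yield identical datasets", {
  u <- synthetic_cohort(3, seed = 7)
  d1 <- generate_session(u, session_spec(seed = 5))
  d2 <- generate_session(u, session_spec(seed = 5))
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$events, d2$events)
  d3 <- generate_session(u, session_spec(seed = 6))
  expect_false(identical(d1$spikes, d3$spikes))
})

test_that("the event schedule has the configured structure", {
  ds <- generate_session(unit_spec("u1", 5), session_spec(seed = 3))
  ev <- ds$events
  expect_equal(nrow(ev), 12L)
  expect_equal(sum(ev$context == "A"), 6L)
  expect_equal(ev$cs_offset_s - ev$cs_onset_s, rep(30, 12))
  expect_equal(min(ev$cs_onset_s), 180)  # pre-tone exposure
  gaps <- diff(ev$cs_onset_s[ev$context == "A"]) - 30
  expect_true(all(gaps >= 160 & gaps <= 200))
  expect_true(all(ds$spikes$u1 >= 0 & ds$spikes$u1 <= ds$span[2]))
  expect_true(all(diff(ds$spikes$u1) > 0))
  expect_error(generate_session(unit_spec("u", 5)[0, ], session_spec()),
               "at least one unit")
})

test_that("a unit with unit gains fires at baseline rate during the CS", {
  tot_cs <- 0; tot_expected <- 0
  for (s in 1:60) {
    ds <- generate_session(unit_spec("u1", 4), session_spec(seed = s))
    ev <- ds$events
    in_cs <- vapply(ds$spikes$u1, function(t)
      any(t >= ev$cs_onset_s & t < ev$cs_offset_s), logical(1))
    tot_cs <- tot_cs + sum(in_cs)
    tot_expected <- tot_expected + 4 * sum(ev$cs_offset_s - ev$cs_onset_s)
  }
  # total CS-window count is Poisson(tot_expected): 3-SE bound
  expect_lt(abs(tot_cs - tot_expected), 3 * sqrt(tot_expected))
})

test_that("null gains yield modulation t-values centered on zero", {
  u <- synthetic_cohort(100, seed = 21)
  ds <- generate_session(u, session_spec(seed = 22))
  m <- modulation_table(ds$spikes, ds$events)
  expect_lt(abs(mean(m$t_value, na.rm = TRUE)), 0.2)
})

test_that("synthetic freezing matches its configured probability", {
  ds <- generate_session(unit_spec("u1", 1), session_spec(seed = 2))
  expect_equal(nrow(generate_freezing(ds$events, c(A = 0, B = 0), seed = 1)),
               0L)
  fz1 <- generate_freezing(ds$events, c(A = 1, B = 1), seed = 1)
  first <- ds$events[1, ]
  expect_equal(freezing_percentage(
    fz1[fz1$context == "A" & fz1$trial_index == 1, c("start_s", "end_s")],
    c(first$cs_onset_s, first$cs_offset_s)), 100)
  pcts <- vapply(1:200, function(s) {
    fz <- generate_freezing(ds$events[1, ], c(A = 0.5), seed = s)
    freezing_percentage(fz[, c("start_s", "end_s"), drop = FALSE],
                        c(first$cs_onset_s, first$cs_offset_s))
  }, numeric(1))
  # binomial oracle: per-trial SD = 100 * sqrt(.25/30); SE over 200 seeds
  se <- 100 * sqrt(0.25 / 30) / sqrt(200)
  expect_lt(abs(mean(pcts) - 50), 3 * se)
  expect_error(generate_freezing(ds$events, c(A = 1.5)), "\\[0, 1\\]")
})

test_that("synthetic startle recovers the configured PPI", {
  tr <- generate_startle(n_per_type = 2000, ss_mean = 200, ppi_true = 60,
                         seed = 8)
  expect_equal(ppi_from_trials(tr)$ppi_percent, 60, tolerance = 0.05)
})
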