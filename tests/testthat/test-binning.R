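schedule1 <- data.frame(session_id = "A", context = "A", trial_index = 1L,
                        cs_onset_s = 1000, cs_offset_s = 1030,
                        us_onset_s = NA_real_)

test_that("alignment subtracts CS onset and applies half-open windows", {
  al <- align_trials(c(999.5, 1005.0, 1033.0), schedule1, c(-1, 3))
  expect_equal(al$trials[[1]], c(-0.5))
  al2 <- align_trials(c(1005.0), schedule1, c(-1, 30))
  expect_equal(al2$trials[[1]], 5.0)
  expect_equal(align_trials(numeric(0), schedule1, c(-1, 3))$trials[[1]],
               numeric(0))
  # spike exactly at the window end is excluded
  expect_equal(align_trials(c(1003.0), schedule1, c(-1, 3))$trials[[1]],
               numeric(0))
  expect_error(align_trials(c(2, 1), schedule1, c(-1, 3)), "sorted")
})

test_that("binning uses half-open 50-ms bins and conserves counts", {
  al <- align_trials(1000 + c(0.01, 0.02, 0.06), schedule1, c(0, 0.2))
  bc <- bin_counts(al, 0.05)
  expect_equal(bc$counts[1, ], c(2L, 1L, 0L, 0L))
  # spike at exactly 0.05 falls in the second bin
  al2 <- align_trials(1000.05, schedule1, c(0, 0.2))
  expect_equal(bin_counts(al2, 0.05)$counts[1, ], c(0L, 1L, 0L, 0L))
  al3 <- align_trials(numeric(0), schedule1, c(0, 0.2))
  expect_true(all(bin_counts(al3, 0.05)$counts == 0L))
  expect_error(bin_counts(al, 0.05, window = c(0, 0.17)), "multiple")
})

test_that("binned counts conserve aligned spikes on random trains", {
  set.seed(31)
  for (i in 1:20) {
    train <- sort(runif(200, 900, 1100))
    al <- align_trials(train, schedule1, c(-20, 30))
    bc <- bin_counts(al, 1)
    expect_equal(sum(bc$counts), length(al$trials[[1]]))
  }
})

test_that("Z profile matches hand arithmetic and flags degenerate baselines", {
  # trial-averaged baseline alternates 0,1 over 20 bins; post bin average 3
  counts <- matrix(c(rep(c(0, 1), 10), 3), nrow = 1)
  bc <- make_binned(counts, 1, c(-20, 1))
  zp <- zscore_profile(bc, c(-20, 0))
  expect_equal(zp$baseline$mean, 0.5)
  expect_equal(zp$baseline$sd, sqrt(5 / 19))
  expect_equal(zp$z[21], (3 - 0.5) / sqrt(5 / 19), tolerance = 1e-12)
  expect_equal(round(zp$z[21], 3), 4.873)
  # all bins equal -> degenerate (sd = 0), z undefined
  zp0 <- zscore_profile(make_binned(matrix(2, 1, 21), 1, c(-20, 1)),
                        c(-20, 0))
  expect_true(zp0$baseline$degenerate)
  expect_true(all(is.na(zp0$z)))
  # zero baseline, nonzero post bins -> degenerate flag set
  zp1 <- zscore_profile(
    make_binned(matrix(c(rep(0, 20), 5), 1), 1, c(-20, 1)), c(-20, 0))
  expect_true(zp1$baseline$degenerate)
  expect_error(zscore_profile(bc, c(-25, 0)), "not covered")
  expect_error(zscore_profile(bc, c(-5, 5)), "precede")
})

test_that("pooled baseline mode uses trial-by-trial baseline statistics", {
  counts <- rbind(c(rep(0, 20), 4), c(rep(2, 20), 4))
  bc <- make_binned(counts, 1, c(-20, 1))
  zp <- zscore_profile(bc, c(-20, 0), baseline_mode = "pooled")
  pooled <- c(rep(0, 20), rep(2, 20))
  expect_equal(zp$baseline$mean, mean(pooled))
  expect_equal(zp$baseline$sd, sd(pooled))
  expect_equal(zp$z[21], (4 - 1) / sd(pooled))
})

test_that("Z profiles are invariant under uniform time translation", {
  set.seed(7)
  train <- sort(runif(500, 900, 1100))
  zp <- unit_zprofile(train, schedule1, 1, c(-20, 30), c(-20, 0))
  sch2 <- schedule1; sch2$cs_onset_s <- sch2$cs_onset_s + 555
  sch2$cs_offset_s <- sch2$cs_offset_s + 555
  zp2 <- unit_zprofile(train + 555, sch2, 1, c(-20, 30), c(-20, 0))
  expect_equal(zp$z, zp2$z, tolerance = 1e-12)
})

test_that("baseline-window exceedances are rare for a homogeneous unit", {
  # specificity of the 3-SD criterion: self-normalized baseline bins rarely
  # cross the threshold
  n_over <- 0; n_bins <- 0
  for (s in 1:200) {
    counts <- matrix(rpois(12 * 20, 0.4), nrow = 12)
    zp <- zscore_profile(make_binned(counts, 1, c(-20, 0)), c(-20, 0))
    if (zp$baseline$degenerate) next
    n_over <- n_over + sum(abs(zp$z) > 3)
    n_bins <- n_bins + length(zp$z)
  }
  expect_lt(n_over / n_bins, 0.05)
})

test_that("spontaneous rate is count over duration", {
  expect_equal(spontaneous_rate(seq(0.5, 179.5, by = 1), c(0, 180)), 1.0)
  expect_equal(spontaneous_rate(numeric(0), c(0, 180)), 0.0)
  expect_equal(spontaneous_rate(seq(1, 180, by = 2), c(0, 180)), 0.5)
  expect_error(spontaneous_rate(1:3, c(5, 5)), "positive")
})
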