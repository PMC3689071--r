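test_that("paired-bin t matches hand and textbook oracles", {
  z <- rnorm(30)
  res0 <- paired_bin_t(z, z)
  expect_equal(res0$t, 0)
  expect_false(res0$significant)
  expect_equal(res0$direction, "none")

  zB <- rep(0, 30); zA <- rep(c(1, 0), 15)  # d alternates 1,0
  res <- paired_bin_t(zA, zB)
  expect_equal(res$mean_d, 0.5)
  expect_equal(res$t, 0.5 / (sd(zA) / sqrt(30)), tolerance = 1e-12)
  expect_equal(round(res$t, 3), 5.385)
  expect_true(res$significant)
  expect_equal(res$direction, "positive")
  expect_equal(res$sum_d, 15)
  expect_equal(res$t, unname(t.test(zA, zB, paired = TRUE)$statistic),
               tolerance = 1e-10)

  resc <- paired_bin_t(rep(0.7, 30), rep(0, 30))
  expect_true(resc$degenerate)
  expect_true(is.na(resc$t))
  expect_equal(resc$direction, "positive")
  expect_error(paired_bin_t(1:3, 1:4), "equal length")
})

test_that("paired-bin t equals stats::t.test on random vectors", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- t.test(a, b, paired = TRUE)
    res <- paired_bin_t(a, b)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter))
  }
})

test_that("direction chi-square reproduces known tables", {
  expect_equal(proportion_chisq(11, 3, 24)$statistic, 6.454,
               tolerance = 1e-3)
  expect_equal(proportion_chisq(7, 7, 24)$statistic, 0)
  expect_equal(proportion_chisq(6, 2, 12)$statistic, 3.0, tolerance = 1e-12)
  ref <- chisq.test(matrix(c(11, 13, 3, 21), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(proportion_chisq(11, 3, 24)$statistic,
               unname(ref$statistic), tolerance = 1e-12)
  expect_error(proportion_chisq(0, 0, 10), "margin")
  expect_error(proportion_chisq(8, 8, 10), "exceeds")
})

test_that("window mean test matches a hand paired-t oracle", {
  mk <- function(v) make_zprofile(v, 1, c(0, 1))
  pa <- list(u1 = mk(2), u2 = mk(3), u3 = mk(5))
  pb <- list(u1 = mk(1), u2 = mk(2), u3 = mk(3))
  res <- window_mean_test(pa, pb, c(0, 1))
  expect_equal(res$t, 4.0, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  same <- window_mean_test(pa, pa, c(0, 1))
  expect_equal(same$t, 0)
  const <- window_mean_test(pa, lapply(pa, function(p) mk(p$z - 2)), c(0, 1))
  expect_true(const$degenerate)
  expect_error(window_mean_test(pa[1], pb[1], c(0, 1)), "at least 2")
  expect_error(window_mean_test(pa, pb[1:2], c(0, 1)), "same units")
})

test_that("population profile averages unit profiles bin-wise", {
  mk <- function(v) make_zprofile(v, 1, c(0, length(v)))
  single <- population_profile(list(u1 = mk(c(1, 2))), context = "A")
  expect_equal(single$mean_z, c(1, 2))
  expect_equal(single$se_z, c(0, 0))
  pair <- population_profile(list(a = mk(c(1, -2)), b = mk(c(-1, 2))))
  expect_equal(pair$mean_z, c(0, 0))
  expect_error(population_profile(list(a = mk(1:2), b = mk(1:3))),
               "mismatched")
})

test_that("two-within RM ANOVA matches stats::aov and is label-symmetric", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:8, 1); a <- sample(2:3, 1); b <- sample(2:3, 1)
    df <- expand.grid(subject = paste0("s", 1:n), f1 = paste0("a", 1:a),
                      f2 = paste0("b", 1:b), stringsAsFactors = FALSE)
    df$value <- rnorm(nrow(df)) +
      rnorm(a)[match(df$f1, unique(df$f1))] +
      rnorm(n)[match(df$subject, unique(df$subject))]
    res <- rm_anova_2within(df)
    ref <- aov_2within_F(df)
    expect_equal(res$f1$F, unname(ref["f1"]), tolerance = 1e-10)
    expect_equal(res$f2$F, unname(ref["f2"]), tolerance = 1e-10)
    expect_equal(res$f1_f2$F, unname(ref["f1_f2"]), tolerance = 1e-10)
  }
  # relabeling the first factor leaves all F values unchanged
  df <- expand.grid(subject = paste0("s", 1:4), f1 = c("A", "B"),
                    f2 = c("early", "late"), stringsAsFactors = FALSE)
  set.seed(3); df$value <- rnorm(nrow(df))
  swapped <- df; swapped$f1 <- ifelse(df$f1 == "A", "B", "A")
  r1 <- rm_anova_2within(df); r2 <- rm_anova_2within(swapped)
  expect_equal(r1$f1$F, r2$f1$F, tolerance = 1e-12)
  expect_equal(r1$f1_f2$F, r2$f1_f2$F, tolerance = 1e-12)
  # all cells identical: zero SS, F flagged undefined
  flat <- df; flat$value <- 1
  rf <- rm_anova_2within(flat)
  expect_equal(rf$f1$ss, 0)
  expect_true(rf$f1$degenerate && is.na(rf$f1$F))
})

test_that("mixed-design ANOVA matches stats::aov", {
  set.seed(23)
  for (i in 1:20) {
    n_per <- sample(3:5, 2); a <- sample(2:3, 1)
    subj <- paste0("s", seq_len(sum(n_per)))
    grp <- rep(c("lesion", "sham"), n_per)
    df <- expand.grid(subject = subj, f1 = paste0("c", 1:a),
                      stringsAsFactors = FALSE)
    df$group <- grp[match(df$subject, subj)]
    df$value <- rnorm(nrow(df)) + (df$group == "lesion") * rnorm(1)
    res <- mixed_anova(df)
    ref <- aov_mixed_F(df)
    expect_equal(res$group$F, unname(ref["group"]), tolerance = 1e-10)
    expect_equal(res$f1$F, unname(ref["f1"]), tolerance = 1e-10)
    expect_equal(res$group_f1$F, unname(ref["group_f1"]), tolerance = 1e-10)
  }
})

test_that("common-baseline context profiles cancel baseline noise in the contrast", {
  ds <- quick_session(unit_spec("u1", 8), seed = 41)
  zp <- context_zprofiles(ds$spikes$u1, ds$events, 1, c(-20, 30), c(-20, 0))
  expect_identical(zp$A$baseline, zp$B$baseline)
  # per-context profiles have context-specific baselines instead
  zpc <- context_zprofiles(ds$spikes$u1, ds$events, 1, c(-20, 30), c(-20, 0),
                           baseline = "per_context")
  expect_false(identical(zpc$A$baseline$mean, zpc$B$baseline$mean))
})

test_that("habituation split matches an independent SS decomposition", {
  u <- rbind(unit_spec("u1", 8, sustained_gain_A = 3),
             unit_spec("u2", 12, sustained_gain_A = 2.5),
             unit_spec("u3", 5, sustained_gain_A = 3.5))
  ds <- quick_session(u, seed = 19)
  hs <- habituation_split(ds$spikes, ds$events, variant = "sustained")
  ref <- aov_2within_F(hs$cells)
  expect_equal(hs$anova$f1$F, unname(ref["f1"]), tolerance = 1e-10)
  expect_equal(hs$anova$f2$F, unname(ref["f2"]), tolerance = 1e-10)
  # swapping context labels leaves the F values unchanged
  ev2 <- ds$events
  ev2$context <- ifelse(ds$events$context == "A", "B", "A")
  hs2 <- habituation_split(ds$spikes, ev2, variant = "sustained")
  expect_equal(hs2$anova$f1$F, hs$anova$f1$F, tolerance = 1e-8)
  # and negates the context effect direction
  mA <- tapply(hs$cells$value, hs$cells$f1, mean)
  mA2 <- tapply(hs2$cells$value, hs2$cells$f1, mean)
  expect_equal(unname(mA["A"] - mA["B"]), -unname(mA2["A"] - mA2["B"]),
               tolerance = 1e-8)
  # silent-baseline units are excluded with a reason
  sp <- ds$spikes; sp$mute <- numeric(0)
  hs3 <- habituation_split(sp, ds$events, variant = "short_latency")
  expect_true("mute" %in% hs3$excluded$unit_id)
  expect_error(habituation_split(ds$spikes[1], ds$events[1:4, ]),
               "6 trials")
})
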