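# Model-free measures on hand-built fixtures with exactly known values
# (fixture builders live in helper-oracles.R), plus the frequentist
# machinery.

test_that("p(high info) is exact on a hand-built session", {
  study <- horizon_study(fixture_high_info())
  hi <- p_high_info(study)
  expect_equal(nrow(hi), 1)
  expect_equal(hi$p_high_info, 3 / 4)
  expect_equal(hi$n_games, 4L)
  # all-seeking behaviour gives 1
  all_hit <- fixture_high_info()
  all_hit$choice[!all_hit$is_forced] <- rep(
    c("left", "left", "right", "right"), each = 6
  )
  expect_equal(p_high_info(horizon_study(all_hit))$p_high_info, 1)
})

test_that("p(low mean) is exact and excludes ties", {
  study <- horizon_study(fixture_low_mean())
  lo <- p_low_mean(study)
  expect_equal(lo$p_low_mean, 2 / 4)
  # make game 11's observed means tie: it drops from the denominator
  tied <- fixture_low_mean()
  tied$reward[tied$game == 11 & tied$trial <= 4] <- c(50, 52, 50, 52)
  lo2 <- p_low_mean(horizon_study(tied))
  expect_equal(lo2$n_games, 3L)
  expect_equal(lo2$p_low_mean, 1 / 3)
})

test_that("confound correlation is exact on a hand-built set of signs", {
  # six horizon-6 games with (sgn dmu, sgn dn) =
  # (+,+), (+,-), (-,+), (-,-), (+,+), (-,-)  ->  r = 1/3
  cc <- confound_correlation(horizon_study(fixture_confound()), 5)
  expect_equal(cc$correlation, 1 / 3)
  # a reward-chasing agent drives the correlation positive by trial 10
  sim <- generate_study(tiny_config(n_subjects = 4, games = 64))
  cc5 <- confound_correlation(sim$study, 5)
  cc10 <- confound_correlation(sim$study, 10)
  expect_true(all(abs(cc5$correlation) < 0.35))
  expect_true(all(cc10$correlation > cc5$correlation))
})

test_that("balanced designs keep the trial-5 confound near zero", {
  sim <- generate_study(tiny_config(n_subjects = 6, games = 160))
  cc <- confound_correlation(sim$study, 5)
  expect_true(all(abs(cc$correlation) < 0.12))
})

test_that("model-free measures are invariant under left/right relabeling", {
  sim <- generate_study(tiny_config(n_subjects = 3, games = 64))
  flipped <- horizon_study(relabel_study(tibble::as_tibble(sim$study)))
  expect_equal(p_high_info(flipped), p_high_info(sim$study))
  expect_equal(p_low_mean(flipped), p_low_mean(sim$study))
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 2x2 within design, 6 subjects: compare against the textbook partition
  set.seed(14)
  d <- expand.grid(subject = paste0("P", 1:6), f1 = c("a", "b"),
                   f2 = c("x", "y"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 10, 2) +
    ifelse(d$f1 == "b", 1.5, 0) + ifelse(d$f2 == "y", -1, 0)
  an <- rm_anova(d, "y", within = c("f1", "f2"))
  expect_equal(an$F[an$effect == "f1"], hand_rm_F(d, "f1"), tolerance = 1e-10)
  expect_equal(an$F[an$effect == "f2"], hand_rm_F(d, "f2"), tolerance = 1e-10)
  expect_equal(an$df2[an$effect == "f1"], 5)
  # constant response: F collapses to 0 (or NaN-free zero SS)
  d0 <- d
  d0$y <- 7
  an0 <- rm_anova(d0, "y", within = c("f1", "f2"))
  expect_true(nrow(an0) == 0 || all(an0$F < 1e-10))
  # incomplete subjects are refused
  expect_error(rm_anova(d[-1, ], "y", within = c("f1", "f2")), "unbalanced")
})

test_that("ANOVA error structure matches the two-session cohort layout", {
  sim <- generate_study(tiny_config(n_subjects = 9, games = 32))
  mf <- model_free_summary(sim$study)
  an <- rm_anova(mf, "p_high_info", within = c("horizon", "tms_condition"))
  # (1, n-1) tests for the within effects
  expect_true(all(an$df1 == 1))
  expect_true(all(an$df2 == 8))
  expect_setequal(
    an$effect,
    c("horizon", "tms_condition", "horizon:tms_condition")
  )
  # with a between factor, order interactions are reported too
  ord <- dplyr::distinct(tibble::as_tibble(sim$study), subject, tms_condition,
                         session_order)
  ord <- ord[ord$session_order == "first", c("subject", "tms_condition")]
  names(ord)[2] <- "first_condition"
  mfo <- dplyr::left_join(mf, ord, by = "subject")
  ano <- rm_anova(mfo, "p_high_info", within = c("horizon", "tms_condition"),
                  between = "first_condition")
  expect_true("first_condition" %in% ano$effect)
  expect_true("horizon:tms_condition:first_condition" %in% ano$effect)
})

test_that("ANOVA p-values are well-behaved under label shuffling", {
  sim <- generate_study(tiny_config(n_subjects = 8, games = 32, seed = 31))
  mf <- model_free_summary(sim$study)
  set.seed(9)
  ps <- replicate(20, {
    shuf <- mf
    for (s in unique(shuf$subject)) {
      if (runif(1) < 0.5) {
        i <- shuf$subject == s
        shuf$tms_condition[i] <- ifelse(shuf$tms_condition[i] == "rfpc",
                                        "vertex", "rfpc")
      }
    }
    an <- rm_anova(shuf, "p_high_info", within = c("horizon", "tms_condition"))
    an$p[an$effect == "tms_condition"]
  })
  # roughly uniform: no pile-up of small p-values
  expect_lt(mean(ps < 0.05), 0.3)
  expect_gt(mean(ps), 0.2)
})

test_that("paired t-test matches the closed form and sidedness", {
  d <- tibble::tibble(
    subject = rep(paste0("P", 1:6), 2),
    tms_condition = rep(c("vertex", "rfpc"), each = 6),
    horizon = 6,
    p_high_info = c(0.8, 0.7, 0.9, 0.6, 0.75, 0.85,
                    0.6, 0.65, 0.7, 0.55, 0.6, 0.7)
  )
  tt <- posthoc_ttest(d, "p_high_info", 6, "greater")
  diffs <- d$p_high_info[1:6] - d$p_high_info[7:12]
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(6))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 5)
  expect_equal(tt$p, pt(t_hand, 5, lower.tail = FALSE), tolerance = 1e-12)
  # identical pairs give t = 0
  d0 <- d
  d0$p_high_info <- rep(d0$p_high_info[1:6], 2)
  expect_equal(posthoc_ttest(d0, "p_high_info", 6, "two.sided")$t, 0)
})

test_that("later-trials analysis produces curves and the 6-level ANOVA", {
  sim <- generate_study(tiny_config(n_subjects = 7, games = 64, seed = 19))
  lt <- later_trials_analysis(sim$study)
  expect_setequal(unique(lt$curves$free_trial), 1:6)
  an <- lt$anova_high_info
  trial_row <- an[an$effect == "free_trial", ]
  expect_equal(trial_row$df1, 5)
  expect_equal(trial_row$df2, 5 * 6)
  # information seeking declines over the game for a reward-driven agent
  curve <- dplyr::summarise(
    dplyr::group_by(lt$curves, free_trial),
    p = mean(p_high_info), .groups = "drop"
  )
  expect_lt(curve$p[curve$free_trial == 6], curve$p[curve$free_trial == 1])
})
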