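# Synthetic-study generator: design balance, determinism, ground truth.

test_that("session design is balanced over the task factors", {
  cfg <- study_config(n_subjects = 1, games_per_session = 160, seed = 5)
  design <- generate_design(cfg)
  expect_equal(nrow(design), 160)
  expect_equal(sum(design$horizon == 1), 80)
  expect_equal(sum(design$horizon == 6), 80)
  expect_equal(sum(design$info_condition == "unequal_13"), 80)
  diffs <- abs(design$mean_left - design$mean_right)
  expect_true(all(diffs %in% c(4, 8, 12, 20)))
  expect_equal(as.vector(table(diffs)), rep(40L, 4))
  # one mean anchored, better side balanced
  expect_true(all(design$mean_left == 40 | design$mean_left == 60 |
                    design$mean_right == 40 | design$mean_right == 60))
  expect_equal(sum(design$mean_left > design$mean_right), 80)
  # forced counts respect the information condition
  n_left <- vapply(design$forced_sequence, function(fs) sum(fs == "left"),
                   integer(1))
  expect_true(all(n_left[design$info_condition == "equal_22"] == 2))
  expect_true(all(n_left[design$info_condition == "unequal_13"] %in% c(1, 3)))
  # non-divisible game counts warn but stay close to balance
  expect_warning(generate_design(study_config(games_per_session = 50)),
                 "not a multiple")
})

test_that("generation is deterministic and stable under cohort growth", {
  cfg <- tiny_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$study, s2$study)
  expect_identical(s1$truth, s2$truth)
  # the same design comes back for the same seed
  expect_identical(generate_design(cfg, seed = 3), generate_design(cfg, seed = 3))
  # adding a subject leaves existing subjects' trials untouched
  bigger <- generate_study(tiny_config(n_subjects = 5))
  small_trials <- tibble::as_tibble(s1$study)
  big_trials <- dplyr::filter(tibble::as_tibble(bigger$study),
                              .data$subject %in% unique(small_trials$subject))
  expect_equal(big_trials, small_trials)
})

test_that("study assembly has the expected shape and validates", {
  cfg <- tiny_config(n_subjects = 3, games = 32)
  sim <- generate_study(cfg)
  trials <- tibble::as_tibble(sim$study)
  # 3 subjects x 2 sessions x 32 games
  expect_equal(length(unique(paste(trials$subject, trials$tms_condition))), 6)
  expect_equal(nrow(dplyr::distinct(trials, subject, tms_condition, game)),
               3 * 2 * 32)
  # horizon-1 games have 5 rows, horizon-6 games 10
  per_game <- dplyr::count(trials, subject, tms_condition, game, horizon)
  expect_true(all(per_game$n[per_game$horizon == 1] == 5))
  expect_true(all(per_game$n[per_game$horizon == 6] == 10))
  # truth ledger covers 13 parameters per subject-session
  expect_equal(nrow(sim$truth), 6 * 13)
  # session order counterbalanced: odd subjects rfpc first
  first <- dplyr::distinct(trials, subject, tms_condition, session_order)
  s1 <- first[first$subject == "S01" & first$session_order == "first", ]
  s2 <- first[first$subject == "S02" & first$session_order == "first", ]
  expect_equal(s1$tms_condition, "rfpc")
  expect_equal(s2$tms_condition, "vertex")
})

test_that("missing-session flag drops exactly one session", {
  cfg <- tiny_config(n_subjects = 3, missing_second_session = 2L)
  sim <- generate_study(cfg)
  sess <- dplyr::distinct(tibble::as_tibble(sim$study), subject, tms_condition)
  expect_equal(nrow(sess), 5)
  expect_equal(sum(sess$subject == "S02"), 1)
  # validation still clean (missing sessions are legal)
  expect_equal(nrow(validate_study(sim$study, expected_games = 32)), 0L)
})

test_that("rewards track the generative means", {
  sim <- generate_study(tiny_config(n_subjects = 2, games = 160))
  trials <- dplyr::filter(tibble::as_tibble(sim$study), is_forced)
  err <- dplyr::summarise(
    dplyr::group_by(trials, chosen_mean = ifelse(choice == "left",
                                                 mean_left, mean_right)),
    m = mean(reward), n = dplyr::n(), .groups = "drop"
  )
  # sample means within 4 standard errors of the generative mean
  expect_true(all(abs(err$m - err$chosen_mean) < 4 * 8 / sqrt(err$n)))
})

test_that("an injected bonus deficit shows up in information seeking", {
  cfg <- study_config(n_subjects = 10, games_per_session = 160,
                      tms_effect = list(A_h6 = -8), seed = 21)
  sim <- generate_study(cfg)
  hi <- p_high_info(sim$study)
  m <- dplyr::summarise(
    dplyr::group_by(hi, .data$tms_condition, .data$horizon),
    p = mean(p_high_info), .groups = "drop"
  )
  p_rfpc_h6 <- m$p[m$tms_condition == "rfpc" & m$horizon == 6]
  p_vert_h6 <- m$p[m$tms_condition == "vertex" & m$horizon == 6]
  expect_lt(p_rfpc_h6, p_vert_h6)
  # and with the default positive bonus truth, h6 seeks more than h1
  p_vert_h1 <- m$p[m$tms_condition == "vertex" & m$horizon == 1]
  expect_gt(p_vert_h6, p_vert_h1)
})

test_that("study bundles round-trip through disk", {
  cfg <- tiny_config(n_subjects = 2)
  sim <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study_bundle(sim, cfg, dir)
  expect_true(file.exists(file.path(dir, "horizon_trials.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_study_csv(file.path(dir, "horizon_trials.csv"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$study))
  truth_back <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_back$value, sim$truth$value, tolerance = 1e-12)
})
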