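#' Configuration of a synthetic Horizon-Task study
#'
#' Describes a full two-session (stimulation vs control) synthetic study
#' with the published task design: 160 games per session, horizons 1 and 6,
#' unequal `[1 3]` and equal `[2 2]` information conditions, Gaussian
#' payoffs with SD 8, generative mean differences \{4, 8, 12, 20\} with one
#' mean anchored at 40 or 60, and session order counterbalanced across
#' subjects.
#'
#' `hyper_truth` holds the group-level generative distributions of the 13
#' subject parameters; defaults are plausible for this task family (prior
#' mean near the generative mean of 50, initial learning rate above the
#' asymptotic one, information bonus and decision noise larger at horizon
#' 6). `tms_effect` injects additive shifts onto the group means of the
#' stimulation (`rfpc`) condition relative to control (`vertex`), e.g.
#' `list(A_h6 = -5)` reduces the horizon-6 information bonus by 5 points.
#'
#' @param n_subjects Number of subjects.
#' @param games_per_session Games per session (default 160).
#' @param reward_sd Payoff standard deviation in points (default 8).
#' @param mean_diffs Candidate |mean difference| values.
#' @param anchor_means Candidate anchor means.
#' @param hyper_truth List of group-level generative parameters; see
#'   [default_hyper_truth()].
#' @param tms_effect Named list of additive shifts applied to `rfpc` group
#'   means; names among `R0`, `alpha1`, `alpha_inf`, `A_h1`, `A_h6`,
#'   `B_<cell>`, `sigma_<cell>`.
#' @param missing_second_session Integer vector of subject indices whose
#'   second session is dropped (emulating attrition).
#' @param seed Master seed; per-subject-session streams are derived from it
#'   arithmetically, so adding subjects never perturbs existing ones.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 25,
                         games_per_session = 160,
                         reward_sd = 8,
                         mean_diffs = c(4, 8, 12, 20),
                         anchor_means = c(40, 60),
                         hyper_truth = default_hyper_truth(),
                         tms_effect = list(),
                         missing_second_session = integer(0),
                         seed = 1L) {
  stopifnot(n_subjects >= 1, games_per_session >= 8, reward_sd > 0)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      games_per_session = as.integer(games_per_session),
      reward_sd = reward_sd,
      mean_diffs = mean_diffs,
      anchor_means = anchor_means,
      hyper_truth = hyper_truth,
      tms_effect = tms_effect,
      missing_second_session = as.integer(missing_second_session),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Default group-level generative parameters
#'
#' Group means/SDs used to draw subject-level parameters in synthetic
#' studies. Values sit in the region reported for adults on this task:
#' prior mean near 50, initial learning rate around 0.6 and asymptotic
#' around 0.25 (a recency bias), information bonus and decision noise both
#' increasing with horizon, and small spatial biases. Learning-rate draws
#' use Beta distributions; decision noise uses Gamma (shape/rate).
#'
#' @return A list with elements `R0` (`mean`, `sd`), `alpha1` / `alpha_inf`
#'   (`a`, `b`), `A` (`mean`, `sd` per horizon), `B` and `sigma`
#'   (per-cell `mean`/`sd`, or `shape`/`rate` for `sigma`).
#' @export
default_hyper_truth <- function() {
  list(
    R0 = list(mean = 50, sd = 6),
    alpha1 = list(a = 6, b = 4),      # mean 0.6
    alpha_inf = list(a = 2, b = 6),   # mean 0.25
    A = list(
      h1 = list(mean = 4, sd = 4),
      h6 = list(mean = 9, sd = 6)
    ),
    B = list(
      h1_u13 = list(mean = 0, sd = 3), h1_u22 = list(mean = 0, sd = 3),
      h6_u13 = list(mean = 0, sd = 3), h6_u22 = list(mean = 0, sd = 3)
    ),
    sigma = list(
      h1_u13 = list(shape = 6, rate = 6 / 7),   # mean 7
      h1_u22 = list(shape = 6, rate = 6 / 5),   # mean 5
      h6_u13 = list(shape = 6, rate = 6 / 11),  # mean 11
      h6_u22 = list(shape = 6, rate = 6 / 9)    # mean 9
    )
  )
}

# Deterministic per-subject-session stream seed from the master seed.
# Primes keep distinct (subject, session) pairs on distinct streams; the
# modulus keeps the value inside R's 32-bit integer range.
.stream_seed <- function(master, subject_idx, session_idx, salt = 0L) {
  (as.double(master) * 2654435761 + subject_idx * 7919 +
     session_idx * 104729 + salt * 15485863) %% 2147483647
}

#' Generate the game designs of one session
#'
#' Balanced factorial allocation over horizon (2) x information condition
#' (2) x |mean difference| (4) x better side (2) = 32 cells; with the
#' default 160 games each cell appears 5 times. Within a cell's
#' repetitions the anchor value (40 / 60) and whether the anchor sits on
#' the better or worse option are cycled; leftover games (when the game
#' count is not a multiple of 32) are allocated round-robin with a warning.
#' Game order and the forced sequences are randomized under the seed: in
#' `[1 3]` games the once-forced side is drawn uniformly and the four
#' forced positions are a random permutation.
#'
#' @param cfg A [study_config()].
#' @param seed Stream seed for this session's design.
#' @return Tibble, one row per game: `game`, `horizon`, `info_condition`,
#'   `mean_left`, `mean_right`, plus list-column `forced_sequence`.
#' @export
generate_design <- function(cfg, seed = cfg$seed) {
  n <- cfg$games_per_session
  cells <- expand.grid(
    horizon = c(1L, 6L),
    info_condition = .info_levels,
    diff = cfg$mean_diffs,
    better_side = c("left", "right"),
    stringsAsFactors = FALSE
  )
  n_cells <- nrow(cells) # 32
  reps <- n %/% n_cells
  extra <- n %% n_cells
  if (extra != 0) {
    warning(sprintf(
      "games_per_session = %d is not a multiple of %d design cells; %d cells get an extra game",
      n, n_cells, extra
    ))
  }
  idx <- c(rep(seq_len(n_cells), each = reps), seq_len(extra))
  games <- cells[idx, , drop = FALSE]
  # Cycle anchor placement across a cell's repetitions: anchor value x
  # whether the anchored mean is the better or the worse one.
  anchor_combos <- expand.grid(
    anchor = cfg$anchor_means, anchor_on = c("better", "worse"),
    stringsAsFactors = FALSE
  )
  within_rep <- stats::ave(seq_len(nrow(games)), idx, FUN = seq_along)
  combo <- anchor_combos[((within_rep - 1) %% nrow(anchor_combos)) + 1, ]
  m_better <- ifelse(combo$anchor_on == "better", combo$anchor,
                     combo$anchor + games$diff)
  m_worse <- m_better - games$diff
  games$mean_left <- ifelse(games$better_side == "left", m_better, m_worse)
  games$mean_right <- ifelse(games$better_side == "left", m_worse, m_better)

  old_seed <- .preserve_rng(seed)
  on.exit(.restore_rng(old_seed), add = TRUE)
  games <- games[sample.int(nrow(games)), , drop = FALSE]
  games$game <- seq_len(nrow(games))
  games$forced_sequence <- lapply(seq_len(nrow(games)), function(i) {
    if (games$info_condition[i] == "equal_22") {
      sample(c("left", "left", "right", "right"))
    } else {
      once <- sample(c("left", "right"), 1)
      thrice <- if (once == "left") "right" else "left"
      sample(c(once, thrice, thrice, thrice))
    }
  })
  tibble::as_tibble(games[, c("game", "horizon", "info_condition",
                              "mean_left", "mean_right", "forced_sequence")])
}

# Seed scoping: run a block under a given seed without clobbering the
# caller's RNG stream.
.preserve_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Draw one subject's 13 parameters per TMS condition from hyper_truth,
# applying tms_effect shifts to the rfpc condition's group means.
.draw_subject_params <- function(ht, tms_effect, tms) {
  shift <- function(name) {
    if (tms == "rfpc" && !is.null(tms_effect[[name]])) tms_effect[[name]] else 0
  }
  clamp01 <- function(x) min(max(x, 1e-4), 1 - 1e-4)
  cells <- c("h1_u13", "h1_u22", "h6_u13", "h6_u22")
  A <- vapply(c("h1", "h6"), function(h) {
    stats::rnorm(1, ht$A[[h]]$mean + shift(paste0("A_", h)), ht$A[[h]]$sd)
  }, numeric(1))
  B <- vapply(cells, function(cl) {
    stats::rnorm(1, ht$B[[cl]]$mean + shift(paste0("B_", cl)), ht$B[[cl]]$sd)
  }, numeric(1))
  sigma <- vapply(cells, function(cl) {
    s <- stats::rgamma(1, shape = ht$sigma[[cl]]$shape, rate = ht$sigma[[cl]]$rate) +
      shift(paste0("sigma_", cl))
    max(s, 0.5)
  }, numeric(1))
  list(
    R0 = stats::rnorm(1, ht$R0$mean + shift("R0"), ht$R0$sd),
    alpha1 = clamp01(stats::rbeta(1, ht$alpha1$a, ht$alpha1$b) + shift("alpha1")),
    alpha_inf = clamp01(stats::rbeta(1, ht$alpha_inf$a, ht$alpha_inf$b) + shift("alpha_inf")),
    A = A, B = B, sigma = sigma
  )
}

#' Simulate one subject's pair of sessions
#'
#' Draws the subject's 13 parameters per stimulation condition from
#' `cfg$hyper_truth` (with `cfg$tms_effect` shifts applied to the `rfpc`
#' group means), generates a fresh session design per session, simulates
#' forced-trial rewards from the generative Gaussians (rounded to integer
#' points), and plays out the free choices with
#' [simulate_free_choices()]. Session order alternates with subject index
#' (odd subjects receive `rfpc` first).
#'
#' @param cfg A [study_config()].
#' @param subject_idx Subject index (1-based).
#' @return List: `trials` (tibble of both sessions) and `truth` (the drawn
#'   parameters per condition).
#' @export
generate_subject <- function(cfg, subject_idx) {
  subject_id <- sprintf("S%02d", subject_idx)
  order_map <- if (subject_idx %% 2 == 1) c("rfpc", "vertex") else c("vertex", "rfpc")
  sessions <- list()
  truth <- list()
  for (session_idx in 1:2) {
    tms <- order_map[session_idx]
    if (session_idx == 2 && subject_idx %in% cfg$missing_second_session) next
    par_seed <- .stream_seed(cfg$seed, subject_idx, session_idx, salt = 1L)
    old <- .preserve_rng(par_seed)
    pars <- .draw_subject_params(cfg$hyper_truth, cfg$tms_effect, tms)
    .restore_rng(old)
    design <- generate_design(
      cfg, seed = .stream_seed(cfg$seed, subject_idx, session_idx, salt = 2L)
    )
    play_seed <- .stream_seed(cfg$seed, subject_idx, session_idx, salt = 3L)
    old <- .preserve_rng(play_seed)
    fa <- vapply(design$forced_sequence, function(fs) {
      as.integer(fs == "right")
    }, integer(4))
    res <- .sim_session_cpp(
      as.integer(design$horizon),
      as.integer(design$info_condition == "equal_22"),
      design$mean_left, design$mean_right, fa, cfg$reward_sd,
      pars$R0, pars$alpha1, pars$alpha_inf, 0L,
      unname(pars$A[c("h1", "h6")]),
      unname(pars$B[c("h1_u13", "h1_u22", "h6_u13", "h6_u22")]),
      unname(pars$sigma[c("h1_u13", "h1_u22", "h6_u13", "h6_u22")])
    )
    .restore_rng(old)
    n_free <- ifelse(design$horizon == 1, 1L, 6L)
    n_tot <- 4L + n_free
    g_idx <- rep(seq_len(nrow(design)), n_tot)
    trial <- unlist(lapply(n_tot, seq_len), use.names = FALSE)
    is_forced <- trial <= 4L
    choice_code <- integer(length(trial))
    reward <- numeric(length(trial))
    fi <- trial - 4L
    fo <- cbind(trial[is_forced], g_idx[is_forced])
    fe <- cbind(fi[!is_forced], g_idx[!is_forced])
    choice_code[is_forced] <- fa[fo]
    choice_code[!is_forced] <- res$free_choice[fe]
    reward[is_forced] <- res$fr[fo]
    reward[!is_forced] <- res$free_reward[fe]
    sess <- tibble::tibble(
      game = design$game[g_idx],
      horizon = design$horizon[g_idx],
      info_condition = design$info_condition[g_idx],
      trial = trial,
      is_forced = is_forced,
      choice = ifelse(choice_code == 1L, "right", "left"),
      reward = reward,
      mean_left = design$mean_left[g_idx],
      mean_right = design$mean_right[g_idx]
    )
    sess$subject <- subject_id
    sess$tms_condition <- tms
    sess$session_order <- c("first", "second")[session_idx]
    sessions[[tms]] <- sess
    truth[[tms]] <- pars
  }
  list(
    trials = dplyr::bind_rows(sessions)[, .trial_cols],
    truth = truth,
    subject = subject_id
  )
}

#' Generate a complete synthetic study with ground truth
#'
#' Assembles `cfg$n_subjects` subjects into a [horizon_study()] and a
#' ground-truth ledger of every generative parameter, suitable for
#' parameter-recovery scoring. Deterministic: the same config and seed give
#' a byte-identical canonical CSV.
#'
#' @param cfg A [study_config()].
#' @return List: `study` (a `horizon_study`) and `truth` (tibble of
#'   subject-level generative parameters, one row per subject x condition
#'   x parameter).
#' @export
generate_study <- function(cfg) {
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) generate_subject(cfg, i))
  trials <- dplyr::bind_rows(lapply(subjects, `[[`, "trials"))
  truth <- dplyr::bind_rows(lapply(subjects, function(su) {
    dplyr::bind_rows(lapply(names(su$truth), function(tms) {
      p <- su$truth[[tms]]
      tibble::tibble(
        subject = su$subject, tms_condition = tms,
        parameter = c("R0", "alpha1", "alpha_inf",
                      paste0("A_", names(p$A)),
                      paste0("B_", names(p$B)),
                      paste0("sigma_", names(p$sigma))),
        value = unname(c(p$R0, p$alpha1, p$alpha_inf, p$A, p$B, p$sigma))
      )
    }))
  }))
  list(
    study = horizon_study(
      trials,
      design_metadata = sprintf(
        "synthetic: %d subjects x 2 sessions x %d games, seed %d",
        cfg$n_subjects, cfg$games_per_session, cfg$seed
      )
    ),
    truth = truth
  )
}

#' Write a synthetic study bundle to disk
#'
#' Canonical trials CSV, JSON truth ledger, and a YAML copy of the config.
#'
#' @param sim Result of [generate_study()].
#' @param cfg The [study_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(sim, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_study_csv(sim$study, file.path(dir, "horizon_trials.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), digits = NA)
  cfg_out <- cfg
  cfg_out$hyper_truth <- NULL # nested truth already serialized in truth.json
  yaml::write_yaml(unclass(cfg_out), file.path(dir, "config.yaml"))
  invisible(dir)
}
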