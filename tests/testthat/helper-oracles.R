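# Independent oracles and small fixture builders shared across tests.

# Variance-space Kalman filter: tracks the posterior mean and variance of
# each option's mean payoff directly in sigma^2 units (observation noise
# sigma_r^2, drift sigma_d^2, prior variance sigma0^2). Written from the
# generative description, independent of the package's learning-rate-space
# implementation.
sigma_space_kalman <- function(choices, rewards, R0, sigma0_sq, sigma_d_sq,
                               sigma_r_sq) {
  R <- c(left = R0, right = R0)
  v <- c(left = sigma0_sq, right = sigma0_sq)
  for (k in seq_along(choices)) {
    i <- choices[k]
    j <- setdiff(c("left", "right"), i)
    v_pre <- v[[i]] + sigma_d_sq
    gain <- v_pre / (v_pre + sigma_r_sq)
    R[[i]] <- R[[i]] + gain * (rewards[k] - R[[i]])
    v[[i]] <- gain * sigma_r_sq # 1/v_post = 1/v_pre + 1/sigma_r^2
    v[[j]] <- v[[j]] + sigma_d_sq
  }
  list(R = R, v = v)
}

# Variance-space parameters matched to a learning-rate parameterization
# (valid whenever the implied prior variance is non-negative).
matched_sigma_params <- function(alpha1, alpha_inf, sigma_r_sq = 64) {
  vr <- implied_variance_ratios(alpha1 = alpha1, alpha_inf = alpha_inf)
  stopifnot(vr[["omega0"]] >= 0)
  list(
    sigma0_sq = vr[["omega0"]] * sigma_r_sq,
    sigma_d_sq = vr[["alpha_d"]] * sigma_r_sq,
    sigma_r_sq = sigma_r_sq
  )
}

# A single hand-buildable game as canonical trial rows.
make_game <- function(subject = "S01", tms = "vertex", game = 1, horizon = 6,
                      info = "unequal_13", forced, rewards, free_choices,
                      free_rewards, mean_left = 60, mean_right = 40,
                      session_order = "first") {
  n_free <- length(free_choices)
  tibble::tibble(
    subject = subject, tms_condition = tms, session_order = session_order,
    game = game, horizon = horizon, info_condition = info,
    trial = seq_len(4 + n_free),
    is_forced = c(rep(TRUE, 4), rep(FALSE, n_free)),
    choice = c(forced, free_choices),
    reward = c(rewards, free_rewards),
    mean_left = mean_left, mean_right = mean_right
  )
}

# Flip left/right in a trials table (choices, means); used by the
# relabeling-invariance tests. Decision parameters must flip B -> -B.
relabel_study <- function(trials) {
  trials <- tibble::as_tibble(trials)
  trials$choice <- ifelse(trials$choice == "left", "right", "left")
  ml <- trials$mean_left
  trials$mean_left <- trials$mean_right
  trials$mean_right <- ml
  trials
}

flip_decision_params <- function(dp) {
  decision_params(A = dp$A, B = -dp$B, sigma = dp$sigma)
}

# Maximum absolute discrepancy between the learning-rate-space learner and
# the variance-space Kalman oracle over random parameterizations and trial
# sequences.
max_kalman_error <- function(n_seq, seed = 421) {
  set.seed(seed)
  max_err <- 0
  for (k in seq_len(n_seq)) {
    repeat {
      a1 <- runif(1, 0.05, 0.95)
      ainf <- runif(1, 0, a1)
      if (implied_variance_ratios(alpha1 = a1, alpha_inf = ainf)[["omega0"]] >= 0) break
    }
    R0 <- runif(1, 30, 70)
    p <- learning_params(R0, a1, ainf)
    sig <- matched_sigma_params(a1, ainf, sigma_r_sq = runif(1, 10, 100))
    n_tr <- sample(3:8, 1)
    choices <- sample(c("left", "right"), n_tr, replace = TRUE)
    rewards <- round(rnorm(n_tr, 50, 8))
    st <- init_state(p)
    for (t in seq_len(n_tr)) {
      other <- setdiff(c("left", "right"), choices[t])
      st <- update_chosen(st, choices[t], rewards[t], p)
      st <- propagate_unchosen(st, other, p)
    }
    oracle <- sigma_space_kalman(choices, rewards, R0, sig$sigma0_sq,
                                 sig$sigma_d_sq, sig$sigma_r_sq)
    max_err <- max(max_err, abs(st$R[["left"]] - oracle$R[["left"]]),
                   abs(st$R[["right"]] - oracle$R[["right"]]))
  }
  max_err
}

# Hand-built model-free fixtures (exact expected values derived in the
# tests that use them).

# Four unequal-condition horizon-6 games, one subject: the free choice at
# trial 5 picks the once-played option in games 1, 3 and 4 -> 3/4.
fixture_high_info <- function() {
  rw <- c(50, 50, 50, 50)
  dplyr::bind_rows(
    make_game(game = 1, forced = c("left", "right", "right", "right"),
              rewards = rw, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),  # once = left, chose left: hit
    make_game(game = 2, forced = c("left", "right", "right", "right"),
              rewards = rw, free_choices = rep("right", 6),
              free_rewards = rep(50, 6)),  # once = left, chose right: miss
    make_game(game = 3, forced = c("right", "left", "left", "left"),
              rewards = rw, free_choices = rep("right", 6),
              free_rewards = rep(50, 6)),  # once = right, chose right: hit
    make_game(game = 4, forced = c("right", "left", "left", "left"),
              rewards = rw, free_choices = rep("right", 6),
              free_rewards = rep(50, 6))   # hit
  )
}

# Four equal-condition games: observed forced means decide the "low" side;
# the subject picks the lower-mean side in games 11 and 12 -> 2/4.
fixture_low_mean <- function() {
  dplyr::bind_rows(
    make_game(game = 11, info = "equal_22",
              forced = c("left", "left", "right", "right"),
              rewards = c(60, 58, 42, 44), free_choices = rep("right", 6),
              free_rewards = rep(50, 6)),  # right mean 43 < 59: mistake
    make_game(game = 12, info = "equal_22",
              forced = c("left", "right", "left", "right"),
              rewards = c(40, 61, 44, 59), free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),  # left mean 42 < 60: mistake
    make_game(game = 13, info = "equal_22",
              forced = c("left", "left", "right", "right"),
              rewards = c(60, 58, 42, 44), free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),  # correct
    make_game(game = 14, info = "equal_22",
              forced = c("right", "left", "right", "left"),
              rewards = c(55, 41, 57, 39), free_choices = rep("right", 6),
              free_rewards = rep(50, 6))   # correct
  )
}

# Six horizon-6 games whose (sgn dmu, sgn dn) pairs at trial 5 are
# (+,+), (+,-), (-,+), (-,-), (+,+), (-,-)  ->  Pearson r = 1/3.
fixture_confound <- function() {
  once_left <- c("left", "right", "right", "right")   # n_left - n_right = -2
  thrice_left <- c("right", "left", "left", "left")   # +2
  rw <- c(50, 50, 50, 50)
  dplyr::bind_rows(
    make_game(game = 1, forced = thrice_left, rewards = rw, mean_left = 60,
              mean_right = 40, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),
    make_game(game = 2, forced = once_left, rewards = rw, mean_left = 60,
              mean_right = 48, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),
    make_game(game = 3, forced = thrice_left, rewards = rw, mean_left = 40,
              mean_right = 60, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),
    make_game(game = 4, forced = once_left, rewards = rw, mean_left = 48,
              mean_right = 60, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),
    make_game(game = 5, forced = thrice_left, rewards = rw, mean_left = 60,
              mean_right = 40, free_choices = rep("left", 6),
              free_rewards = rep(50, 6)),
    make_game(game = 6, forced = once_left, rewards = rw, mean_left = 48,
              mean_right = 60, free_choices = rep("left", 6),
              free_rewards = rep(50, 6))
  )
}

# Hand F ratio for a 2x2 within-subject design (main effect of factor f),
# from the textbook sums-of-squares partition.
hand_rm_F <- function(d, f) {
  n <- length(unique(d$subject))
  gm <- mean(d$y)
  m_f <- tapply(d$y, d[[f]], mean)
  m_s <- tapply(d$y, d$subject, mean)
  m_fs <- tapply(d$y, list(d[[f]], d$subject), mean)
  ss_f <- 2 * n * sum((m_f - gm)^2)
  ss_fs <- 2 * sum((m_fs - outer(m_f - gm, m_s - gm, `+`) - gm)^2)
  (ss_f / 1) / (ss_fs / (n - 1))
}

# Small standard config for tests that need a quick full study.
tiny_config <- function(n_subjects = 4, games = 32, seed = 7, ...) {
  study_config(n_subjects = n_subjects, games_per_session = games,
               seed = seed, ...)
}
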