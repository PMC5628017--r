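# Learning model: learning-rate-space Kalman filter and its
# reparameterization.

test_that("learning-rate recursion matches hand-evaluated values", {
  # alpha_d = 0, alpha_prev = 0.5 -> 0.5 / 1.5
  expect_equal(alpha_step(0.5, 0), 1 / 3)
  # closed-form asymptote
  expect_equal(alpha_infinity(0), 0)
  expect_equal(alpha_infinity(1), (-1 + sqrt(5)) / 2)
  expect_error(alpha_infinity(-0.1), "alpha_d")
})

test_that("alpha_step converges monotonically to the closed-form fixed point", {
  for (ad in c(0, 0.01, 0.1, 0.5, 1, 2, 5)) {
    a_inf <- alpha_infinity(ad)
    # fixed point identity
    if (a_inf > 0) expect_equal(alpha_step(a_inf, ad), a_inf, tolerance = 1e-12)
    for (a0 in c(0.01, 0.3, 0.99)) {
      a <- a0
      diffs <- numeric(1000)
      for (t in 1:1000) {
        a <- alpha_step(a, ad)
        diffs[t] <- a - a_inf
      }
      if (ad > 0) {
        expect_lt(abs(a - a_inf), 1e-8) # geometric contraction
      } else {
        # no drift: the zero fixed point is only polynomially attracting,
        # a_t = 1/(t + 1/a_0) exactly (perfect averaging of t samples)
        expect_equal(a, 1 / (1000 + 1 / a0), tolerance = 1e-9)
      }
      # monotone approach from either side
      expect_true(all(diff(abs(diffs[1:50])) <= 1e-15))
    }
  }
})

test_that("initial state applies alpha1 to the first observation", {
  p <- learning_params(50, 0.5, 0.2)
  st <- init_state(p)
  expect_equal(unname(st$R), c(50, 50))
  st2 <- update_chosen(st, "left", 70, p)
  # alpha1 = 0.5 -> halfway to the reward
  expect_equal(st2$R[["left"]], 60)
  expect_equal(st2$R[["right"]], 50)
  # alpha1 -> 1 overwrites the prior
  p1 <- learning_params(50, 1 - 1e-12, 0.2)
  st1 <- update_chosen(init_state(p1), "left", 70, p1)
  expect_equal(st1$R[["left"]], 70, tolerance = 1e-6)
  expect_error(learning_params(50, 1.2, 0.2), "alpha1")
})

test_that("zero prediction error leaves the estimate unchanged", {
  p <- learning_params(50, 0.7, 0.3)
  st <- update_chosen(init_state(p), "right", 50, p)
  expect_equal(st$R[["right"]], 50)
})

test_that("unchosen option drifts additively and is inert at alpha_d = 0", {
  p0 <- learning_params(50, 0.6, 0)
  st <- init_state(p0)
  expect_equal(propagate_unchosen(st, "left", p0)$omega, st$omega)
  p <- learning_params(50, 0.6, 0.4)
  st <- init_state(p)
  st2 <- propagate_unchosen(propagate_unchosen(st, "left", p), "left", p)
  expect_equal(st2$omega[["left"]], st$omega[["left"]] + 2 * p$alpha_d)
})

test_that("alpha-space learner reproduces the variance-space Kalman filter", {
  # the central equivalence: across random parameterizations and random
  # trial sequences, value trajectories agree to <= 1e-10 (the full
  # 1000-sequence sweep runs in the acceptance suite)
  expect_lt(max_kalman_error(100), 1e-10)
})

test_that("skip-then-play matches the variance-space oracle", {
  p <- learning_params(50, 0.8, 0.3)
  sig <- matched_sigma_params(0.8, 0.3)
  st <- init_state(p)
  st <- update_chosen(st, "left", 62, p)
  st <- propagate_unchosen(st, "right", p)
  st <- update_chosen(st, "right", 41, p)
  st <- propagate_unchosen(st, "left", p)
  oracle <- sigma_space_kalman(c("left", "right"), c(62, 41), 50,
                               sig$sigma0_sq, sig$sigma_d_sq, sig$sigma_r_sq)
  expect_equal(unname(st$R), unname(oracle$R), tolerance = 1e-12)
})

test_that("forced-trial values: perfect averaging and trivial cases", {
  # rewards equal to the prior leave both values at R0
  p <- learning_params(50, 0.5, 0.2)
  fv <- forced_trial_values(c("left", "left", "right", "right"),
                            rep(50, 4), p)
  expect_equal(unname(fv), c(50, 50))
  # alpha1 ~ 1, alpha_inf ~ 0: perfect averaging of what was seen
  p_avg <- learning_params(50, 1 - 1e-9, 1e-9)
  fv <- forced_trial_values(c("left", "right", "left", "right"),
                            c(60, 40, 60, 40), p_avg)
  expect_equal(unname(fv), c(60, 40), tolerance = 1e-6)
  expect_error(forced_trial_values(c("left", "right"), c(1, 2), p), "4")
  expect_error(forced_trial_values(c("left", "left", "right", "right"),
                                   c(50, NA, 50, 50), p), "missing")
})

test_that("positive asymptotic rate produces a recency bias", {
  # same reward multiset on the thrice-played option, different orders:
  # a later large reward must leave a higher estimate
  p <- learning_params(50, 0.6, 0.3)
  late_big <- forced_trial_values(c("right", "left", "left", "left"),
                                  c(50, 40, 40, 70), p)
  early_big <- forced_trial_values(c("right", "left", "left", "left"),
                                   c(50, 70, 40, 40), p)
  expect_gt(late_big[["R_left"]], early_big[["R_left"]])
  # steady-state weights on past rewards decay geometrically
  a_inf <- alpha_infinity(p$alpha_d)
  # weight of reward k plays ago ~ a_inf * (1 - a_inf)^(k-1) in steady state
  n <- 30
  st <- init_state(p)
  for (t in 1:n) st <- update_chosen(st, "left", 0, p)
  base <- st$R[["left"]]
  bump <- function(at) {
    st <- init_state(p)
    for (t in 1:n) st <- update_chosen(st, "left", ifelse(t == at, 1, 0), p)
    st$R[["left"]] - base
  }
  w1 <- bump(n); w2 <- bump(n - 1); w3 <- bump(n - 2)
  expect_equal(w2 / w1, w3 / w2, tolerance = 1e-6)
  expect_lt(w2, w1)
})

test_that("learning-rate pair maps to a unique variance parameterization", {
  # (alpha1, alpha_inf) -> (omega0, alpha_d) is invertible on the valid
  # region: recomputing the learning rates from the implied variances
  # returns the originals
  set.seed(77)
  for (k in 1:50) {
    a1 <- runif(1, 0.05, 0.95)
    ainf <- runif(1, 0, a1)
    vr <- implied_variance_ratios(alpha1 = a1, alpha_inf = ainf)
    if (vr[["omega0"]] < 0) next
    # alpha_inf from alpha_d via the closed form
    expect_equal(alpha_infinity(vr[["alpha_d"]]), ainf, tolerance = 1e-10)
    # alpha1 from omega0: first-play gain with drift increment
    omega_pre <- vr[["omega0"]] + vr[["alpha_d"]]
    expect_equal(omega_pre / (1 + omega_pre), a1, tolerance = 1e-10)
  }
})

test_that("variance-ratio reading of the initial rate is available", {
  p <- learning_params(50, 0.5, 0, alpha1_mode = "variance_ratio")
  st <- update_chosen(init_state(p), "left", 70, p)
  # omega_pre = 0.5 -> applied gain 1/3
  expect_equal(st$R[["left"]], 50 + (70 - 50) / 3)
})
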