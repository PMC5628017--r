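#' Learning-model parameters
#'
#' The Kalman-filter learner is parameterized by its identifiable
#' quantities: the prior mean `R0` (points) and the initial and asymptotic
#' learning rates `alpha1`, `alpha_inf`, both in (0, 1). The underlying
#' observation/drift/prior variances are never instantiated; everything is
#' tracked in learning-rate units \eqn{\omega = \sigma^2 / \sigma_r^2}.
#' The drift ratio \eqn{\alpha_d = \sigma_d^2/\sigma_r^2} is derived from
#' `alpha_inf` by inverting the fixed-point relation:
#' \eqn{\alpha_d = \alpha_\infty^2 / (1 - \alpha_\infty)}.
#'
#' `alpha1` is interpreted by default as the learning rate actually applied
#' to the first observed outcome (a Kalman gain in (0,1), the support of its
#' Beta prior). Setting `alpha1_mode = "variance_ratio"` instead treats it
#' as the pre-observation variance ratio \eqn{(\sigma_0^2+\sigma_d^2)/\sigma_r^2},
#' whose applied gain is `alpha1 / (1 + alpha1)`.
#'
#' `alpha1 >= alpha_inf` is *not* enforced: the model permits either
#' ordering, the data decide.
#'
#' @param R0 Prior mean reward, points.
#' @param alpha1 Initial learning rate, in (0,1).
#' @param alpha_inf Asymptotic learning rate, in (0,1); 0 allowed (no drift).
#' @param alpha1_mode `"gain"` (default) or `"variance_ratio"`.
#' @return A `learning_params` list with fields `R0`, `alpha1`, `alpha_inf`,
#'   `alpha_d`, `alpha1_mode`.
#' @export
learning_params <- function(R0, alpha1, alpha_inf,
                            alpha1_mode = c("gain", "variance_ratio")) {
  alpha1_mode <- match.arg(alpha1_mode)
  if (!is.finite(R0)) stop("R0 must be finite")
  if (!is.finite(alpha1) || alpha1 <= 0 || alpha1 >= 1) {
    stop("alpha1 must be in (0, 1)")
  }
  if (!is.finite(alpha_inf) || alpha_inf < 0 || alpha_inf >= 1) {
    stop("alpha_inf must be in [0, 1)")
  }
  R0 <- unname(R0); alpha1 <- unname(alpha1); alpha_inf <- unname(alpha_inf)
  structure(
    list(
      R0 = R0, alpha1 = alpha1, alpha_inf = alpha_inf,
      alpha_d = alpha_inf^2 / (1 - alpha_inf),
      alpha1_mode = alpha1_mode
    ),
    class = "learning_params"
  )
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf(
    "<learning_params> R0 = %.3g, alpha1 = %.3g (%s), alpha_inf = %.3g (alpha_d = %.3g)\n",
    x$R0, x$alpha1, x$alpha1_mode, x$alpha_inf, x$alpha_d
  ))
  invisible(x)
}

# Pre-observation uncertainty (omega units) such that the first update of an
# option played on trial 1 applies exactly alpha1 (gain mode), or is alpha1
# itself (variance-ratio mode). init_state stores omega *before* the trial-1
# drift increment, so omega0 = omega_pre(target) - alpha_d.
.omega0 <- function(params) {
  omega_pre <- switch(params$alpha1_mode,
    gain = params$alpha1 / (1 - params$alpha1),
    variance_ratio = params$alpha1
  )
  omega_pre - params$alpha_d
}

#' Initialize the learner's state
#'
#' Both options start at the prior mean `R0`; the scaled uncertainty
#' `omega` is set so that the first observation of an option played on
#' trial 1 is weighted by `alpha1` exactly. Options first played later have
#' accumulated drift and are weighted slightly more.
#'
#' @param params A [learning_params()] object.
#' @return A `kalman_state`: list with `R` and `omega`, each a named
#'   numeric of length 2 (`left`, `right`), and trial counter `t`.
#' @export
init_state <- function(params) {
  stopifnot(inherits(params, "learning_params"))
  structure(
    list(
      R = c(left = params$R0, right = params$R0),
      omega = c(left = .omega0(params), right = .omega0(params)),
      t = 0L
    ),
    class = "kalman_state"
  )
}

#' One step of the learning-rate recursion
#'
#' The applied learning rate evolves as
#' \eqn{\alpha_t = (\alpha_{t-1} + \alpha_d) / (1 + \alpha_{t-1} + \alpha_d)}
#' under repeated play, i.e. \eqn{1/\alpha_t = 1/(\alpha_{t-1}+\alpha_d) + 1}.
#' It converges monotonically to [alpha_infinity()] of `alpha_d`.
#'
#' @param alpha_prev Previous applied learning rate, in (0,1).
#' @param alpha_d Drift ratio, >= 0.
#' @return The next learning rate, in (0,1).
#' @export
alpha_step <- function(alpha_prev, alpha_d) {
  stopifnot(all(alpha_prev > 0), all(alpha_prev < 1), all(alpha_d >= 0))
  (alpha_prev + alpha_d) / (1 + alpha_prev + alpha_d)
}

#' Asymptotic learning rate for a given drift ratio
#'
#' Closed-form fixed point of [alpha_step()]:
#' \eqn{\alpha_\infty = \tfrac12(-\alpha_d + \sqrt{\alpha_d^2 + 4\alpha_d})}.
#'
#' @param alpha_d Drift ratio \eqn{\sigma_d^2/\sigma_r^2}, >= 0.
#' @return Value in [0, 1).
#' @export
alpha_infinity <- function(alpha_d) {
  if (any(alpha_d < 0)) stop("alpha_d must be >= 0")
  0.5 * (-alpha_d + sqrt(alpha_d^2 + 4 * alpha_d))
}

#' Update the learner after observing a reward
#'
#' For the chosen option: uncertainty first grows by the drift ratio
#' (`omega_pre = omega + alpha_d`), the applied gain is
#' `omega_pre / (1 + omega_pre)`, the value estimate moves toward the
#' reward by that gain, and the stored `omega` becomes the gain itself
#' (post-update uncertainty in learning-rate units). Use
#' [propagate_unchosen()] for the other option on the same trial.
#'
#' @param state A `kalman_state`.
#' @param option `"left"` or `"right"`.
#' @param reward Observed reward, points.
#' @param params A [learning_params()] object.
#' @return Updated `kalman_state`.
#' @export
update_chosen <- function(state, option, reward, params) {
  if (!is.finite(reward)) stop("reward must be finite")
  option <- match.arg(option, c("left", "right"))
  omega_pre <- state$omega[[option]] + params$alpha_d
  alpha <- omega_pre / (1 + omega_pre)
  state$R[[option]] <- state$R[[option]] + alpha * (reward - state$R[[option]])
  state$omega[[option]] <- alpha
  state$t <- state$t + 1L
  state
}

#' Propagate the unchosen option's uncertainty
#'
#' The value estimate is unchanged; the scaled uncertainty grows by the
#' drift ratio, reflecting the learner's assumption that the unobserved
#' mean drifts between trials. With `alpha_d = 0` this is a no-op.
#'
#' @inheritParams update_chosen
#' @return Updated `kalman_state`.
#' @export
propagate_unchosen <- function(state, option, params) {
  option <- match.arg(option, c("left", "right"))
  state$omega[[option]] <- state$omega[[option]] + params$alpha_d
  state
}

#' Option values entering the first free choice
#'
#' Runs the learner over the four forced trials of a game, in order, and
#' returns both option-value estimates at the moment of the first free
#' choice.
#'
#' @param forced_choices Character vector, 4 forced choices (`"left"`/`"right"`).
#' @param forced_rewards Numeric vector, the 4 observed rewards.
#' @param params A [learning_params()] object.
#' @return Named numeric: `R_left`, `R_right`.
#' @export
forced_trial_values <- function(forced_choices, forced_rewards, params) {
  if (length(forced_choices) != 4 || length(forced_rewards) != 4) {
    stop("need exactly 4 forced choices and rewards")
  }
  if (any(!is.finite(forced_rewards))) stop("missing forced rewards")
  st <- init_state(params)
  for (k in 1:4) {
    chosen <- forced_choices[k]
    other <- if (chosen == "left") "right" else "left"
    st <- update_chosen(st, chosen, forced_rewards[k], params)
    st <- propagate_unchosen(st, other, params)
  }
  c(R_left = unname(st$R[["left"]]), R_right = unname(st$R[["right"]]))
}

#' Map initial/asymptotic learning rates to implied variance ratios
#'
#' Inverse of the learning-rate parameterization: given `alpha1` and
#' `alpha_inf`, returns the implied drift ratio
#' \eqn{\alpha_d = \sigma_d^2/\sigma_r^2} and prior-variance ratio
#' \eqn{\sigma_0^2/\sigma_r^2}. Useful for constructing a matched
#' variance-space Kalman filter.
#'
#' @inheritParams learning_params
#' @return Named numeric: `alpha_d`, `omega0` (\eqn{\sigma_0^2/\sigma_r^2}).
#' @export
implied_variance_ratios <- function(R0 = 0, alpha1, alpha_inf,
                                    alpha1_mode = c("gain", "variance_ratio")) {
  p <- learning_params(R0, alpha1, alpha_inf, alpha1_mode)
  c(alpha_d = p$alpha_d, omega0 = .omega0(p))
}
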