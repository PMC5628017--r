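#' Decision-model parameters
#'
#' The decision rule has three parameter families, all in units of points:
#' an information bonus `A` per horizon (defined only in the unequal
#' `[1 3]` condition, where one option is more informative), a spatial bias
#' `B` per horizon-by-information cell, and a decision noise `sigma` per
#' horizon-by-information cell. Positive `B` pushes choice toward the left
#' option (it enters the exponent with the same sign as
#' \eqn{\Delta R = R_{left} - R_{right}}).
#'
#' @param A Named numeric, information bonus per horizon: `c(h1 = , h6 = )`.
#' @param B Named numeric, spatial bias per cell:
#'   `c(h1_u13 = , h1_u22 = , h6_u13 = , h6_u22 = )`.
#' @param sigma Named numeric, decision noise (> 0) per cell, same names as `B`.
#' @return A `decision_params` list.
#' @export
decision_params <- function(A = c(h1 = 0, h6 = 0),
                            B = c(h1_u13 = 0, h1_u22 = 0, h6_u13 = 0, h6_u22 = 0),
                            sigma = c(h1_u13 = 1, h1_u22 = 1, h6_u13 = 1, h6_u22 = 1)) {
  cells <- c("h1_u13", "h1_u22", "h6_u13", "h6_u22")
  if (!all(c("h1", "h6") %in% names(A))) stop("A needs names h1, h6")
  if (!all(cells %in% names(B))) stop("B needs names ", paste(cells, collapse = ", "))
  if (!all(cells %in% names(sigma))) stop("sigma needs names ", paste(cells, collapse = ", "))
  if (any(!is.finite(sigma[cells])) || any(sigma[cells] <= 0)) {
    stop("sigma must be > 0 in every cell")
  }
  structure(list(A = A[c("h1", "h6")], B = B[cells], sigma = sigma[cells]),
            class = "decision_params")
}

.cell_name <- function(horizon, info_condition) {
  paste0("h", horizon, "_", ifelse(info_condition == "unequal_13", "u13", "u22"))
}

#' Probability of choosing the right option
#'
#' Logistic choice rule
#' \deqn{p(\mathrm{right}) = \frac{1}{1 + \exp\left(\frac{\Delta R + A\,\Delta I + B}{\sigma}\right)}}
#' where \eqn{\Delta R = R_{left} - R_{right}} and \eqn{\Delta I} is +1 when
#' left is the more informative option, -1 when right is, and 0 in the
#' equal-information condition (where the `A` term drops out).
#'
#' @param delta_R Estimated value difference, left minus right (points).
#' @param delta_I Information sign, in \{-1, 0, +1\}.
#' @param horizon Game horizon, 1 or 6.
#' @param info_condition `"unequal_13"` or `"equal_22"`.
#' @param params A [decision_params()] object.
#' @return Probability in (0, 1). Vectorised over the inputs.
#' @export
p_choose_right <- function(delta_R, delta_I, horizon, info_condition, params) {
  cell <- .cell_name(horizon, info_condition)
  sigma <- unname(params$sigma[cell])
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  A <- ifelse(delta_I == 0, 0, unname(params$A[paste0("h", horizon)]))
  B <- unname(params$B[cell])
  stats::plogis(-(delta_R + A * delta_I + B) / sigma)
}

#' Log-likelihood of one free choice
#'
#' Bernoulli log-probability of the observed free choice under
#' [p_choose_right()]. Probabilities are not artificially clipped; only
#' floating-point underflow bounds them.
#'
#' @param choice `"left"` or `"right"` (the observed free choice).
#' @param is_forced Logical; forced trials are rejected.
#' @inheritParams p_choose_right
#' @return Log-probability (scalar or vector).
#' @export
choice_loglik <- function(choice, delta_R, delta_I, horizon, info_condition,
                          params, is_forced = FALSE) {
  if (any(is_forced)) stop("choice_loglik is defined for free choices only")
  p_right <- p_choose_right(delta_R, delta_I, horizon, info_condition, params)
  ifelse(choice == "right", log(p_right), log1p(-p_right))
}

#' Simulate the free choices of one game
#'
#' Plays out the free portion of a game under the learning + decision
#' model: learning continues across free trials (chosen option updated,
#' unchosen option's uncertainty drifts), rewards are drawn from the
#' option's Gaussian and rounded to the nearest integer, and the
#' information sign on trials after the first free choice is the sign of
#' the cumulative play-count deficit, `sign(n_right - n_left)`, so the
#' bonus keeps favouring the less-played side (0 on ties).
#'
#' @param game One-row tibble or list with `horizon`, `info_condition`,
#'   `mean_left`, `mean_right`, and `reward_sd` (defaults to 8 if absent).
#' @param forced_choices,forced_rewards The four forced trials.
#' @param lp A [learning_params()] object.
#' @param dp A [decision_params()] object.
#' @return Tibble of free trials: `trial`, `choice`, `reward`,
#'   `delta_R`, `delta_I`, `p_right`.
#' @export
simulate_free_choices <- function(game, forced_choices, forced_rewards, lp, dp) {
  horizon <- game$horizon
  info <- game$info_condition
  sd_r <- if (!is.null(game$reward_sd)) game$reward_sd else 8
  st <- init_state(lp)
  n_play <- c(left = 0L, right = 0L)
  for (k in 1:4) {
    chosen <- forced_choices[k]
    other <- if (chosen == "left") "right" else "left"
    st <- update_chosen(st, chosen, forced_rewards[k], lp)
    st <- propagate_unchosen(st, other, lp)
    n_play[chosen] <- n_play[chosen] + 1L
  }
  n_free <- if (horizon == 1) 1L else 6L
  out <- vector("list", n_free)
  for (j in seq_len(n_free)) {
    delta_R <- unname(st$R[["left"]] - st$R[["right"]])
    delta_I <- if (info == "equal_22") 0L else
      as.integer(sign(n_play[["right"]] - n_play[["left"]]))
    p_right <- p_choose_right(delta_R, delta_I, horizon, info, dp)
    choice <- if (stats::runif(1) < p_right) "right" else "left"
    mean_c <- if (choice == "left") game$mean_left else game$mean_right
    reward <- round(stats::rnorm(1, mean_c, sd_r))
    out[[j]] <- tibble::tibble(
      trial = 4L + j, choice = choice, reward = reward,
      delta_R = delta_R, delta_I = delta_I, p_right = unname(p_right)
    )
    other <- if (choice == "left") "right" else "left"
    st <- update_chosen(st, choice, reward, lp)
    st <- propagate_unchosen(st, other, lp)
    n_play[choice] <- n_play[choice] + 1L
  }
  dplyr::bind_rows(out)
}
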