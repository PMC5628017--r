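# Figure analogues: model-free bars, confound curve, later-trial curves.
# Structural reproductions of the standard panels for this task, built on
# ggplot2.

#' Plot the model-free exploration measures
#'
#' Mean p(high info) and p(low mean) at the first free choice by horizon
#' and stimulation condition, with s.e.m. error bars.
#'
#' @param mf Output of [model_free_summary()].
#' @return A ggplot object.
#' @export
plot_model_free <- function(mf) {
  long <- tidyr::pivot_longer(
    mf, c("p_high_info", "p_low_mean"),
    names_to = "measure", values_to = "p"
  )
  long <- dplyr::filter(long, !is.na(.data$p))
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$horizon, .data$tms_condition),
    mean_p = mean(.data$p),
    sem = stats::sd(.data$p) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(
    agg,
    ggplot2::aes(
      x = factor(.data$horizon), y = .data$mean_p,
      fill = .data$tms_condition
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_p - .data$sem,
                   ymax = .data$mean_p + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "horizon", y = "proportion", fill = "stimulation") +
    ggplot2::theme_minimal()
}

#' Plot the reward-information confound curve
#'
#' Correlation of the sign of the generative mean difference with the sign
#' of the play-count difference, per free trial of horizon-6 games and
#' stimulation condition.
#'
#' @param study A `horizon_study`.
#' @return A ggplot object.
#' @export
plot_confound_curve <- function(study) {
  conf <- dplyr::bind_rows(lapply(5:10, function(t) {
    confound_correlation(study, t)
  }))
  conf$free_trial <- conf$trial_index - 4L
  ggplot2::ggplot(
    conf,
    ggplot2::aes(x = .data$free_trial, y = .data$correlation,
                 colour = .data$tms_condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "free-choice trial", y = "corr(sgn Δmean, sgn Δn)",
                  colour = "stimulation") +
    ggplot2::theme_minimal()
}

#' Plot later-trial exploration curves
#'
#' p(high info) and p(low mean) per free choice of horizon-6 games, by
#' stimulation condition.
#'
#' @param lt Output of [later_trials_analysis()].
#' @return A ggplot object.
#' @export
plot_later_trials <- function(lt) {
  long <- tidyr::pivot_longer(
    lt$curves, c("p_high_info", "p_low_mean"),
    names_to = "measure", values_to = "p"
  )
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$free_trial, .data$tms_condition),
    mean_p = mean(.data$p, na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(
    agg,
    ggplot2::aes(x = .data$free_trial, y = .data$mean_p,
                 colour = .data$tms_condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "free-choice trial", y = "proportion",
                  colour = "stimulation") +
    ggplot2::theme_minimal()
}
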