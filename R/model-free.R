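# Model-free exploration measures and the frequentist analyses: p(high
# info) in the unequal condition, p(low mean) in the equal condition, the
# reward-information confound curve, mixed repeated-measures ANOVA and
# post-hoc paired t-tests.

# Per-game indicators at a given trial index. For trial 5 the play counts
# are the forced counts; for later trials (horizon-6 games) they are
# cumulative over all preceding trials. "High info" = the currently
# less-played side; "low mean" = the side with the lower observed sample
# mean of the rewards seen so far. Ties are excluded (NA).
.game_indicators <- function(trials, trial_index) {
  stopifnot(trial_index >= 5)
  pre <- dplyr::filter(trials, .data$trial < !!trial_index)
  at <- dplyr::filter(trials, .data$trial == !!trial_index)
  pre_sum <- dplyr::summarise(
    dplyr::group_by(pre, .data$subject, .data$tms_condition, .data$game),
    n_left = sum(.data$choice == "left"),
    n_right = sum(.data$choice == "right"),
    mean_obs_left = mean(.data$reward[.data$choice == "left"]),
    mean_obs_right = mean(.data$reward[.data$choice == "right"]),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    dplyr::select(at, "subject", "tms_condition", "game", "horizon",
                  "info_condition", "choice", "mean_left", "mean_right"),
    pre_sum,
    by = c("subject", "tms_condition", "game")
  )
  dplyr::mutate(
    out,
    high_info_side = dplyr::case_when(
      .data$n_left < .data$n_right ~ "left",
      .data$n_right < .data$n_left ~ "right",
      TRUE ~ NA_character_
    ),
    low_mean_side = dplyr::case_when(
      .data$mean_obs_left < .data$mean_obs_right ~ "left",
      .data$mean_obs_right < .data$mean_obs_left ~ "right",
      TRUE ~ NA_character_
    ),
    chose_high_info = .data$choice == .data$high_info_side,
    chose_low_mean = .data$choice == .data$low_mean_side
  )
}

#' Probability of choosing the high-information option
#'
#' Fraction of unequal (`[1 3]`) games in which the choice at
#' `trial_index` lands on the less-played option -- the model-free measure
#' of directed exploration. At the first free choice (trial 5) that is the
#' option forced only once; at later trials it is the side with the
#' smaller cumulative play count (ties excluded).
#'
#' @param study A `horizon_study` (any subset of sessions).
#' @param trial_index Trial at which the choice is scored (default 5).
#' @return Tibble: `subject`, `tms_condition`, `horizon`, `p_high_info`,
#'   `n_games`.
#' @export
p_high_info <- function(study, trial_index = 5) {
  ind <- .game_indicators(tibble::as_tibble(study), trial_index)
  ind <- dplyr::filter(ind, .data$info_condition == "unequal_13",
                       !is.na(.data$chose_high_info))
  if (nrow(ind) == 0) stop("no qualifying unequal-condition games at trial ",
                           trial_index)
  dplyr::summarise(
    dplyr::group_by(ind, .data$subject, .data$tms_condition, .data$horizon),
    p_high_info = mean(.data$chose_high_info),
    n_games = dplyr::n(), .groups = "drop"
  )
}

#' Probability of choosing the low-mean option
#'
#' Fraction of equal (`[2 2]`) games in which the choice at `trial_index`
#' lands on the option whose observed sample mean (of the outcomes seen so
#' far -- at trial 5, the forced-trial outcomes) is lower: the "mistake"
#' rate, the model-free measure of random exploration. Ties in observed
#' means are excluded from the denominator.
#'
#' @inheritParams p_high_info
#' @return Tibble: `subject`, `tms_condition`, `horizon`, `p_low_mean`,
#'   `n_games`.
#' @export
p_low_mean <- function(study, trial_index = 5) {
  ind <- .game_indicators(tibble::as_tibble(study), trial_index)
  ind <- dplyr::filter(ind, .data$info_condition == "equal_22",
                       !is.na(.data$chose_low_mean))
  if (nrow(ind) == 0) stop("no qualifying equal-condition games at trial ",
                           trial_index)
  dplyr::summarise(
    dplyr::group_by(ind, .data$subject, .data$tms_condition, .data$horizon),
    p_low_mean = mean(.data$chose_low_mean),
    n_games = dplyr::n(), .groups = "drop"
  )
}

#' Model-free summary of first-free-choice behaviour
#'
#' Joins [p_high_info()] and [p_low_mean()] at trial 5 into one table per
#' subject x condition x horizon.
#'
#' @param study A `horizon_study`.
#' @param complete_cases_only Keep only subjects with both sessions
#'   (required for the repeated-measures tests).
#' @return Tibble with `p_high_info`, `p_low_mean` columns (and game
#'   counts).
#' @export
model_free_summary <- function(study, complete_cases_only = TRUE) {
  hi <- p_high_info(study)
  lo <- p_low_mean(study)
  out <- dplyr::left_join(
    hi, lo,
    by = c("subject", "tms_condition", "horizon"),
    suffix = c("_hi", "_lo")
  )
  if (complete_cases_only) {
    both <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(study), .data$subject),
      n_cond = length(unique(.data$tms_condition)), .groups = "drop"
    )
    keep <- both$subject[both$n_cond == 2]
    out <- dplyr::filter(out, .data$subject %in% keep)
  }
  out
}

#' Reward-information confound correlation
#'
#' Pearson correlation, across horizon-6 games, of the sign of the
#' generative mean difference, `sgn(mean_left - mean_right)`, with the
#' sign of the play-count difference before the given trial,
#' `sgn(n_left - n_right)`. The forced trials balance this to about zero
#' at the first free choice; it grows over later trials as subjects chase
#' reward. Computed per stimulation condition.
#'
#' @param study A `horizon_study`.
#' @param trial_index Trial before which play counts are accumulated.
#' @return Tibble: `tms_condition`, `trial_index`, `correlation`,
#'   `n_games` (`correlation` is `NA` when either sign vector is
#'   constant).
#' @export
confound_correlation <- function(study, trial_index = 5) {
  trials <- dplyr::filter(tibble::as_tibble(study), .data$horizon == 6)
  if (nrow(trials) == 0) stop("no horizon-6 games")
  ind <- .game_indicators(trials, trial_index)
  dplyr::summarise(
    dplyr::group_by(ind, .data$tms_condition),
    trial_index = !!trial_index,
    correlation = {
      s_mu <- sign(.data$mean_left - .data$mean_right)
      s_n <- sign(.data$n_left - .data$n_right)
      if (stats::sd(s_mu) == 0 || stats::sd(s_n) == 0) NA_real_
      else stats::cor(s_mu, s_n)
    },
    n_games = dplyr::n(),
    .groups = "drop"
  )
}

#' Repeated-measures ANOVA for model-free measures
#'
#' Mixed-design ANOVA with within-subject factors (and optionally one
#' between-subject factor such as session order). The within effects are
#' tested against their subject-by-effect interaction strata
#' (`Error(subject/(f1*f2))`), which with two 2-level within factors and
#' `n` complete subjects gives F(1, n-1) tests; a between factor is tested
#' in the between-subject stratum and its interactions with the within
#' factors in theirs.
#'
#' @param data Long tibble with one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Subject-identifier column.
#' @param between Optional single between-subject factor column.
#' @return Tibble: `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(data, dv, within, subject = "subject", between = NULL) {
  data <- tibble::as_tibble(data)
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  if (!is.null(between)) data[[between]] <- factor(data[[between]])
  cell_counts <- table(data[[subject]])
  if (length(unique(cell_counts)) != 1) {
    stop("unbalanced within-subject cells: each subject must contribute ",
         "every within-factor combination exactly once (complete cases only)")
  }
  if (stats::var(data[[dv]]) == 0) {
    # a constant response carries no effects; aov's 0/0 strata are noise
    effects <- c(within, if (length(within) > 1)
      paste(within, collapse = ":"), between)
    return(tibble::tibble(effect = effects, df1 = NA_integer_,
                          df2 = NA_integer_, F = 0, p = 1))
  }
  rhs <- paste(c(within, between), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
  f <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(f, data = data)
  out <- list()
  for (stratum in names(summary(fit))) {
    tab <- summary(fit)[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    resid_row <- which(terms == "Residuals")
    if (length(resid_row) == 0) next
    df2 <- tab[resid_row, "Df"]
    for (i in seq_len(nrow(tab))) {
      if (i == resid_row || is.na(tab[i, "F value"])) next
      out[[length(out) + 1]] <- tibble::tibble(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df2,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Post-hoc paired t-test between stimulation conditions
#'
#' Paired t across subjects, within one horizon, of a model-free measure
#' between the control (vertex) and stimulation (rfpc) sessions. The
#' horizon-6 directed-exploration prediction is one-sided
#' (vertex > rfpc); use `alternative = "two.sided"` elsewhere.
#'
#' @param data Tibble with `subject`, `tms_condition`, `horizon`, and the
#'   measure column.
#' @param dv Measure column name.
#' @param horizon Which horizon to test (1 or 6).
#' @param alternative `"greater"` tests vertex > rfpc.
#' @return Tibble: `t`, `df`, `p`, `alternative`, `mean_diff`
#'   (vertex - rfpc).
#' @export
posthoc_ttest <- function(data, dv, horizon,
                          alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  d <- dplyr::filter(tibble::as_tibble(data), .data$horizon == !!horizon)
  wide <- tidyr::pivot_wider(
    d[, c("subject", "tms_condition", dv)],
    names_from = "tms_condition", values_from = dplyr::all_of(dv)
  )
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2) stop("need at least 2 paired subjects")
  diffs <- wide$vertex - wide$rfpc
  if (stats::sd(diffs) == 0 && mean(diffs) == 0) {
    # identical pairs: no evidence either way
    return(tibble::tibble(
      t = 0, df = nrow(wide) - 1,
      p = if (alternative == "two.sided") 1 else 0.5,
      alternative = alternative, mean_diff = 0
    ))
  }
  tt <- stats::t.test(wide$vertex, wide$rfpc, paired = TRUE,
                      alternative = alternative)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    alternative = alternative, mean_diff = unname(tt$estimate)
  )
}

#' Later-trials model-free analysis of horizon-6 games
#'
#' Computes p(high info) and p(low mean) at each of the six free choices
#' of horizon-6 games (trials 5--10, free-trial numbers 1--6), the
#' stimulation-related differences, and the trial-number x stimulation
#' repeated-measures ANOVA per measure (five-level trial effect, so
#' F(5, 5(n-1)) tests with `n` complete subjects).
#'
#' @param study A `horizon_study`.
#' @return List: `curves` (subject x condition x free_trial measures),
#'   `change` (per free-trial mean rfpc - vertex difference),
#'   `anova_high_info`, `anova_low_mean`.
#' @export
later_trials_analysis <- function(study) {
  trials <- dplyr::filter(tibble::as_tibble(study), .data$horizon == 6)
  if (nrow(trials) == 0) stop("no horizon-6 games")
  both <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject),
    n_cond = length(unique(.data$tms_condition)), .groups = "drop"
  )
  trials <- dplyr::filter(trials, .data$subject %in% both$subject[both$n_cond == 2])
  curves <- dplyr::bind_rows(lapply(5:10, function(tix) {
    hi <- p_high_info(horizon_study(trials), trial_index = tix)
    lo <- p_low_mean(horizon_study(trials), trial_index = tix)
    m <- dplyr::left_join(hi, lo, by = c("subject", "tms_condition", "horizon"),
                          suffix = c("_hi", "_lo"))
    m$free_trial <- tix - 4L
    m
  }))
  change <- dplyr::summarise(
    dplyr::group_by(curves, .data$free_trial),
    d_high_info = mean(.data$p_high_info[.data$tms_condition == "rfpc"]) -
      mean(.data$p_high_info[.data$tms_condition == "vertex"]),
    d_low_mean = mean(.data$p_low_mean[.data$tms_condition == "rfpc"]) -
      mean(.data$p_low_mean[.data$tms_condition == "vertex"]),
    .groups = "drop"
  )
  # the ANOVAs need every subject in every trial x condition cell; small
  # sessions can lose cells to tie exclusion, so keep complete subjects
  # per measure
  complete_for <- function(col) {
    d <- curves[!is.na(curves[[col]]), ]
    counts <- dplyr::count(d, .data$subject)
    dplyr::filter(d, .data$subject %in% counts$subject[counts$n == 12])
  }
  list(
    curves = curves,
    change = change,
    anova_high_info = rm_anova(complete_for("p_high_info"), "p_high_info",
                               within = c("free_trial", "tms_condition")),
    anova_low_mean = rm_anova(complete_for("p_low_mean"), "p_low_mean",
                              within = c("free_trial", "tms_condition"))
  )
}
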