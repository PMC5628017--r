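#' @useDynLib horizontask, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom dplyr filter mutate group_by summarise ungroup arrange select
#'   distinct n left_join bind_rows across all_of first
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbeta rgamma sd cor aov t.test pnorm qnorm
#'   quantile setNames median var dnorm dbeta dgamma plogis
NULL

# Canonical column order for trial-level data.
.trial_cols <- c(
  "subject", "tms_condition", "session_order", "game", "horizon",
  "info_condition", "trial", "is_forced", "choice", "reward",
  "mean_left", "mean_right"
)

.info_levels <- c("unequal_13", "equal_22")
.tms_levels <- c("rfpc", "vertex")

#' Construct a Horizon-Task study object
#'
#' Bundles trial-level data from a Horizon-Task experiment into a validated
#' `horizon_study` object. Each row is one trial of one game. A game has four
#' forced-choice trials (trials 1--4) followed by one (horizon 1) or six
#' (horizon 6) free choices, i.e. 5 or 10 trials in total. Rewards are drawn
#' from option-specific Gaussians with a common standard deviation; the
#' forced trials set up either an unequal `[1 3]` or an equal `[2 2]`
#' information condition.
#'
#' @param trials A data frame with columns `subject`, `tms_condition`
#'   (`"rfpc"` or `"vertex"`), `session_order` (`"first"`/`"second"`),
#'   `game`, `horizon` (1 or 6), `info_condition` (`"unequal_13"` or
#'   `"equal_22"`), `trial` (1-based within game), `is_forced` (logical),
#'   `choice` (`"left"`/`"right"`), `reward`, `mean_left`, `mean_right`.
#' @param design_metadata Optional free-form description of the
#'   counterbalancing scheme, kept as an attribute.
#'
#' @return A `horizon_study`: a tibble of trials with class attributes.
#' @export
horizon_study <- function(trials, design_metadata = NULL) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(.trial_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  trials <- trials[, .trial_cols]
  if (is.numeric(trials$choice)) {
    trials$choice <- ifelse(trials$choice == 1, "right", "left")
  }
  if (!all(trials$choice %in% c("left", "right"))) {
    stop("choice must be 'left'/'right' (or serialized 0/1)")
  }
  trials <- dplyr::arrange(
    trials, .data$subject, .data$tms_condition, .data$game, .data$trial
  )
  structure(trials,
    class = c("horizon_study", class(trials)),
    design_metadata = design_metadata
  )
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.horizon_study <- function(x, ...) {
  attr(x, "design_metadata") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
print.horizon_study <- function(x, ...) {
  ns <- dplyr::distinct(
    tibble::as_tibble(x),
    .data$subject, .data$tms_condition
  )
  cat(sprintf(
    "<horizon_study> %d trials, %d subjects, %d sessions\n",
    nrow(x), length(unique(ns$subject)), nrow(ns)
  ))
  NextMethod()
}

#' One session (one subject under one stimulation condition)
#'
#' @param study A `horizon_study`.
#' @param subject Subject identifier.
#' @param tms_condition `"rfpc"` or `"vertex"`.
#' @return A `horizon_study` restricted to that session.
#' @export
study_session <- function(study, subject, tms_condition) {
  out <- dplyr::filter(
    tibble::as_tibble(study),
    .data$subject == !!subject, .data$tms_condition == !!tms_condition
  )
  if (nrow(out) == 0) stop("no such session: ", subject, "/", tms_condition)
  horizon_study(out)
}

#' Extract the first free choice of a game
#'
#' The first free choice is always trial 5, immediately after the four
#' forced trials; for horizon-6 games the later free trials are ignored.
#' Model fitting targets this trial only, because the forced trials hold the
#' reward--information confound at zero there.
#'
#' @param session A `horizon_study` (typically one session).
#' @param game_id Game identifier within the session.
#' @return A one-row tibble: the trial-5 record.
#' @export
first_free_choice <- function(session, game_id) {
  g <- dplyr::filter(tibble::as_tibble(session), .data$game == !!game_id)
  if (nrow(g) == 0) stop("no such game: ", game_id)
  t5 <- dplyr::filter(g, .data$trial == 5)
  if (nrow(t5) != 1) {
    stop("malformed game ", game_id, ": expected exactly one trial 5, found ",
         nrow(t5))
  }
  if (isTRUE(t5$is_forced)) stop("malformed game ", game_id, ": trial 5 is forced")
  t5
}

#' Information-difference sign of a game
#'
#' Returns \eqn{\Delta I}: +1 when the left option is the more informative
#' one (it was forced only once, so less is known about it), -1 when the
#' right option is more informative, and 0 in the equal `[2 2]` condition.
#'
#' @param forced_choices Character vector of the four forced-trial choices
#'   (`"left"`/`"right"`), in order.
#' @return Integer in \{-1, 0, +1\}.
#' @export
information_sign <- function(forced_choices) {
  if (length(forced_choices) != 4 ||
      !all(forced_choices %in% c("left", "right"))) {
    stop("forced_choices must be 4 values in {'left','right'}")
  }
  n_left <- sum(forced_choices == "left")
  switch(as.character(n_left),
    "1" = 1L,
    "3" = -1L,
    "2" = 0L,
    stop("invalid forced counts: ", n_left, " left of 4")
  )
}

# Delta-I per game for the first free choice, vectorised over a trials tibble.
.game_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  forced <- dplyr::filter(trials, .data$trial <= 4)
  dplyr::summarise(
    dplyr::group_by(
      forced,
      .data$subject, .data$tms_condition, .data$session_order, .data$game
    ),
    horizon = dplyr::first(.data$horizon),
    info_condition = dplyr::first(.data$info_condition),
    mean_left = dplyr::first(.data$mean_left),
    mean_right = dplyr::first(.data$mean_right),
    n_forced_left = sum(.data$choice == "left"),
    delta_i = {
      nl <- sum(.data$choice == "left")
      if (nl == 1) 1L else if (nl == 3) -1L else 0L
    },
    .groups = "drop"
  )
}

#' Validate a study dataset against the task design invariants
#'
#' Report-only check of the structural invariants: 5 or 10 trials per game
#' matching the horizon, trials 1--4 forced and the rest free, forced counts
#' `{1,3}` or `{2,2}` matching the stated information condition, mean
#' difference in \{4, 8, 12, 20\} with one mean anchored at 40 or 60, unique
#' subject-by-condition sessions, and (as a warning-level entry) 160 games
#' per session.
#'
#' @param study A `horizon_study`.
#' @param expected_games Games per complete session (160 in the published
#'   design; set accordingly for reduced synthetic studies).
#' @return A tibble of violations (zero rows when clean) with columns
#'   `severity` (`"error"`/`"warning"`), `where`, `problem`.
#' @export
validate_study <- function(study, expected_games = 160) {
  trials <- tibble::as_tibble(study)
  bad <- list()
  note <- function(severity, where, problem) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      severity = severity, where = where, problem = problem
    )
  }

  sess_tbl <- dplyr::distinct(trials, .data$subject, .data$tms_condition,
                              .data$session_order)
  dup <- dplyr::count(
    dplyr::distinct(trials, .data$subject, .data$tms_condition,
                    .data$session_order),
    .data$subject, .data$tms_condition
  )
  for (i in which(dup$n > 1)) {
    note("error", paste0(dup$subject[i], "/", dup$tms_condition[i]),
         "duplicate subject x tms_condition session")
  }

  per_game <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject, .data$tms_condition, .data$game),
    horizon = dplyr::first(.data$horizon),
    info_condition = dplyr::first(.data$info_condition),
    n_trials = dplyr::n(),
    n_forced = sum(.data$is_forced),
    forced_first4 = all(.data$is_forced == (.data$trial <= 4)),
    n_forced_left = sum(.data$choice[.data$trial <= 4] == "left"),
    mean_left = dplyr::first(.data$mean_left),
    mean_right = dplyr::first(.data$mean_right),
    .groups = "drop"
  )
  for (i in seq_len(nrow(per_game))) {
    g <- per_game[i, ]
    where <- sprintf("%s/%s game %s", g$subject, g$tms_condition, g$game)
    expect_n <- if (g$horizon == 1) 5L else 10L
    if (!g$horizon %in% c(1, 6)) {
      note("error", where, paste0("horizon must be 1 or 6, got ", g$horizon))
    } else if (g$n_trials != expect_n) {
      note("error", where, sprintf("horizon-%d game has %d trials, expected %d",
                                   g$horizon, g$n_trials, expect_n))
    }
    if (g$n_forced != 4 || !g$forced_first4) {
      note("error", where, "trials 1-4 must be forced and the rest free")
    }
    ok_counts <- switch(g$info_condition,
      unequal_13 = g$n_forced_left %in% c(1, 3),
      equal_22 = g$n_forced_left == 2,
      FALSE
    )
    if (!isTRUE(ok_counts)) {
      note("error", where, sprintf(
        "forced counts (%d left) inconsistent with %s",
        g$n_forced_left, g$info_condition
      ))
    }
    diff <- abs(g$mean_left - g$mean_right)
    if (!diff %in% c(4, 8, 12, 20)) {
      note("error", where, sprintf("|mean difference| = %g not in {4,8,12,20}", diff))
    }
    if (!any(c(g$mean_left, g$mean_right) %in% c(40, 60))) {
      note("error", where, "neither mean anchored at 40 or 60")
    }
  }

  n_games <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject, .data$tms_condition),
    n = length(unique(.data$game)), .groups = "drop"
  )
  for (i in which(n_games$n != expected_games)) {
    note("warning",
         paste0(n_games$subject[i], "/", n_games$tms_condition[i]),
         sprintf("session has %d games, design specifies %d",
                 n_games$n[i], expected_games))
  }

  if (length(bad) == 0) {
    tibble::tibble(severity = character(), where = character(),
                   problem = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Read / write the canonical long-format CSV
#'
#' One row per trial with the canonical columns; `choice` is serialized as
#' 0 = left, 1 = right and `is_forced` as 0/1. The round trip through
#' [write_study_csv()] and [read_study_csv()] is lossless.
#'
#' @param study A `horizon_study`.
#' @param path File path.
#' @return `read_study_csv` returns a `horizon_study`; `write_study_csv`
#'   returns `path` invisibly.
#' @export
write_study_csv <- function(study, path) {
  out <- tibble::as_tibble(study)
  out$choice <- as.integer(out$choice == "right")
  out$is_forced <- as.integer(out$is_forced)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  trials$is_forced <- as.logical(trials$is_forced)
  horizon_study(trials)
}

#' Map a local copy of the deposited study data into the canonical format
#'
#' Adapter stub for the public deposit of the original TMS study. The
#' deposit's on-disk layout (Matlab structures) cannot be resolved without
#' the files themselves, so this function accepts a directory that must
#' contain either a ready-made canonical CSV (`horizon_trials.csv`) or
#' per-session CSV exports with the canonical columns, and returns a
#' validated `horizon_study`.
#'
#' @param dir Directory containing the deposited data, converted to CSV.
#' @return A `horizon_study`.
#' @export
read_deposited_study <- function(dir) {
  if (!dir.exists(dir)) {
    stop("deposited-data directory not found: ", dir,
         "\nDownload the study deposit and export its sessions to CSV ",
         "with the canonical columns first.")
  }
  main <- file.path(dir, "horizon_trials.csv")
  files <- if (file.exists(main)) main else
    list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no CSV files found in ", dir)
  trials <- dplyr::bind_rows(lapply(files, function(f) {
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }))
  trials$is_forced <- as.logical(trials$is_forced)
  horizon_study(trials)
}
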