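# Hierarchical Bayesian estimation of the 13 subject-level parameters per
# stimulation condition, with the group-level priors and hyperpriors of the
# published model, via the package's adaptive Metropolis-within-Gibbs
# sampler (src/sampler.cpp).

.cells <- c("h1_u13", "h1_u22", "h6_u13", "h6_u22")

.group_names <- c(
  "mu_R0", "sd_R0", "a_alpha1", "b_alpha1", "a_alpha_inf", "b_alpha_inf",
  "mu_A_h1", "mu_A_h6", "sd_A_h1", "sd_A_h6",
  paste0("mu_B_", .cells), paste0("sd_B_", .cells),
  paste0("k_sigma_", .cells), paste0("lambda_sigma_", .cells)
)

.subject_names <- c(
  "R0", "alpha1", "alpha_inf", "A_h1", "A_h6",
  paste0("B_", .cells), paste0("sigma_", .cells)
)

# First-free-choice observations of one stimulation condition, in the layout
# the C++ sampler expects. `subjects` fixes the subject set (and ordering)
# so that subjects missing this condition's session still receive
# parameters (drawn from the group prior, contributing no likelihood).
.model_data <- function(study, tms_condition, subjects = NULL,
                        alpha1_mode = "gain", prior_only = FALSE) {
  trials <- tibble::as_tibble(study)
  if (is.null(subjects)) subjects <- sort(unique(trials$subject))
  sess <- dplyr::filter(trials, .data$tms_condition == !!tms_condition)
  forced <- dplyr::filter(sess, .data$trial <= 4)
  forced <- dplyr::arrange(forced, .data$subject, .data$game, .data$trial)
  free5 <- dplyr::filter(sess, .data$trial == 5)
  if (prior_only) {
    forced <- forced[0, ]
    free5 <- free5[0, ]
  }
  if (nrow(free5) == 0 && !prior_only) {
    stop("no free choices found for condition '", tms_condition, "'")
  }
  key <- paste(forced$subject, forced$game)
  key5 <- paste(free5$subject, free5$game)
  stopifnot(all(table(key) == 4), all(key5 %in% unique(key)))
  ord <- match(key5, unique(key))
  fr <- matrix(forced$reward, nrow = 4)[, ord, drop = FALSE]
  fa <- matrix(as.integer(forced$choice == "right"), nrow = 4)[, ord, drop = FALSE]
  n_left <- colSums(fa == 0)
  di <- ifelse(n_left == 1, 1L, ifelse(n_left == 3, -1L, 0L))
  cell <- (free5$horizon == 6) * 2L + (free5$info_condition == "equal_22") * 1L
  list(
    fr = fr, fa = fa,
    subj = match(free5$subject, subjects) - 1L,
    cell = as.integer(cell),
    di = as.integer(di),
    ch = as.integer(free5$choice == "right"),
    S = length(subjects),
    mode = if (alpha1_mode == "gain") 0L else 1L,
    subjects = subjects
  )
}

# Chain initialization: hyperparameters drawn from their hyperpriors, with
# scale-type draws truncated to [0.05, 50] so chains do not start in flat
# likelihood regions (the Gamma(1, 0.001) hyperprior has mean 1000); the
# priors themselves are untouched. Subject values then drawn from the
# initialized priors.
.init_values <- function(S) {
  tr <- function(x) pmin(pmax(x, 0.05), 50)
  g <- numeric(26)
  names(g) <- .group_names
  g["mu_R0"] <- stats::rnorm(1, 50, 14)
  g["sd_R0"] <- tr(stats::rgamma(1, 1, 0.001))
  g["a_alpha1"] <- stats::runif(1, 0.1, 10)
  g["b_alpha1"] <- stats::runif(1, 0.5, 10)
  g["a_alpha_inf"] <- stats::runif(1, 0.1, 10)
  g["b_alpha_inf"] <- stats::runif(1, 0.1, 10)
  g[paste0("mu_A_", c("h1", "h6"))] <- stats::rnorm(2, 0, 100)
  g[paste0("sd_A_", c("h1", "h6"))] <- tr(stats::rgamma(2, 1, 0.001))
  g[paste0("mu_B_", .cells)] <- stats::rnorm(4, 0, 100)
  g[paste0("sd_B_", .cells)] <- tr(stats::rgamma(4, 1, 0.001))
  g[paste0("k_sigma_", .cells)] <- tr(stats::rexp(4, 0.1))
  g[paste0("lambda_sigma_", .cells)] <- pmin(pmax(stats::rexp(4, 10), 0.01), 5)

  sp <- matrix(NA_real_, nrow = 13, ncol = S,
               dimnames = list(.subject_names, NULL))
  sp["R0", ] <- stats::rnorm(S, g["mu_R0"], g["sd_R0"])
  sp["alpha1", ] <- pmin(pmax(
    stats::rbeta(S, g["a_alpha1"], g["b_alpha1"]), 0.01), 0.99)
  sp["alpha_inf", ] <- pmin(pmax(
    stats::rbeta(S, g["a_alpha_inf"], g["b_alpha_inf"]), 0.01), 0.99)
  sp["A_h1", ] <- stats::rnorm(S, g["mu_A_h1"], g["sd_A_h1"])
  sp["A_h6", ] <- stats::rnorm(S, g["mu_A_h6"], g["sd_A_h6"])
  for (cl in .cells) {
    sp[paste0("B_", cl), ] <- stats::rnorm(S, g[paste0("mu_B_", cl)],
                                           g[paste0("sd_B_", cl)])
    sp[paste0("sigma_", cl), ] <- pmax(stats::rgamma(
      S, g[paste0("k_sigma_", cl)], g[paste0("lambda_sigma_", cl)]
    ), 0.2)
  }
  list(group = g, subject = sp)
}

#' Fit the hierarchical model to one stimulation condition
#'
#' Estimates the 13 subject-level parameters (prior mean `R0`, learning
#' rates `alpha1` and `alpha_inf`, information bonus `A` per horizon,
#' spatial bias `B` and decision noise `sigma` per horizon-by-information
#' cell) for every subject, together with the group-level prior parameters,
#' from the first free choice of every game. Priors: `R0 ~ N(mu, sd)`,
#' learning rates `~ Beta(a, b)`, `A` and `B` Gaussian per condition cell,
#' `sigma ~ Gamma(shape, rate)`; hyperpriors: `mu_R0 ~ N(50, 14)`,
#' Gaussian SDs `~ Gamma(1, 0.001)`, Beta shapes uniform
#' (`a ~ U(0.1, 10)`, `b_alpha1 ~ U(0.5, 10)`, `b_alpha_inf ~ U(0.1, 10)`),
#' `mu_A, mu_B ~ N(0, 100)`, `k_sigma ~ Exp(0.1)`, `lambda_sigma ~ Exp(10)`.
#'
#' Sampling protocol defaults to 4 chains x 1000 retained draws with 500
#' burn-in per chain (during which proposal scales adapt) and thinning 1.
#' Convergence requires split-Rhat <= 1.05 and effective sample size >= 400
#' for every sampled group-level parameter; on failure the fit is rerun
#' once with doubled iterations (`refit_on_failure`).
#'
#' Subjects missing this condition's session (pass `subjects` to include
#' them) contribute no likelihood and are sampled from the group prior.
#'
#' @param study A `horizon_study`.
#' @param tms_condition `"rfpc"` or `"vertex"`.
#' @param n_chains,n_iter,burn_in,thin MCMC protocol (retained draws per
#'   chain = `n_iter`).
#' @param seed Integer seed; chain `k` runs under `seed + k`.
#' @param subjects Optional character vector fixing the subject set/order.
#' @param alpha1_mode `"gain"` or `"variance_ratio"`; see [learning_params()].
#' @param fix_group Optional named numeric clamping group parameters.
#' @param fix_subject Optional named numeric clamping subject parameters
#'   (applied to every subject).
#' @param sample_group If `FALSE`, all group parameters stay at their
#'   initial/fixed values (subject-level model with fixed priors).
#' @param prior_only If `TRUE`, drop the likelihood (prior recovery runs).
#' @param refit_on_failure Rerun once at doubled iterations if convergence
#'   diagnostics fail.
#' @return A `horizon_fit` with draw arrays, diagnostics and metadata.
#' @export
fit_hierarchical <- function(study, tms_condition,
                             n_chains = 4, n_iter = 1000, burn_in = 500,
                             thin = 1, seed = 1,
                             subjects = NULL, alpha1_mode = c("gain", "variance_ratio"),
                             fix_group = NULL, fix_subject = NULL,
                             sample_group = TRUE, prior_only = FALSE,
                             refit_on_failure = TRUE) {
  alpha1_mode <- match.arg(alpha1_mode)
  md <- .model_data(study, tms_condition, subjects, alpha1_mode, prior_only)
  S <- md$S

  fixg <- rep(FALSE, 26)
  names(fixg) <- .group_names
  fixs <- matrix(FALSE, 13, S, dimnames = list(.subject_names, NULL))
  if (!is.null(fix_group)) {
    stopifnot(all(names(fix_group) %in% .group_names))
    fixg[names(fix_group)] <- TRUE
  }
  if (!is.null(fix_subject)) {
    stopifnot(all(names(fix_subject) %in% .subject_names))
    fixs[names(fix_subject), ] <- TRUE
  }

  run_once <- function(n_iter, burn_in) {
    chains <- vector("list", n_chains)
    for (k in seq_len(n_chains)) {
      set.seed(seed + k)
      init <- .init_values(S)
      if (!is.null(fix_group)) init$group[names(fix_group)] <- fix_group
      if (!is.null(fix_subject)) {
        init$subject[names(fix_subject), ] <- fix_subject
      }
      chains[[k]] <- .run_chain_cpp(
        md, init$group, init$subject, fixg, fixs,
        sample_group, as.integer(burn_in), as.integer(n_iter), as.integer(thin)
      )
    }
    chains
  }

  assemble <- function(chains, n_iter, burn_in) {
    group <- array(
      NA_real_, dim = c(n_iter, n_chains, 26),
      dimnames = list(NULL, NULL, .group_names)
    )
    subject <- array(
      NA_real_, dim = c(n_iter, n_chains, 13, S),
      dimnames = list(NULL, NULL, .subject_names, md$subjects)
    )
    for (k in seq_len(n_chains)) {
      group[, k, ] <- chains[[k]]$group
      subject[, k, , ] <- array(chains[[k]]$subject, dim = c(n_iter, 13, S))
    }
    sampled <- !fixg & (sample_group | FALSE)
    if (!sample_group) sampled[] <- FALSE
    diag <- tibble::tibble(
      parameter = .group_names,
      sampled = unname(sampled),
      rhat = vapply(seq_len(26), function(j) split_rhat(group[, , j]), numeric(1)),
      ess = vapply(seq_len(26), function(j) ess_bulk(group[, , j]), numeric(1))
    )
    structure(
      list(
        group = group, subject = subject, diagnostics = diag,
        tms_condition = tms_condition, subjects = md$subjects,
        n_obs = length(md$ch),
        meta = list(
          n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
          thin = thin, seed = seed, alpha1_mode = alpha1_mode,
          prior_only = prior_only, sample_group = sample_group
        ),
        accept = lapply(chains, function(ch) {
          list(subject = ch$accept_subject, group = ch$accept_group)
        })
      ),
      class = "horizon_fit"
    )
  }

  chains <- run_once(n_iter, burn_in)
  fit <- assemble(chains, n_iter, burn_in)
  if (refit_on_failure && !all(converged(fit))) {
    n_iter2 <- 2L * n_iter
    burn_in2 <- 2L * burn_in
    chains <- run_once(n_iter2, burn_in2)
    fit <- assemble(chains, n_iter2, burn_in2)
    fit$meta$refitted <- TRUE
  }
  fit
}

#' @export
print.horizon_fit <- function(x, ...) {
  cat(sprintf(
    "<horizon_fit> condition %s: %d subjects, %d first-free-choice observations\n",
    x$tms_condition, length(x$subjects), x$n_obs
  ))
  cat(sprintf(
    "  %d chains x %d draws (burn-in %d, thin %d), max split-Rhat %.3f\n",
    x$meta$n_chains, x$meta$n_iter, x$meta$burn_in, x$meta$thin,
    max(x$diagnostics$rhat[x$diagnostics$sampled], na.rm = TRUE)
  ))
  invisible(x)
}

#' Convergence status of the sampled group-level parameters
#'
#' @param fit A `horizon_fit`.
#' @param rhat_max,ess_min Thresholds (split-Rhat <= 1.05, ESS >= 400).
#' @return Named logical per sampled group parameter.
#' @export
converged <- function(fit, rhat_max = 1.05, ess_min = 400) {
  d <- fit$diagnostics[fit$diagnostics$sampled, ]
  if (nrow(d) == 0) return(stats::setNames(logical(0), character(0)))
  stats::setNames(d$rhat <= rhat_max & d$ess >= ess_min, d$parameter)
}

#' Split-chain Rhat of a draws matrix
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain drift also registers.
#'
#' @param draws Matrix, iterations x chains.
#' @return Scalar Rhat (NA for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[(n + 1):(2 * n), , drop = FALSE])
  if (stats::sd(halves) < 1e-12) return(NA_real_)
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size of a draws matrix
#'
#' Computed with coda's spectral estimator, summed over chains.
#'
#' @param draws Matrix, iterations x chains.
#' @return Scalar ESS.
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  if (stats::sd(draws) < 1e-12) return(NA_real_)
  ml <- coda::as.mcmc.list(lapply(seq_len(ncol(draws)), function(k) {
    coda::as.mcmc(draws[, k])
  }))
  unname(coda::effectiveSize(ml))
}

#' Extract posterior draws
#'
#' `group_draws` returns an iterations x chains matrix for one group-level
#' parameter; `subject_draws` an iterations x chains x subjects array for
#' one subject-level parameter.
#'
#' @param fit A `horizon_fit`.
#' @param parameter Parameter name (see `fit$diagnostics$parameter` and
#'   the subject-level names `R0`, `alpha1`, `alpha_inf`, `A_h1`, `A_h6`,
#'   `B_<cell>`, `sigma_<cell>`).
#' @return Matrix or array of draws.
#' @export
group_draws <- function(fit, parameter) {
  stopifnot(parameter %in% .group_names)
  fit$group[, , parameter]
}

#' @rdname group_draws
#' @export
subject_draws <- function(fit, parameter) {
  stopifnot(parameter %in% .subject_names)
  fit$subject[, , parameter, , drop = TRUE]
}

#' Posterior summary table
#'
#' Tidy per-parameter summary (group level, plus subject-level posterior
#' means) mirroring the layout used to report the model fit: mean, SD,
#' central 95% interval, split-Rhat and ESS.
#'
#' @param fit A `horizon_fit`.
#' @return A tibble.
#' @export
posterior_summary <- function(fit) {
  g <- fit$group
  tibble::tibble(
    level = "group",
    parameter = .group_names,
    mean = vapply(.group_names, function(p) mean(g[, , p]), numeric(1)),
    sd = vapply(.group_names, function(p) stats::sd(g[, , p]), numeric(1)),
    q2.5 = vapply(.group_names, function(p) stats::quantile(g[, , p], 0.025),
                  numeric(1)),
    q97.5 = vapply(.group_names, function(p) stats::quantile(g[, , p], 0.975),
                   numeric(1)),
    rhat = fit$diagnostics$rhat,
    ess = fit$diagnostics$ess
  )
}

#' Subject-level posterior means
#'
#' @param fit A `horizon_fit`.
#' @return Tibble: `subject`, `parameter`, `post_mean`, `post_sd`.
#' @export
subject_posterior_means <- function(fit) {
  out <- list()
  for (p in .subject_names) {
    arr <- fit$subject[, , p, , drop = FALSE]
    pm <- apply(arr, 4, mean)
    ps <- apply(arr, 4, stats::sd)
    out[[p]] <- tibble::tibble(
      subject = fit$subjects, parameter = p, post_mean = pm, post_sd = ps
    )
  }
  dplyr::bind_rows(out)
}

#' Fit both stimulation conditions of a study
#'
#' Runs [fit_hierarchical()] separately per condition over the union of
#' subjects (so a subject missing one session is retained, prior-only, in
#' that condition), enabling paired posterior contrasts.
#'
#' @inheritParams fit_hierarchical
#' @param ... Passed to [fit_hierarchical()].
#' @return A `horizon_fit_pair`: list with elements `rfpc` and `vertex`.
#' @export
fit_study <- function(study, seed = 1, ...) {
  subjects <- sort(unique(tibble::as_tibble(study)$subject))
  fits <- lapply(.tms_levels, function(tms) {
    fit_hierarchical(study, tms, seed = seed + 1000 * match(tms, .tms_levels),
                     subjects = subjects, ...)
  })
  names(fits) <- .tms_levels
  structure(fits, class = "horizon_fit_pair")
}

#' @export
print.horizon_fit_pair <- function(x, ...) {
  cat("<horizon_fit_pair>\n")
  print(x$rfpc)
  print(x$vertex)
  invisible(x)
}

#' Posterior contrast of a group-level parameter between conditions
#'
#' Pairs draws by (chain, iteration) across the two condition fits and
#' summarises the stimulation-related change `cond_a - cond_b` (default
#' `rfpc - vertex`, so an inhibitory stimulation effect is negative).
#'
#' @param pair A `horizon_fit_pair` (or list of two `horizon_fit`s).
#' @param parameter Group-level parameter name, e.g. `"mu_A_h6"`.
#' @param cond_a,cond_b Condition names; the contrast is `a - b`.
#' @return List: `mean`, `frac_below_0`, `frac_above_0`, `draws`.
#' @export
contrast <- function(pair, parameter, cond_a = "rfpc", cond_b = "vertex") {
  da <- group_draws(pair[[cond_a]], parameter)
  db <- group_draws(pair[[cond_b]], parameter)
  if (!all(dim(da) == dim(db))) {
    stop("draw counts differ between conditions; refit with a common protocol")
  }
  diff <- as.vector(da - db)
  list(
    parameter = parameter,
    mean = mean(diff),
    frac_below_0 = mean(diff < 0),
    frac_above_0 = mean(diff > 0),
    draws = diff
  )
}

#' Horizon-related information-bonus change and its stimulation contrast
#'
#' Directed exploration is the growth of the information bonus with
#' horizon, \eqn{\Delta A = A(h{=}6) - A(h{=}1)} (group means). This
#' returns per-draw \eqn{\Delta A} in each condition, the
#' stimulation-related change (`rfpc - vertex`), the fraction of change
#' draws below zero, and the trade-off diagnostics: the draw-wise Pearson
#' correlation of the \eqn{\Delta A} change with the `R0` change (expected
#' near zero), and of the per-horizon `A` change with the `R0` change
#' (expected negative -- the prior-mean/information-bonus trade-off).
#'
#' @param pair A `horizon_fit_pair`.
#' @return List with elements `dA_rfpc`, `dA_vertex`, `change`, `mean`,
#'   `frac_below_0`, `cor_change_R0`, `cor_A_R0_h1`, `cor_A_R0_h6`.
#' @export
delta_A_contrast <- function(pair) {
  a6 <- lapply(pair[c("rfpc", "vertex")], group_draws, parameter = "mu_A_h6")
  a1 <- lapply(pair[c("rfpc", "vertex")], group_draws, parameter = "mu_A_h1")
  r0 <- lapply(pair[c("rfpc", "vertex")], group_draws, parameter = "mu_R0")
  dA <- lapply(c(rfpc = "rfpc", vertex = "vertex"), function(cc) {
    as.vector(a6[[cc]] - a1[[cc]])
  })
  change <- dA$rfpc - dA$vertex
  r0_change <- as.vector(r0$rfpc - r0$vertex)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(
    dA_rfpc = dA$rfpc, dA_vertex = dA$vertex, change = change,
    mean = mean(change), frac_below_0 = mean(change < 0),
    cor_change_R0 = safe_cor(change, r0_change),
    cor_A_R0_h1 = safe_cor(as.vector(a1$rfpc - a1$vertex), r0_change),
    cor_A_R0_h6 = safe_cor(as.vector(a6$rfpc - a6$vertex), r0_change)
  )
}

#' Serialize posterior draws to a long-format table
#'
#' @param fit A `horizon_fit`.
#' @param path Optional CSV path; when given, the table is also written.
#' @return Tibble: `level`, `parameter`, `subject`, `chain`, `iteration`,
#'   `value`.
#' @export
draws_table <- function(fit, path = NULL) {
  n_iter <- dim(fit$group)[1]
  n_chains <- dim(fit$group)[2]
  grid <- expand.grid(iteration = seq_len(n_iter), chain = seq_len(n_chains))
  gtab <- dplyr::bind_rows(lapply(.group_names, function(p) {
    tibble::tibble(
      level = "group", parameter = p, subject = NA_character_,
      chain = grid$chain, iteration = grid$iteration,
      value = as.vector(fit$group[, , p])
    )
  }))
  stab <- dplyr::bind_rows(lapply(.subject_names, function(p) {
    dplyr::bind_rows(lapply(seq_along(fit$subjects), function(s) {
      tibble::tibble(
        level = "subject", parameter = p, subject = fit$subjects[s],
        chain = grid$chain, iteration = grid$iteration,
        value = as.vector(fit$subject[, , p, s])
      )
    }))
  }))
  out <- dplyr::bind_rows(gtab, stab)
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
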