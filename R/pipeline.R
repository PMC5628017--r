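# End-to-end pipeline: simulate (or load), validate, model-free analyses,
# hierarchical fit, posterior contrasts, report. Each run writes a manifest
# (config hash, seed, package version) next to its outputs.

# Location draws for each of the 13 parameter families on the group level:
# Gaussian families use their mean parameter, Beta families a/(a+b), Gamma
# families shape/rate.
.location_draws <- function(fit, parameter) {
  if (parameter %in% .group_names) return(group_draws(fit, parameter))
  stopifnot(parameter %in% .subject_names)
  switch(parameter,
    R0 = group_draws(fit, "mu_R0"),
    alpha1 = group_draws(fit, "a_alpha1") /
      (group_draws(fit, "a_alpha1") + group_draws(fit, "b_alpha1")),
    alpha_inf = group_draws(fit, "a_alpha_inf") /
      (group_draws(fit, "a_alpha_inf") + group_draws(fit, "b_alpha_inf")),
    A_h1 = group_draws(fit, "mu_A_h1"),
    A_h6 = group_draws(fit, "mu_A_h6"),
    {
      cell <- sub("^(B|sigma)_", "", parameter)
      if (startsWith(parameter, "B_")) group_draws(fit, paste0("mu_B_", cell))
      else group_draws(fit, paste0("k_sigma_", cell)) /
        group_draws(fit, paste0("lambda_sigma_", cell))
    }
  )
}

#' Stimulation contrasts for all 13 parameter families
#'
#' Applies [contrast()] to the group-level location of each of the 13
#' subject-parameter families (Gaussian means; Beta means `a/(a+b)` for the
#' learning rates; Gamma means `k/lambda` for decision noise), reporting
#' the stimulation-related change (rfpc - vertex) and tail fractions --
#' the tabular analogue of the posterior-change column of the model-fit
#' figure.
#'
#' @param pair A `horizon_fit_pair`.
#' @return Tibble: `parameter`, `mean_change`, `frac_below_0`,
#'   `frac_above_0`.
#' @export
all_contrasts <- function(pair) {
  dplyr::bind_rows(lapply(.subject_names, function(p) {
    da <- .location_draws(pair$rfpc, p)
    db <- .location_draws(pair$vertex, p)
    diff <- as.vector(da - db)
    tibble::tibble(
      parameter = p, mean_change = mean(diff),
      frac_below_0 = mean(diff < 0), frac_above_0 = mean(diff > 0)
    )
  }))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on either a synthetic study
#' (pass a [study_config()]) or an existing canonical CSV (pass `input`).
#' Artifacts are written under `out_dir`; a `manifest.json` records the
#' configuration hash, seed, stages and package version. Existing outputs
#' are never overwritten unless `overwrite = TRUE`.
#'
#' @param cfg A [study_config()] for synthetic data (used by the
#'   `simulate` stage), or `NULL` when `input` is given.
#' @param input Path to a canonical trials CSV (alternative to `cfg`).
#' @param stages Subset of `c("simulate", "validate", "model_free", "fit",
#'   "contrasts", "report")`.
#' @param out_dir Output directory.
#' @param seed Seed for the fitting stage.
#' @param mcmc List of MCMC settings passed to [fit_study()]
#'   (`n_chains`, `n_iter`, `burn_in`, `thin`, `refit_on_failure`).
#' @param overwrite Allow overwriting an existing manifest/outputs.
#' @param quiet Suppress per-stage messages.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg = NULL, input = NULL,
                         stages = c("simulate", "validate", "model_free",
                                    "fit", "contrasts", "report"),
                         out_dir, seed = 1,
                         mcmc = list(), overwrite = FALSE, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(cfg) && is.null(input)) stop("provide cfg or input")
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output directory already contains a run (", manifest_path,
         "); pass overwrite = TRUE to replace it")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  results <- list()
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      err <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(err, file.path(out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("stage %s done (%.1f s)", name, timings[[name]])
    out
  }

  if ("simulate" %in% stages && !is.null(cfg)) {
    results$sim <- stage("simulate", {
      sim <- generate_study(cfg)
      write_study_bundle(sim, cfg, out_dir)
      sim
    })
    study <- results$sim$study
  } else {
    study <- read_study_csv(input)
  }
  results$study <- study

  if ("validate" %in% stages) {
    results$violations <- stage("validate", {
      v <- validate_study(study)
      readr::write_csv(v, file.path(out_dir, "validation.csv"))
      v
    })
  }

  if ("model_free" %in% stages) {
    results$model_free <- stage("model_free", {
      mf <- model_free_summary(study)
      readr::write_csv(mf, file.path(out_dir, "model_free_summary.csv"))
      conf <- dplyr::bind_rows(lapply(5:10, function(t) {
        confound_correlation(study, t)
      }))
      readr::write_csv(conf, file.path(out_dir, "confound_curve.csv"))
      an_hi <- rm_anova(mf, "p_high_info", within = c("horizon", "tms_condition"))
      an_lo <- rm_anova(mf, "p_low_mean", within = c("horizon", "tms_condition"))
      lt <- later_trials_analysis(study)
      readr::write_csv(lt$curves, file.path(out_dir, "later_trials.csv"))
      jsonlite::write_json(
        list(anova_high_info = an_hi, anova_low_mean = an_lo,
             ttest_h6 = posthoc_ttest(mf, "p_high_info", 6),
             ttest_h1 = posthoc_ttest(mf, "p_high_info", 1, "two.sided")),
        file.path(out_dir, "model_free_tests.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE
      )
      list(summary = mf, confound = conf, anova_high_info = an_hi,
           anova_low_mean = an_lo, later = lt)
    })
  }

  if ("fit" %in% stages) {
    results$fit <- stage("fit", {
      args <- c(list(study = study, seed = seed), mcmc)
      pair <- do.call(fit_study, args)
      for (tms in names(pair)) {
        readr::write_csv(posterior_summary(pair[[tms]]),
                         file.path(out_dir, paste0("posterior_", tms, ".csv")))
        draws_table(pair[[tms]],
                    file.path(out_dir, paste0("draws_", tms, ".csv")))
      }
      pair
    })
  }

  if ("contrasts" %in% stages && !is.null(results$fit)) {
    results$contrasts <- stage("contrasts", {
      ac <- all_contrasts(results$fit)
      readr::write_csv(ac, file.path(out_dir, "contrasts.csv"))
      dA <- delta_A_contrast(results$fit)
      jsonlite::write_json(
        dA[c("mean", "frac_below_0", "cor_change_R0",
             "cor_A_R0_h1", "cor_A_R0_h6")],
        file.path(out_dir, "delta_A_contrast.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(table = ac, delta_A = dA)
    })
  }

  if ("report" %in% stages) {
    stage("report", {
      lines <- c(
        "Horizon-Task pipeline report",
        sprintf("generated: %s", format(t_start)),
        sprintf("trials: %d, subjects: %d", nrow(study),
                length(unique(study$subject))),
        if (!is.null(results$violations)) {
          sprintf("validation: %d violations", nrow(results$violations))
        },
        if (!is.null(results$model_free)) {
          mfh <- results$model_free$anova_high_info
          row <- mfh[mfh$effect == "horizon:tms_condition", ]
          sprintf("p(high info) horizon x stimulation: F(%d,%d) = %.2f, p = %.3g",
                  row$df1, row$df2, row$F, row$p)
        },
        if (!is.null(results$contrasts)) {
          sprintf("delta-A stimulation change: %.2f points (%.0f%% of draws below 0)",
                  results$contrasts$delta_A$mean,
                  100 * results$contrasts$delta_A$frac_below_0)
        }
      )
      writeLines(lines, file.path(out_dir, "report.txt"))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("horizontask")),
    seed = seed, stages = stages,
    config_hash = rlang::hash(list(cfg = cfg, input = input, mcmc = mcmc)),
    timings_s = timings,
    created = format(t_start)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(results)
}
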