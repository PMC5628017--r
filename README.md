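# horizontask

Analysis toolkit for **Horizon-Task** experiments — two-armed Gaussian
bandit studies designed to dissociate **directed exploration**
(information seeking) from **random exploration** (decision noise), here
in a two-session within-subject design comparing an inhibitory
brain-stimulation condition (`rfpc`) with a control site (`vertex`).

Each game pays out from two Gaussian slot machines (SD 8 points; one mean
anchored at 40 or 60, the other 4/8/12/20 points away). Four forced
choices set up an unequal `[1 3]` or equal `[2 2]` information condition,
then the subject makes 1 (*horizon 1*) or 6 (*horizon 6*) free choices;
sessions comprise 160 counterbalanced games. Because the forced trials
decouple information from reward on the first free choice, directed and
random exploration separate cleanly there.

The package provides, for researchers modelling explore–exploit
behaviour:

* **Learning model** — a Kalman-filter value learner kept entirely in
  learning-rate space, parameterized by the prior mean $R_0$ and the
  initial/asymptotic learning rates $\alpha_1, \alpha_\infty \in (0,1)$,
  with drift ratio $\alpha_d = \alpha_\infty^2/(1-\alpha_\infty)$ and
  update $R \leftarrow R + \alpha_t\,(r - R)$,
  $1/\alpha_t = 1/(\alpha_{t-1}+\alpha_d) + 1$.
* **Decision model** — logistic choice with an information bonus and
  spatial bias:
  $p(\text{right}) = 1\big/\bigl(1 + e^{(\Delta R + A \Delta I + B)/\sigma}\bigr)$.
* **Hierarchical Bayesian fitting** of the 13 subject-level parameters
  per stimulation condition (group priors: Gaussian for $R_0$, $A$, $B$;
  Beta for the learning rates; Gamma for $\sigma$; broad hyperpriors),
  via a fast adaptive Metropolis-within-Gibbs sampler (C++), with
  split-$\hat R$/ESS diagnostics, posterior contrasts between
  conditions, and the $\Delta A = A(h{=}6)-A(h{=}1)$ directed-exploration
  summary.
* **Model-free statistics** — p(high info), p(low mean), the
  reward–information confound curve, mixed repeated-measures ANOVA and
  paired post-hoc t-tests, later-trial analyses.
* **Synthetic-study generator** with known ground truth (and injectable
  stimulation effects) for parameter-recovery testing, plus an
  end-to-end `run_pipeline()` and a CLI wrapper
  (`inst/scripts/horizontask.R`).

See the methods vignette (`vignettes/horizon-task-methods.Rmd`) for the
model, priors, sampler and design choices in detail.

## Worked example

Simulate a small cohort with a known −5-point stimulation effect on the
horizon-6 information bonus, then analyse it model-free and
model-based:

```r
library(horizontask)

cfg <- study_config(n_subjects = 8, games_per_session = 160,
                    tms_effect = list(A_h6 = -5), seed = 42)
sim <- generate_study(cfg)

mf <- model_free_summary(sim$study)
dplyr::summarise(dplyr::group_by(mf, tms_condition, horizon),
                 p_high_info = mean(p_high_info),
                 p_low_mean = mean(p_low_mean), .groups = "drop")
#>   tms_condition horizon p_high_info p_low_mean
#> 1 rfpc                1       0.559      0.225
#> 2 rfpc                6       0.531      0.329
#> 3 vertex              1       0.584      0.176
#> 4 vertex              6       0.669      0.258

pair <- fit_study(sim$study, seed = 7, n_chains = 4, n_iter = 1000,
                  burn_in = 1000, refit_on_failure = FALSE)
con <- contrast(pair, "mu_A_h6")      # rfpc - vertex group-mean change
dA  <- delta_A_contrast(pair)
```

Reading the output: under the control condition information seeking
rises with horizon (p(high info) 0.58 → 0.67) — directed exploration —
and mistakes rise too (p(low mean) 0.18 → 0.26) — random exploration.
Under stimulation the horizon-6 information seeking drops to 0.53, while
the p(low mean) difference between conditions (0.33 vs 0.26 at horizon
6) is within what subject-level noise produces at this cohort size — no
noise effect was injected. The posterior contrast agrees: this run gives
a horizon-6 bonus change of −10.7 points with 93% of draws below zero
(the generative effect is −5; with only 8 subjects the estimate is
noisy), a ΔA change of −7.4 points (87% below zero), and essentially no
draw-wise correlation between the ΔA change and the prior-mean change
(−0.02), the diagnostic that the bonus effect is not a prior-mean
trade-off artifact.

The confound diagnostic confirms the design does its job at trial 5:

```r
confound_correlation(sim$study, 5)
#>   tms_condition trial_index correlation n_games
#> 1 rfpc                    5     0.00442     640
#> 2 vertex                  5    -0.0486      640
```

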