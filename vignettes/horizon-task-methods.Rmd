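---
title: "Modelling directed and random exploration in the Horizon Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling directed and random exploration in the Horizon Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horizontask)
```

# The task and the two kinds of exploration

The Horizon Task is a two-armed Gaussian bandit designed to dissociate two
strategies for resolving the explore--exploit dilemma. Each game presents
two slot machines whose payoffs are Gaussian with a fixed standard
deviation of 8 points; one machine's mean is anchored at 40 or 60 and the
other differs from it by 4, 8, 12 or 20 points. Every game opens with four
*forced* choices that set up an information condition — unequal `[1 3]`
(one option seen once, the other three times) or equal `[2 2]` — followed
by either one (*horizon 1*) or six (*horizon 6*) free choices. A session
comprises 160 games, counterbalanced over horizon, information condition,
mean gap and better side.

Because the forced trials fix how much is known about each option
independently of its payoff, the first free choice cleanly separates:

* **directed exploration** — an *information bonus* added to the value of
  the less-sampled option, which should grow with horizon; and
* **random exploration** — *decision noise*, choice stochasticity that
  also grows with horizon.

The package analyses studies with two within-subject sessions
(an inhibitory-stimulation condition, `rfpc`, and a control, `vertex`),
but all machinery works for any two-session design.

# Learning component

Subjects are assumed to track each option's mean payoff with a Kalman
filter whose generative model allows the mean to drift between trials.
All bookkeeping is done in learning-rate space: the posterior variance of
an option's value enters only as the ratio
$\omega = \sigma^2/\sigma_r^2$, because only three combinations of the
four variance parameters are behaviourally identifiable. The model is
parameterized by the prior mean $R_0$, the initial learning rate
$\alpha_1$, and the asymptotic learning rate $\alpha_\infty$:

* chosen option: $\omega_{\mathrm{pre}} = \omega + \alpha_d$, applied gain
  $\alpha = \omega_{\mathrm{pre}}/(1+\omega_{\mathrm{pre}})$, value update
  $R \leftarrow R + \alpha\,(r - R)$, and $\omega \leftarrow \alpha$;
* unchosen option: $R$ unchanged, $\omega \leftarrow \omega + \alpha_d$;
* drift ratio $\alpha_d = \alpha_\infty^2 / (1 - \alpha_\infty)$, the
  inverse of the fixed-point relation
  $\alpha_\infty = \tfrac12\bigl(-\alpha_d + \sqrt{\alpha_d^2 + 4\alpha_d}\bigr)$.

Under repeated play the applied gain follows
$1/\alpha_t = 1/(\alpha_{t-1} + \alpha_d) + 1$ and converges to
$\alpha_\infty$. $\alpha_\infty > 0$ produces a recency bias whose weights
decay geometrically; $\alpha_1 < 1$ means the prior is never fully
abandoned. The test suite proves this learning-rate formulation exactly
equivalent (to $10^{-10}$) to an independently written variance-space
Kalman filter over a thousand random parameterizations and trial
sequences.

Two deliberate modelling choices:

* **Interpretation of $\alpha_1$.** A literal variance-ratio reading of
  the initial learning rate ($(\sigma_0^2+\sigma_d^2)/\sigma_r^2$) can
  exceed 1, which contradicts its Beta prior. We therefore interpret
  $\alpha_1$ as the gain actually applied to the first observed outcome,
  which is always in $(0,1)$; `learning_params(alpha1_mode =
  "variance_ratio")` switches to the literal reading for comparison.
* **No ordering constraint.** $\alpha_1 \ge \alpha_\infty$ is *not*
  enforced; empirically initial rates exceed asymptotic ones, but that is
  a finding, not an assumption.

A boundary worth knowing: at $\alpha_d = 0$ exactly (no assumed drift)
the fixed point $\alpha_\infty = 0$ is only polynomially attracting
($\alpha_t = 1/(t + 1/\alpha_0)$, perfect sample averaging), so numerical
convergence tests use the exact harmonic bound there and the geometric
tolerance elsewhere.

# Decision component

The first free choice is modelled with a logistic rule,

$$p(\text{right}) = \frac{1}{1 + \exp\!\bigl(\tfrac{\Delta R + A\,\Delta I + B}{\sigma}\bigr)},$$

with $\Delta R = R_{\text{left}} - R_{\text{right}}$ from the learning
component, $\Delta I \in \{+1, -1, 0\}$ (+1 when the left option is the
more informative, 0 in the equal condition), information bonus $A$,
spatial bias $B$ and decision noise $\sigma$, all in points. All three
terms share the noise denominator. Positive $B$ pushes choice toward the
left option — the sign convention is arbitrary and documented, chosen so
$B$ enters the exponent exactly as $\Delta R$ does.

Per session a subject has 13 parameters: $R_0, \alpha_1, \alpha_\infty$
(shared across conditions), $A$ per horizon (undefined in the equal
condition), and $B$ and $\sigma$ per horizon-by-information cell.
Directed exploration is the horizon-related change
$\Delta A = A(h{=}6) - A(h{=}1)$; random exploration is the corresponding
change in $\sigma$.

For forward simulation beyond the first free choice (where the published
analyses stop), learning continues over free trials and $\Delta I$ is
defined as the sign of the cumulative play-count deficit, so the bonus
keeps favouring the less-played side; ties give $\Delta I = 0$.

# Hierarchical estimation

Each of the 13 parameters is drawn per subject from a group-level prior,
fit separately per stimulation condition:

| parameter | prior | hyperpriors |
|---|---|---|
| $R_0$ | Gaussian$(\mu, \sigma)$ | $\mu \sim \mathcal N(50, 14)$, $\sigma \sim$ Gamma$(1, 0.001)$ |
| $\alpha_1$ | Beta$(a, b)$ | $a \sim U(0.1, 10)$, $b \sim U(0.5, 10)$ |
| $\alpha_\infty$ | Beta$(a, b)$ | $a, b \sim U(0.1, 10)$ |
| $A$, $B$ | Gaussian$(\mu, \sigma)$ per cell | $\mu \sim \mathcal N(0, 100)$, $\sigma \sim$ Gamma$(1, 0.001)$ |
| $\sigma$ (noise) | Gamma$(k, \lambda)$ per cell | $k \sim$ Exp$(0.1)$, $\lambda \sim$ Exp$(10)$ |

Gammas are shape/rate; exponentials are rate-parameterized. The two Beta
hyperprior boxes differ (the $b$ lower bound is 0.5 for $\alpha_1$ and
0.1 for $\alpha_\infty$) — implemented as printed in the source model.
Subjects missing one session stay in that condition's model and are
sampled from the group prior alone; this is why the model-based analysis
tolerates attrition that the model-free analysis cannot.

Only the first free choice of each game enters the likelihood (a
Bernoulli over the logistic rule), because later trials re-confound
reward and information.

## Sampler

Sampling uses an adaptive Metropolis-within-Gibbs scheme written for this
model (C++ core): random-walk proposals per parameter (log scale for
scales, logit for learning rates) with Robbins–Monro adaptation toward
44% acceptance during burn-in only; conjugate Gibbs updates for the
Gaussian group means and for the Gamma rate hyperparameter; and a
translation move per Gaussian family that shifts all subjects and the
group mean together. The translation move matters: the task induces a
strong trade-off between the prior mean and the information bonus (a
higher $R_0$ inflates the value of the less-sampled option much as a
bonus does), and plain componentwise walks crawl along that ridge.

The default protocol is 4 chains × 1000 retained draws after 500 burn-in
sweeps, thinning 1. Convergence is assessed with split-$\hat R \le 1.05$
and bulk ESS $\ge 400$ per sampled group-level parameter; on failure the
fit reruns once at doubled length. Chains initialize from hyperprior
draws, except that scale-type hyperparameters are truncated into
$[0.05, 50]$ — the Gamma$(1, 0.001)$ hyperprior has mean 1000, and
unmoderated draws routinely start chains in flat likelihood regions; the
priors themselves are untouched. Heavy-tailed scale hyperparameters mix
slowest; interval summaries of group *means* are stable well before every
scale parameter clears the ESS gate.

Posterior contrasts pair draws by (chain, iteration) across the two
condition fits. The stimulation-related change is reported as
`rfpc - vertex`, so an inhibitory effect is negative; published figure
captions in this literature sometimes state the opposite orientation, so
the package fixes one convention and documents it. For the Beta and
Gamma families the group-level location is taken as $a/(a+b)$ and
$k/\lambda$ respectively.

# Model-free measures

* `p_high_info`: fraction of unequal-condition games whose free choice at
  a given trial lands on the less-played option (at trial 5, the
  once-forced option; later, the cumulative-count deficit side; ties
  excluded).
* `p_low_mean`: fraction of equal-condition games choosing the option
  with the *lower observed sample mean* of the outcomes seen so far.
  Observed means are used, not generative means, because the measure
  models subject-visible mistakes; ties are excluded from the
  denominator (the original analysis does not state its tie rule — this
  is our choice, and it only matters for integer-rounded rewards).
* `confound_correlation`: Pearson correlation across horizon-6 games of
  sgn(mean difference) with sgn(play-count difference) — near zero at
  trial 5 by design, increasingly positive afterwards.

The repeated-measures ANOVA tests within effects against their
subject-by-effect strata. With $n$ complete subjects and 2×2 within
factors this yields $F(1, n-1)$ tests; the published analysis reports
that df pattern while also naming session order as a factor, which in a
standard mixed layout would cost a denominator df — so by default order
effects are reported from the between-subject stratum without entering
the within-effect error terms. Post-hoc stimulation comparisons are
paired $t$-tests, one-sided for the directional horizon-6 prediction.
Subjects missing a session are excluded from all model-free analyses.

# Synthetic studies and what they do (and don't) show

`study_config()` + `generate_study()` emulate the full design: balanced
32-cell allocation (horizon × information × gap × better side, anchor
placement cycled within cells), randomized forced sequences, Gaussian
rewards rounded to integer points (display convention; the source task
shows integer scores), counterbalanced session order, optional missing
second sessions, and choices generated by the learning + decision model
with subject parameters drawn from configurable group-level truths.
Default truths sit where adult cohorts on this task family land: $R_0
\sim \mathcal N(50, 6)$, $\alpha_1 \sim$ Beta(6,4), $\alpha_\infty \sim$
Beta(2,6), bonus means 4 (h1) and 9 (h6) with SDs 4 and 6, biases
$\mathcal N(0,3)$, noise means 7/5/11/9 points across the four cells
(Gamma, shape 6). `tms_effect` injects additive group-mean shifts in the
stimulation condition; recovery experiments use $\Delta A_{h6} = -5$.

Per-subject-per-session RNG streams are derived arithmetically from the
master seed, so enlarging a cohort never perturbs existing subjects, and
identical configurations are byte-identical on disk. The generator
deliberately does *not* emulate shared forced-trial seeds across early
subjects, reaction times, payment, or any physiological effect of
stimulation; and because synthetic choices come from the fitted model
family itself, passing recovery tests demonstrates estimator correctness,
not that real subjects follow the model.

# Problem sizes used in the checks

The test suite runs the sampler-vs-grid oracle on one subject × 160
games with 4 × 20,000 draws (agreement within 2% on posterior means and
SDs of the free bonus/noise pair), and the study-scale recovery on six
replications of 25 subjects × 2 sessions × 160 games at 4 × 500 retained
draws with 1000 burn-in — sizes chosen to exercise the full design while
keeping a complete run in minutes. Coverage is scored against the
injected effect with central 80% intervals; subject-level recovery pools
the bonus (and noise) cells over replications before correlating with
truth. The acceptance script fits one full synthetic study at 4 × 1000
draws.

# Known limitations

* The published headline statistics depend on the original study's
  deposited trial data; without a local copy of that deposit the package
  can only verify its machinery on synthetic cohorts (the acceptance
  suite documents this as an expected failure).
* Decision noise for a single subject-cell rests on ~40 Bernoulli
  observations per session; its subject-level recovery is adequate pooled
  across cells but noisy per cell.
* The sampler is specialized to this model family; it is not a
  general-purpose MCMC engine.
* Model comparison (information criteria, alternative choice kernels)
  and fitting of later free choices are out of scope.
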