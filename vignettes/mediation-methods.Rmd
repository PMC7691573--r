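---
title: "Causal mediation analysis for surgical trials: models, estimands and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal mediation analysis for surgical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medsurg)
```

## The problem

Pragmatic trials of surgical interventions often permit co-interventions at
the surgeon's discretion.  When a co-intervention (for example, removal of
the left atrial appendage during cardiac ablation surgery) is applied much
more often in one arm than the other, part of the apparent treatment effect
may travel through it.  `medsurg` partitions the total effect of a
randomised binary treatment $T$ on a binary outcome $Y$ into natural direct
and indirect components with respect to a binary mediator $M$, under
surgeon-level clustering, and asks the policy questions: what would the
treatment effect be if the co-intervention were mandated, or prohibited,
for everyone?

## Estimands

Let $Y_i(t, m)$ be the potential outcome of patient $i$ under treatment $t$
and mediator value $m$, and $M_i(t)$ the potential mediator under $t$.  All
effects are on the probability-difference scale, where they compose
additively (they would not on the odds-ratio or risk-ratio scale, which is
why that scale is used throughout):

* natural indirect effects $\delta(t) = E[Y(t, M(1)) - Y(t, M(0))]$,
* natural direct effects $\zeta(t) = E[Y(1, M(t)) - Y(0, M(t))]$,
* total effect $\tau = E[Y(1, M(1)) - Y(0, M(0))] = \delta(1) + \zeta(0)
  = \delta(0) + \zeta(1)$,
* controlled direct effects $\zeta_c(m) = E[Y(1, m) - Y(0, m)]$,

plus the arm-averages $\delta(a^*) = (\delta(0)+\delta(1))/2$ and
$\zeta(a^*) = (\zeta(0)+\zeta(1))/2$.  The estimands are *marginal* over
the trial's empirical covariate distribution and over the population of
surgeons, in contrast to the conditional odds ratios reported by the
regression models.

Identification rests on the stable-unit-treatment assumption and on
sequential ignorability: (i) treatment is independent of potential outcomes
and mediators given baseline covariates — guaranteed by randomisation — and
(ii) the mediator is independent of potential outcomes given treatment and
covariates.  Condition (ii) is not testable and is the target of the
sensitivity analysis.  `run_pipeline()` prints this assumption ledger in
every report; nothing in the package pretends to verify it.

## The two working models

Both are logistic mixed models with a Gaussian surgeon random intercept:

$$\mathrm{logit}\,P(M_i = 1) = \alpha_0 + \alpha_1 T_i + \alpha_2^\top X_i
  + v_{s(i)}, \qquad v_s \sim N(0, \sigma_v^2)$$
$$\mathrm{logit}\,P(Y_i = 1) = \theta_0 + \theta_1 T_i + \theta_2 M_i +
  \theta_3 T_i M_i + \theta_4^\top X_i + u_{s(i)}, \qquad
  u_s \sim N(0, \sigma_u^2)$$

The treatment-by-mediator interaction is included by default
(`tm_interaction = FALSE` disables it).  Fitting is by adaptive
Gauss–Hermite quadrature over the random intercept (`quad_points`, default
7; 1 gives the Laplace approximation), delegated to `lme4::glmer()`, with
the absolute gradient convergence check relaxed to 0.05 (the default 0.002
flags fits whose parameters are settled far beyond any tolerance that
matters here, which would make the bootstrap discard perfectly good
refits; degenerate-Hessian and identifiability checks remain active and do
mark fits non-converged) and one automatic `bobyqa` restart when a
convergence warning remains; the
`cluster = NULL` spec is the $\sigma = 0$ special case fitted by ordinary
logistic regression.  On trial-scale data, 7 and 15 quadrature points agree
to better than $10^{-3}$ (tested).  Estimated random-intercept SDs below
$10^{-4}$ are reported as exactly 0.  The intra-cluster correlation uses the
latent-variable formulation, $\mathrm{ICC} = \sigma^2/(\sigma^2 + \pi^2/3)$,
the level-1 residual variance of a logistic model being $\pi^2/3$.

Rank-deficient designs are rejected naming the aliased columns.  Fits with
any |coefficient| above 25 on the logit scale are rejected as completely
separated (penalised regression is out of scope); quasi-separated bootstrap
resamples, which plateau around 18, are deliberately retained because their
predicted probabilities are finite and usable.

## The potential-outcome Monte Carlo engine

`estimate_natural_effects()` simulates, for each of `n_sims` replicates
(default 2000) and each patient: potential mediators $M(0), M(1)$ from the
mediator model with $T$ forced to each arm, then the four potential
outcomes $Y(t, M(t'))$ from the outcome model.  Averaging gives the
$2\times2$ table $\bar P(t, t') = \hat P(Y(t, M(t')) = 1)$ from which every
natural effect is read off, so the composition identity
$\tau = \delta(1)+\zeta(0) = \delta(0)+\zeta(1)$ holds to machine
precision by construction.  Three deliberate choices:

* **Common random numbers.**  Within a replicate, one uniform drives both
  mediator draws and one uniform drives all four outcome cells, and the
  random-intercept realisation is shared.  Structural zeros are then exact:
  if $\theta_2 = \theta_3 = 0$ the estimated indirect effects are
  identically 0, not merely small.
* **Random-intercept rule.**  The default `re_rule = "draw"` draws fresh
  $N(0, \hat\sigma^2)$ surgeon effects per replicate, matching the marginal,
  population-of-surgeons estimand; `"zero"` (population-median surgeon) and
  `"mode"` (each patient's own estimated surgeon) are available.
* **Fixed coefficients.**  Point estimates plug in the fitted coefficients
  without quasi-Bayesian parameter draws; all parameter uncertainty is
  carried by the bootstrap instead.

Controlled direct effects (`estimate_controlled_effects()`) set $M = m$ for
everyone and do not use the mediator model.  Moderation
(`estimate_moderated_effects()`) re-runs the engine with every patient's
moderator pinned to each grid value, using fits that include the
moderator's interactions with $T$ (and with $M$ in the outcome model); with
zero interaction coefficients the profile is exactly flat.

Engine output was validated against a closed form: for covariate-free
models all seven natural-effect quantities and both controlled effects
equal a one-dimensional Gaussian quadrature mixture, and the suite checks
agreement within 3 Monte Carlo standard errors at `n_sims = 2000`.

## Bootstrap inference

`bootstrap_effects()` resamples patients with replacement *within arm*
(default) or whole surgeon clusters with replacement (drawn copies treated
as new clusters), refits both models, and reruns the engine with a
replicate-specific sub-seed; intervals are percentile intervals (default
`n_boot = 999`, level 95%).  Percentile rather than BCa is the simplest
defensible default; BCa would be an extension.  Refits that error or fail
to converge are dropped and counted — never imputed — and more than 20%
failures aborts with an error.  Percentile intervals need not contain the
point estimate in finite samples, and the suite does not pretend they must.

Calibration was checked two ways (problem sizes chosen to keep the default
suite in minutes): coefficient bias and 95% Wald coverage over 200
simulated trials of 1000 patients in 20 clusters, and type-I error of the
95% bootstrap interval for $\tau$ under a global-null generator over 200
runs of 199 replicates each.  The null calibration study generates trials
with $\sigma_v = \sigma_u = 0$ and analyses them with the matching
no-random-intercept model — the $\sigma = 0$ special case of the same
pipeline — which is the model that generator actually implies.

## Sensitivity analysis for unmeasured mediator–outcome confounding

Postulate a scalar unobserved confounder $U$ with variance 1, log odds
ratio $\beta$ on the outcome given $(T, M, X)$, and mediator association
expressed through mean contrasts
$E(U \mid M=1, T=t) - E(U \mid M=0, T=t) = \lambda_0 + \lambda_1 t$.
Because the exact adjustment for the binary–binary case is not available in
closed form, the package commits to a **first-order coefficient-shift
correction**, documented as an approximation:

1. Under randomisation $E(U \mid T) = 0$, so
   $E(U \mid M=m, T=t) = (\lambda_0 + \lambda_1 t)(m - p_t)$ with $p_t$ the
   observed arm-$t$ mediator uptake.
2. A logistic model fitted without $U$ absorbs
   $\beta\,E(U \mid M, T)$ into its linear predictor (to first order, after
   logistic–normal scaling); in particular the mediator coefficient absorbs
   $\beta\lambda_0$ and the interaction absorbs $\beta\lambda_1$.
3. The de-confounded *interventional* cell probability restores $U$ to its
   marginal $N(0,1)$ and integrates it out with the standard
   logistic–normal factor, giving
   $$\mathrm{logit}\,P(Y(t,m)=1) \approx \hat\eta(t,m) -
     \frac{\beta(\lambda_0+\lambda_1 t)(m - p_t)}
          {\sqrt{1 + \beta^2 c^2}}, \qquad c^2 = 16\sqrt3/(15\pi).$$

`adjusted_effects()` reruns the engine with this cell shift.  The
construction is exact at the no-confounding origin — $\beta = 0$ or
$\lambda_0 = \lambda_1 = 0$ reproduce the unadjusted run draw-for-draw —
and first-order correct, which the suite verifies against an independent
enumeration oracle: a discrete world with $U = \pm 1$ where the exact
confounded observed models and the exact de-confounded effects can both be
enumerated.  Because the factual cells shift by approximately zero in
expectation (the $m$-average of $m - p_t$ vanishes at the observed uptake),
the total effect is approximately preserved while the correction trades
direct against indirect effect — the behaviour the question "how strong
must confounding be to explain away the direct effect?" requires.  On
generated trials containing a real confounder, adjusting at the true
$(\beta, \lambda_0, \lambda_1)$ removes most of the bias of the naive
analysis (tested over 100 replicates).

`sensitivity_surface()` evaluates the adjusted effects over a
$\beta \times \lambda_0$ grid (default $\{-1, -0.75, \dots, 1\}$, 0 meaning
no unexplained confounding and $\pm 1$ large effects) at fixed $\lambda_1$
(default 0), reusing identical engine draws at every grid point so the
surface is smooth and its origin matches the unadjusted estimate to
$10^{-12}$.  The significance mask bootstraps the whole grid per refit; to
keep that affordable it uses a marginalised variant of the engine that
averages cell probabilities instead of drawing binary outcomes (identical
expectation, lower noise) and evaluates all grid shifts vectorised.  The
reported frontier collects grid cells where the adjusted direct effect
changes sign or loses significance; for a positive direct effect it lies in
the quadrants where $\beta$ and $\lambda_0$ have opposite signs, i.e.
confounding must act in opposite directions on outcome and mediator to
explain the effect away.

## The synthetic trial generator

`trial_config()` defaults describe the study conditions the package is
designed around, a pragmatic cardiac-surgery trial of ablation with
discretionary left-atrial-appendage removal: 352 patients randomised 1:1 at
patient level, dealt round-robin to 20 surgeons (surgeon counts and
cluster-size profiles of such trials are rarely published; 20 near-equal
clusters is a stand-in, not an estimate); mediator uptake near 55% versus
30% with mediator ICC 0.5 (strong surgeon preference, $\sigma_v = 1.81$);
outcome ICC 0.1 ($\sigma_u = 0.60$); age $\sim N(72, 8^2)$ entering both
models linearly on the log-odds scale, and baseline sinus rhythm
$\sim$ Bernoulli(0.2) strongly prognostic for success.  The outcome
coefficients (treatment log-OR 0.46, mediator $-0.29$, interaction 0.94)
were set once so that the implied marginal effects land near a total effect
of 0.17–0.18 with a dominant direct component, the situation of scientific
interest.  These defaults are fixed study conditions, not tuning knobs.

An optional confounder spec adds a standard-normal $U$ per patient to both
models: its outcome loading is `beta_true` directly, while its mediator
loading is found by one-dimensional root finding so that the realised
$E(U \mid M, T)$ contrast matches `lambda0_true + lambda1_true * t` at the
covariate means (the sensitivity parameters are defined by that contrast,
not by a structural coefficient).  `true_effects()` computes ground-truth
effects of a confounder-free config by direct Monte Carlo from the
generating model with common random numbers, sharing the engine's
composition-exactness; it refuses configs with a confounder, since the
unconfounded estimand is not defined there.

What the generator does *not* emulate: informative cluster sizes,
non-normal random effects, missing outcomes (the package enforces a
complete-case contract at the door), treatment-dependent covariates, and
multiple or time-varying mediators.  Green tests therefore speak to the
estimation machinery under the stated conditions, not to robustness against
those features of real data.

## Numerical choices and degenerate inputs

* Seeds: every exported function takes an explicit seed; sub-streams are
  derived deterministically (Lehmer step, kept below $2^{31}$), and the
  caller's RNG state is always restored.
* `n_sims` below 100 warns; the Monte Carlo error of every reported
  quantity shrinks as $n_\text{sims}^{-1/2}$ (tested).
* An all-identical simulated mediator triggers a saturation warning, not an
  error.
* Categorical covariates are dummy-coded against the first level in sorted
  order unless the schema declares a reference, making file round-trips
  deterministic; cluster labels are opaque strings.
* Sensitivity parameters beyond $|\beta| > 5$ or $|\lambda| > 2$ warn as
  outside the plausible range.

## Known limitations

The sensitivity correction is first-order in $\beta\lambda$; for very
strong postulated confounding it understates curvature, and exact
replication of any particular published contour is not claimed.  Estimands
are probability differences only.  One mediator, one clustering level, no
random slopes, no missing-data machinery, percentile intervals only, and
pointwise (not simultaneous) moderation profiles.
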