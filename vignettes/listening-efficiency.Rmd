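---
title: "Listening efficiency from hierarchical LBA models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Listening efficiency from hierarchical LBA models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Speech-in-noise tests usually score either accuracy or response speed. When
a task is easy enough that accuracy saturates (a yes/no probe-word task at
positive SNRs), almost all of the behavioural signal moves into response
times, and any analysis of one measure alone is confounded by the
speed-accuracy trade-off. `listeff` analyses both jointly with a linear
ballistic accumulator (LBA): on every trial two accumulators — one for the
correct response, one for the incorrect one — gather evidence linearly from
a start point drawn uniformly on $[0, A]$ toward a threshold $b = A + k$;
the first to arrive determines the choice, and the observed RT is the
decision time plus a non-decision constant $t_0$. Each accumulator's drift
rate is drawn per trial from a normal distribution with mean $v$ and
between-trial SD $s_v$, fixed to 1 as the scaling constraint.

The quantity of interest is the *differential drift rate*

$$ v_\Delta = v_{\text{correct}} - v_{\text{incorrect}}, $$

the net rate at which a listener accumulates evidence toward the correct
answer — *listening efficiency*. It is computed per SNR condition (Easy,
Med, Hard) and per trial type: *sentence* trials require actual listening,
*null* trials (muted sentence, instructed button press) isolate task
execution, so a group difference that appears only in sentence trials is
attributable to listening rather than motor or strategic factors.

Each participant contributes a 15-parameter vector: 12 drift means
(2 responses x 3 conditions x 2 trial types) plus $A$, $k$ and $t_0$, which
are constant across trials. Trials with no response inside the 3 s deadline
enter the likelihood through a latent response time above the deadline with
accuracy fixed at chance: the contribution is
$\tfrac12 g_\text{correct}(\tau) + \tfrac12 g_\text{incorrect}(\tau)$ where
$g$ is the defective joint density of (choice, RT) and $\tau$ is estimated
per missing trial. The latent $\tau$ is capped at 10 s by default
(`cap` in `build_model()`); the cap is arbitrary but innocuous because the
defective density decays fast beyond the deadline.

# Hierarchical structure and priors

Individual parameter vectors $\alpha_i$ (drifts on the natural scale,
$\log A$, $\log k$, $\log t_0$) follow a multivariate normal population
distribution per group, $\alpha_i \sim N(\mu_g, \Sigma_g)$, so individual
estimates are shrunk toward their group and the full covariance among the
15 parameters is estimated. We place a conjugate Normal-Inverse-Wishart
prior on $(\mu_g, \Sigma_g)$:

* $\Sigma_g \sim \mathrm{IW}(\nu_0 = 17,\ S_0)$ with $S_0$ diagonal — prior
  individual SDs of 1 for drifts and 0.2 for the log-scale structural
  parameters;
* $\mu_g \mid \Sigma_g \sim N(m_0, \Sigma_g/\kappa_0)$ with $\kappa_0 =
  0.25$ and $m_0$ placing drift means at 2.5 (prior SD about 2), $A$ at 1,
  $k$ at 2 and $t_0$ at 0.25 s (prior SD about 0.4 on each log scale).

These are weakly informative but *calibrated*: drift rates are where the
data are rich, so their prior is broad; start-point ranges, thresholds and
non-decision times do not plausibly vary by an order of magnitude across a
screened adult cohort, and a 250 ms centre for $t_0$ is the standard
perceptual-motor ballpark. Recovery simulations drove this calibration —
with order-of-magnitude-diffuse structural priors, the near-ceiling (NH)
group leaves $A$ and $t_0$ almost unidentified and their posteriors simply
reproduce whatever spread the prior asserts. The conjugate family was chosen deliberately: the
group level can then be updated by exact Gibbs draws, which is what makes a
random-walk-based sampler (below) meet a strict convergence contract. A
covariance prior split into scales and a correlation matrix would prevent
those exact updates while expressing essentially the same prior beliefs;
`lba_priors()` exposes $m_0$, $\kappa_0$, $\nu_0$, $S_0$ if a user wants a
different calibration. Covariances are group-specific; whether $A$, $k$,
$t_0$ are hierarchical within group (default) or a single shared value per
group is a switch (`structural` in `build_model()`): the default follows
the more general reading, the switch the more literal one ("fixed across
trials, varying across groups").

Drifts enter the individual-level multivariate normal on the natural scale
(the group mean is then directly the quantity whose contrasts are
reported); $A$, $k$, $t_0$ enter on the log scale so positivity is
structural. The data generator, by contrast, draws *all* individual
parameters log-normally — positivity by construction, with an optional sign
field for negative generative drifts. The mild mismatch between a
log-normal generative population and a Gaussian fitted population is
deliberate: it is exactly the kind of misspecification a real cohort would
present, and parameter recovery is tested under it.

# The sampler

Stan-style gradient samplers are the common route for hierarchical LBA
models; `listeff` instead ships a self-contained MH-within-Gibbs sampler
designed around the posterior's known geometry. Any sampler is acceptable
that passes the recovery and convergence suites; this one consists of:

* **Conjugate group updates.** $(\mu_g, \Sigma_g)$ are drawn exactly from
  their Normal-Inverse-Wishart full conditional each iteration.
* **Laplace preconditioning.** Before sampling, each participant's
  15-parameter vector is optimized (penalized MAP against that
  participant's trials) and the inverse curvature, plus prior-scale
  precision, becomes the initial Metropolis proposal covariance. Chains
  start at the MAP.
* **Cell-block moves.** The (correct, incorrect) drift pair of each
  design cell is updated jointly, evaluating only that cell's trials
  (per-trial likelihood caching makes this a sixth of a full evaluation).
* **Structural moves with RT-preserving drift maps.** $(\log A, \log k,
  \log t_0)$ moves rotate over three variants: a plain random walk; a walk
  where every drift follows the deterministic map
  $v' = c'v/(c + v\,\Delta t_0)$ (with caution $c = k + A/2$) that keeps
  each accumulator's mean RT $t_0 + c/v$ invariant — the likelihood ridge
  direction — with the exact Jacobian; and a caution-preserving walk of the
  start-point ratio $a = A/b$, the flattest likelihood direction, whose
  $(\mathrm{logit}\,a, \log c)$ parameterization has unit Jacobian.
* **Joint learned-covariance moves** over the full 15-dimensional vector.
* **Group translations and scalings.** For each group and coordinate
  block, a translation shifts the group mean and every member jointly (the
  non-centred direction — the only way likelihood-weak coordinates such as
  incorrect-response drifts of a near-ceiling group can move quickly), and
  a scaling expands or contracts the members' deviations around their mean
  (the variance funnel direction). A grouped structural translation applies
  the RT-preserving map to every member at once.
* **Latent missing RTs** move by Metropolis on $\log(\tau - \text{deadline})$.

All proposal scales adapt by Robbins-Monro during warmup only and are
frozen afterwards, preserving detailed balance in the sampling phase.
`mh_sweeps` controls how many refresh sweeps compose one retained
iteration; recovery-scale fits in the test-suite use `mh_sweeps = 10`.
R-hat is the rank-normalized split statistic (maximum of bulk and folded
versions) computed for every stored parameter; values outside
$[0.99, 1.01]$ raise a warning naming the offenders.

# What the synthetic cohort emulates

`design_spec()` defaults reproduce the study design this package targets:
24 cochlear-implant users and 25 normally-hearing controls, two runs of
three 28-trial SNR blocks (18 sentence + 10 null trials in random
interleaving, block order randomized per run), a 3 s response deadline, and
two participants (one per group) who completed a single run — 8,064
observations in all. Stimulus-onset jitter (6-10 s) is carried as schedule
metadata only.

`ground_truth()` defaults place the generative differential drift rates at
the published group-level posterior means of the target study
(sentence trials: NH 4.14/4.04/3.62, CI 2.79/2.16/1.57 across
Easy/Med/Hard; null trials analogous), with `v_incorrect = 1` in every
cell, $A = 1$, response caution 2.76 (NH) / 2.70 (CI) and $t_0 = 0.21$ s.
The published table reports only the differential rates, so the incorrect
accumulator's level is a package choice; 1.0 reproduces the qualitative
error-rate pattern (well under 1% for NH-like, several percent for
CI-like parameters) and sub-1% missing rates. Individual log-scale SDs
default to 0.15 (drifts, $A$, $k$) and 0.10 ($t_0$), uncorrelated: there is
no published individual-level dispersion to copy, and these values give
between-participant variation (population SD of mean sentence efficiency of
roughly 0.35-0.45) comparable to the spread visible in the study's
individual-level figures.

The generator emulates choices, RTs, censoring, bounded ratings and score
tables — not audio, adaptive test procedures, or physiological channels.
Ratings come from the ordered beta model with participant random
intercepts; scores come from a Gaussian-copula construction with
controllable population correlation to the true individual efficiencies
(clipping to instrument ranges slightly attenuates realized correlations,
so calibration tests use unclipped scores). Passing tests therefore show
that the pipeline recovers what this generative family produces at the
study's size; they cannot certify behaviour under real-data pathologies
(contaminant RTs, non-stationarity, response bias) that the family does
not produce.

# Downstream analyses

**Contrasts.** Per posterior draw, cell-level $v_\Delta$, its mean across
the three conditions, and its slope on equally spaced condition codes
(1, 2, 3) — for three points the OLS slope is exactly
$(\text{Hard} - \text{Easy})/2$ — then between-group (NH - CI) differences,
summarized by posterior means and 95% highest-density intervals (shortest
window of the sorted draws; ties break toward the smaller lower bound).

**Effect sizes.** Cliff's delta on posterior-predicted participant-level
data, one delta per draw (a pooled variant is available), giving a
posterior distribution of a nonparametric effect size.

**Plausible values.** Individual-level sentence efficiency (mean across
conditions) is extracted per draw; each draw's Pearson correlation with an
external score is one plausible correlation. The population correlation
posterior mixes, over draws, the exact posterior $p(\rho \mid r, n)$ under
a uniform prior, evaluated on a 2,001-point grid via the hypergeometric
series (the Fisher-z approximation is kept as a test oracle, not used).
Pearson is used throughout, matching the plausible-values literature. A
correlation is flagged *reliable* when the 95% credible interval excludes
zero or the directional certainty exceeds 0.90. At $n \approx 24$ this
rule is liberal by construction: its false-positive rate under a null
correlation is in the 10-20% range depending on how much posterior
uncertainty the plausible-value draws carry; the tests document this
operating characteristic rather than hiding it.

**Relative importance.** LMG decomposition (R-squared increments averaged
over all predictor orderings, exact enumeration up to 8 predictors),
applied per posterior draw of the response by default; a posterior-mean
mode is a flag away.

**Ratings.** Bounded visual-analog ratings use ordered beta regression
(point masses at exactly 0 and 1 through two ordered logistic cutpoints, a
beta interior with mean $\mathrm{logit}^{-1}(\eta)$ and precision $\phi$):
cell means per group x condition with participant random intercepts whose
SD is group-specific. Priors: Normal(0, 5) on cell coefficients and
cutpoints, exponential(0.1) on $\phi$, half-normal(0, 1) on intercept SDs.
Unbounded outcomes (age, momentary-fatigue change) use the
unequal-variance Gaussian group model, which is conjugate under flat means
and Jeffreys variances and is sampled exactly. Questionnaire totals
rescale to $[0,1]$ as EAS/60, (FAS - 10)/30, HHQ/100, SSQ12/10; the FAS
map follows the instrument's construction (10 items scored 1-5, so totals
live in 10-40) even though a 0-40 range is sometimes quoted. Instruments
with reversed scoring are handled by an explicit orientation column in the
instrument table.

# Numerical choices

* Densities are floored at $10^{-300}$ before logging; a structural
  violation (RT at or below $t_0$) yields $-\infty$ and is reported, not
  silently dropped.
* Quadrature uses `stats::integrate` with tight tolerances; choice
  probabilities report non-convergence as a warning.
* The $\rho$-posterior grid is open (excludes $\pm 1$); the hypergeometric
  series is evaluated once on a 4,001-point kernel grid in $u = \rho r$ and
  interpolated, making mixtures over thousands of draws cheap. Results are
  stable to grid refinement beyond 2,001 points (mean changes < $10^{-3}$).
* Sampler determinism: a fixed seed plus chain index determines every
  draw; the pipeline derives per-stage substreams from one top-level seed.
* The test-suite's recovery fit uses 15 + 15 participants x 168 trials and
  2 chains x (500 + 500) at `mh_sweeps = 10`; these sizes keep a full
  suite run comfortably on one CPU while leaving the group-level
  posteriors informative.

# Known limitations

* The sampler is specialized to this model family; it is not a general
  probabilistic-programming backend, and very different designs (many more
  conditions, other scaling constraints) would need new move tuning.
* Individual-level structural parameters ($A$, $k$, $t_0$) are weakly
  identified at 168 trials per participant; their posteriors leanheavily on
  the hierarchy, and their chains are the slowest-mixing quantities in the
  model. The convergence contract is enforced on every stored parameter,
  so fits that leave this regime warn loudly.
* No model comparison (WAIC/LOO) is provided, and no within-trial
  variability in $A$ or $t_0$ — both outside this package's scope.
* The missing-response treatment assumes chance accuracy for late trials;
  if late responses were systematically correct, efficiency would be
  underestimated slightly — at the sub-1% missing rates the generator
  produces, the effect is negligible.
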