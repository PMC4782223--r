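---
title: "Working-memory capacity, locality effects, and retrieval failure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory capacity, locality effects, and retrieval failure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actrlocality)
```

## The scientific problem

When a reader meets the head of an unbounded dependency ("what … did"),
the dependent must be retrieved from memory. Cue-based retrieval theories
predict *locality effects*: the longer the dependent has sat in memory,
the lower its activation and the slower the retrieval, so reading times at
the head should grow with dependent–head distance. Self-paced-reading
evidence complicates this picture: high-capacity readers can show locality
effects while low-capacity readers show *antilocality* — a speedup with
distance. This package implements, end to end on synthetic data, the
modeling chain needed to study that interaction:

1. a simplified ACT-R retrieval simulator with three linking hypotheses
   from working-memory capacity (WMC) to model parameters;
2. exact closed-form locality algebra used as oracles for the simulator;
3. a modified retrieval mechanism in which sub-threshold retrievals abort
   early, producing *fast failures*;
4. a generator of trial-level self-paced-reading datasets with the
   2 × 2 × 5-region design, crossed random effects, and participant-varying
   shifts;
5. Bayesian shifted-lognormal hierarchical models of reading times with
   effect sizes, split R-hat convergence checks and WAIC comparison;
6. partial-credit-unit (operation span) and rapid-naming fluency scoring.

## The retrieval model

A single retrieval is governed by four equations. Latency is exponential
in activation,

$$\mathrm{Latency} = F e^{-A}, \qquad A = BA + S + \epsilon,$$

with latency factor $F$ (seconds) and logistic noise $\epsilon$ of scale
$\sigma$ (variance $\pi^2\sigma^2/3$; $\sigma$ is the *scale*, not an SD).
For an item encoded once, $t$ seconds ago, the base-level activation
decays as a power law of time,

$$BA = -d \log t + \beta,$$

with decay rate $d$ and base-level constant $\beta$. (Printed renderings
of this law sometimes typeset the exponent inline, as the log of
$t^{-d}$; since $d$ is a *rate* and a literal $\log(t - d)$ would be
undefined for $t < d$, the power-law reading is the only coherent one and
is what `base_activation()` implements.) Spreading activation from the
retrieval cues is

$$S = W \sum_{c} w_c \,(\mathit{MAS} - \log n_c),$$

where $W$ is the source activation shared between cues, $w_c$ are cue
weights summing to one, $\mathit{MAS}$ the maximum associative strength,
and $n_c$ the fan — the number of memory items matching cue $c$. The
study design has one unique cue (+wh, fan 1) and two cues shared by five
noun phrases (+animate, +NP, fan 5), the default `fan_profile(1, 5, 5)`.
$\mathit{MAS} - \log n_c$ must stay positive; `spreading_activation()`
enforces this. The mismatch-penalty term of full ACT-R is omitted: only
the retrieval of the fully matching wh-element is modeled, not the
competitor noun phrases.

A threshold $\tau$ bounds retrievable activation, giving the time-out

$$\max(\mathrm{Latency}) = F e^{-\tau}.$$

### Capacity mappings

The linking hypotheses are implemented as `capacity_mapping()` objects
that interpolate one parameter linearly over a normalized WMC index in
$[0,1]$ (the published accounts state ranges and directions, not a
functional form; linear interpolation is the minimal monotone choice and
the endpoints are configurable):

| mapping | parameter | direction with capacity | default range | modified range |
|---|---|---|---|---|
| capacity-as-decay-rate | $d$ | decreasing | [0.06, 1.5] | [0.33, 0.62] |
| capacity-as-source-activation | $W$ | increasing | [0.5, 3.5] | [0.9, 1.2] |
| capacity-as-interference | $w_{wh}$ | increasing | [0.1, 1] | [0.2, 0.5] |

For the interference mapping the residual weight $1 - w_{wh}$ is split
equally between the two shared cues so the weights keep summing to one.
`actr_preset()` returns the two published configurations: the `"default"`
variant ($F = 1.6$, $\mathit{MAS} = 2$, $\sigma = 0.25$; $\beta = -0.65$
for the decay mapping and $-1$ otherwise — the source publishes both
values without comment, and both are honored; $\tau = 0$ or $-\infty$)
and the `"modified"` variant ($\beta = -0.3$ for all three mappings,
$\tau = 0$, narrower ranges chosen so capacity affects activation only
weakly). Whether $\sigma$ should itself vary with capacity is an open
question in the literature; it is held constant here.

### Two failure mechanisms

`simulate_retrieval()` draws one noise value per attempt; the same
realized activation decides success and latency. If $A \ge \tau$ the
retrieval completes at $F e^{-A}$. If not:

* **default variant** — the failure consumes the full time-out
  $F e^{-\tau}$ (the threshold acts as a ceiling);
* **modified variant** — the retrieval is aborted at a time drawn
  uniformly on $(0, F e^{-\tau})$. Any abort-time distribution with mean
  below the mean completed latency produces the same qualitative pattern,
  so the sampler is pluggable (`abort_sampler`).

The closed-form failure probability is the logistic CDF
$\mathrm{logit}^{-1}((\tau - BA - S)/\sigma)$
(`failure_probability()`), which the Monte Carlo failure proportions must
match within binomial error — one of the package's standing test suites.

### What the algebra proves

`locality_raw()`, `locality_wmc_interaction_raw()` and `locality_log()`
implement the exact cell algebra. Two consequences anchor the test suite:

* On *raw* latencies, locality is
  $F e^{-S}(e^{-BA_{low}} - e^{-BA_{high}}) \ge 0$ whenever distance
  decays activation: without a threshold, all three linking models can
  only predict slowdowns with distance, never the observed low-capacity
  speedup.
* On *log* latencies, locality is $BA_{high} - BA_{low}$ — independent of
  both $S$ and $F$. So if capacity enters only through spreading
  activation (source-activation and interference mappings), the
  WMC × locality interaction on log latencies is *exactly zero*, for every
  parameter setting. `check_identities()` verifies this to machine
  precision on randomized draws. Note the identity concerns the
  difference of log latencies; the log of the raw-latency difference is a
  different (and less useful) quantity.

The modified variant escapes both constraints: low-capacity readers fail
more often, their completed retrievals are slow, so their uniform
early-abort failures are *faster* than their successes and drag the
long-condition mean down — antilocality. High-capacity readers rarely
fail and keep their locality effect. `run_grid()` +
`grid_locality()` reproduce this crossover for all three mappings under
the modified presets.

## The synthetic data generator

`generate_dataset()` emulates the self-paced-reading design: a 2 × 2
within-participant manipulation (embedded-subject length × dependency
type, sum-coded −1/+1), five regions per sentence (precritical,
critical1, critical2, spillover1, spillover2), a Latin-square rotation of
conditions over items, and crossed random intercepts for participants,
items and sentences (a sentence being one participant × item trial
instance, which is how region-internal correlation enters). Reading
times are shifted lognormal,

$$rt = \psi_{participant} + \mathrm{LogNormal}(\mu, \sigma),$$

with $\psi \sim \mathrm{Uniform}(100, 250)$ ms by default — below typical
minimum RTs, matching the view of the shift as the floor of motor and
encoding time. True effects are specified on the standardized
effect-size scale $\delta$ and converted as $\beta = \delta\sigma$; the
default magnitudes echo the kind of values reported for this design
(three-way interaction $\delta \approx 0.04$), as a *realistic default
only* — nothing in the package asserts they are recoverable truths of any
real study. Defaults: $\mu_0 = \log 300$ (so typical RTs fall near
400–550 ms), $\sigma = 0.4$, random-intercept SDs 0.15/0.05/0.05.

Participant covariates are drawn independently (`generate_participants()`
— the motivating experiments found WMC and reading fluency uncorrelated,
$r \approx -0.04$) from truncated normals over ranges typical of student
samples: PCU 0.28–0.92 around 0.63, naming fluency 1.4–3.6 characters/s
around 2.5.

`inject_retrieval_mixture()` couples the generator to the simulator: in
unbounded trials, the critical-region RT becomes baseline plus a realized
retrieval latency resampled from the matching simulation cell (nearest
WMC grid point after scaling the observed score range to $[0,1]$; short
vs. long cell via the length code). The additive form means the expected
shift of the cell mean is exactly the cell's expected retrieval time —
the mixture decomposition
$T = T_{baseline} + P\,T_{retrieval} + (1-P)\,T_{failure}$
(`expected_cell_time()`), with the generated RT playing the role of
$T_{baseline}$ (the generator's intercept governs the non-retrieval
regions, which is how the otherwise-unquantified baseline is fixed).

`apply_rt_filter()` trims RTs below 150 ms (likely accidental key
presses, which would corrupt the shift estimates) and above 5000 ms;
boundary values are *kept*, since the rule excludes values strictly
under/above the bounds.

## The reading-time model

`build_design()` assembles the fixed-effect matrix: sum-coded factors,
covariates scaled and centered, Helmert region contrasts
(`helmert_regions()`; each region compared with the mean of those before
it — columns orthogonal and zero-sum), and the locality interactions up
to length:dependency:covariate. Passing a single region gives the nested
per-region fits.

`fit_shifted_lognormal()` fits
$rt - \psi_{j[i]} \sim \mathrm{LogNormal}(X_i\beta + u_{p[i]} + w_{k[i]} + v_{s[i]},\ \sigma)$
by MCMC in JAGS. The shifted likelihood is expressed with the zeros
trick (a Poisson pseudo-observation per data point whose rate is the
negative log density plus a constant), since JAGS has no native shifted
lognormal. Priors, all configurable in the code and deliberately weakly
informative: $\beta_0 \sim N(6, 2.5^2)$ on the log-ms scale, other
$\beta_k \sim N(0,1)$, half-normal(0, 1) for $\sigma$, half-normal(0, 0.5)
for random-effect SDs, and $\psi_j \sim \mathrm{Uniform}(0, \min_i rt_{ij}
- 0.1\,\mathrm{ms})$ — the uniform over the feasible range, which encodes
the hard support constraint that every shift lies below its participant's
minimum RT. With `shift = FALSE` the same model runs with $\psi \equiv 0$,
the unshifted comparison model for WAIC.

Three analysis choices to be aware of:

* **Effect sizes.** $\hat\delta_k = \hat\beta_k / \hat\sigma$ is computed
  draw by draw with $\sigma$ the lognormal scale parameter (one could
  argue for other residual-SD transforms; this is the interpretation
  implemented), then summarized as posterior mean, 95% credible interval
  and $P(\delta > 0)$, the fraction of positive draws.
* **Convergence.** `check_convergence()` computes *split* R-hat (each
  chain halved, between/within variance ratio over half-chains) and flags
  anything above 1.01 — "close to one" made operational, stricter than
  eyeballing. Constant parameters are reported as exactly 1.
* **WAIC.** `waic()` computes $-2(\mathrm{lppd} - p_{waic})$ from the
  pointwise log-likelihood matrix (log-mean-exp stabilized);
  `compare_waic()` ranks models fitted to the same observations, lower
  deviance-scale WAIC better.

### Random-effect structure

The fits estimate random *intercepts* for participant, item and sentence.
The maximal structure (by-participant and by-item slopes for length,
dependency and their interaction, with estimated correlations) is
generated by the synthetic-data module, but the estimation model does not
include the slopes: correlated-slope priors of the LKJ type have no JAGS
analogue, and at the package's reduced problem sizes slope variances are
weakly identified anyway. This is a known limitation, not a claim that
intercept-only models suffice for real confirmatory analyses. A grouping
with one level per observation (e.g. sentences in a single-region fit) is
dropped automatically, as it is not identifiable.

### Problem sizes and sampler budgets

Desk-scale defaults are deliberately small and stated here as the
package's own choices: recovery studies use 20 participants × 16 items at
one region with 2 chains × 400 post-warmup iterations (the recovery
claims are majority-over-replicates, robust to short chains); the WAIC
comparison uses all five regions (1600 observations) because a 200 ms
shift is only weakly identified from a single region's 320 observations —
at that size the shifted and unshifted models land within WAIC noise of
each other, while the five-region fit separates them by ~50–100 WAIC
units; simulation sweeps use 5000 trials per cell. The recovery true
effects are set at $|\delta| = 0.15$–$0.3$: large enough that sign and
coverage are meaningful at this scale, unlike the tiny empirical
$\delta$'s of real reading-time studies, which no 320-observation fit
could sign reliably.

## Individual-difference scores

`pcu_score()` implements partial-credit-unit scoring: the mean over
recall sets of the within-set proportion recalled in the correct serial
position (recall is instructed in presentation order; `score_span_set()`
offers a lenient position-free variant as a flag). Equation-verification
accuracy does not gate the score. `ran_fluency()` is the reciprocal of
the mean per-item naming time — per-trial averaging first, then the
reciprocal — in characters per second, higher = more fluent.

## Reproducibility pipeline

`run_pipeline()` chains simulate → generate (+ mixture) → filter → fit →
summarize → identity suite, with per-stage seeds derived from one global
seed (`stage_seed()` hashes the stage name, so stages can be re-run
independently), and writes CSV outputs plus a JSON manifest recording
seeds, sizes and the package version. Simulation and generation stages
are bit-reproducible; MCMC summaries are reproducible given the same JAGS
version and seed. A failing stage aborts with an error naming the stage.

## What passing tests do and do not show

The generator produces data *from the model family being fitted*
(including the mixture injection, whose latencies come from the package's
own simulator). Green recovery and WAIC tests therefore demonstrate
internal correctness — the sampler targets the right posterior, the
algebra is exact, the mixture produces the crossover it should — not that
real self-paced-reading data satisfy the shifted-lognormal or early-abort
assumptions. Real data bring at minimum: non-uniform abort-time
distributions, region-position confounds, comprehension-accuracy
selection, slow drifts over the session, and item-specific lexical
effects, none of which are emulated. The original empirical effect
estimates cannot be reproduced here because the raw reading-time data
were never deposited; all quantitative claims in this package are about
synthetic data whose generating truth is known.

## Numerical notes and degenerate inputs

$\sigma = 0$ yields deterministic noise (exactly zero) and 0/1 failure
probabilities; $\tau = -\infty$ encodes "no threshold" (infinite
time-out, failure probability 0). `base_activation()` rejects $t \le 0$.
The identity suite uses an absolute tolerance of $10^{-12}$; the Helmert
and filter fixtures are exact. Latin-square balance requires item counts
divisible by four; other counts still run but are only approximately
balanced. The RT filter keeps boundary values by design. Mapping
endpoints outside the published exploration ranges warn rather than
error, so sensitivity analyses stay possible.
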