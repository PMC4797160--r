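---
title: "Models and methods for winter PIT-tracking analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for winter PIT-tracking analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterpit)
```

winterpit analyses weekly detection records of PIT-tagged stream fish
over a boreal winter. This vignette documents the models it implements,
the tunable parameters that matter, the numerical choices made, what the
synthetic-data generator does and does not emulate, and the package's
known limitations.

## The ice model

Surface ice on a snow-covered stream grows with accumulated frost. The
package uses the degree-day (Stefan) approach coupled to a snow layer:

$$h_i = \sqrt{\frac{2\,k_{s/i}\,S'}{\rho\,L}},
\qquad
k_{s/i} = \frac{h_i + h_s}{h_i/k_i + h_s/k_s},$$

where $S'$ is the cumulative freezing degree-day sum converted to
degree-seconds (86 400 s/day), $\rho$ the ice density (default
1000 kg m$^{-3}$), $L$ the latent heat of fusion (333 400 J kg$^{-1}$),
and $k_i$, $k_s$ the thermal conductivities of ice and snow. The
effective conductivity $k_{s/i}$ is the series (resistance-sum)
combination of the two layers, so snow — a far poorer conductor —
strongly damps growth. $k_i$ and $k_s$ are not universal constants for
river ice; the defaults (2.24 and 0.2 W m$^{-1}$ K$^{-1}$) are standard
literature values and both are configurable through `ice_physics()`.

Because $k_{s/i}$ depends on $h_i$, the two displayed equations form a
coupled system. `ice_thickness()` solves it self-consistently by
fixed-point iteration started from the bare-ice closed form (an upper
bound); the iteration is a contraction on the physical parameter range
and converges to $10^{-10}$ m within a handful of steps (a 100-iteration
cap guards pathological inputs). With $h_s = 0$ the solution equals the
closed-form Stefan law exactly, which the tests verify to $10^{-10}$ m;
with any snow the thickness is strictly smaller at equal degree-days.

Two conventions are configurable because the field description leaves
them open: degree-days accumulate from the first sub-zero day
(`accumulate_from = "freezeup"`, the default) or from the start of the
series; and after each snow-shoveling occasion the snow depth entering
$k_{s/i}$ is reset to 3 cm until the observed series accumulates again.
Note the per-date solution is a static approximation: when deep snow
returns after a shoveling reset the computed thickness can dip, and the
model contains no spring decay, anchor ice or aufeis dynamics.

## From tracking records to encounter histories

Each fish's weekly record becomes a bit vector: a marking bit (always 1)
followed by one bit per tracking occasion, 1 for a detection anywhere in
the reach. Three rules, applied in this order, prepare the histories for
modelling:

1. **Fate classification** (`classify_fate`). A fish is a *transient* —
   it permanently left the sampled reach, or its signal cannot be told
   apart from a shed or dead tag — if it was never detected after
   release, or if it showed no discernible activity beyond downstream
   displacement *and* was not recaptured in spring. A discernible move
   is a displacement beyond the 0.5-m tracking accuracy; the
   along-stream coordinate increases upstream, so "upstream" is a sign
   test. Lateral activity (carried as a flag on detections, since
   positions are 1-D) qualifies a fish as resident, as does a spring
   recapture. "Linear downstream movement" is operationalised as *all*
   discernible moves pointing downstream; no tortuosity measure is used.
2. **Mortality truncation** (`truncate_mortality`). For fish judged dead
   within the reach, bits after the last occasion with discernible
   upstream movement are zeroed — later detections belong to the
   stationary tag. The judgement ("prolonged cessation of movements",
   confirmed in spring) has no universal duration, so it is supplied by
   the caller as a flag rather than defaulted silently. Truncation is
   applied at weekly resolution, before pooling.
3. **Pooling** (`pool_occasions`). Adjacent weeks are OR-ed pairwise:
   detected in either week codes 1, missed in both codes 0, the marking
   bit is kept. 27 weekly bits become 14 pooled occasions. Pooling
   counters the data sparseness of 26-occasion histories.

Individual covariates (`covariate_table`) summarise biometry and habitat
use: Fulton condition $K = 100\,W/L_{cm}^3$ at tagging, the
representative depth and structural complexity (CV of maximal depths) of
the subreaches a fish used (autumn subreach values, occupancy-weighted),
the mean distance to the closest reach end, and the tag burden
(tag weight / body weight). The weekly mean ice thickness, pooled to the
biweekly occasions, is the temporal covariate.

## The Cormack–Jolly–Seber engine

Apparent survival $\varphi_t$ (interval $t \to t+1$) and detection
probability $p_{t+1}$ are modelled on the logit scale through design
matrices built from a compact model string, e.g.
`"{phi(t x cond)p(g x ice + complex x t)}"`. Within a term, categorical
effects (`g`, `t`) are crossed and coded as full one-hot cell
indicators; a continuous covariate crossed with them contributes one
slope per cell (so `g x ice` is 3 intercepts + 3 group-specific ice
slopes, and `t x cond` over 13 intervals is 26 columns). Overlapping
terms may produce linearly dependent columns; exact dependencies are
removed by pivoted QR before fitting and the remaining (possibly
non-linear) deficiencies are resolved by the estimability analysis
below. This mirrors how design-matrix CMR software lets users specify
over-parameterised structures and reports the estimable count
afterwards.

The likelihood is computed at the individual level — individual
covariates such as condition preclude pooling into sufficient
statistics — conditional on first release:

$$\log L_i = \sum_{t=1}^{l_i-1}\left[\log\varphi_{it} +
y_{i,t+1}\log p_{i,t+1} + (1-y_{i,t+1})\log(1-p_{i,t+1})\right] +
\log\chi_{i,l_i},$$

with $\chi_{i,T}=1$ and
$\chi_{it} = (1-\varphi_{it}) + \varphi_{it}(1-p_{i,t+1})\chi_{i,t+1}$
the probability of never being seen after occasion $t$. Identical rows
can carry frequency weights. The exhaustive conservation property
($\sum_h L(h) = 1$ over all $2^{T-1}$ histories) and the equality with
the m-array product-multinomial likelihood in the absence of individual
covariates are both tested.

**Optimisation.** BFGS with the analytic gradient (the $\chi$-recursion
derivative is propagated by cumulative products), 25 multistarts from
jittered zeros by default, relative tolerance $10^{-8}$, and simulated
annealing as a fallback when no start converges. The winning start is
always polished at reltol $10^{-13}$: the rank-based estimability count
needs the genuinely flat directions of the likelihood to be numerically
flat, and a loosely converged optimum shows spurious curvature there.
Linear predictors are clamped to $\pm 30$ so boundary fits
($\hat p \to 1$) remain finite.

**Estimability.** Standard errors come from the eigendecomposition of
the numerically estimated Hessian, inverted on the subspace of
eigenvalues above $10^{-8}$ of the largest; `count_estimable()` reports
that rank. In fully time-dependent models only the product
$\varphi_{T-1} p_T$ is identified; the classical $2T-3$ rank of the
single-group model is recovered numerically and the fit flags the
terminal confound. For richer structures the reported rank is the
package's own numerical rank — the estimable count of an
over-parameterised model depends on the data and is not forced to match
any external software's bookkeeping.

**Real parameters.** `cjs_reals()` evaluates $\varphi$ and $p$ on a
grid of groups, times and covariate values (defaults: data means) with
delta-method standard errors; after an overdispersion adjustment these
inflate by $\sqrt{\hat c}$.

## Overdispersion and model selection

`median_chat()` estimates the overdispersion factor of a global
group-by-time model (individual covariates are excluded from this step).
Data sets are simulated from the fitted model at a ladder of known
levels $c$; overdispersion is induced by replicating each simulated
individual's latent fate — its entire encounter history — in clusters of
average size $c$ (integer sizes mixed for fractional $c$, totals kept at
the observed group sizes). Each simulated set is refitted (one start,
from the observed solution) and its deviance statistic — m-array
deviance over its degrees of freedom, $df = \sum_{g,i:R_{gi}>0}(T-i) -
K$ — is compared with the observed one. A logistic regression of
$\mathbb{1}(\text{simulated} \ge \text{observed})$ on the level locates
the level at which that probability is one half. Degenerate outcomes
(all simulated statistics on one side) return the range boundary with a
warning. Null calibration (ĉ within [0.9, 1.1] on homogeneous data) and
directional sensitivity (duplicated fates give ĉ well above 1) are both
tested. Note that *individual heterogeneity is overdispersion* with
respect to a group-by-time model: data generated with condition-driven
survival and complexity-driven detection legitimately show ĉ above 1.

Candidate models — a user-supplied list, not an all-subsets search — are
ranked by
$$\mathrm{QAICc} = -2\log L/\hat c + 2K + \frac{2K(K+1)}{n_{\mathrm{eff}}-K-1},$$
with Akaike weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ and
the model likelihood $e^{-\Delta_i/2}$. $K$ is the estimable count and
$n_{\mathrm{eff}}$ defaults to the number of released individuals; the
convention is contested across CMR software, so it is an argument.
`adjust_for_overdispersion()` floors ĉ at 1 (with a warning) and scales
the covariance. The full ranking table is always returned so users apply
their own $\Delta$ cutoff.

The association between maturity state and detection-history class uses
the single-stratum continuity-corrected Mantel–Haenszel chi-square
$(|a - E[a]| - \tfrac12)^2 / \mathrm{Var}(a)$ under the hypergeometric
null (no strata are involved; the installed multi-stratum implementation
rejects single-stratum input, so the three-line formula is computed
directly and cross-checked in the tests), together with the descriptive
risk ratio of transient proportions.

## The synthetic-data generator

`simulate_dataset()` produces a complete study bundle with known ground
truth: three groups (sculpin and juvenile trout with 12-mm/0.1-g tags,
adult trout with 23-mm/0.6-g tags; default sizes 182/50/161), 26 weekly
occasions, a daily winter, and tracking records. Design choices:

* **Winter.** A sinusoidal seasonal temperature (+1.5 °C at the margins,
  −10 °C mid-winter, daily SD 3 °C), frequent light snowfall during
  frost with daily settling (factor 0.99) and temperature-proportional
  melt, and three fixed shoveling days (51, 72, 133 — late December,
  mid-January, mid-March). These values were chosen once so that the
  synthetic ice trajectory matches a snow-insulated boreal stream:
  roughly 30 cm by late January, a 50–65 cm season maximum, snow cover
  persisting through the window.
* **Fish.** Lengths uniform within group tagging bounds (sculpin
  >70 mm, juvenile trout 110–150 mm, adult >150 mm). Fulton condition is
  drawn from a per-group truncated normal (default mean 1.0, SD 0.1 —
  the field description does not state the distribution, so any
  plausible unimodal choice is configurable) and weight is then set
  exactly through the cube law $W = K L_{cm}^3/100$, which makes
  condition recovery tests exact.
* **Dynamics.** Weekly survival is Bernoulli with
  $\mathrm{logit}\,\varphi = 6.0 + 3.0\,(K - 1)$ (≈0.995 biweekly at
  average condition); detection of alive, present fish is Bernoulli with
  group intercepts (1.8, 1.8, 3.4), per-cm ice slopes (−0.10, −0.07,
  −0.033) and a complexity slope (−0.03, centred at 33), spanning
  roughly 0.05–0.85 weekly detection for the small-tag groups and ≥0.8
  for adult trout over a 0–50 cm winter.
* **Transience and tag loss.** Transients emigrate at release
  (per-group fractions 0.20/0.16/0.32) and are never detected again
  inside the reach — emigration, not elevated first-interval mortality,
  matching the exclusion of transients before fitting. Among adult
  trout the transient probability of spawning fish is 2.1 times that of
  spent fish (group mean preserved). Tags shed in week 1 (5% of adults)
  produce no further detections. Residents move between detections with
  upstream drift and occasional lateral flags; dead fish are not
  detected after death (a hard generator invariant).

What the generator does **not** emulate: 2-D home ranges, antenna
read-range physics, detections of stationary shed or dead tags (so the
"only-downstream-movement" transient clause is exercised by chance
patterns rather than by simulated dead tags), ice decay and breakup, and
within-winter changes in condition. Passing tests therefore demonstrate
the correctness of the estimation machinery under the stated generating
model, not robustness to every failure mode of real field data.

## Problem sizes used by the tests

The test suite exercises the engine at the study's scale where that
matters and smaller where it does not: exhaustive likelihood
conservation up to 6 occasions; parameter recovery and interval coverage
on 100 replicates of 400 released fish over 14 pooled occasions;
model-selection behaviour on 20 such replicates; median-ĉ calibration on
three seeds with 100 replicates per level at full study size; and the
ice fixed point over a parameter grid ($k_s \in [0.05, 0.5]$,
$h_s \in [0, 1]$ m, $S \in [0, 3000]$ °C·day).

## Known limitations

* Apparent survival confounds mortality with permanent emigration; the
  package inherits this CJS property.
* The ice model is a static per-date approximation with no decay term;
  late-season thickness is overestimated once snow melts.
* Wald intervals on the logit scale degrade near boundaries
  ($\hat\varphi \to 1$); profile likelihood is not implemented.
* The median-ĉ SE from the logistic regression is wide at moderate
  replicate counts; treat it as indicative.
* `fish_covariates` uses autumn subreach descriptors, not per-occasion
  depths.
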