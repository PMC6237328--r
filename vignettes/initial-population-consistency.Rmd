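---
title: "Constructing and validating synthetic initial populations for chronic-disease micro-simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating synthetic initial populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

Chronic-disease micro-simulation models follow individuals characterised by
sex, age, a categorical risk-factor state and a vector of disease states.
Starting such a model requires an initial population with the right *joint*
distribution of all of these, but the available inputs are almost always
*marginal*: age/sex-specific risk-factor prevalence, disease prevalence,
incidence, excess mortality, and relative risks. `chronicsim` implements

1. the approximate construction of the joint distribution from marginals
   under the assumption that prevalence odds ratios (PORs) equal incidence
   rate ratios (RRs),
2. a partial micro-simulation engine consistent with that construction, and
3. a validation protocol: simulate disease-free newborns to demographic
   equilibrium under stationary risk-factor prevalence and measure how far
   the constructed population deviates from the equilibrium one.

All computations are stratified by sex (two mandatory levels) and integer
age on `0..a_max` (default 95), with all rates piecewise-constant over
one-year age intervals `[a, a + 1)`. The first risk-factor state listed is
the reference state; all RR tables are expressed relative to it.

## The construction

For each (sex, age) and each *independent* disease (one with no causal
parent), the baseline odds $b_i$ — the odds of prevalent disease in the
reference stratum — solve the strictly monotone equation

$$\Pr(d_i = 1) \;=\; \sum_r w_r\,\frac{RR_{r \to i}\, b_i}{RR_{r \to i}\, b_i + 1},$$

after which $\Pr(d_i = 1 \mid r) = RR_{r\to i} b_i/(RR_{r\to i} b_i + 1)$:
by construction the POR of every stratum against the reference equals the
input RR exactly. Within a risk state, independent diseases are combined by
conditional independence — the construction has no other coupling channel.
Dependent diseases (at most one causal layer is allowed; the validator
rejects deeper graphs) are handled by re-running the same solve on composite
strata $r^{*} = (r \times \text{causal-disease states})$, weighting by the
stage-one joint masses, with stratum RR equal to
$RR_{r \to i}\prod_j RR_{c_j \to i}$ over the causal diseases present — the
same product form the incidence hazard uses, so construction and dynamics
stay consistent. Diseases with a cured fraction have their prevalent mass
split proportionally into not-cured and cured by the age-specific cured
fraction; the inputs do not identify the diagnosis age of prevalent cases,
so the split uses the current-age fraction (the minimal assumption; see
Limitations).

**Numerics.** The baseline-odds solver brackets the root in $[0, \infty)$
(doubling from $p/(1-p)$) and polishes with Newton steps that fall back to
bisection whenever they leave the bracket, stopping at a residual of
$10^{-12}$; monotonicity of the left-hand side makes convergence
unconditional. Degenerate inputs are handled explicitly: $p = 0$ yields
$b = 0$; $p \ge 1$ and targets exceeding the attainable mass
$\sum_{w_r RR_r > 0} w_r$ are errors naming the disease and (sex, age) cell.

Sampling a discrete population from the joint distribution assigns
`floor(n * mass)` individuals per risk state first (quota), draws the
remainder from the residual distribution, and then draws disease states from
the conditional distribution given the assigned risk state.

## Net transitions

Stationary exposure is enforced by per-age transition matrices over the
*ordered* risk states. The signed net flow across adjacent boundary $k$
between ages $a$ and $a+1$ is $F_k(a) - F_k(a+1)$ with $F_k$ the cumulative
prevalence of states $1..k$; positive flow moves mass $k \to k+1$, negative
$k+1 \to k$. This minimal-flow solution of the balance equations makes
$\text{prev}(a)\,T(a) = \text{prev}(a+1)$ exact (residual at machine
precision) and uses only adjacent, single-direction flows per boundary. Two
consequences are deliberate:

* a never-smoker share that *rises* with age (the generational pattern of
  women in many Western populations) can only be kept stationary by flows
  from current back to never — demographically impossible transitions whose
  downstream footprint on within-disease distributions and comorbidity
  ratios is precisely one of the artifacts the validation is designed to
  expose; and
* no mortality adjustment is applied when estimating the transitions, so
  with risk-dependent mortality the among-the-living risk distribution may
  drift from the schedule at high ages. The drift is part of the behaviour
  under study and is not corrected.

The matrix at the top age is the identity (no older target exists).

## The engine

The hazard model is: incidence
$I_i(r, C) = I_{0,i}\,RR_{r\to i}\prod_j RR_{c_j\to i}$ over the causal
diseases present; mortality equal to baseline other-cause mortality
(optionally, and by default not, multiplied by a risk-state RR) plus the sum
of the attributable mortalities of the diseases present — cured copies
contribute zero — plus, for each acutely-fatal disease *not yet* present,
the acute-fatality hazard $M_{0,CF_i}\,RR_{r\to i}\prod_j RR_{c_j\to i}$.
The acute hazard models instantly fatal incident cases, hence the
restriction to the still-disease-free; applying it to prevalent cases would
double-count their excess mortality, which the attributable-mortality term
already carries. The baseline incidence $I_{0,i}$ is calibrated per
(sex, age) against the joint-distribution mass renormalised among those
without disease $i$, so the first simulated year reproduces the input
population incidence to $10^{-10}$.

**Within-year evolution** is the exact exponential (`Matrix::expm`) of the
piecewise-constant competing-risk generator over the joint states of each
*cluster* — a connected component of the causal graph — plus an absorbing
dead state, with the risk state frozen at its start-of-year value. Because
hazards are additive across clusters and each disease's rates depend only on
states within its own cluster (and $r$), the full-population exponential
factorises exactly into per-cluster kernels times a scalar other-cause
survival factor, counted exactly once; the test suite checks the factorised
engine against a dense full-joint exponential to $10^{-10}$. Using the exact
exponential rather than a first-order yearly probability update removes any
step-size ambiguity: the stochastic cohort and the deterministic recursion
then agree up to Monte-Carlo error only.

Two cohort engines share the same precomputed kernels:

* `simulate_newborn_cohort()` — the partial micro-simulation: stochastic
  risk biographies per individual, disease/survival carried as exact
  probabilities conditional on the biography; alive-weighted aggregation
  with between-individual standard errors;
* `forward_expectation()` — the deterministic twin, evolving the full joint
  (risk state × all-cluster states) distribution; exact because all hazards
  are functions of the current (r, D) state. It serves as the oracle for the
  Monte-Carlo engine and as a noise-free equilibrium in deterministic
  comparisons.

## Validation metrics

Within-disease risk-factor distributions
($\Pr(r \mid d_i, \text{sex}, \text{age})$), comorbidity ratios
$P_{AB}/(P_A P_B)$ per (sex, age) pair, difference tables at report ages
(default 50, 65, 75, 85) in percent points, and replicate summaries with
normal-approximation CIs of the mean over Monte-Carlo replicates (default
protocol 100 replicates, 95% level; replicate $k$'s seed is element $k$ of
`sample.int(2^31 - 2)` under the master seed, so single replicates are
reproducible). Cells with zero prevalence are reported as missing, never as
zero — at young ages no simulated disease has meaningful prevalence and a
zero would silently bias summaries. The initial side of every comparison is
the exact joint distribution rather than a sampled population, so all
Monte-Carlo error is attributable to the newborn cohorts. An
independence-baseline joint (plain product of marginals) provides the
comparator construction.

## The synthetic scenario generator

No external data ship with the package; `synthetic_scenario()` builds
self-contained scenarios whose defaults are chosen once to emulate the
settings in which this construction is used and stressed:

* `smoking_like` — three ordered states (never/current/former) with
  adolescent uptake and a strong generational pattern (the female
  never-share rises with adult age); eight diseases: a diabetes-like chronic
  disease unaffected by smoking but causal (RR ≈ 2–3.5, mildly declining
  with age) for two acutely-fatal cardiovascular diseases and heart failure;
  COPD-like and three cancer-like diseases (cured-fraction kind) with
  rising-then-falling RR age-shapes peaking near age 60 (maxima ≈ 7–14);
  cardiovascular RRs decline with age from ≈ 2.4–3.2 toward 1.2. Incidence
  curves are logistic-in-age with plateaus between 5·10⁻⁴ (larynx-like) and
  1.2·10⁻² (CHD-like) per person-year, zero below age 20; attributable
  mortality 0.008–0.25 per person-year by disease; other-cause mortality is
  Gompertz (≈ 2·10⁻⁵·e^{0.088·age}). Disease inputs are capped at age 87,
  the conventional sparse-data treatment at high ages.
* `bmi_like` — three states whose composition shifts with age toward
  overweight/obesity (physiological aging rather than generation), diabetes
  with a high declining RR of obesity, the same causal cardiovascular block,
  and several modest-RR cancers, including sex-specific ones (prevalence
  identically zero for the other sex, exercising the undefined-cell paths).
* `pearce_ideal` — the steady-state limit: age-constant RRs and exposure, no
  excess mortality, cumulative incidence ≤ 2% (rare disease). Under these
  conditions the POR equals the RR, so the construction and the newborn
  equilibrium must agree; the acceptance suite requires agreement within 1
  percentage point, using the deterministic equilibrium so the bound is not
  blurred by Monte-Carlo noise.
* `causal_pair` / `independent_pair` — two-disease probes for the
  comorbidity metrics, with and without a causal link; the independent pair
  gives both diseases RR 1 on the risk factor, which makes the equilibrium
  comorbidity ratio exactly 1 and — since disease states are carried as
  probabilities — makes the Monte-Carlo cohort reproduce the deterministic
  recursion to float precision.

Scenario parameters are mildly jittered by a private Lehmer stream keyed on
the seed (never touching the session RNG), so property tests can sweep many
valid scenarios reproducibly. Prevalence inputs are derived from the
incidence/excess-mortality curves by a crude alive-mass recursion: broadly
consistent with the dynamics, though not the exact simulation equilibrium —
matching the real situation in which observed prevalence and modelled rates
come from different sources.

What the generator does *not* emulate: calendar-time trends, migration,
historically accurate generation-specific exposure, survey noise, or
real-registry rate levels. Passing tests therefore demonstrate internal
consistency of construction and simulation under plausible rate structures,
not agreement with any real population.

## Problem sizes

The default test and acceptance runs use `a_max = 95`, 2000 individuals per
sex for risk-factor comparisons and 500 for comorbidity-focused runs, with
replicate counts of 3–8 in the pipeline tests; the full smoking-like
scenario tracks a joint state space of 3 × 864 alive states in the
deterministic recursion. A full 100-replicate validation of the
smoking-like scenario is a few minutes of single-core time.

## Known limitations

* The cured/not-cured split of *prevalent* cases uses the current-age cured
  fraction, as the marginal inputs cannot identify diagnosis age.
* The causal-pair overestimation is a property of the construction itself
  (the causal RR is applied to all co-occurrences, although in the dynamics
  it only operates when the causal disease comes first). A corrected
  construction replacing the causal RR by a weighted average of the RR and 1
  — weighted by the two diseases' incidence — is a documented extension
  point, not implemented.
* Net transitions are the minimal-flow stationary schedule, not an estimate
  of real initiation/cessation behaviour.
* Comorbidity ratios are compared descriptively (differences with CIs); no
  formal equality tests are provided.
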