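---
title: "Models and methods: growth trajectories and sexual size dimorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: growth trajectories and sexual size dimorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvagrowth)
```

## The scientific question

In most insects, females are the larger sex. For a species with a fixed
number of larval instars, that dimorphism must arise from some combination of
(i) a longer growth period, (ii) a genuinely faster growth rate, and (iii)
other features of the non-linear larval growth curve such as pre-pupal mass
loss. Separating (i) from (ii) is harder than it sounds, because the common
growth-rate summaries are size-dependent: if females are already bigger, a
size-dependent index will mislabel size as "rate". This package implements a
trajectory-level analysis that makes the separation cleanly, together with a
calibrated stochastic simulator so that every stage of the pipeline is
testable without access to any raw rearing data.

## Growth model and the three rate indices

During the "free growth" phase of an instar (after the gut has been refilled
following the moult, and before preparations for the next moult begin),
lepidopteran larval growth is well described by a cubic curve: the cube root
of body mass grows linearly in time. Writing $c = m^{1/3}$,

$$ m(t) = (c_0 + g\,t)^3, $$

where $g$ (mg$^{1/3}$ day$^{-1}$) is the *allometric differential growth
rate*. From the masses bounding a 24 h interval the package computes three
day-specific indices:

* absolute: $m_{d} - m_{d-1}$ (mg/day) — grows with larval size;
* relative: $\log_{10}(m_d / m_{d-1})$ (1/day) — falls with larval size,
  because under cubic growth a fixed absolute gain in $c$ is a shrinking
  proportional gain in $m$;
* allometric: $m_d^{1/3} - m_{d-1}^{1/3}$ — exactly constant on a cubic
  trajectory, hence size-independent.

The size-independence of the allometric index is what licenses a sex
comparison unconfounded by the sexes' different average sizes; the package's
`size_dependence()` regressions verify it (exactly, on noise-free cubic
trajectories; statistically, on simulated data).

Day convention: day 0 is the intermolt-stasis mass (the instar's initial
mass); the increment of day $d$ is $m_d - m_{d-1}$. The analysis window
defaults to days 2–5: day 1 is excluded because its gain is dominated by gut
filling, and later days because growth tapers towards the pre-pupal peak. The
covariate attached to the day-$d$ rate for size regressions is $m_{d-2}$,
the mass recorded one day *before* the 24 h interval, so the regression's two
variables share no measurement.

## The synthetic-data generator

`simulate_population()` generates last-instar trajectories with the
statistical structure the analysis assumes:

1. development time to the last instar and the day-0 mass are drawn from
   sex-specific normals (the latter on the cube-root scale, so downstream
   transformations are exact);
2. day 1 adds $g \cdot \text{gutfill}$ with gutfill factor 1.5 — gut filling
   roughly half again the somatic gain;
3. free-growth days add $g_i + \varepsilon_d$, where the individual rate
   $g_i$ = sex mean + host shift + brood effect + individual effect, and
   $\varepsilon_d$ is day-level noise;
4. from the taper-start day the expected increment decays linearly to zero
   just past the individual's drawn peak day;
5. after the peak, mass declines geometrically to the final feeding-day mass
   (peak mass divided by the sex's maximal/final ratio), emulating the
   wandering-stage loss; pupal mass is the recorded maximum divided by the
   sex's maximal/pupal ratio, with 3% multiplicative noise.

### Calibration of the defaults

The default parameter set *is* the study condition the package emulates:
109 broods, 12 larvae per brood on the primary host plant and 3 on the
secondary, sexes drawn independently at ratio 0.5; sex means 18.17/17.58 d
(time to the last instar), 29.18/25.30 mg (initial mass), 0.279/0.270
mg$^{1/3}$/day (allometric rate), peak day 9.75/8.67, instar duration
11.46/10.10 d, maximal/final mass ratio 1.39/1.37, and maximal/pupal ratios
120.24/73.57 and 98.91/63.28 (female/male throughout).

Quantities the observed study does not report were fixed once, as follows.

* Dispersions of development time, initial mass, peak day and duration were
  back-calculated from published standard errors times $\sqrt{n}$ at
  $n \approx 690$ per sex (e.g. initial-mass cube-root sd 0.125
  mg$^{1/3}$).
* Variance components of the rate are not published. The day-level sd
  (0.095) sits between the value implied by the published per-day increment
  SEs (~0.117) and the value implied by the published allometric sex F
  statistic (~0.09); individual (0.02) and brood (0.015) sds split the
  remaining between-larva scatter. This calibration is approximate by
  necessity, and the package treats every re-derived population statistic as
  stochastic, never exact.
* The taper's starting factor is not identifiable from printed values with a
  linear-decay shape anchored at 1 (that shape overshoots the published mean
  maximal masses by ~25%), so the decay starts from a calibrated factor
  (0.385 female, 0.298 male), fixed once by simulation so the mean simulated
  maximal masses match the observed 120.24/98.91 mg. The taper's functional
  form is a modelling choice; nothing downstream depends on it except
  through the descriptors it was calibrated to.
* The host-plant effect on the rate defaults to 0 mg$^{1/3}$/day: the study
  detected a host effect but never printed its magnitude, and a nonzero
  default would bias the pooled mean rate away from the published
  sex-specific values that calibration targets.

Reproducibility is structural: one L'Ecuyer-CMRG stream per brood, one
substream per individual, all derived from a single seed. Two consequences
are tested: the same seed gives bit-identical populations, and enlarging a
design (more broods, or more larvae appended to a brood) leaves previously
generated individuals untouched.

### What the generator deliberately does not emulate

* Real trajectories' day-to-day autocorrelation beyond the individual rate
  intercept (weather-free lab rearing justifies little more).
* Measurement error proportional to mass (gut content fluctuation). In real
  data this inflates relative-rate residual variance roughly threefold over
  what cube-root-scale noise implies; simulated relative-rate sex tests are
  therefore somewhat *more* powerful than the study's own, and a simulated
  study occasionally flags the small male-ward relative-rate difference that
  the observed analysis reported as null.
* Realized size-rate covariance at day 3: because individual rates persist,
  the day-3 covariate mass already contains the individual's rate, which
  cancels the relative index's negative size slope at day 3 in simulations.
  Day 2 — whose covariate is the day-0 mass — is the clean test of the
  size-dependence contrast, and the tests use it.
* Mortality: an optional `dropout_rate` flags larvae as censored but does
  not truncate records; the instar-level mortality observed was ~1.4%.
* The consistency constraint that the peak precedes the end of feeding
  right-shifts simulated instar durations by roughly half a day relative to
  their nominal means; the sex ordering of durations is unaffected.

## The mixed ANOVAs

Descriptor tests (`feature_anova()`) use a mixed linear model with fixed sex
and host plant and a random brood intercept — brood-mates are sibs, not
independent replicates. Rate tests (`repeated_anova()`) treat the day 2–5
rates as repeated measures: fixed sex, day (a centred numeric covariate),
host, sex:day and sex:host; random intercepts for brood and for individual
larva. A flat sex:day interaction is the built-in diagnostic that the window
really is free growth: growth tapering earlier in one sex would surface
there.

Three deliberate methodological choices:

* **Denominator df from larvae, not measurements.** Between-subject terms
  get $n_\text{larvae} - p_\text{between}$ and within-subject terms
  $n_\text{obs} - n_\text{larvae} - p_\text{within}$ (containment-style).
  With 1275 larvae measured on 4 days this yields ddf 1271 for sex and 3823
  for day. Satterthwaite/Kenward-Roger approximations are intentionally not
  used.
* **Estimation.** Variance components by REML (`lme4`); marginal (Type III)
  Wald F tests on the fixed effects with sum-to-zero contrasts. On balanced
  designs with zero realized variance components these reduce exactly to the
  classical fixed-effects F statistics, which the test suite checks against
  an independent sums-of-squares oracle to machine precision. On REML
  non-convergence the fit falls back to method-of-moments variance
  components followed by exact GLS, flagged in the result's `method`
  attribute.
* **Effect sizes.** The per-factor $R^2$ is the factor's Type III
  sum-of-squares share of the total sum of squares, computed from an OLS
  companion fit. It is a transparent approximation to mixed-model $R^2$
  partitions, declared as such rather than claimed equivalent to any
  particular published formulation.

No multiple-testing correction is applied across descriptor responses,
matching the analysis style the package reproduces.

## Decomposing SSD into rate versus duration

Under the cubic model the two candidate sources of dimorphism can be
compared directly. From a common starting mass $m_0$:

$$ \text{rate contribution} =
   \frac{(m_0^{1/3} + g_F d)^3}{(m_0^{1/3} + g_M d)^3}, \qquad
   \text{duration contribution} =
   \frac{(m_0^{1/3} + g (d + e))^3}{(m_0^{1/3} + g d)^3}. $$

With the calibrated inputs ($m_0 = 25.30$ mg, $g_F = 0.279$, $g_M = 0.270$,
$d = 5$, $e = 1$):

```{r}
decompose_ssd()
```

A 3% rate advantage sustained for five days produces a 1.03-fold mass
difference; a single extra day of growth produces ~1.20-fold. The common
$m_0$ (the male mean initial mass) isolates the rate effect; the exact
extra-day ratio depends mildly on the inputs chosen (plausible choices span
roughly 1.20–1.25), so the calculator exposes them instead of hard-coding a
headline number.

## Numerical and design notes

* Ties for the maximal mass resolve to the earliest day; day 0 (the initial
  mass) participates, since the maximum is over all recorded masses.
* "Final mass" is the last feeding-day larval mass, distinct from pupal
  mass: the maximal/final ratio (~1.38) and the maximal/pupal ratio (~1.6)
  are different quantities.
* Missing daily masses are preserved as explicit `NA` through IO and
  feature extraction; a day's rate record exists only when both bounding
  masses exist, and the day-4 and day-5 records both vanish when the day-4
  mass is missing.
* The relative rate uses $\log_{10}$; natural log is available behind an
  argument but is never the default.
* Trajectory generation rejects and redraws non-finite or non-positive
  draws with a hard cap of 100 attempts, then errors naming the parameters
  as degenerate.
* Ratio descriptors are means of per-individual ratios (each carries an SE),
  not ratios of means.

## Problem sizes used by the tests

The test suite judges stochastic claims at the default design size (1635
larvae) with a priori fixed seeds: parameter recovery within 3 Monte-Carlo
SEs; the qualitative repeated-measures pattern (allometric sex difference
present, sex:day flat, relative sex difference absent) by majority over five
replicate simulated studies, since any single simulated study is one
stochastic draw; and the null size of the sex test over 500 simulated null
data sets of 180 larvae in 30 broods, which must stay within binomial error
of the nominal 5%.
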