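---
title: "Methods: behavioral individuality statistics and the bet-hedging life-history model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral individuality statistics and the bet-hedging life-history model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Individual fruit flies reared and assayed under near-identical conditions
differ strikingly and persistently in where they rest on a light/shade
gradient and on an 18-30 C thermal gradient.  `flybet` implements two
linked analyses of that observation:

1. **Is the variability real?**  Statistics that compare the observed
   distribution of per-fly preference scores to the distribution expected
   if all flies shared one choice probability, partition trait variance
   into individual versus sampling components, and ask whether individual
   preference is heritable across a parent-offspring cross.
2. **Could the variability be adaptive?**  A temperature-dependent
   life-history model in which a fly's *thermal preference index*
   `p` in [0, 1] sets how much of the sun/shade temperature difference it
   captures each day.  Two inheritance rules are raced against each other
   on the same seasonal weather: *bet-hedging* (BH; every birth redraws
   `p` from a fixed distribution) and *adaptive tracking* (AT; progeny
   inherit the mother's `p` exactly, so the population mean can evolve
   within a season).

# Behavioral statistics

## The binomial null and overdispersion

With `n` trials per fly and a common light-choice probability, per-fly
light counts are binomial.  `overdispersion_test()` compares the observed
counts to that null three ways: a one-sample KS statistic against the
binomial CDF, a chi-square test of the variance of per-fly fractions
against the binomial sampling variance, and a bootstrap test on the
between-fly variance.  Counts are discrete, so the asymptotic KS
distribution would be anti-conservative; the KS and bootstrap p-values are
instead computed by parametric-bootstrap Monte Carlo in which each null
dataset re-estimates the pooled probability, making observed and simulated
statistics exchangeable under the null.  The test suite verifies both the
size of all three tests (type-I error within a factor of two of nominal
over 2,000 null simulations) and their power at the studied design (219
flies, 24 trials, per-fly probabilities Beta-distributed with mean 0.32
and SD 0.13: rejection at alpha = 0.001 in more than 95% of experiments).

## Variance partitions

For binary data the observed variance of per-fly fractions is the sum of
true between-fly variance and binomial noise;
`variance_partition_binary()` subtracts the unbiased within-fly sampling
variance `mean(p_i (1 - p_i) / (n_i - 1))` and truncates at zero.  For
gradient positions, `variance_partition_continuous()` uses a one-way
fixed-effects ANOVA on fly identity and the mean-squares method with the
unbalanced-design correction `n0`.  Confidence intervals are percentile
bootstrap over flies (not trials), 1,000 draws by default.  Bootstrap
percentile intervals on variance components at 41 flies are only
approximately calibrated; the acceptance checks therefore require coverage
in most, not all, replicate designs.

## Heritability

`heritability_fisher()` implements the selection estimator `h2 = R / S`:
parents are drawn from the extreme quantiles of a scored population, `S`
is the midparent deviation from the population mean and `R` the
progeny-mean deviation.  Rather than averaging the shade-arm and
light-arm ratios -- unstable when one arm's `S` is small -- both arms
enter a single regression of brood means on midparent scores through the
population mean.  The synthetic cross generator defines the phenotype as
the *measured* score and inherits from measured midparents, so the
estimator is consistent for the generating `h2`; the suite recovers
`h2 = 0, 0.5, 1`.

## Sequential dependence

`sequential_mutual_information()` reports the mean plug-in mutual
information (bits, `0 log 0 = 0`) between successive choices.  Plug-in MI
is biased upward in short sequences (about 0.03 bits for 24 i.i.d.
trials), so a jackknife bias estimate is reported alongside rather than
silently subtracted.

# The life-history model

## Ingredients

* **Life curves.**  Egg-to-adult development time `M(T)` (minimum at
  25 C) and lifespan `A(T)` (strictly decreasing), packaged as
  constant-temperature tables under `inst/extdata/` and interpolated with
  monotone piecewise cubics.  The development curve is interpolated as two
  monotone pieces glued at the minimum knot so the interior optimum sits
  exactly at 25 C.  The tables are synthetic digitizations constructed
  from classic published laboratory values and constrained by the shape
  requirements above (see the file headers); `A(T) > M(T)` throughout the
  12-32 C domain so the overwintered seed-age interval `[M(T), A(T)]` is
  never empty.
* **Thermal experience.**  On day `j` a fly with preference `p`
  experiences `T_j + p * shadeDiff * (1 - cloud_j)` with `shadeDiff = 7` C,
  the measured clear-sky sun/shade difference.  Cloud cover enters as the
  clear-sky fraction `(1 - cloud)`: clouds shrink the temperature range
  behavior can exploit.
* **Rate summation.**  Development and senescence accumulate daily as
  `1/M(T_exp)` and `1/A(T_exp)`; eclosion at cumulative development 1,
  thermal death at cumulative senescence 1, counted from the egg so death
  occurs near age `A(T)` under constant conditions.  Rate summation is the
  standard way to extend constant-temperature curves to varying
  temperatures; it is exact at constant temperature and brackets the
  outcome between the constant-temperature extremes otherwise.
* **Demography.**  Adults lay one egg with daily probability `beta`
  (Bernoulli by default; a Poisson option exists); all flies die randomly
  with daily probability `delta`.  An egg develops entirely in sun or in
  shade, chosen once at laying with probability equal to the mother's
  preference (a flag switches to development at the progeny's own
  preference, which gives qualitatively identical results).  The within-day
  order -- random death, then accumulation/eclosion/thermal death, then
  reproduction, newborns starting to develop the next day -- is fixed and
  shared by both implementations.

## Two implementations, one expectation

`run_season()` simulates individual flies (stochastic, seeded with 100
overwintered adults whose ages are uniform on `[M(T1), A(T1)]`).
`run_season_det()` propagates real-valued cohort densities keyed by
(preference bin, birth day, developmental site); all members of such a
cohort share one temperature path, so the only discretization is the
preference grid itself (101 bins by default; end-of-season outputs move by
less than 0.1% between 101 and 201 bins).  Because the dynamics are
density-independent, the agent model's expectation equals the
difference-equation model exactly on a matched grid; the suite checks the
replicate-averaged agent trajectory against the deterministic one within
three Monte-Carlo standard errors, which is the operative correctness
standard linking the two.

## Weather

`synthetic_normals()` supplies a Boston-like baseline: a 214-day season
(April 1 - October 31) rising along a quarter sinusoid from 7 C to a
23.5 C peak near day 115 and back.  Daily deviations from normal are
modeled with an order-30 autoregression of Gaussian white noise
(`fit_ar()`, Yule-Walker, innovation SD stored as the implied extra
parameter; the packaged synthetic history is AR(1)-like with daily SD
3.3 C).  Random cloud series are *surrogates* of a historical record:
values are drawn from its empirical distribution and rearranged by a
constrained pair-swap anneal until the new series is decorrelated from the
original (|r| < 0.1) while its autocorrelation function still matches the
historical one (r > 0.998).  The ACF match is treated as the hard
constraint and decorrelation as the objective; the annealer is initialized
from a rank-remapped Gaussian AR surrogate and returns an explicit failure
flag if the budget is exhausted.  Deviation and cloud streams are
generated independently, mirroring their negligible correlation in
historical data.  Real station records can be used anywhere via
`read_weather()`; the package ships only synthetic stand-ins so that
nothing requires a download.

## Calibration

`beta` and `delta` are unknown in the wild.  `fit_birth_death()` fixes
them by two equilibrium assumptions evaluated under the AT
difference-equation model: the season neither grows nor shrinks the
population (`|fitness ratio - 1| <= 0.01`) and the mean preference does
not evolve (`|drift| <= 0.005`).  Those tolerances are chosen an order of
magnitude below the ~1-2% BH-vs-AT effects being measured.  The solver
exploits that log seasonal fitness is strictly increasing in `beta`: an
inner root find yields `beta(delta)`, and the preference drift is scanned
and root-found along that curve (a Nelder-Mead alternative is provided).
On the packaged Boston-like normals the fit lands at `beta ~ 0.10`/day and
`delta ~ 0.043`/day, inside the plausible ranges for wild flies.
Calibration uses a 31-bin grid; the fitted point moves by less than the
tolerances under refinement.

# Experiment suite

`compare_strategies()` races BH against AT on one season (always paired on
the same weather).  On the calibrated Boston-like baseline BH wins by
about +1.7% of final population; under constant 17.5 C weather (calibrated
for that season) the difference is within +/-0.2%, the expected signature
that the advantage comes from seasonal fluctuation, not from variability
per se.  `ensemble_random_seasons()` summarizes many random seasons
(fraction of BH wins, quadratic fits of advantage against season mean and
SD of temperature); `multi_season_accumulation()` compounds per-season
fitness quotients multiplicatively (populations reset each season --
overwintering is outside the model); `climate_offset_sweep()` warms the
season and interpolates the offset at which AT overtakes BH (about +1.4 C
here, with `(beta, delta)` held at baseline by default to represent a
sudden change; a flag recalibrates per offset); `season_length_sweep()`
compresses or stretches histories into 107-365-day seasons;
`variance_sweep()` rescales the preference SD at fixed mean;
`plasticity_sweep()` overlays a behavioral plasticity rule in which adults
close a fraction lambda of the gap to a 25 C target within the attainable
sun/shade band (the BH advantage persists at moderate lambda and vanishes
as plasticity dominates).

# Numerical and design choices

* Preference-distribution moments: mean 0.32, SD 0.13 (the fitted
  phototactic distribution) converted to beta shapes by method of moments
  (alpha ~ 3.80, beta ~ 8.08); SDs at or above `sqrt(m(1 - m))` are
  rejected as infeasible.
* Within-fly gradient noise is clipped at the 18/30 C arena walls rather
  than resampled; for extreme per-fly means this biases scores toward the
  interior, which is what a walled arena does to a real fly.
* The thermotaxis generator's within-fly SD (3.37 C) is derived from the
  observed 14.7% between-fly variance fraction read as an intraclass
  correlation on raw trials, since no within-fly trial SD is reported.
* Binary immobility: repeated identical choices are legitimate behavior,
  so immobility in choice data travels as an explicit indicator set by the
  generator's injection flag; for positions, exactly repeated values are
  themselves the no-movement signature and are detected directly.
* KS p-values on counts are Monte Carlo, never asymptotic; all bootstrap
  CIs are percentile over flies; ties in the two-sample KS use the
  asymptotic statistic.
* Seeds are explicit everywhere; ensemble functions derive per-season
  streams from one root seed, so every figure-level result is bit-for-bit
  reproducible from `(seed, n)`.

# Problem sizes used by the checks

The test suite runs the statistical calibrations at the study's design
sizes (2,000 null datasets for test size; 100 datasets for power; 10
replicate designs for estimator recovery), the model-identity checks on a
matched 60-day, 7-bin configuration with 200 agent replicates, and the
seasonal-dynamics checks on the full 214-day season with a 31-bin grid.
These sizes were chosen so each property is measured with comfortable
Monte-Carlo margin.

# Known limitations

* The synthetic generators emulate the *statistical structure* the
  estimators assume (beta-distributed choice probabilities, Gaussian
  fly effects, independent trials, independent missingness).  Passing
  tests show the estimators recover truth under that structure; they
  cannot show that real assay data satisfy it.
* The packaged life-curve tables and weather records are synthetic
  stand-ins; quantitative headline numbers (e.g. the exact advantage
  percentages) depend on real station normals and archived assay data and
  are expected to differ.  Under this package's study conditions the
  variance sweep shows performance decreasing monotonically in preference
  SD on the deviation-free baseline season rather than an interior
  optimum; probing that prediction properly requires fluctuating
  historical weather.
* The model is asexual, density-independent, and has no overwinter
  dynamics, humidity, photoperiod, or within-day temperature cycles.
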