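---
title: "Temporal species-area relationships in closed microcosms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal species-area relationships in closed microcosms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsar)
```

## The system and its assumptions

A closed microcosm study seals replicate flasks of a well-mixed microbial
suspension across a volumetric gradient and samples them destructively over
time. Because the flasks are hermetic, the community dynamics are governed
by local extinction alone: no dispersal, and no speciation on the time
scale of weeks. The species pool — the taxon set of the shared starting
material — is therefore the fixed reference against which all later loss is
scored.

Three measurement definitions drive everything downstream:

* **Richness** of a sample is the number of ASVs detected (count > 0),
  bacteria and fungi counted together.
* **Extinction rate** of a sample is the fraction of pool ASVs it fails to
  detect. True extinction and non-detection are indistinguishable in
  amplicon data; this is a measurement definition, not a claim about latent
  state, and the simulator lets us quantify the gap (observed rate is an
  upper bound on true loss; see `extinction_records()` and the
  detection-loss test in `test-simcosm.R`).
* **Annihilation** is the state of a microcosm in which nothing is detected
  at all; the annihilation rate at a day is the fraction of microcosms
  annihilated.

## The per-time-point SAR model

At each sampled day we fit the semi-logarithmic SAR, `S = c + b*log10(A)`,
by ordinary least squares with a two-sided t-test on the slope, and
classify the day `positive`, `negative`, or `none` at alpha = 0.05.
Choices worth stating:

* **Log base 10.** The base only rescales the slope; classification,
  p-value and R-squared are base-invariant (property-tested). Base 10 makes
  the slope read as "ASVs per decade of volume".
* **No multiple-testing correction by default.** Each day is reported as
  its own panel, as is conventional for per-time-point significance maps; a
  Benjamini-Hochberg option exists (`adjust_p = "BH"`).
* **All replicates, not volume means.** The default fits all 21 flasks
  (7 volumes x 3 replicates); `aggregate = TRUE` fits the 7 volume means
  instead. Replicate-level fitting uses the real error structure.
* **Annihilated flasks count as richness 0.** A flask in which everything
  died is a genuine observation of the community, not missing data, so it
  enters the fit by default; `drop_annihilated = TRUE` excludes such
  flasks for sensitivity analysis.
* **Degenerate days** (fewer than 3 usable points, a single volume, or zero
  richness variance — e.g. every flask annihilated) are reported as
  `not_assessable`, distinct from `none`.

The **occurrence summary** reports (a) the fraction of time points
classified positive and (b) the fraction of the observation period covered,
where a maximal run of consecutive positive schedule days from d1 to d2
contributes d2 - d1 + 1 calendar days and an isolated positive day
contributes 1. "Consecutive" means adjacent schedule positions — with a
1/2/5-day sampling cadence, a run from day 22 to day 30 spans 9 calendar
days even though only 5 samplings occur inside it. Negative-SAR days are
reported separately and never counted in the positive fractions.

## Preprocessing

Two rules, in a fixed order:

1. **Rarefaction to the minimum positive depth**, without replacement
   (multivariate hypergeometric) — the standard ecological convention for
   equalising sequencing effort. Rarefaction is applied per kingdom,
   because the two markers are sequenced in separate libraries with
   unrelated depth distributions. All-zero samples (annihilated flasks)
   bypass rarefaction and are retained: the annihilation analysis needs
   them.
2. **Rare-ASV filtering**: drop every taxon whose grand-total count is
   strictly below a fraction (default 1e-5, i.e. 0.001%) of the table's
   grand total, after merging the kingdoms. Whether the filter should act
   per marker or on the combined table is genuinely ambiguous for this kind
   of design; the merged grand total is the default and
   `filter_per_kingdom = TRUE` gives the alternative. The rule is strict
   `<`, so a taxon exactly at the threshold is retained.

## Extinction, annihilation, and mass-extinction detection

The per-day Pearson correlation of extinction rate with volume uses raw
volume by default (`log_volume = TRUE` is available); Pearson r is
invariant to affine rescaling of the volume axis, which is property-tested.
A day is flagged when r < 0 at p < alpha.

`detect_mass_extinctions()` flags a day when the mean extinction rate rises
by at least `delta` over the previous sampled day. `delta` is an **absolute
jump on the rate scale** (default 0.10 = 10 percentage points). Reported
jump magnitudes in this kind of system are most naturally read as
percentage-point changes of a quantity that is itself a percentage, and an
absolute threshold does not shrink spuriously late in the series when rates
approach 1; a relative-change reading would make the late-phase threshold
nearly unreachable. Phase means use the sample (n-1) standard deviation.

## Bell regression and phase segmentation

The "bell form" is Gaussian-plus-offset,
`y(t) = d + a*exp(-(t-mu)^2/(2*sigma^2))`, with free-sign amplitude: a pH
trajectory that falls and recovers is a dip (a < 0). The fit minimises SSE
over a deterministic multi-start grid (mu at the quartiles of the day
range, sigma at range/8 and range/4, amplitude and offset from data
extremes; ties broken by grid order), polished by Gauss-Newton; sigma is
optimised on the log scale to stay positive. R-squared is measured against
the constant-mean model and the p-value is an F-test with (3, n - 4)
degrees of freedom. Non-convergence returns a diagnosable `converged =
FALSE` result, never an exception. Note the tension in fitting a symmetric
bell to an annihilation-rate series that is non-decreasing by construction:
the fit is reported because it is the conventional summary, but its
parameters should be read as a smooth of the trajectory, not a mechanism.

Segmentation works on the mean pH series. The threshold is 25% of the
maximum observed per-day |change|. Phase 1 ends at the last day before the
per-day change magnitude first falls below the threshold *after the
steepest interval* (the guard matters: pH is flat for a day or two before
the crash begins). Phase 3 starts at the end of the first interval whose
rise exceeds the threshold sustained for two consecutive intervals —
sustained, because a single noisy uptick is not a recovery. Fewer than
three detectable regimes yield a best-effort segmentation with a warning,
and `phases = data.frame(label, start, end)` forces a manual segmentation.

Shannon diversity uses the natural log and is undefined (NA) for
annihilated samples. Between-phase tests are two-sided Wilcoxon rank-sum
tests (exact null for small untied samples, tie-corrected normal
approximation otherwise). Beta diversity is Bray-Curtis with Kruskal NMDS
(stress-1), deterministic given the seed.

## The simulator: what it emulates

`simulate_study()` generates the full design — by default 7 volumes
(10–1000 mL), 3 replicates, 26 time points over 60 days, 546 samples plus a
day-0 pool reference — from explicit mechanisms:

* **Pool**: 783 bacterial + 889 fungal ASVs, lognormal relative abundances
  (sigma = 1.5, a typical amplicon rank-abundance spread). 30% of bacteria
  are acid producers. Every taxon draws a pH tolerance; bacterial
  tolerances centre at 3.8 (sd 0.25), fungal at 2.5 — fungi are
  non-acid-producing but acid-tolerant, so the crash passes them by.
* **Assembly** is a multinomial draw of `density_per_ml * volume`
  individuals. The default density (1e5 /mL; real ferments run orders of
  magnitude denser) is deliberately *saturating*: computed analytically
  from the occupancy formula `E[S0] = sum_i 1 - (1 - p_i)^N`, expected
  day-0 richness differs by well under 1% between the smallest and largest
  flask (asserted in `test-simcosm.R`). This is essential twice over: it
  reproduces the absence of an initial SAR, and it makes flasks
  exchangeable across volumes under the null preset, which the calibration
  criterion requires.
* **Demographic extinction**: per-day hazard `base_hazard * mult *
  v^(-gamma_volume)` with base 0.02/day, gamma 0.5, and `mult` = 7.5 for
  acid-intolerant bacteria. The intolerant group is both stress-sensitive
  and demographically fragile — one vulnerability axis — which is what lets
  the pH crash *reset* the volume signal: the taxa that carried the early
  richness gradient are the ones the crash removes everywhere, and the SAR
  must then rebuild from the slow hazard of the tolerant survivors
  (~2 weeks to regain significance, matching a mid-experiment SAR gap).
* **pH trajectory**: logistic fall from 6.2 to a flask-specific floor
  (3.2 +/- 0.15) around a flask-specific midpoint (day 5 +/- 0.45, scale
  0.8 days), flat bottom, then linear recovery from day 40 at 0.3 pH/day
  capped at 6.0. Non-acid producers die when flask pH crosses below their
  tolerance, so the first mass extinction lands on days ~6-7. The
  between-flask jitter desynchronises the crash just enough that
  mid-crash richness is dominated by crash progress, not volume — which is
  how the SAR disappears during the event itself.
* **Second mass extinction**: a resource-collapse hazard (0.15/day on all
  surviving taxa, days 37-42) plus a whole-flask annihilation surge
  (0.01/day from day 30, 0.10/day from day 42, volume-independent as
  parameterised). Annihilation jumps a flask's extinction rate to 1, so
  the mean-rate series jumps around day 40 and the late SAR dissolves into
  zero-richness noise.
* **Observation**: multiplicative lognormal abundance noise (sigma 0.25
  per day) and multinomial sequencing at 20000 reads.

One flask lineage per (volume, replicate) is simulated and sampled
non-destructively at every schedule day. The real design is destructive —
statistically equivalent for per-day analyses — but lineages make latent
extinction and annihilation monotone within a flask, which is what the
monotonicity invariants test.

`scripted_windows()` exposes the generator's own event geometry to the
tests: the crash bracket (days 5-8) inside which the first extinction jump
may register, its core (days 6-7) where the SAR is expected absent, the
collapse bracket (days 30-46), and the stable window (days 22-30) where
positive SARs are expected.

### What the generator does *not* emulate

Taxon-level presence/absence hazards replace birth-death demography;
abundance dynamics are a noise process, not competition; pH is scripted
rather than produced by acid-producer biomass; fermentation chemistry,
primer/PCR artefacts, chimeras and taxonomy errors are absent; and the
hazard functional forms are the package's own — the source system offers no
quantitative mechanism to fit. A green simulation test therefore
establishes that the *pipeline recovers the patterns a mechanism of this
shape produces*, not that the mechanism is the one operating in any real
ferment. Real data should be expected to show, e.g., overdispersed
replicate richness and day-1 SARs that this generator deliberately avoids.

## Calibration and power: how the criteria are evaluated

* **Calibration.** Under the null preset (`sim_params_null()`: gamma = 0,
  no crash, no collapse, no annihilation) flasks are exchangeable across
  volumes, so a day should be classified positive with probability
  ~alpha/2. Within one simulated study, richness trajectories are strongly
  autocorrelated across days — the 26 day-tests of a seed are nearly one
  draw, and pooling them would wreck the variance of the Monte-Carlo
  estimate. The calibration run therefore simulates one independent
  single-day study per seed (600 seeds) and checks the positive rate
  against two-sided 99% binomial bounds around alpha/2.
* **Power and pattern recovery.** 100 seeds of the default preset feed
  four criteria from one shared run: positive-SAR coverage of the stable
  window with none in the crash core (majority of seeds); mass-extinction
  flags confined to the scripted windows (>= 95% of seeds); segmentation
  breakpoints within one schedule position of the scripted truth (>= 90%);
  and Phase 1 < Phase 2 < Phase 3 mean extinction (>= 95%). The scripted
  truth for segmentation is defined as the breakpoints the segmentation
  rule yields on the *noise-free* scripted pH trajectory, so the test
  measures recovery under noise and finite sampling, while the rule itself
  is validated against hand-constructed series in the unit tests.

Generator parameters were fixed from the design analysis above before the
acceptance thresholds were evaluated, and the package treats them as the
stated world: they are not tuning knobs for the test suite.

## Numerical conventions

* OLS, Pearson, Wilcoxon and Bray-Curtis all have brute-force oracles in
  the test suite (normal equations, covariance formula, full enumeration of
  rank splits, min-sum formula) at 1e-10.
* Sample SD uses n-1 throughout. Fisher-z confidence intervals for r use
  the n-3 denominator and are omitted below n = 4.
* All randomness flows through R's global RNG, seeded once per entry point
  (`simulate_study(seed=)`, `rarefy_to_min(seed=)`,
  `nmds_ordination(seed=)`, pipeline `config$seed`); identical seeds give
  byte-identical outputs.
* Counts are integers end to end; TSV round-trips are bit-exact.

## Known limitations

* The extinction definition conflates loss with non-detection; rarefaction
  depth directly moves the observed extinction floor.
* Segmentation assumes a fall-flat-rise pH shape; other environmental
  trajectories need the manual override.
* The bell p-value's F-test assumes well-behaved residuals, which a
  saturated annihilation series violates; treat it as descriptive.
* With 21 points per day, single-flask outliers (early annihilations)
  can flip borderline SAR classifications; `drop_annihilated` quantifies
  that sensitivity.
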