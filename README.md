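# microsar

Temporal species–area relationships (SARs) in closed microcosm time series.

## The problem

Classical island biogeography predicts that larger habitats hold more
species, and that smaller habitats lose them faster. Sealed microcosms of
fermenting vegetable soup are a clean system for testing the extinction side
of that prediction: every flask starts from the same well-mixed species
pool, nothing immigrates, speciation is negligible over weeks, so all
community change is local extinction. Monitoring replicate flasks across a
volumetric gradient (10–1000 mL) over 60 days asks a sharp question: *is the
SAR a persistent law, or a transient property that mass extinctions can
erase and succession can rebuild?*

`microsar` is an analysis pipeline for ASV (amplicon sequence variant)
feature-table time series from such designs, plus a mechanistic stochastic
simulator of the whole experiment used to calibrate and power-test every
statistic in the pipeline.

## The statistics at its core

* **Semi-log SAR, per time point.** At each sampled day, species richness
  `S` (bacterial + fungal ASVs jointly) is regressed on volume `A`:
  `S = c + b·log10(A)` (OLS, two-sided t-test on `b`). A day is classified
  `positive` / `negative` / `none` at level alpha = 0.05. An occurrence
  summary reports the fraction of time points with a positive SAR and the
  fraction of the observation period covered by maximal runs of consecutive
  positive days.
* **Extinction rate** of a sample: the fraction of species-pool ASVs
  undetected in it. **Annihilation rate** of a day: the fraction of
  microcosms with no detected organisms at all. Per-day Pearson correlation
  of extinction rate with volume; mass-extinction detection as a jump of
  ≥ 10 percentage points in mean extinction rate between consecutive
  sampled days.
* **Phase structure.** Bell-form regression
  `y(t) = d + a·exp(-(t-mu)^2 / (2·sigma^2))` of pH and annihilation rate
  against time; threshold-based segmentation of the pH series into three
  successional phases; Shannon diversity with pairwise Wilcoxon rank-sum
  tests between phases; Bray–Curtis dissimilarity with NMDS ordination.
* **Traits.** Extinction stratified by acid-producing versus
  non-acid-producing bacteria, and Pearson forest tables of trait/gene
  relative abundance versus volume.

The simulator draws a lognormal species pool, assembles flasks by saturating
multinomial sampling (`density_per_ml · volume` individuals), and advances
each flask daily: a volume-dependent demographic extinction hazard
`base_hazard · v^(-gamma_volume)`, a scripted pH crash that kills
acid-intolerant taxa (first mass extinction), a late resource collapse and
whole-flask annihilation surge (second mass extinction), multiplicative
lognormal abundance noise, and multinomial sequencing at fixed depth.

## Worked example

```r
library(microsar)

design <- mc_design()           # 7 volumes x 3 replicates x 26 time points
sim <- simulate_study(design, sim_params(), seed = 42)
ds  <- join_dataset(sim$features, sim$metadata)

scan <- sar_scan(ds)            # one semi-log SAR fit per sampled day
head(as.data.frame(scan), 8)
#>   day  n slope r_squared  p_value classification
#> 1   1 21  13.8    0.3827 2.80e-03       positive
#> ...
#> 6   6 21  30.9    0.0470 3.45e-01           none
#> 7   7 21  11.5    0.0239 5.04e-01           none
#> 8   8 21  18.6    0.3575 4.20e-03       positive

summarize_occurrence(scan, design)
#> Positive SAR at 18/26 time points (69.23%), covering 26 days (43.33% of the period)

rec <- extinction_records(ds)
ser <- mean_extinction_series(rec)
detect_mass_extinctions(ser$day, ser$mean_rate)
#> [1]  7 40

ph  <- aggregate(pH ~ day, sim$metadata[sim$metadata$day > 0, ], mean)
seg <- segment_phases(ph$day, ph$pH)
phase_mean_extinction(rec, seg)
#>     phase start end   n  mean     sd
#> 1 Phase 1     1   7 147 0.182 0.0885
#> 2 Phase 2     8  40 315 0.477 0.1032
#> 3 Phase 3    45  60  84 0.911 0.0919

fit_bell(ph$day, ph$pH)
#> Bell fit: y = 8.469 -5.58 exp(-(t - 25.1)^2 / (2 * 22.91^2)); R2 = 0.758, p = 5.6e-07
```

Reading the output: the SAR is present early, is wiped out by the pH-driven
mass extinction around days 6–7 (extinction rate jumps, classification
drops to `none`), re-emerges through the stable mid-phase (days 22–30), and
disappears again when the late collapse and annihilation surge hit around
day 40. Mean extinction rises monotonically across the three detected
phases, and the pH trajectory is a broad dip (negative bell amplitude).

A full run (`run_pipeline(config, out_dir = "out")`) writes one tidy TSV
per result plus a JSON run manifest; the same entry points are available
from the shell via `inst/scripts/microsar simulate|run`.

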