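# nanosyn

Quantitative analysis of synapse nanoscale organization and protein
dynamics from live-cell and super-resolution imaging. The package is
aimed at neuroscientists measuring how adhesion molecules and receptors
behave at excitatory synapses — how mobile they are, how fast they turn
over, how much of them sits at the surface, and how precisely pre- and
postsynaptic nanodomains align.

It covers five readouts, each with a synthetic-data generator that
plants known parameters, so every estimator is validated by parameter
recovery:

* **Single-particle tracking** (`spt_config()`, `compute_msd()`,
  `classify_tracks()`, `summarize_population()`): time-averaged MSD
  curves; diffusion coefficients from a 4-point linear fit with free
  intercept, D = slope/4; immobile/confined/diffusive classification
  with the resolution-derived immobility threshold
  D_thr = res² / (4 · n_fit · Δt) = 0.005 µm²/s and the confinement
  model MSD(t) = (4/3) r²_conf (1 − e^(−t/τ)), τ = r²_conf/(3 D_conf),
  with a 100 ms τ cut; synaptic sorting (>50% of frames inside a
  synapse mask) and dwell times.
* **FRAP** (`normalize_frap()`, `frap_qc()`, `fit_frap()`):
  background-subtracted, bleach-corrected, affinely normalized traces;
  quality filters (bleach depth ≥ 50%, no negative recoveries); the
  double-exponential model
  F(t) = F(0) + p(1 − e^(−t/τf)) + q(1 − e^(−t/τs)), whose fitted q is
  the slow-pool fraction.
* **pH-switch pools** (`estimate_pools()`, `partition_spine_shaft()`):
  surface vs intracellular pools from five-phase pHluorin protocols
  (baseline / pH 5.5 / baseline / NH₄Cl / baseline); intracellular =
  total − surface, plus quench percentage and the spine share of the
  intracellular pool.
* **dSTORM subsynaptic domains** (`dbscan_cluster()`, `segment_ssds()`,
  `build_synapse_regions()`, `pair_nanocolumns()`): DBSCAN segmentation
  (RIM1/2: 80 nm / 40 pts; GluA1/2: 70 nm / 30 pts), SSD centroids,
  counts and convex-hull surfaces, synapse regions from intersected
  channel masks, and trans-synaptic nanocolumn pairing — each receptor
  SSD to its nearest scaffold SSD within 350 nm.
* **Exocytosis** (`detect_events()`, `fit_event_decay()`,
  `event_frequency()`): appearance-event detection in post-bleach
  movies with a σ-scaled jump-plus-persistence criterion, and
  single-exponential decay fits A·e^(−t/τ) + c.

Everything takes and returns data frames, chains with the pipe, and has
`tidy()` / `glance()` methods and `autoplot()` plots where a fitted
object or curve is involved. A single command-line entry point
(`nanosyn_run()`, installed script `inst/cli/nanosyn`) exposes
`simulate`, `spt`, `frap`, `ph`, `smlm`, and `exo` subcommands with a
YAML config and a provenance manifest.

## A worked example

Simulate a mixed tracking population, classify it, then fit FRAP
recoveries and pair nanocolumns:

```r
library(nanosyn)
library(dplyr)

cfg <- sim_config(seed = 42)

## motion classification on a planted 1/3-1/3-1/3 population
sim <- simulate_trajectories(cfg, n_per_class = c(brownian = 200,
                                                  confined = 200,
                                                  immobile = 200))
reports <- classify_tracks(sim$tracks, spt_config())
summarize_population(reports)
#> # A tibble: 1 × 7
#>   n_tracks frac_immobile frac_confined frac_diffusive ...
#> 1      600         0.378          0.34          0.282

## FRAP: five regions at p = 0.5, tauf = 5 s, q = 0.3, taus = 120 s
frap <- simulate_frap_traces(cfg, frap_truth(5, noise_sd = 5))
normalize_frap(frap) |> fit_frap() |>
  select(region_id, p, tauf, q, taus, slow_pool_fraction)
#> # A tibble: 5 × 6
#>   region_id     p  tauf     q  taus slow_pool_fraction
#> 1         1 0.501  4.88 0.296  114.              0.296
#> 2         2 0.501  4.97 0.301  124.              0.301
#> ...

## nanocolumns: 16 synapses with a planted 60 nm RIM-GluA offset
cfg_s <- sim_config(42, field_size = c(6, 6))
locs <- simulate_localizations(cfg_s,
          nanocolumn_truth(cfg_s, n_synapses = 16, offset_nm = 60))
pair_nanocolumns(segment_ssds(locs$glua), segment_ssds(locs$rim)) |>
  pairing_summary()
#> # A tibble: 1 × 5
#>   n_glua n_paired mean_distance_paired_nm ...
#> 1     16       16                    61.0
```

The classified fractions track the planted thirds (classification is
imperfect by design at these diffusion parameters — short tracks are
noisy); the FRAP fits recover the planted pool fractions and time
constants; the mean centroid distance lands on the planted 60 nm offset
broadened by centroid noise.

The methods vignette (`vignettes/nanosyn-methods.Rmd`) documents every
model, default, and numerical choice.

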