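---
title: "Models and methods behind nanosyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanosyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosyn)
```

nanosyn quantifies how synaptic adhesion proteins and receptors are
organized and exchanged at excitatory synapses, from five kinds of
imaging readouts: single-particle tracking (uPAINT-style), FRAP,
pHluorin pH-switch protocols, dual-color dSTORM localization tables, and
post-bleach exocytosis movies. This vignette explains the models each
stage fits, the defaults and why they hold, what the synthetic-data
generators emulate, and the numerical choices made where the design was
open. Every empirical statement here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing is quoted from external
data.

## Single-particle tracking

A trajectory is a time-ordered sequence of 2D positions at a fixed frame
interval `dt` (default 0.02 s). Tracks shorter than `min_points = 10`
frames (200 ms) are discarded: shorter tracks do not support a stable
4-point MSD fit.

**MSD.** `compute_msd()` uses the time-averaged estimator: for lag $k$,
the mean squared displacement over *all* (overlapping) position pairs
separated by exactly $k$ frames. The number of pairs per lag is
recorded so downstream code can weight by it. The overlapping-pair
choice maximizes information from short tracks; its cost is correlation
between lags, which is why classification never uses more than the
first 10 lags.

**Diffusion coefficient.** An ordinary least-squares line through the
first `n_fit_points = 4` (lag, MSD) points, with a *free intercept*,
gives $D = \text{slope}/4$. The free intercept matters: localization
noise of sd $\sigma$ per coordinate adds a constant $4\sigma^2$ to every
MSD lag, which the intercept absorbs, leaving the slope — and hence $D$
— unbiased. A negative fitted slope (possible for immobile molecules in
noise) clamps $D$ to 0 with a flag.

**Immobility threshold.** A molecule is called immobile when it explores
less than the resolution-limited area during the time spanned by the
linear fit:
$$D_{\mathrm{thr}} = \frac{\text{resolution}^2}{4 \cdot n_{\mathrm{fit}} \cdot dt}
 = \frac{(0.04\,\mu m)^2}{4 \times 4 \times 0.02\,s} = 0.005\,\mu m^2 s^{-1}.$$
`spt_config(D_threshold = "auto")` computes this closed form; the
defaults reproduce 0.005 exactly.

**Confinement.** The remaining tracks are fitted with the confined-
diffusion MSD model
$$\mathrm{MSD}(t) = \tfrac{4}{3} r_{\mathrm{conf}}^2 (1 - e^{-t/\tau}),
 \qquad \tau = \frac{r_{\mathrm{conf}}^2}{3 D_{\mathrm{conf}}},$$
over the first `conf_fit_lags = 10` lags (a 200 ms window). Tracks with
$\tau$ at or below `tau_threshold = 0.1` s — half the MSD window — are
confined, the rest diffusive; a tie at the threshold counts as confined.
The fit is unweighted nonlinear least squares (Levenberg–Marquardt); a
non-converging fit is flagged and the track treated as diffusive, the
conservative choice. For diffusive tracks the reported
$D_{\mathrm{diff}}$ is the same 4-point linear estimate.

One numerical caution we verified by simulation: when motion is
simulated as Brownian steps reflected inside a disc of radius $r$, the
long-lag MSD plateaus near $r^2$ (two independent uniform points in a
disc), while the model above plateaus at $\tfrac{4}{3} r_{\mathrm{fit}}^2$ —
so $r_{\mathrm{fit}} \approx \sqrt{3}/2 \cdot r$. Tests therefore
compare plateaus, the measurable quantity, not radii across
conventions. Time-averaged MSDs on finite tracks are also biased
slightly low at long lags; the property tests allow 20% for this.

**Synaptic sorting.** Synapses are binary rasters (nonzero = synaptic
area) with a stated pixel size; a coordinate maps to a pixel by floor
after scaling (0-based indices). A track is synaptic when *more than*
50% of its frames fall inside; dwell time is inside-frame count times
`dt`, reported both per entry-to-exit visit and per track, and the
population mean is taken over tracks that cross a synapse at least
once. Coordinates outside the raster count as outside and are tallied.

## FRAP

Raw region traces carry ten pre-bleach frames. Normalization proceeds
in two steps: background subtraction plus bleach correction — division
by the unbleached reference region, itself background-subtracted and
scaled to its own pre-bleach mean — then an affine map sending the
pre-bleach mean to 1 and the first post-bleach value to 0. Division by
a reference is the standard correction and is exactly what the
synthetic generator's multiplicative acquisition-bleaching model
inverts. Regions are excluded when the bleach depth is below 50% or
when any post-bleach normalized value drops below $-0.02$; the small
tolerance keeps traces whose noise merely dips under zero, and the
depth rule is monotone (lowering the cut never excludes a previously
included region).

Recovery is fitted with the double exponential
$$F(t) = F(0) + p(1 - e^{-t/\tau_f}) + q(1 - e^{-t/\tau_s}),$$
where $p$ and $q$ are the fast and slow pool fractions. Constraints:
$F(0), p, q \ge 0$, $F(0) + p + q \le 1$, and $\tau_s$ capped at five
times the trace duration (beyond that the slow pool is not identifiable
from the record). $F(0)$ is kept free even though normalization forces
the first sample to zero, matching the model as written. Fitting uses
three Levenberg–Marquardt starts with time constants at 10% and 60% of
the trace duration jittered by 0.5/1/2; the pools are relabeled after
fitting so $\tau_f < \tau_s$, and a violated sum constraint triggers a
penalized bounded refinement. The slow-pool fraction reported per
region is the fitted $q$. A flat trace is flagged degenerate
($p = q = 0$) and omitted from population means. On noiseless
model-generated traces the fit recovers all five parameters to better
than $10^{-3}$ relative; at noise sd 0.03 on the normalized scale, the
mean $\hat q$ over 30 regions is within 0.05 of truth (both checked in
the tests).

## pH-switch pool quantification

The five-phase protocol (baseline pH 7.4, pH 5.5, baseline, NH~4~Cl,
baseline) separates pools: the surface pool is the mean over the three
baseline phases, the total pool the mean under NH~4~Cl, and the
intracellular pool their difference — conserved exactly by
construction. The quench percentage compares the pH 5.5 phase to
baseline. Phase boundaries come from the frame labels (perfusion timing
is known experimentally), not from change-point detection; the first
two frames after each switch are excluded from phase means to avoid
mixed-solution frames (configurable to 0). The spine share of the
intracellular pool is the summed intracellular signal of spine objects
over all objects, in percent. All percentages are invariant to
rescaling the intensities.

## dSTORM subsynaptic domains and nanocolumns

Subsynaptic domains (SSDs) are segmented per channel by DBSCAN with the
published parameters — presynaptic scaffold (RIM1/2): radius 80 nm,
minPts 40; receptor (GluA1/2): radius 70 nm, minPts 30. Two semantic
details are fixed explicitly because implementations differ: minPts
counts the point itself, and border points go to the first cluster that
claims them in deterministic input order (a non-semantic tie-break; the
tests compare partitions up to relabeling and accept any admissible
border assignment). The clusterer is validated against an independent
distance-matrix reference on random instances.

Per SSD we report the centroid, the localization count, and the
cluster surface as the area of the 2D convex hull — reproducible and
parameter-free; degenerate hulls get area 0 with a flag. Synapse
regions are built by rendering each channel at 100 nm pixels,
Gaussian-smoothing (sd 1 px), Otsu thresholding, dilating by 2 px, and
taking 8-connected components of the two masks' intersection — the
package renders from the localization tables themselves, and a
user-supplied mask bypasses rendering when dedicated low-resolution
images exist. SSDs are assigned to the region containing their
centroid.

Trans-synaptic pairing takes, for each receptor SSD, the nearest
scaffold SSD centroid; pairs farther than 350 nm are reported
unpaired. Distances are computed in double precision with no binning
before pairing; the distribution is summarized as a relative-frequency
histogram (default 20 nm bins) plus the mean over paired SSDs (the mean
over all receptor SSDs is reported alongside, since capping at 350 nm
is itself an analysis choice).

## Exocytosis detection

The detection operator is a deliberate, documented default — simple
enough to characterize fully. The movie is disk-averaged (radius 2 px),
and the noise scale of a one-frame jump is estimated from
frame-to-frame differences in a leading baseline window. A candidate is
a pixel rising more than $k\sigma$ (default $k = 5$) above its local
pre-event baseline — the mean of up to three preceding frames — within
one frame, and staying above $0.75\,k\sigma$ in the next frame. The
three-frame baseline and the persistence check are what push the
expected false-positive count on a pure-noise movie (128² px, 200
frames) below 0.05: a single-frame threshold alone, applied to millions
of correlated tests, cannot get there at $k = 5$. Candidates within
6 px and 2 frames merge into the strongest. Event decay is fitted from
the peak onward with a single exponential plus offset,
$A e^{-t/\tau} + c$ — the simplest model consistent with a fluorescence
decay; the fitter refuses constant traces. Event frequency is count per
cell area per duration. The detector's operating range, verified by
simulation: amplitudes from about 8 noise-sd and decay constants at or
above the frame interval; faster decays can fail the persistence check
by design.

## The synthetic generators

Every analysis stage has a paired generator that plants known
parameters and returns them as ground truth, so each estimator is
scored by parameter recovery without external data:

* **Trajectories** — Brownian steps of per-axis variance $2D\,dt$;
  confined motion as Brownian steps reflected radially at a circular
  boundary (chosen because its MSD saturates like the confinement
  model); immobile as a fixed point; i.i.d. Gaussian localization noise
  of 0.02 µm per coordinate (half the 0.04 µm resolution scale) added
  per frame. Track lengths are uniform over 10–60 points so the length
  filter is exercised from both sides.
* **FRAP traces** — the double-exponential model embedded in a raw
  intensity trace: ten pre-bleach plateau frames, a bleach step of
  configurable depth, multiplicative per-frame acquisition bleaching,
  an unbleached reference trace and a constant background trace, and
  Gaussian noise. The normalization pipeline inverts the construction
  exactly when noise is zero.
* **pH traces** — five labeled phases with plateau levels set by the
  planted surface fraction and quench efficiency (defaults 0.8 and 0.9,
  matching ~20% intracellular and ~90% quench), with two
  linearly-mixed transition frames per switch.
* **Localization tables** — SSD pairs at planted centroid offsets
  (default 60 nm), localizations drawn isotropic Gaussian with sd half
  the SSD radius and counts Poisson (default mean 100), plus uniform
  background. Multiple pairs per synapse sit on a 150 nm ring so they
  remain resolvable by DBSCAN at the published radii.
* **Exocytosis movies** — 2D Gaussian spots appearing at planted onsets
  with exponentially decaying amplitude on a flat baseline with
  Gaussian read noise, clipped at zero, written as 16-bit multi-page
  TIFF.

The generators emulate the statistical structure the estimators rely
on, not camera physics: no EMCCD gain or Poisson shot-noise chains, no
fluorophore blinking or photophysics, no 3D, no drift. Passing tests
therefore demonstrate correctness of the estimators under their stated
models — unbiasedness of the MSD slope under localization noise,
identifiability of the double exponential, DBSCAN recovery at the
published densities — not robustness to every artifact of real
acquisitions. Where the literature gives no distributional ground truth
(true $D$ distributions, SSD localization counts), the defaults are
scenario parameters chosen once at realistic scales, not estimates of
any particular dataset.

## Problem sizes and determinism

The test suite and the acceptance script run at sizes chosen to give
stable statistics at interactive cost: 1000 tracks for diffusion
recovery, 500 per class for classification, 30 traces for FRAP
recovery, 50 synapses for pairing, 128² × 100-frame movies for
detection. All generators consume a single integer seed through
`sim_config()`; identical seed and configuration reproduce outputs
bit-for-bit, and the command-line interface threads one seed through
every stage.

## Known limitations

* The pipeline consumes localization and trajectory *tables*; spot
  detection, localization fitting, linking, and drift correction are
  upstream.
* Motion classification is per-track; molecules switching state within
  a track are assigned their dominant regime (no HMM segmentation).
* FRAP fitting is purely kinetic; reaction–diffusion coupling is out of
  scope, and the $\tau_s$ identifiability cap means very slow pools are
  reported at the cap rather than extrapolated.
* Cluster surface via convex hull slightly overestimates concave
  clusters; an alpha-shape alternative would need a shape parameter and
  is not provided.
* The exocytosis detector assumes a quiescent post-bleach background;
  it is not designed for movies with ongoing bulk recovery.
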