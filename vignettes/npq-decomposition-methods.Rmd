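---
title: "Decomposing single-cell NPQ into qE, qT and qI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing single-cell NPQ into qE, qT and qI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npqcell)
library(dplyr)
```

## The measurement and the problem

Pulse-amplitude-modulated (PAM) fluorometry probes the regulatory state of
photosystem II: a brief saturating light pulse (SP) transiently closes all
reaction centers, so the fluorescence emitted during the pulse — the maximal
fluorescence yield, Fm in darkness or Fm′ under actinic light — reflects only
the non-photochemical de-excitation pathways. Tracking Fm′ pulse after pulse
through a high-light/dark protocol yields a per-cell time series whose shape
encodes the cell's non-photochemical quenching (NPQ) machinery:

* **qE** (energetic quenching): engages within seconds of light onset,
  typically passes a transitory maximum before partially relaxing in the
  light, and relaxes within seconds in darkness;
* **qT** (state transitions): antenna migration that *raises* Fm′ over
  minutes in the light and relaxes over minutes in darkness;
* **qI** (photoinhibition): a slow decline that does not recover within the
  dark phase.

A wild-type cell expresses a superposition of all three. `npqcell` turns each
91-point Fm′ trace into three interpretable coordinates — a qT, a qE and a qI
score — and provides the downstream statistics to quantify cell-to-cell
heterogeneity in these traits.

The reference illumination protocol is 15 min of high light
(400 µmol photons m⁻² s⁻¹) followed by 15 min of darkness, with SPs every
20 s starting at t = 0; over 1800 s this gives

```{r}
length(pulse_times(reference_protocol()))
```

samples per trace. Phase intervals are half-open, `[start, start+duration)`:
a pulse exactly at the light→dark boundary samples the dark phase. Since the
actinic light is switched off during each SP anyway, this convention affects
only the simulator, and it is fixed once here. Placing the first pulse at
t = 0 is what yields the 91-sample dimension; an initial dark-adaptation
offset would shorten the trace and is not used.

## The scoring model

Training uses four reference populations, each expressing at most one
component: a quenching-null population (`pop_0`), and single-component qE,
qT and qI populations, with reference sizes 433, 480, 936 and 453 cells
(2302 in total). The pipeline is:

1. **Filtering.** Segmented cells with area < 5 px are discarded. Each trace
   is then normalized by its sum (so it becomes a probability distribution
   over pulses and absolute brightness drops out), and traces whose nearest
   neighbour lies further than D = 0.01 in Euclidean distance are removed as
   outliers. The isolation filter runs *after* sum-normalization: on raw
   fluorescence (hundreds of a.u.) a radius of 0.01 would remove everything,
   while on sum-normalized traces (entries ≈ 1/91) it is a meaningful
   neighbourhood scale. Ties at exactly D are kept.

2. **Sparse dictionary learning.** On a balanced random subsample of 300
   traces (75 per class), we learn 10 unit-norm atoms `D` and sparse codes
   `X` minimizing ½‖Y − XD‖² + λ‖X‖₁ with λ = 10⁻⁶, by alternating a lasso
   sparse-coding step (cyclic coordinate descent plus a feature-sign
   active-set polish, which lands on the exact subproblem minimizer even
   when atoms are strongly correlated) with a block-coordinate atom update
   on the unit sphere. Both steps decrease the objective, so the recorded
   fit history is non-increasing by construction. Codes are not
   sign-constrained. Ten atoms is the smallest size whose mean per-trace
   squared reconstruction error (on sum-normalized traces — the only
   reading under which the 2·10⁻⁴ selection threshold is dimensionless and
   attainable) falls below that threshold; in practice the synthetic
   training set reconstructs to ~4·10⁻⁶.

   Alternating dictionary learning has a long, flat objective tail. The
   default stops at 80 iterations (relative tolerance 10⁻⁷): by iteration
   20 the reconstruction error is already two orders of magnitude below the
   selection threshold, and further iterations change scores negligibly
   while multiplying runtime.

3. **Linear discriminant analysis.** All surviving labelled codes (not just
   the dictionary subsample — the larger sample stabilizes the scatter
   matrices) feed a 4-class LDA: between-class scatter `S_B` (class-size
   weighted) against pooled within-class scatter `S_W`, solved by whitening
   `S_W` (ridge 10⁻⁸ × mean diagonal) and eigendecomposing the whitened
   `S_B`. Four classes give a 10 → 3 projection.

4. **Axis alignment.** In the 3D discriminant space, the first principal
   direction of each expressing class (qT, qE, qI clouds) forms a column of
   the transfer matrix `R` — an *oblique* change of basis (the class
   directions need not be orthogonal, and forcing orthogonality would
   misattribute variation); a condition-number guard (default 10³) rejects
   degenerate geometries. Coordinates are transformed by `R⁻¹`, and each
   axis origin is anchored by the populations biologically known to lack
   that component: the qT origin is the pooled mean of the qE, qI and null
   cells (all lack the state-transition kinase), the qE origin the mean of
   the qI cells (never light-acclimated, no LHCSR), the qI origin the pooled
   mean of qE, qT and null cells (their last Fm′ returns to the initial Fm).
   These three class-mean constraints hold to 10⁻¹⁰ by construction on every
   training run. Axis signs point from the origin toward the expressing
   class centroid. Origins are frozen at training time; scoring a new
   dataset does not re-anchor them (re-anchoring would absorb genuine batch
   differences into the origin).

Scoring a new trace is then: sum-normalize (idempotent), lasso-encode
against the trained atoms, project through the LDA, apply `R⁻¹`, subtract
origins.

## The synthetic-data generator

The generator is the package's study design: it fixes the conditions under
which every end-to-end property is tested.

Each cell's clean trace is `F0 · (1 − A_qE·e(t) + A_qT·g(t) − A_qI·h(t))`,
an additive combination of elementary kinetics — the same linear-combination
hypothesis the scoring model rests on (a multiplicative variant exists
behind a flag for robustness exploration only). The elementary kinetics are
first-order: qE rises with τ = 30 s modulated by a transitory relaxation
(τ = 300 s) toward a retained fraction of 0.6, and relaxes with τ = 30 s in
darkness; qT rises with τ = 200 s and relaxes with τ = 300 s; qI rises with
τ = 900 s and is frozen in darkness. These constants reproduce the
qualitative time scales (seconds / minutes / non-recovering) of the three
components; no functional forms are claimed beyond that.

Cell-to-cell amplitude dispersion is log-normal — positive support and a
directly tunable CV — parameterized by median and CV per component
(`sdlog = sqrt(log(1+cv²))`, so the distribution's CV equals the requested
value exactly). Defaults: medians 0.6 (qE), 0.3 (qT), 0.35 (qI) — peak NPQ
around 1.1 for a light-acclimated cell, Fm′ rises of ~30% for state
transitions — with CVs 0.35/0.20/0.30, chosen to emulate the 20–40%
trait CVs observed in single-cell data. Baseline F0 is log-normal
(median 1000 a.u., CV 0.3). Amplitude draws that would push Fm′ below 5% of
baseline are rejection-resampled (deterministically under the seed).
Measurement noise is multiplicative Gaussian per sample (default
σ = 0.02), reflecting intensity-proportional fluorescence noise.

Repeat pairs share per-cell amplitudes and differ only in the noise
realization, emulating two consecutive runs of the protocol on the same
immobilized cells. Simulated movies plant non-overlapping disks at
rejection-sampled positions, one frame per pulse, with optional Poisson
shot noise, and return the ground-truth mask and traces.

What the generator does *not* emulate: kinetic-parameter dispersion across
cells (only amplitudes vary), cell morphology beyond disks, illumination
gradients across the field of view, focus drift, or segmentation ambiguity
from overlapping cells. Tests passing on these synthetics therefore
validate the pipeline's statistical machinery, not its robustness to every
real-world artefact.

## Numerical choices and degenerate inputs

* Lasso coding stops on the *objective* (relative decrease < 10⁻¹⁰), not on
  coefficient movement: with strongly correlated atoms, coefficients drift
  along near-flat directions long after the fit — which is all downstream
  stages consume — has converged. The feature-sign polish then solves the
  KKT system on the active set exactly, so codes match an exhaustive
  active-set oracle to 10⁻⁸ in objective.
* `class_principal_direction()` refuses exactly isotropic clouds (relative
  eigengap < 10⁻⁹): the axis would be arbitrary.
* The nearest-neighbour outlier filter computes exact blocked pairwise
  distances; its removal set is identical to the brute-force definition
  (this is asserted, not assumed, in the tests). At trace dimension 91 a
  spatial index would degenerate to brute force anyway.
* Watershed thresholding applies Otsu to log-intensities: cell brightness
  is approximately log-normal across cells, and a linear-domain Otsu can
  bisect the bright-cell distribution instead of separating it from
  background. Pulse-window frame aggregation is the mean (robust to noise);
  background is not subtracted by default (raw SP responses are analyzed).
* Repeat-distance diagonals are computed from coordinate differences
  directly, so identical repeats give exact zeros.
* The variance contrast between same-cell and cell-to-population distances
  uses the median-centered Levene (Brown–Forsythe) test by default —
  robust to the skew of distance distributions; the classical F test is
  selectable.
* Per-cloud trend fits default to total least squares because both score
  axes carry comparable noise; OLS is available for comparison. Grid-trace
  bounds default to the 1st–99th percentile rectangle of the data.
* Model files store all numeric payloads at 17 significant digits, so a
  reloaded model reproduces scores bit-exactly.

## Problem sizes

Default end-to-end runs use the reference design: 2302 training cells
(433/480/936/453), 91-point traces, a 300-trace balanced dictionary
subsample, 10 atoms; held-out evaluations use 200 cells per class over
three seeds, 300-cell wild-type mixtures, 176-cell repeat pairs, and
150-cell 512×512 simulated movies. A full training run takes seconds on a
single core.

## Known limitations

* **Mixture crosstalk.** A sum-normalized mixed trace is a *rational*, not
  linear, function of the component amplitudes; its second-order
  qE×qT interaction points in a direction absent from all four
  single-component training clouds, so the axis alignment cannot cancel it.
  Empirically the qT score of a wild-type-like mixture behaves as
  ≈ 1.32·A_qT + 0.19·A_qE: qE expression shifts qT scores upward, and the
  Pearson correlation between true A_qT and the qT score saturates around
  0.89–0.91 at realistic amplitudes (the qE score is essentially immune,
  r ≈ 0.99). Any analysis comparing qT across conditions that also differ
  in qE should bear this in mind.
* Scores are in arbitrary per-axis units fixed by the training geometry;
  they are comparable within one trained model, not across models.
* The four-class design caps the discriminant space at three dimensions; a
  fourth co-occurring quenching process would be projected onto the
  existing axes.
* `select_n_atoms()` averages over seeds but still inherits the usual
  instability of dictionary learning for very small training sets.
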