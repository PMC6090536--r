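---
title: "Population coding of interval timing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding of interval timing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timecellmap)
```

## The model

`timecellmap` simulates temporal memory as a population of hippocampal time
cells held in a spatially ordered (topological) map: index 0 is the most
ventral cell and stores the shortest preferred duration, the last index the
most dorsal and longest. Cell $n$ fires with a Gaussian tuning curve

$$a_n(t) = A_n \exp\!\left(-\frac{(t - t_n)^2}{2\sigma_n^2}\right),
\qquad \sigma_n = \mathrm{cv}\cdot t_n,$$

where $A_n$ is its amplitude (the learned weight) and the proportionality of
width to peak time encodes, at the single-cell level, the same
accuracy-degrades-with-duration relation seen behaviorally. The population
readout is the *average time field* $a(t) = \sum_k A_k a_k(t)$ (implemented
as this weighted sum, not as an upper envelope of the individual curves —
the weighted sum is the model's only defining formula, and it is linear in
the weights, which the tests exploit).

Learning toward a criterion time $T$ is multiplicative and error driven: each
trial computes $\mathrm{err}_k = |T - t_k| + \varepsilon$ and replaces
$A_k \leftarrow A_k / \mathrm{err}_k$. Because the error signal does not
depend on the weights, $n$ trials give the closed form
$A_k(n) = A_0(|T - t_k| + \varepsilon)^{-n}$, which `closed_form_weights()`
exposes and the suite uses as an independent oracle against the iterative
`train()` path. Multi-criterion memory (`train_multi()`) simply trains the
criteria in sequence, carrying weights forward with no reset, decay, or
normalization between criteria; after training $T_1 = 10$ s then
$T_2 = 100$ s for one trial each, the cells at both criteria hold the equal,
strictly largest weight $1/(\varepsilon(90 + \varepsilon))$ — the map stores
both durations without a counter distinguishing them. A normalized view of
the weights exists (`normalized_weights()`) but is never applied implicitly.

## Parameters

* **cv** (dimensionless, default **0.2**) — the $\sigma/t$ proportionality
  constant. No published value pins it down; 0.2 makes the sparse-map example
  below peak near 8 s and produces tuning curves with visually plausible
  overlap. It is a configuration knob everywhere.
* **ε** (seconds, default **0.5**) — regularizer of the error signal. It
  prevents the division singularity for a cell exactly at the criterion and
  sets the half-width of the learned weight profile. The default reproduces
  the reference five-cell weight trajectories exactly
  ($1/2.5 = 0.4$, $1/4.5 \approx 0.22$, $1/6.5 \approx 0.15$), so it is the
  package default even though the analytic regime arguments treat ε as small.
* **boundary factor** (default **3**) — the map covers peak times uniformly
  over $(0, 3T]$: the temporal analogue of place-field boundaries, giving the
  criterion comfortable margin on both sides. Cells are placed at
  $t_i = i\,\mathrm{boundary}/N$, $i = 1..N$; no cell sits at $t = 0$, where
  the proportional width would degenerate to zero.
* **initial weight** $A_0$ (default **1**) — uniform before learning; the
  model converges from arbitrary initial weights, but $A_0 = 1$ makes the
  printed trajectories exact.
* **grid step** (default $T/1000$ over $[0, \mathrm{boundary}]$) — about
  0.1 % relative peak-location error at negligible cost.

## Width analysis and the scalar property

`measure_width()` is nonparametric: it takes the field's argmax (a tie
between equal maxima is broken toward the smaller time) and finds the
half-maximum crossing on each side by linear interpolation between grid
samples. A side that never falls to half maximum inside the grid is reported
as `NA` and excluded from the mean rather than extrapolated; a constant field
is an error. No Gaussian is ever fitted to the output.

Two mechanisms bound the field's width: the intrinsic half-width of the cell
nearest the criterion, $\sigma\sqrt{2\ln 2}$ (which scales with $T$), and the
ε-determined half-width of the weight profile (constant). `scalar_regime()`
classifies which dominates; scalar timing requires *strict* dominance of the
cell width, so the exact tie $\sigma\sqrt{2\ln 2} = \varepsilon$ is
classified `learning_limited` — a documented convention, tested at the
boundary. The pipeline is exactly scale covariant: multiplying $T$, all peak
times, all σ, ε, and the grid by $k$ multiplies the field peak and
half-widths by $k$ to floating-point accuracy. With ε fixed instead of
scaled, the width ratio between a 30 s and a 10 s run is approximately — not
exactly — 3 (2.95 for the packaged five-cell layouts, 2.55 for dense uniform
maps), which is the ε-induced deviation from pure scalar behavior.

## Fixtures, lesions, and what the tests do not show

The packaged configurations (`make_fixture_population()`) are the five-cell
layouts at {4, 6, 8, 12, 14} s and {12, 18, 24, 36, 42} s and the sparse
asymmetric map {6, 8, 12, 20, 30} s. The sparse map illustrates the model's
accuracy bound `timing_error()` $= \min_k |T - t_k|$: with no cell closer
than 2 s to $T = 10$ s, the trained field peaks near 8 s however long one
trains. One caveat the package documents rather than hides: with
$\mathrm{cv} = 0.2$ the five-cell $T = 10$ s field's global maximum sits
near 12.3 s, not 10 s, because the 12 s and 14 s cells are wider than their
mirror images at 8 s and 6 s and the weighted sum skews right. Peak-at-$T$
behavior is a property of dense uniform coverage (peak 10.07 s at $N = 100$;
$N$-invariant across 10–1000 cells), and the peak-proximity tests are stated
for those maps.

`lesion()` removes $\lfloor f N \rfloor$ cells from one end of the ordered
map (floor: deterministic, conservative) and leaves survivors' weights
untouched; populations are immutable values, so pre/post comparisons are
trivial. Dorsal ablation removes the long-duration cells and shifts the
trained field peak leftward; ventral ablation shifts it rightward — the
directional signature of hippocampal lesions. Only the direction is a model
claim; shift magnitudes depend on every parameter above.

The generator emulates idealized tuning: noiseless Gaussian rates, exact
width-peak proportionality, uniform coverage, and a criterion delivered
without trial-to-trial jitter. Real time-cell data have firing noise,
heterogeneous and drifting tuning, non-uniform coverage, and behavioral
variability in reinforcement times; passing tests therefore validate the
model's internal logic and its qualitative lesion/scalar signatures, not
quantitative fits to recordings. There is likewise no behavioral
response-threshold (start/stop) machinery and no spiking biophysics.

## Numerical and testing choices

The model is deterministic end to end; `run_simulate()` outputs are
byte-identical across runs and every artifact ships with a JSON manifest
sufficient to reproduce it. The test suite sizes are: uniform maps up to
$N = 1000$, analysis grids of $\le 12{,}000$ points, 200 randomized
configurations for the train/closed-form equivalence, and five-trial
narrowing ladders — the full suite runs in seconds. Reported weights are
rounded (two decimals) only at presentation and serialization boundaries
chosen by the caller; all internal state is double precision.

## Known limitations

* Absolute envelope half-widths for a given criterion depend jointly on cv,
  $N$, and trial count; the package asserts the reproducible claims —
  trial-to-trial narrowing and the ≈3 width ratio across a threefold
  criterion change — not any absolute width.
* The two-criterion weight algebra is exact, but the relative attenuation of
  a far cell after one trial is $\varepsilon/(90+\varepsilon)$ — $1/181$ at
  the default ε, approaching 0 (not $1/90$) as $\varepsilon \to 0$; the
  package reports exact ratios only.
* The ventral→dorsal axis is an index order; no spatial geometry, anatomy,
  or dopaminergic circuitry is modeled.
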