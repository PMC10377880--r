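---
title: "Methods: 4D box-counting fractal dimension of source activations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D box-counting fractal dimension of source activations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fd4d)
```

## The measure and its assumptions

`fd4d` computes, per subject, the box-counting (Minkowski–Bouligand)
dimension of the 4D set traced out by supra-threshold cortical activations —
three spatial axes plus time — inside non-overlapping 1-s windows of a
source-space EEG epoch. The pipeline assumes its input is already a
source-reconstructed current matrix (sources × samples) with 3D dipole
positions; sensor-space preprocessing and the inverse solution are upstream
concerns and deliberately outside the package.

The measure rests on three modelling choices:

1. **Activation = magnitude exceedance.** Source *i* is active at sample *t*
   when `|x_i(t)|` strictly exceeds `mean(|x_i|) + sd(|x_i|)` computed over
   the *entire* epoch. The per-source threshold makes the rule
   scale-equivariant (multiplying one source's gain changes nothing), and
   using the whole epoch — never the window — keeps the supra-threshold set
   comparable across windows.
2. **Windowed 4D geometry.** The active (source, sample) pairs of each
   window become points `(x, y, z, (t − t0)/W)` on `[0, 1)^4`: positions are
   affinely mapped from the subject's bounding box of *all* sources, time
   from the window. An epoch of `T` seconds with 1-s windows yields exactly
   `floor(T)` FD values (trailing partial window dropped); their mean is the
   subject statistic.
3. **Dimension = log–log slope.** Occupied-box counts `n(r)` on grids of
   `r = 1, 2, 4, …, 128` divisions per axis are fitted by unweighted least
   squares of `log n(r)` on `log r` over `r = 8 … 64`; the slope is the FD.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_seconds` | 1 | s | the windowing the measure is defined on; 120 values per 120-s epoch |
| `resolutions` | `2^(0:7)` | grid divisions/axis | dyadic ladder up to 128; finer grids only count isolated points |
| `fit_range` | `c(8, 64)` | divisions/axis | the scaling regime between the trivial coarse grids and point-isolation saturation |
| `normalization` | `"subject"` | — | each subject's own bounding box; `"cohort"` pools boxes for cross-subject geometric comparability |

The fit range matters most. Below `r = 8` the counts are dominated by the
gross extent of the activations; above `r = 64` a finite cloud saturates
toward one box per point and the local slope decays to 0. Desk-scale clouds
(≈ 2–3 × 10⁴ points/window) already feel the saturation inside `8…64`, which
is why desk-scale FDs (≈ 1.2) sit lower than full-scale ones — the measure
is comparable *within* a run of fixed geometry, which is how it is used.

## Numerical choices

* **SD convention**: sample SD (N−1 denominator), fixed and documented.
* **Strict inequality**: a source exactly at threshold is inactive; a
  constant-magnitude source (SD 0) therefore never activates.
* **Half-open `[0, 1)` everywhere**: bounding-box maxima map to the largest
  double below 1, so the top boundary falls in the last box; cell index is
  `floor(coord · r)`, clamped to `r − 1` against floating-point round-up.
* **Empty windows**: FD is defined as 0 with a warning rather than dropping
  the window, keeping the per-second series aligned across subjects. A
  fitted slope outside `[0, 4]` is an error, never silently clipped.
* **Counting kernel**: each point maps to a mixed-radix 64-bit cell key;
  distinct keys are counted by sort + unique (C++). No `r^dim` occupancy
  array is ever allocated (`128^4` would need 2.7 × 10⁸ cells). The kernel
  is contract-checked against a brute-force tuple-set oracle in the tests.
* **Regression**: unweighted least squares on `log n(r)` vs `log r`
  (equivalent to the `log(1/r)` form up to sign; the slope is reported
  positive).
* **Exact vs approximate U test**: exact enumeration p (via the null U
  distribution) when `n1·n2 ≤ 400` and the pooled sample is tie-free,
  otherwise the tie-corrected normal approximation without continuity
  correction. U is reported max-oriented (≥ n₁n₂/2) with a direction flag.
* **PCA on z-scored variables**: the clinical instruments have incomparable
  scales, so standardization is forced.

## What the synthetic generator emulates — and what it does not

`simulate_epoch()` targets the statistical structure the analysis is
sensitive to, not biophysics. Sources sit on a radially deformed sphere
(radius ≈ 80 mm). `n_clusters` Gaussian bumps of spatial scale `dispersion`
(mm) ride on i.i.d. Gaussian noise; bump amplitudes follow an
Ornstein–Uhlenbeck process (time constant 0.2 s) so thresholds select
temporally coherent blobs, and bumps relocate with probability
`temporal_jump_rate` per sample. Defaults (desk scale): 2,000 sources,
100 Hz, 20 s, 3 clusters, jump rate 0.02/sample, noise SD 0.25 against a
mean bump amplitude of 1. The two groups differ only in dispersion — 30 mm
(patient-like group A) vs 15 mm (control-like group B), a 2× ratio chosen
once as the documented effect size. `paper_scale = TRUE` restores the
full-study geometry (15,002 sources, 500 Hz, 120 s; ≈ 7 GB per epoch
matrix).

One property deserves emphasis because it is easy to get wrong: the
epoch-wide mean + SD rule is **rate-equalizing**. Every source — bump member
or pure-noise — activates at roughly the folded-normal fraction
(≈ 16 %) of samples. A cluster therefore does *not* show up as an elevated
activation rate; it shows up as **synchrony**: sources inside a bump share
its amplitude fluctuations and activate at the same samples. Wider, more
mobile bumps spread these synchronized activations over more space and more
of the time axis, occupying more boxes — that is the mechanism by which
dispersion raises 4DFD, and it is what the property tests assert. A
noise-free static bump is degenerate under this rule (the signal is rank-1
in space, so all sources cross threshold at the same samples), which is why
no test uses that configuration.

What a green test does **not** establish: realism of cortical geometry,
volume-conduction leakage, 1/f spectra, or any claim that real patient
groups differ — only that the pipeline detects the dispersion structure it
is built to detect, reproducibly under a fixed seed.

`simulate_scores()` is a one-factor model over UPDRS-III-, MoCA-, MMP- and
Hoehn–Yahr-like columns (cognitive instruments load negatively), with a
configurable latent correlation to mean 4DFD (default 0, a null
construction). With loading 0.95 on 4 standardized instruments the PC1
variance fraction converges to `(1 + 3·0.95²)/4 ≈ 0.93`.

## Known limitation: dyadic grids on base-3 fractals

The validation families include products of middle-thirds Cantor sets, whose
analytic dimension is `d·log 2/log 3`. Exact enumeration of the true Cantor
set shows its *dyadic* box counts over `r = 8, 16, 32, 64` are
6, 10, 16, 28 — a local slope of 0.7345 per axis, not 0.6309. This is a
property of short dyadic scaling ranges on base-3 self-similar sets
(log-periodic oscillation of the count ratio), not of the estimator: the
estimator reproduces the exact-set counts to better than 0.01 and is tested
against that oracle. Consequently a Cantor product measured with this
package's (deliberately standard) resolution ladder reads ≈ 0.73·d, and the
acceptance expectation of recovering `0.63·d ± 0.15` is left failing by
design. The Sierpinski-carpet extrusion, whose exact dyadic slope (2.923)
happens to sit near its analytic dimension (2.893), is recovered within
tolerance.

Relatedly, a "filled" hypercube is represented as a regular lattice
(`make_fractal(..., lattice = TRUE)`): a lattice of 64 points per axis gives
exactly `r^dim` occupied boxes for `r ≤ 64`, whereas i.i.d. uniform
sampling would need tens of millions of points in 4D before Poisson
coverage stops biasing the slope (at 10⁶ random points the 4D slope reads
≈ 2.7, not 4).

## Design choices where the design was open

* **Time-axis scaling.** Nothing pins the relative scale of time vs space
  before 4D counting. The package scales the within-window sample index to
  `[0, 1)`, symmetrically with the spatial axes — the least-arbitrary
  choice, and configurable only through the window length.
* **Normalization frame.** Per-subject bounding box by default (all
  sources, not only active ones, so all windows of a subject share a
  frame); a cohort-pooled box is available for cross-subject geometry.
* **Bonferroni multiplier** = number of score–FD pairs tested in one call,
  recorded as an attribute of the result.
* **Two-sided tests throughout**; chi-squared without Yates correction by
  default (flag available).
* **Per-subject seeds** are derived from the master seed by multiplicative
  mixing modulo 2³¹−1, so cohorts are reproducible subject-by-subject and
  streams stay inside R's 32-bit seed range.

## Limitations

* Desk-scale FD values are depressed by point-count saturation inside the
  fit range (see above); compare FDs only across runs of identical
  geometry.
* The U-test exact path requires a tie-free pooled sample; midrank ties fall
  back to the normal approximation even at small n.
* `paper_scale` epochs are memory-hungry (≈ 7 GB per values matrix) and are
  not exercised by the test suite.
* Gray-scale (differential) box counting and alternative complexity
  measures (correlation dimension, Higuchi FD, entropies) are out of scope.
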