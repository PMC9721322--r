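---
title: "Robust bad-pixel mask generation: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust bad-pixel mask generation: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustmask)
```

## The problem

Megapixel X-ray detectors used in serial crystallography — integrating
detectors such as AGIPD or JUNGFRAU, counting detectors such as PILATUS or
EIGER — contain pixels whose readout misbehaves: abnormal dark offsets,
abnormal temporal noise, stuck values, indistinguishable or shifted gain
stages, and pixels that are too bright or too dim too often under
illumination.  Unmasked, such pixels masquerade as Bragg peaks, inflate hit
rates with false positives, and depress indexing rates.  For detectors with
hundreds of analogue memory cells and several gain stages, drawing masks by
hand is impractical; the masking must be automatic, per memory cell and per
gain stage.

`robustmask` builds such masks from two easy-to-collect data sets: frames
recorded in the dark, and frames recorded under approximately uniform
("flat-field") illumination, e.g. foil fluorescence.

## The model

The central assumption is that the *majority* of pixels behave normally and
that a normal pixel's feature values follow an approximately Gaussian
distribution.  Bad pixels are whatever does not fit that model; no attempt
is made to model defect behaviour itself.  For a feature vector
$x = \{x(i)\}$ a Gaussian is fitted robustly, giving a robust average
$\mu_R$ and robust scale $\sigma_R$ of the inlier mode, and each element is
scored by its statistical separability

$$\mathrm{SNR}(i) = \frac{x(i) - \mu_R}{\sigma_R},$$

with $x(i)$ an inlier iff $|\mathrm{SNR}(i)| < \lambda$.  A single global
threshold $\lambda$ (default 8.0) governs every decision in the pipeline,
which is what makes the method essentially parameter-free in routine use:
at $\lambda = 8$ a truly Gaussian population contributes false positives at
rate $P(|Z|\ge 8) \approx 1.2\times10^{-15}$, so everything flagged is far
outside normal behaviour, while the robustness of the fit ensures
$\sigma_R$ is not inflated by the defects themselves (a non-robust fit
inflates the scale, hides defects, and forces per-data-set parameter
tuning).

### The robust estimator

The location/scale estimator is deterministic and median-anchored.
Starting from the median, absolute residuals are sorted and the accepted
set grows from the minimal admissible size
$\lceil f_{\min} n \rceil$ (default $f_{\min} = 0.5$, the maximal-breakdown
choice) while the next residual is within $k_{\mathrm{grow}} = 3$ running
standard deviations of the accepted set.  The pass is iterated with the
accepted-set mean as the new centre until the centre converges; without
this iteration a single pass retains an appreciable location bias when the
contamination is strongly one-sided.  Because the accepted set is a
truncated Gaussian, its standard deviation is deflated; the truncation
radius $R$ (the largest accepted residual) is inverted through the
truncated-normal variance factor
$g(z)^2 = 1 - 2z\phi(z)/(2\Phi(z)-1)$ by solving
$\sigma = s_{\mathrm{acc}}/g(R/\sigma)$ self-consistently.  Estimating the
truncation point from the radius, rather than from the accepted *fraction*,
is essential: the accepted fraction under-counts the inlier coverage when
genuine outliers are present and would inflate $\sigma$ by more than a
factor 2 at 40% contamination.  As implemented, for 2000 inliers plus up to
40% contamination at $50\sigma$ the location error stays below $0.1\sigma$
and the scale ratio within about $[0.95, 1.05]$ (the test suite asserts
$[0.8, 1.2]$).

An independent brute-force reference, `oracle_fit_gaussian()`, scans every
contiguous window of the sorted sample of every admissible size, scoring
each window by the complete-data likelihood of a two-component mixture:
Gaussian inliers (window members, with the truncation-corrected scale,
the truncation point solved by bisection from the window radius) and
uniform outliers over the data range, each weighted by its mixing
proportion.  The mixing terms matter — without them the score prefers
tight inner windows even on clean data.  The reference shares no code
path with the fast estimator and anchors the oracle-equivalence test.

### Features

For each (module, memory cell, gain stage) context:

* **Frame quality (F1).** The robust mean over all pixels of each frame;
  frames whose mean is an outlier (beam trips, common-mode excursions) are
  discarded.  An optional cap retains the most typical frames — facility
  dark runs of 512 frames are commonly reduced to 200 this way.
* **Dark offset (F2).** The per-pixel temporal mean over retained dark
  frames.  Offsets vary smoothly *within* an ASIC, so the module is tiled
  into ASIC-aligned windows (default 64×64, never straddling an ASIC
  boundary) and a robust plane is fitted per tile; the SNR is the residual
  from the tile plane over the tile's robust residual scale.  Labelling is
  two-sided: an abnormally low offset is as much a defect as an abnormally
  high one.
* **Dark noise (F3).** The per-pixel temporal standard deviation, fitted
  globally per context.  Two-sided labelling flags both noisy pixels and
  zero-variance (stuck) pixels; a stuck pixel sits $\sqrt{2(T-1)}$
  population scales below the model, so stuck detection needs roughly
  $T \gtrsim 35$ dark frames at $\lambda = 8$.
* **Gain separability (F4).** Per pixel and stage, the temporal mean
  $\bar g_H$ and standard deviation $s_H$ of the gain-stage indicator; a
  pixel is masked when for any stage pair the gap
  $|\bar g_H - \bar g_{H'}|$ is within $k_{\mathrm{sep}}(s_H + s_{H'})$
  (touching 1-σ intervals, $k_{\mathrm{sep}} = 1$): such a pixel cannot
  tell its gain stages apart.
* **Gain level (F5).** The per-pixel temporal mean of the indicator for
  one stage, fitted globally; two-sided labelling.
* **Illuminated response (F6).** For every flat-field frame a plane is
  fitted robustly to each pixel's local window (15×15 by default; at least
  200 usable pixels) and the pixel's SNR against the plane is computed; the
  *non-robust temporal mean* of these SNRs is the feature, fitted globally
  and labelled two-sided.  A pixel that is modestly bright in most frames
  (flicker) accumulates a mean of (duty cycle × amplitude) while normal
  pixels concentrate at $0 \pm 1/\sqrt{T}$, so persistence, not amplitude,
  is what is detected.  The local plane absorbs smooth illumination
  gradients (a 20% ramp across the module adds no flags), and the SNR is
  invariant under affine rescaling of the frame values.

The final 8-bit mask is the bitwise OR of the per-feature labels: bit 0
marks insensitive ASIC-edge pixels (masked without analysis), bits 1–5 the
features above, bit 6 pixels that could not be analysed (pre-masked input,
starved tiles or windows — masked conservatively), bit 7 an externally
supplied manual mask.  Zero means good.  Masks are kept per memory cell and
gain stage, with a collapsed any-context mask for convenience, and written
to HDF5 with the bit legend and a configuration echo sufficient to
reproduce them.

## Counting detectors

Counting detectors report mostly zero in the dark, so the dark variance is
degenerate and the Gaussian scale cannot be estimated.  Setting
`counting_mode = TRUE` floors every fitted scale at $1/6$, so a pixel stuck
at count $v$ has SNR $6v$: at $\lambda = 8$ it is masked exactly when
$v \ge 2$ (the smallest integer with $6v \ge 8$).  The gain features do not
apply; offset, noise and illuminated features run unchanged.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lambda` | 8.0 | population σ | global outlier threshold, the only routine knob |
| `min_fraction_inliers` | 0.5 | fraction | assumed inlier share; bounds tolerable contamination |
| `min_scale` | 0 (1/6 counting) | feature units | floor on fitted scales for degenerate populations |
| `tile_size` | 64 | pixels | dark-offset plane window, ASIC-aligned |
| `half_width` | 7 | pixels | 15×15 illuminated-feature window (≥ 200 px) |
| `min_pixels` | 200 | pixels | minimum usable pixels per window |
| `stride` | 1 | pixels | block-sharing approximation of F6 for large modules |
| `max_frames` | none | frames | cap after frame filtering (200 reproduces facility practice) |
| `edge_width` | 1 | pixels | insensitive ASIC border masked without analysis |
| `k_grow`, `k_plane`, `k_sep` | 3, 4, 1 | σ | internal robustness margins; not routine knobs |

Two implementation choices deserve a note.  Windows at module borders are
*shifted inward* rather than clipped, so every window keeps its full area;
clipping would starve all windows near ASIC boundaries and module borders
below `min_pixels` and force conservative masking of wide stripes of good
pixels.  And inside the plane-fit trimming loop the residual scale is
estimated by the median/MAD with a final truncation-corrected trimmed
standard deviation; this is deterministic, consistent at the Gaussian, and
an order of magnitude cheaper than re-running the full estimator per
window, which matters when a plane is fitted for every pixel of every
frame.

## The synthetic detector

All validation runs on a seeded synthetic module; no facility data are
required.  The generator emulates: per-ASIC smooth offset planes (ramps up
to 0.01 ADU/pixel around 1000 ADU) with 2 ADU pixel scatter; 3 ADU dark
noise with 1 ADU common-mode frame jitter; gain-indicator levels
5000/7000/9000 with 10 units temporal noise and 5 units pixel scatter; a
500 ADU flat field with 10 ADU noise and an optional linear gradient;
anomalous frames as global shifts; and eight defect classes (hot/cold
offset, noisy, stuck, gain overlap, gain level shift, flicker, dead under
light) injected at configurable rates with amplitudes expressed in units of
the population scale of the feature that should detect them, so
detectability is scale-free by construction.  Identical configurations
generate bit-identical stacks.

What the generator does *not* emulate: charge sharing between pixels,
pedestal drift within a run, Poisson photon statistics (beyond the counting
mode's spurious counts), correlated electronic noise, and Bragg peaks in
the bright run (the tool assumes a crystal-free flat run, as documented).
Passing tests therefore demonstrate that the statistical machinery detects
the modelled defect phenomenology at the stated effect sizes — they do not
certify behaviour under detector pathologies outside that phenomenology.

## Validation and problem sizes

`validate_synthetic_recovery()` generates a full 128×512 module (2×8 ASICs
of 64×64) with 3 gain stages and 2 memory cells, 300 dark and 200 flat
frames per context, 0.5% defects per class at 12 population σ, runs the
whole pipeline and scores the collapsed mask against ground truth.  Across
5 seeds the test suite requires recall 1.0 for every class and a
false-positive fraction ≤ 10⁻⁴ among normal pixels; the illuminated
feature runs with stride 8 on the full module and densely (per-pixel
windows) on a 128×128 crop as a fidelity check of the approximation.
These sizes were chosen as the smallest configuration that exercises every
code path — multi-ASIC tiling, multi-cell, multi-stage, frame filtering,
both F6 modes — while estimating the false-positive bound with reasonable
power (about 6×10⁵ normal-pixel decisions across seeds).

Monotonicity in λ (masks at λ = 6 ⊇ 8 ⊇ 10) is checked on a fixed seeded
module with frame anomalies disabled, so the retained frame set is
identical at every λ and the comparison isolates the threshold; with frame
rejection active, a different retained set could legitimately perturb
features by fractions of a σ.

## Numerical choices and degenerate inputs

* Constant input: the estimator returns σ = 0 exactly; scoring then
  requires a positive `min_scale`, and `snr_scores()` says so.
* Exact planar windows: residuals are numerically zero; SNR denominators
  are floored at $10^{-9}$ of the window's value scale so that exact fits
  give SNR ≈ 0 rather than 0/0.
* Ties in the oracle's window scan break toward the smaller start index;
  the estimator itself is tie-stable because the merge outward from the
  centre prefers the left value at equal distance.
* Non-finite inputs are pre-masked everywhere: excluded from every mean,
  standard deviation and fit; pixels unevaluable in more than half of
  their frames (or in starved tiles) are masked conservatively under the
  not-evaluable bit.
* All estimators are deterministic; reproducibility of the synthetic data
  is per-context seeded, and parallelism over memory cells cannot change
  any output bit.

## Known limitations

* Defects below ~6 population σ are by design invisible at λ = 8; the
  generator warns when asked to inject them.
* Stuck-pixel detection in the dark needs $T \gtrsim 35$ frames (see F3).
* The gain-separability rule uses touching 1-σ intervals; indicator
  distributions with heavy non-Gaussian tails could defeat it.
* The flat-field analysis assumes a crystal-free, smoothly illuminated
  run; sharp illumination structure within a window would be flagged.
* Per-module processing assumes defects are independent across modules;
  system-wide common-mode pathologies only appear through F1.
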