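# robustmask

Automatic bad-pixel mask generation for X-ray pixel detectors used in
serial crystallography.

Megapixel detectors — integrating (AGIPD, JUNGFRAU, CSPAD) and photon
counting (PILATUS, EIGER) — contain pixels whose readout misbehaves:
abnormal dark offsets or noise, stuck values, indistinguishable gain
stages, responses that are too bright or too dim too often under
illumination.  Unmasked, these pixels are picked up as Bragg peaks,
inflate hit rates with false positives and depress indexing rates.  With
hundreds of analogue memory cells and several gain stages per pixel,
masking must be automatic, per memory cell and per gain stage.

`robustmask` builds masks from two easy-to-collect runs — dark frames and
near-flat-field frames — using robust statistics.  For each per-pixel
feature *x(i)* (dark offset, dark noise, gain-indicator separability and
level, mean separability from the local planar background under
illumination) a Gaussian is fitted robustly to the inlier majority, giving
a robust average μ_R and robust scale σ_R, and each pixel is scored by

    SNR(i) = (x(i) − μ_R) / σ_R

A pixel is masked when |SNR(i)| ≥ λ for any feature, with a single global
threshold λ = 8.0.  Because the fit is robust, σ_R is not inflated by the
defects themselves, which is what makes the procedure essentially free of
per-data-set tuning.  Masks are 8-bit codes (0 = good; one bit per
flagging feature, plus ASIC-edge, not-evaluable and manual bits), kept per
(memory cell, gain stage) and written to HDF5 together with the bit legend
and a configuration echo sufficient to reproduce them.  Counting detectors
are handled by flooring fitted scales at 1/6, so a stuck count v has
SNR = 6v and is masked exactly when v ≥ 2.

## Worked example

A complete synthetic module — dark, gain-indicator and flat-field stacks
with injected ground-truth defects — is generated in a few lines; no
facility data are needed.

```r
library(robustmask)

layout <- detector_layout(32, 32, 2, 2)   # 64 x 64 module, 2 x 2 ASICs
sim <- sim_config(layout = layout, T_dark = 100, T_flat = 60, seed = 7)

gains <- generate_gain_stacks(sim, memory_cell = 0)
flat <- generate_flat_stack(sim, memory_cell = 0)

contexts <- lapply(names(sim$gain_levels), function(s) {
  list(memory_cell = 0, gain_stage = s,
       dark = generate_dark_stack(sim, 0, s)$stack,
       gain = gains$stacks[[s]],
       flat = if (s == "high") flat$stack)
})
mm <- build_module_mask(contexts, layout, fit_config())
mm
#> <module_mask>  3 context(s): cell0_high, cell0_medium, cell0_low
#>   any-context bad pixels: 640 of 4096 (15.62%)

summarize_mask(mm$collapsed, layout)
#> <mask_summary>  4096 pixels, 640 bad (15.62%)
#>  bit              flag count    fraction
#>    0         asic_edge   496 0.121093750
#>    1            offset    36 0.008789062
#>    2             noise    36 0.008789062
#>    3 gain_separability    18 0.004394531
#>    4        gain_level    36 0.008789062
#>    5       illuminated    36 0.008789062
```

The 496 edge pixels are the insensitive ASIC borders (masked without
analysis); the remaining counts are exactly the injected defects: 18
pixels per class (0.5% of the 3600 non-edge pixels, rounded), two classes
per bit — hot and cold offsets under `offset`, noisy and stuck under
`noise`, gain-level shifts and overlaps under `gain_level` (overlap pixels
are also caught by `gain_separability`), flickering and dead pixels under
`illuminated`.  `write_mask()` stores the result as HDF5;
`tidy()`/`glance()` and `autoplot()` expose masks, feature maps and
summaries as tibbles and ggplots.

A command-line front end ships in `inst/cli/rmm.R`:

```sh
Rscript inst/cli/rmm.R simulate  --output sim/ --seed 1 --cells 2
Rscript inst/cli/rmm.R make-dark --config sim/run.yaml --output mask_dark.h5
Rscript inst/cli/rmm.R make-flat --config sim/run.yaml --output mask_flat.h5
Rscript inst/cli/rmm.R combine   --inputs mask_dark.h5,mask_flat.h5 \
                                 --config sim/run.yaml --output mask.h5
Rscript inst/cli/rmm.R summarize --input mask.h5
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "robustmask",
                   load_package = "installed")
```

The suite covers the robust core (contamination up to 40% at 50σ,
equivalence with a brute-force window-scan reference, affine
equivariance), every feature on constructed and generated stacks,
mask-bit arithmetic, HDF5 round-trips (cross-checked against h5py), the
CLI, and end-to-end defect recovery on full synthetic modules.

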