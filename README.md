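# y90quant

Quantitative analysis of yttrium-90 bremsstrahlung SPECT/CT for hepatic
radiomicrosphere therapy (radioembolization), with a synthetic-phantom module
that makes every stage testable without clinical data.

## The problem

After ⁹⁰Y microsphere therapy of liver tumors, the only routinely available
image of where the spheres actually lodged is bremsstrahlung SPECT/CT.
Because ⁹⁰Y emits no photopeak — the detected x-ray spectrum is continuous —
these images have poor contrast and resolution, which limits their use for
verifying the pre-treatment ⁹⁹ᵐTc-MAA plan and for voxel-level dosimetry.
This package implements a practical post-reconstruction pipeline for that
setting:

1. **Contrast recovery.** Richardson–Lucy deconvolution with a Gaussian
   collimator–detector PSF,
   `A'_i = [A / (A'_{i-1} ⊗ PSF) ⊗ PSF] · A'_{i-1}`, `A'_0 = A`,
   with the stopping iteration chosen on a hot-sphere phantom: the iteration
   where the contrast recovery coefficient
   `Q_H = 100 (C_S/C_B − 1)/(R − 1)` of the largest sphere peaks while the
   RMSE between consecutive estimates is still declining.
2. **Calibration and activity.** The calibration factor CF (cps/MBq) is the
   slope of an OLS regression of reconstructed counts on administered
   activity (whole field of view, or liver VOI only); voxel values divided
   by CF give MBq, and `%error = (true − estimated)/true × 100`.
3. **Registration selection.** Candidate co-registrations of the MAA and
   ⁹⁰Y studies are ranked by mutual information
   `I(A,B) = H(A) + H(B) − H(A,B)` (bits, shared joint histogram).
4. **Segmentation and TLR.** Chan–Vese two-phase active-contour delineation
   of high-uptake regions inside the liver VOI; the tumor-to-liver ratio is
   the ratio of mean counts per voxel, tumor over healthy liver.
5. **Dosimetry.** Voxel S-value convolution `D = Ã ⊗ S` with kernels
   linearly interpolated between tabulated voxel sizes, cumulated activity
   `Ã = A₀·T½/ln2` (permanent implant, physical decay only), cumulative
   DVHs and isodose levels.

A digital Jaszczak phantom (eight spheres, 2–34 mm, 13:1 hot ratio) and
paired MAA-like/⁹⁰Y-like liver studies with known ground truth (true TLR,
true transform, true activities) drive the tests and the acceptance script.

## Worked example

```r
library(y90quant)

qc <- run_phantom_qc(jaszczak_phantom_spec(),
                     model = acquisition_model(cf = 9049, psf_fwhm = 12,
                                               noise = "poisson", seed = 1),
                     psf = psf_model(12), max_iterations = 15)
print(qc)
```

```
<phantom_qc_report> CF = 8536 cps/MBq, iteration 15 selected on d34
 sphere qh_initial qh_selected activity_error_pct
    d34       67.6        85.9                 12
    d31       65.4        86.1                 15
    d25       54.8        78.8                 17
    d16       35.8        73.3                 33
    d12       23.6        58.1                 44
    d10       16.7        45.3                 80
     d8        8.3        19.1                 90
     d2        0.2         0.2               -162
```

Reading: the phantom calibration factor (total counts over true activity)
came out at 8536 cps/MBq; deconvolution raised the 34 mm sphere's contrast
recovery from 68% to 86% of the true 13:1 contrast, recovery shrinks with
sphere size, and the 2 mm sphere — far below the 12 mm FWHM resolution — is
not recovered at all. Per-sphere activity errors are largest for the small
spheres, as expected from partial-volume effects.

A command-line front end over the same functions is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/y90quant-cli.R", package="y90quant"))')" \
    qc-run --out-dir qc --seed 1
```

## Bundled data

`inst/extdata/` contains small plain-text inputs: the patient
administered/estimated activity table and the paired-volume summary used by
the error-accounting examples, the phantom sphere activity table, and two
**synthetic** voxel S-value kernels (3 mm and 6 mm, energy-conserving
exponential fall-off, labelled `_synthetic`) that exercise the kernel
interpolation and dose engine. No published S-value tables are
redistributed; `read_kernel_csv()` documents the CSV schema for supplying
real ones.
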