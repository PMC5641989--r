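# ktqa — accelerated PC-CINE MRI analysis for local pulse wave velocity

`ktqa` measures **local pulse wave velocity (PWV)** — the speed of the
arterial pulse, a stiffness surrogate — from through-plane flow-encoded
phase-contrast cine MR images with the **flow–area (QA) method**: during the
reflection-free early systolic upstroke, volume flow Q and lumen
cross-sectional area A are linearly related and

PWV = dQ/dA.

It is written for small-animal cardiovascular MR work (murine abdominal
aorta at ultra-high field), where mapping the PWV *distribution* along the
vessel requires both fast acquisition and operator-free analysis. The
package provides:

- **k-t BLAST acceleration** — sheared-lattice k-t undersampling and x-f
  space unfolding with a central-line training estimate,
  ρ = M² 1ᴴ (1 M² 1ᴴ)⁻¹ ρ_alias, giving a 6× effective acceleration at
  r = 10 with 10 training lines — plus the fully sampled reference
  reconstruction with zero-filling and optional Fermi/Hann apodization;
- **voxel-wise velocity mapping** from three flow encodings
  (first moments −0.3/0/+0.3 s/m; phase convention φ = 2π m v) with a
  per-pixel R² screen (R² < 0.85 excluded) and volume-flow integration;
- **semi-automatic lumen segmentation** choosing the threshold τ that
  minimises the inter-encoding variance of thresholded pixel counts,
  arg min E[(P(τ) − E[P(τ)])²], with area = mean count × pixel area;
- **QA fitting** — 10–90 % upstroke detection and the Q(A) slope with its
  confidence interval;
- **agreement statistics** — Bland–Altman, regression concordance, paired
  t-test and the noncentral-t paired sample-size calculation;
- a **synthetic pulsatile-vessel phantom** with known ground-truth PWV
  (parabolic flow, inflow enhancement, complex Gaussian noise, seeded) that
  makes the whole chain testable without scanner data.

See the methods vignette (`vignettes/qa-pwv-methods.Rmd`) for the models,
the numerical choices, and a candid account of what the synthetic
validation does and does not establish.

## Worked example

```r
library(ktqa)

params <- acquisition_params()      # 22 mm FOV, 150->256, 1 ms frames
spec   <- phantom_spec(pwv_true = 3.5, seed = 1)
cine   <- render_cine(spec, params) # three flow encodings, SNR 30
kt     <- encode_kspace(cine)

qa_pipeline(kt, "full")             # fully sampled estimate
#> local PWV: 3.921 m/s (95% CI 3.810 - 4.033), R^2 = 1.000, frames 8-13

pattern <- make_lattice_pattern(150, 10, 10, 40)
effective_acceleration(pattern)
#> [1] 6

qa_pipeline(undersample(kt, pattern), "ktblast")  # 6x accelerated
#> local PWV: 5.995 m/s (95% CI 4.860 - 7.131), R^2 = 0.982, frames 8-13

sample_size_paired_t(0.5, 0.5, alpha = 0.05, power = 0.8)
#> [1] 10
```

The fully sampled estimate recovers the 3.5 m/s ground truth to ~12 % on
this seed (median ~8 % across the recovery grid; repeatability SD
0.05–0.17 m/s). The residual bias is the area-pulse transfer of threshold
segmentation at this vessel-to-resolution ratio (radius ≈ 3.4 acquisition
pixels, systolic radius change ≈ 0.2 pixels). The accelerated estimate
reads high because the x-f unfolding adaptively attenuates the weak edge
dynamics carrying A(t) while the strong bulk flow signal passes — both
effects are quantified in the vignette. The sample-size call reproduces the
protocol's n = 10 animals for detecting a 0.5 m/s difference (SD 0.5 m/s,
α = 0.05, power 0.8).

A thin command-line front end over the same functions ships in
`inst/cli/ktqa.R` (`simulate`, `reconstruct`, `segment`, `pwv`, `compare`).

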