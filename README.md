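# luquant

Multi-photopeak activity and depth quantification for Lu-177 planar imaging
with a small pixelated CZT gamma-camera.

## The problem

Planar count rates from a Lu-177 source depend strongly on how much tissue
sits between the source and the collimator, so a raw count rate is not a
measure of activity. Lu-177 emits photons at three energies — 55-keV
characteristic X-rays and 113- and 208-keV gammas — that tissue attenuates
to different degrees. From the *relative* count rates in the three photopeak
windows of a single planar acquisition, the source depth can be estimated,
the attenuation corrected, and the activity recovered, without any extra
imaging. This package implements that multi-photopeak method for a hand-held
camera whose 16×16-pixel CZT detector records a full 0.1-keV-binned energy
spectrum per pixel, making it useful for quantifying superficial lesions in
patients and subcutaneous tumours in small animals.

## The method

The measured ROI count rate in photopeak window *i* is modelled as

    R_i(A, d) = A · ε_i(d) · exp(−d·μ_i) · B_i(d·μ_i)

where `A` is the source activity (MBq), `d` the depth from the collimator
face to the nearest source surface (mm), `ε_i(d) = c0 + c1·exp(−d·c2)` the
distance-dependent system sensitivity (distance-dependent for this camera
because of septal penetration), `μ_i` the linear attenuation coefficient of
the medium at the window's photon energy, and `B_i(x) = 1 + k_i·x` a linear
build-up factor. Scatter is optionally removed first with the
triple-energy-window (TEW) estimate — the trapezoid spanned by narrow
windows flanking each photopeak. `(A, d)` are then estimated jointly by
weighted nonlinear least squares over the windows (damped least-squares
scheme, weights from the measured count rates), starting from a linearized
estimate at a fixed 20-mm depth. Calibration (`c0, c1, c2` per window from
an in-air distance series; `k` from a PMMA transmission series) and a
Poisson-noise simulator of the whole chain are included.

## Worked example

Simulate a 10-MBq source at 20-mm depth in soft tissue, reduce the spectral
image to TEW net rates, and estimate activity and depth:

```r
library(luquant)

truth  <- synthetic_truth_calibration("MEGP", scatter_corrected = TRUE)
tissue <- material_library()$soft_tissue
mu     <- linear_attenuation(tissue)   # mm^-1: 0.0223 / 0.0172 / 0.0141

spec <- scenario_spec(true_A = 10, true_d = 20, material = tissue,
                      calibration = truth, duration_s = 300, seed = 7,
                      image = list())
img <- simulate_spectral_image(spec)   # 16 x 16 x 2500 counts, 61,532 total
ms  <- measure_spectral_image(img)     # windowing -> auto ROI -> TEW
ms
#> <measurement_set> MEGP (TEW), 300 s
#>  window rate_cps  variance clamped
#>      55 29.44496 0.2317896   FALSE
#>     113 64.20671 0.4068156   FALSE
#>     208 49.62459 0.2060153   FALSE

res <- estimate_activity_depth(ms, mu, truth, weight_mode = "provided")
res
#> <quantification_result> A = 10.34 +/- 0.48 MBq, d = 20.97 +/- 1.5 mm
#>   chi2 = 1.877, 5 iterations, converged: TRUE
#>   windows: 55, 113, 208 | weights: provided

relative_deviation(res$A, 10)   # +3.4% activity deviation at this seed
depth_error(res$d, 20)          # +0.97 mm depth error
```

The estimate recovers the true activity within its standard error: the
three measured rates over-determine the two parameters, and the differential
attenuation between 55 and 208 keV pins the depth. A command-line interface
wrapping the same functions (`calibrate-sensitivity`, `calibrate-buildup`,
`quantify`, `simulate`) ships in `inst/cli/luquant.R`.

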