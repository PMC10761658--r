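---
title: "Multi-photopeak activity and depth quantification for Lu-177 planar imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-photopeak activity and depth quantification for Lu-177 planar imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luquant)
```

## The problem

Planar gamma-camera counts of a Lu-177 source depend on how much tissue lies
between the source and the collimator: a superficial lesion and a deep one
with the same activity produce very different count rates. Conventional
planar quantification removes this dependence with extra imaging (conjugate
views, a CT for the attenuation map). For a small hand-held camera that is
often impractical — but its pixelated CZT detector stores a full energy
spectrum per pixel, and Lu-177 conveniently emits photons at three energies
(the 55-keV characteristic X-rays and the 113- and 208-keV gammas) that are
attenuated by tissue to *different* degrees. The relative count rates of the
three photopeaks therefore encode the source depth, and once the depth is
known the attenuation can be corrected and the activity recovered — all from
a single acquisition.

`luquant` implements this multi-photopeak method: per-pixel spectra are
reduced to photopeak-window count rates, scatter is estimated with the
triple-energy-window (TEW) method, and activity $A$ and depth $d$ are
estimated jointly through a calibrated forward model.

## The forward model

For photopeak window $i \in \{55, 113, 208\}$ the modelled count rate is

$$R_i(A, d) = A \; \varepsilon_i(d) \; e^{-d\mu_i} \; B_i(d\mu_i),$$

with four factors:

* **Activity** $A$ (MBq) — the model is linear in $A$, which gives the
  estimator its scale equivariance.
* **Distance-dependent system sensitivity**
  $\varepsilon_i(d) = c_{0,i} + c_{1,i}e^{-d\,c_{2,i}}$ (cps/MBq), the
  exponential-plus-floor form used for planar sensitivity characterization.
  For a conventional parallel-hole camera $\varepsilon$ is nearly constant;
  for this compact camera septal penetration and collimator scatter make it
  fall off with distance, most strongly for the LEHR collimator at 208 keV.
* **Attenuation** $e^{-d\mu_i}$, with $\mu_i$ the linear attenuation
  coefficient of the intervening medium at the window's photon energy.
  $d$ is the distance from the collimator face to the *nearest* surface of
  the source (not an effective depth).
* **Build-up** $B_i(x) = 1 + k_i x$ in the dimensionless product
  $x = d\mu_i$: broad-beam transmission exceeds the narrow-beam exponential
  because scattered photons re-enter the window. When TEW correction is
  applied the build-up slope shrinks but is retained, because TEW does not
  fully discriminate scatter in CZT spectra (worst at 55 keV, where
  low-energy tailing contaminates the scatter windows).

Depth is identifiable only because $\mu_{55} > \mu_{113} > \mu_{208}$ for
tissue-like materials; the estimator refuses to run when the included
windows' coefficients agree within 1%.

## Spectral reduction

The camera records counts for each of $16\times16$ detector elements in
0.1-keV bins from 0 to 250 keV. Windows follow a half-open $[lo, hi)$
convention so the abutting lower-scatter / main / upper-scatter windows of a
photopeak can never double-count a bin — the default window set places, for
example, the 113-keV main window at 100.5–120.8 keV flanked by 96.5–100.5
and 120.8–124.8 keV scatter windows. ROIs are circles placed automatically
at the count-weighted centre of mass of the 113-keV-window image with radius
= source radius + FWHM/2, and the *identical* circle is reused for every
window: septal-penetration counts are spatially broad, so sensitivity
calibration and quantification must share one delineation rule. Membership
is pixel-center-in-circle with a 2.46-mm pitch — the simplest rule that is
exactly reproducible on a 16×16 grid; partial-area weighting was rejected as
spurious precision at this resolution.

TEW estimates the scatter under a peak as the trapezoid spanned by the two
flanking windows, $R_{sc} = (R_l/w_l + R_u/w_u)\,w_m/2$. Net rates are
clamped at zero and flagged: a scatter overestimate must degrade gracefully
rather than feed a negative rate to the estimator, and clamped windows are
excluded from the fit (a clamped zero has no defined weight). Uniformity
corrections are user-supplied per (radionuclide, collimator, window) and
applied multiplicatively; since corrected counts are no longer Poisson, ROI
variances are propagated from the raw counts times the squared correction.

## Calibration

Two characterization series calibrate the model per window, collimator,
scatter-correction mode and source geometry:

* **Sensitivity**: in-air acquisitions of a known activity at distances
  0–160 mm, fitted by ordinary (unweighted) nonlinear least squares.
  Initialization follows the characterization convention: $c_0$ starts at
  the lowest measured sensitivity and $(c_1, c_2)$ from a log-linear
  regression of the excess over it (points where the excess is non-positive
  are excluded). A series with no resolvable exponential is flagged
  degenerate rather than silently fitted.
* **Build-up**: a fixed-distance series through 0–90 mm of PMMA. With the
  PMMA parametrization ($\rho = 1.18$ g/cm³; $\mu/\rho$ = 0.20, 0.16,
  0.13 cm²/g at 55, 113, 208 keV) this spans $d\mu$ from 0 to 2.1 at
  55 keV. Empirical factors $B(s\mu) = R(s)/R(0)\,e^{s\mu}$ are fitted by
  $B = 1 + kx$ with the intercept *fixed* at 1 — $B(0)=1$ is an identity of
  the definition, so fitting an intercept would only launder noise from the
  $s=0$ reference into the slope.

Fitted pairs live in a calibration library keyed exactly by (radionuclide,
collimator, window, scatter mode, geometry). Lookups never default: a
missing key is an error listing what exists, a gross-mode quantification
cannot use TEW-mode entries, and cross-geometry lookups are refused without
an explicit override because source size changes the septal-penetration
fraction (a recovery-curve-like size dependence, strongest for LEHR at
208 keV).

Mass attenuation coefficients for water, soft tissue and cortical bone are
log-log interpolations of the standard NIST/ICRU-44 tables at the three
photopeak energies; PMMA is pinned to the printed calibration
parametrization above so the build-up range reproduces exactly. Mixtures
(e.g. 50% tissue / 50% cortical bone for skeletal lesions) combine
$\mu/\rho$ mass-weighted with density $1/\sum_j w_j/\rho_j$.

## The estimator

Given measured rates $R_{i,\mathrm{meas}}$, the package minimizes

$$\chi^2(A, d) = \sum_i \frac{(R_{i,\mathrm{meas}} - R_i(A, d))^2}{\sigma_i^2}$$

with a damped least-squares (gradient-expansion) scheme: damping factor
×10 on a failed step, ÷10 on success, convergence when the relative change
of both parameters falls below $10^{-8}$, at most 200 iterations, analytic
Jacobian. Three weighting modes are provided. The default takes
$\sigma_i^2 = R_{i,\mathrm{meas}}/t$ (Poisson variance of a rate); a literal
inverse-measured-count-rate mode ($\sigma_i^2 = R_{i,\mathrm{meas}}$) is
identical up to a global factor when all windows share one duration and so
has the same optimum; a third mode uses the TEW-propagated variances, which
additionally carry the scatter-window noise.

Startup uses the linearized model at a fixed depth $d_\mathrm{fix} = 20$ mm
(configurable): $\log(R_i/\varepsilon_i(d_\mathrm{fix}))$ is regressed on
$-\mu_i$, giving $d$ as the slope and $\log A$ as the intercept. Because an
arbitrary calibration can put that linearization in the wrong basin, the
fit is additionally seeded from a coarse depth profile — the model is linear
in $A$, so the profiled optimum $A(d)$ is closed-form on a 1-mm grid — and
the better of the two converged fits is returned. Against an exhaustive
$(A, d)$ grid search at 0.1% × 0.1 mm resolution the fit agrees in every
tested scenario; agreement is assessed in $\chi^2$ because the $(A, d)$
confidence region is a diagonal valley, so no grid can localize the
*parameters* beyond the resolution the objective itself supports.

The fit is unconstrained by default: when the relative rates deviate from
what the model predicts at any positive depth (e.g. excess 55-keV counts),
the minimum lies at $d < 0$ and the result is flagged `negative_depth`
rather than hidden — this reproduces a real failure mode of the method. A
bounded mode reparameterizes $d = q^2$, keeping the objective smooth while
confining the depth to $d \ge 0$; constructed pathological scenarios then
converge to the $d = 0$ boundary.

Two post-corrections are available: decay correction
$A \cdot 2^{\Delta t/T_{1/2}}$ with $T_{1/2} = 6.4$ d, and an intra-source
self-attenuation factor for calibration/measurement source-thickness
mismatch. The latter models each source as a uniform slab viewed face-on
with mean escape probability $f(T) = (1-e^{-\mu T})/(\mu T)$ and multiplies
the activity by $f(T_\mathrm{cal})/f(T_\mathrm{meas})$; this slab form is a
documented modelling choice — the real sources are cylinders and spheres,
for which the correction is approximate.

## What the simulator emulates — and what it does not

The generator draws everything from the forward model with Poisson noise:
window-rate measurements, in-air sensitivity series on the 0–160 mm grid,
PMMA build-up series on the 0–90 mm grid, and full per-pixel spectral
images. In an image, each window's expected counts are spread spatially as
an isotropic Gaussian (linear resolution model FWHM $= a + b\,d$, defaults
4 mm + 0.05·d, truncated to the detector and renormalized), uniformly
across the window's 0.1-keV bins, on top of an optional uniform background
fraction; every (pixel, bin) cell is Poisson sampled from one recorded
seed. Scatter is injected as an explicit per-window fraction of the primary
rate (synthetic defaults 0.6 / 0.25 / 0.10 for 55 / 113 / 208 keV,
reflecting that contamination is worst at 55 keV), with scatter-window
rates chosen so the TEW trapezoid removes exactly the injected fraction in
expectation.

The truth calibration constants are synthetic — order-of-magnitude
realistic for this camera class (sensitivities of a few to tens of cps/MBq,
distance dependence strongest for LEHR at 208 keV, build-up slopes larger
in gross mode) — since no instrument characterization is shipped.

The simulator deliberately does **not** model CZT low-energy tailing,
septal-penetration star patterns, collimator X-ray fluorescence, dead time,
or energy-calibration drift. Passing tests therefore demonstrate that the
estimation chain correctly inverts its own physics under counting noise;
they do not demonstrate accuracy on real CZT spectra, where TEW residuals
and penetration backgrounds are the dominant error sources.

## Numerical choices and problem sizes

* Window bounds live on the 0.1-keV bin grid; off-grid bounds are errors,
  not rounded.
* Poisson draws switch to a moment-matched normal above a mean of $10^7$
  counts (integer overflow territory), used only by
  law-of-large-numbers checks.
* Degenerate inputs fail loudly: all-zero images, empty ROI membership,
  missing $s=0$ build-up reference, non-positive uniformity entries,
  sub-1% spread in $\mu$.
* The test and acceptance workloads use 100 noise-free recovery scenarios,
  50 grid-oracle scenarios at ~20,000 counts in the 113-keV window (the
  statistics of a typical patient acquisition), 100-seed calibration
  closure, and 50 end-to-end spectral replicates at 10 MBq / 20 mm /
  300 s — sizes chosen to make Monte-Carlo standard errors small against
  the tested tolerances while keeping the default suite fast.

## Known limitations

* Accuracy on real data is bounded by how well TEW + linear build-up
  absorb the camera's true scatter and penetration response; the package
  reproduces the method, not the instrument.
* The sensitivity model is fitted per discrete source geometry; sources
  unlike any calibrated geometry require an explicit override and judgment.
* The intra-source correction assumes slab geometry and face-on viewing.
* Uniformity arrays are consumed, never derived; energy recalibration is
  reduced to an optional whole-bin global shift on read.
* The spectral-image reader supports the open CSV + YAML dialect only.
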