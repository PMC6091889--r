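---
title: "Methods: foveal spatial summation and the computational observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foveal spatial summation and the computational observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovsum)
```

# The scientific problem

Ricco's law states that, at detection threshold, luminous energy falling
within a critical retinal area is pooled completely: below that area,
threshold energy (luminance × area × duration) is constant, and beyond it
sensitivity gains with size diminish.  In the central fovea the estimate of
this *Ricco's area* is confounded by two preneural factors — optical blur,
which sets a floor on the retinal size of any stimulus, and fixational eye
movements, which smear a brief stimulus across photoreceptors.  `fovsum`
implements the full analysis chain used to separate those factors from
postreceptoral neural pooling: adaptive-optics-style psychophysics analysis
on one side, and a physiologically-inspired computational observer on the
other, with synthetic generators of known ground truth connecting the two.

# The psychophysical path

## Psychometric model

Detection data are yes/no responses at 8-bit stimulus intensities in
$[0,1]$.  The psychometric function is a logistic
$$\psi(x) = \gamma + \frac{1-\gamma-\lambda}{1+e^{-\beta(x-\alpha)}}$$
fit by maximum likelihood (`fit_yes_no_psychometric()`), with the threshold
defined as the intensity detected on 78% of trials.  A yes-no task without
catch trials cannot identify the guess rate from data, so $\gamma = 0.03$
and $\lambda = 0.02$ are fixed defaults, overridable by argument.  The
likelihood is maximized with BFGS from five deterministic starts (location
quantiles crossed with a slope ladder); ties break by likelihood then by the
smaller $\alpha$, so fits are exactly reproducible.  Because thresholds span
about two decades across stimulus sizes, the session-level pipeline fits on
$\log_{10}$ intensity (`log10_intensity = TRUE`); the covariate choice is
exposed because slope parameters are only comparable within one convention.

Trials are collected by a Bayesian QUEST-style staircase
(`run_staircase()`): a uniform prior over a log-spaced intensity grid,
posterior updates with the same fixed-shape logistic, and each trial placed
at the posterior mode.  Twenty trials per staircase and three staircases per
size give the 60 trials/size used throughout.

## Two-segment regression and the bootstrap

`fit_two_segment()` regresses $\log_{10}$ threshold energy on $\log_{10}$
area with a flat first segment (slope fixed at zero), a free-slope second
segment, and continuity at the breakpoint; the breakpoint is Ricco's area.
All stimulus sizes enter the fit.  The breakpoint is found by a dense grid
(1000 candidates over the observed area range, closed-form conditional least
squares at each) plus local refinement, which makes the optimum global and
deterministic — a generic curve fitter can stall in the flat RSS valleys
this objective produces.  The search range is the data's own area range (the
bounds are not prescribed elsewhere); a fit whose breakpoint lands at the
range edge, or that fails to improve on a single flat line, is flagged
`boundary` rather than silently reported.

Precision comes from a stratified bootstrap (`bootstrap_ricco()`): trials
are resampled with replacement *within* each stimulus size, psychometric
functions refitted (warm-started at the point estimates), the curve rebuilt
and the two-segment model refitted, 500 times; intervals are the 5th to 95th
percentiles.  Replicates with degenerate refits (e.g. an all-yes resample)
are recorded as missing and a warning is raised if they exceed 5%.

Cone counts within an area use `round(area × density)` with exact halves
rounded away from zero — a tie rule that must simply be fixed and
documented.

# The computational observer

## Optics

PSFs are computed by the pupil-function method: the generalized pupil (unit
amplitude inside the aperture, phase $2\pi/\lambda \sum_j c_j Z_j$ from
OSA-indexed Zernike coefficients in microns) is Fourier transformed and
squared.  The aperture edge is anti-aliased with a one-sample ramp so that
radial metrics (first Airy zero at $1.22\,\lambda/D$, half-max width
$1.029\,\lambda/D$) are accurate within 2% at the default grids.  The
corrected condition uses diffraction-limited optics with an 8-mm pupil; the
natural-optics condition uses a 3-mm pupil with aberrations.  The exact
population-mean coefficient set that describes typical adult eyes is
external reference data, so `typical_aberrations()` ships an explicitly
illustrative synthetic set (~0.05 µm higher-order RMS over 3 mm); supply
measured coefficients for quantitative work.  The treatment is
monochromatic at 550 nm — the stimulus band is ±15 nm and the narrowband
approximation changes nothing at the precision tested.

## Cone mosaic and isomerizations

`build_hex_mosaic()` generates a hexagonal lattice whose spacing follows
from the areal density ($s = \sqrt{2/(\sqrt3\,\rho)}$), clipped to a square
field: 0.26° at 104,000 cones/mm² and 0.30 mm/deg gives 635 cones.  The
retinal magnification (mm/deg) is a config scalar, so cone-count agreement
is tolerance-based, not exact.  L/M/S classes are drawn independently per
cone at 0.67:0.33:0.

Mean isomerizations per cone and 5-ms bin follow the chain: photon-rate
image → integration over the 3-µm circular aperture → axial photopigment
absorption $1-10^{-0.5}$ → class spectral sensitivity at 550 nm → quantal
efficiency 0.67 → bin duration.  Two choices deserve comment:

* **Aperture integration, not point sampling.**  The smallest stimulus
  (0.43 arcmin) is about 2.2 µm on the retina — smaller than one cone
  aperture.  Sampling the image at the cone position and multiplying by the
  aperture area then miscounts photons (it can collect more light than the
  stimulus contains), and it abolishes the aperture-summation flattening
  that small-spot curves show.  The image is therefore convolved with a
  top hat whose integral is the aperture collecting area before sampling.
* **Spectral template.**  Tabulated cone fundamentals are external data;
  since only the 550-nm value enters a narrowband simulation, class
  sensitivities use an analytic A1 pigment template (peaks 559/530/421 nm),
  normalized to 1 at peak.  Pre-receptoral filtering is not modeled; its
  absolute effect folds into the intensity calibration.

The epoch is 155 ms in 31 bins with a centered 100-ms (20-bin) stimulus
window; a background pedestal (mean isomerizations per bin, default 10, a
photopic resting level standing in for the instrument's ~8 cd/m²
three-wavelength background whose absolute calibration is hardware-specific)
is added to every bin.  Poisson response instances are drawn independently
per cone × bin × instance.  There are no eye movements in the observer.

## Decoding and thresholds

Each trial concatenates a stimulus-interval and a null-interval response
(order balanced and randomized), giving 39,370-entry vectors for the
unpooled 635-cone mosaic or 62-entry vectors after Gaussian pooling
(`pooling_kernel()`, weights centered on the central cone; kernel radius
convention $2\sigma$, area $\pi(2\sigma)^2$).  Classification is a linear
SVM (cost 1) under 10-fold cross-validation; features are standardized and,
on the unpooled path only, projected onto the leading 60 principal
components.  Standardization and PCA are fitted within training folds —
the leakage-safe reading of a globally ambiguous recipe.  Proportion
correct is $1-r_{err}$; a Weibull sigmoid on log energy (guess 0.5, no
lapse — the standard two-interval convention) is fitted by binomial
likelihood and the threshold read at its 75% crossing.

Energies are not prescribed anywhere, so each size runs a coarse pilot scan
(7 luminances spanning 3 decades at 120 instances) to bracket the 75%
point, then a final ladder of 10 log-spaced energies (±0.4 decades) at the
full instance count.  At the reduced scale used for routine runs (0.15°
mosaic ≈ 203 cones, 300 instances) a 14-size curve takes under two minutes
on one core; the full scale (0.26°, 2000 instances) reproduces the
39,370-entry geometry exactly.

## Kernel interpolation

Simulated summation curves for bracketing kernels $\sigma_1 = 1$ and
$\sigma_2 = 2$ arcmin are combined as
$T_{interp} = T_1\alpha + T_2(1-\alpha) + \beta$ and fitted to experimental
curves by RMSE minimization (`interpolate_and_fit()`); the implied kernel is
$\sigma_{interp} = \sigma_1\alpha + \sigma_2(1-\alpha)$.  In joint mode one
$\alpha$ is shared across conditions while each keeps its own vertical
shift $\beta$ (absolute sensitivity is not comparable between model and
observer, nor across optical conditions).  $\alpha$ is found by a 400-point
grid plus refinement; $\beta$ is the conditional mean residual, so the fit
matches a two-dimensional grid search to grid resolution by construction.

# Eye motion, delivery filtering and registration

Delivery traces are three per-frame stimulus positions (arcmin, image
convention).  Stabilized-condition trials are excluded unless all three
frames fall inside a closed 4.75′ × 4.75′ window centered on the median
delivery location.  Intratrial travel is
$|p_2-p_1| + |p_3-p_2|$; the scalar "delivery standard deviation" of a 2-D
point cloud is defined here as the mean of the per-axis SDs (both axes are
also reported — some scalarization must be chosen and this one is stated).

The synthetic trace generator uses Brownian drift plus compound-Poisson
microsaccades between frames (1/16 s apart), or i.i.d. tracking-error
jitter in stabilized mode.  The presets are *calibrated*, not derived: the
jitter SD (0.172′) and drift diffusion (8.45 arcmin²/s, with rate-0.25/s,
6′ microsaccades and 5.08′ per-axis fixation scatter) were tuned by Monte
Carlo so that median three-frame travel is ≈0.58′ stabilized and ≈1.79′
unstabilized.  Note one deliberate simplification: i.i.d. jitter matching
the stabilized travel median implies a stabilized delivery SD of ≈0.17′,
slightly below the ≈0.25′ typically reported for retinally-contingent
delivery; matching both would need temporally correlated tracking error.

Registration (`register_pair_dft()`) finds the cross-correlation peak in
the Fourier domain and refines it with a matrix-multiply upsampled DFT
(default 1/20 px).  A Hann window suppresses wrap-around for camera frames;
windowing pulls subpixel estimates toward zero by roughly 1.5% of the
shift, so the synthetic fixtures — which are circularly shifted by a phase
ramp and hence periodic — are registered with `window = FALSE`.  TCA
combines per-frame offsets by componentwise median within a session and the
mean of pre- and post-session medians.

# Synthetic ground truth and what passing tests show

`ground_truth_observer()` embodies the two-segment model (default: flat
level 0.95 log units, breakpoint at the area of a 2.41′ disk, second slope
0.59, logistic slope 22 per log₁₀ intensity — steep enough that fit error,
not response noise, dominates recovery).  The default flat level places
staircase thresholds comfortably inside the 8-bit intensity range for all
ten sizes at the 828 cd/m² full-scale calibration.  Sessions, traces and
image pairs are pure functions of their seeds.

The generators emulate staircase sampling, binomial response noise,
drift/microsaccade kinematics and sensor noise — they do not emulate
lapses in criterion stability, learning, calibration drift, or real
retinal image statistics.  Recovery and coverage results on synthetic data
therefore validate the *estimators* (absence of bias, honest intervals),
not the instrument.

# Numerical choices and known limitations

* Breakpoint and $\alpha$ grids: 1000 and 400 candidates plus local
  refinement; degenerate fits are flagged, never silently returned.
* PSF grids must satisfy the Nyquist margin (pixel ≤ $\lambda/D/4$); the
  constructor refuses undersampled scales.
* Poisson draws, fold assignments and interval orderings each take seeds
  derived from one master seed (kept below $2^{31}$), so every pipeline
  stage is reproducible.
* Problem sizes used in the shipped tests: reduced-scale observer (0.15°,
  300 instances, 10-energy ladders), 40-replicate coverage experiments
  with 500-rep bootstraps — sizes chosen to exercise every stage at
  meaningful statistical power while keeping a full run on one core in
  minutes.
* **Lattice scalloping.**  On a perfect hexagonal lattice with a cone at
  the stimulus center, a sub-aperture stimulus is collected at ~0.91
  efficiency while stimuli near one cone spacing fall partly between
  apertures (~0.70–0.74), so the pooled observer's threshold-energy curve
  is not perfectly flat below the kernel scale: it scallops by up to
  ~0.07 log units across the 0.43–1.16′ sizes, and two-segment fits to
  such curves inherit that structure.  This is a property of regular-
  lattice front ends (real mosaics are disordered and stimuli are not
  delivered cone-aligned), worth keeping in mind when comparing simulated
  small-spot thresholds at cone-scale sizes.
* The observer's absolute sensitivity depends on the photon calibration
  and background pedestal (config scalars); only curve *shapes* are
  meaningful, which is why every model-data comparison carries a free
  vertical shift.
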