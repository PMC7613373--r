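---
title: "Hybrid retrieval of canopy nitrogen content: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid retrieval of canopy nitrogen content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The retrieval problem

Canopy nitrogen content (CNC, g/m^2) is the aboveground nitrogen mass per
unit ground area of a vegetated surface. Most leaf nitrogen sits in
proteins, whose absorption features lie in the shortwave infrared, so a
spectrometer covering 400-2500 nm carries a physical (rather than purely
statistical) nitrogen signal. `cncmap` implements a *hybrid* retrieval: a
physically based radiative transfer model generates a labelled training
database spanning a wide range of canopy states, and a probabilistic
machine-learning regressor -- Gaussian process regression (GPR) -- learns
the inverse mapping from reflectance to CNC. No field data are consumed at
training time except as a small validation set that steers the
active-learning reduction of the training pool.

The chain, end to end:

1. **Forward simulation.** A protein-resolving leaf optical properties
   model (plate model with leaf dry matter split into protein content
   `C_p` and carbon-based constituents) coupled to a four-stream canopy
   model with an ellipsoidal leaf inclination distribution and a hot-spot
   correction. Each of the 1000 parameter draws is labelled
   `CNC = LAI * C_p * 10000 / 4.43`, where 4.43 g protein per g N is the
   protein-to-nitrogen conversion factor and LAI upscales the per-leaf-area
   protein to the canopy.
2. **Band handling.** Simulated 1 nm spectra are degraded to the sensor
   band grid through normalised Gaussian spectral response functions
   (SD = FWHM / 2.3548) and restricted to the harmonized subset: centers
   in [470, 2143] nm minus the water-absorption windows [1345, 1510] and
   [1795, 2000] nm (207 bands of the shipped nominal table).
3. **Compression.** Centered (unscaled) PCA to 20 components.
4. **Sample reduction.** Euclidean-distance-based diversity active
   learning against the validation set.
5. **Generalisation.** 24 non-vegetated spectra appended with label 0.
6. **Final fit.** GPR with an automatic-relevance-determination kernel;
   maps carry the per-pixel predictive mean, SD, and coefficient of
   variation (CV), masked at CV > 20% -- the Global Climate Observing
   System accuracy goal.

## Sampling scheme of the training database

`database_config()` fixes per-variable ranges and distributions: uniform
draws for leaf structure (1-2.5), chlorophyll (0-80 ug/cm^2), water
(0.001-0.02 cm), carotenoids (0-15 ug/cm^2), anthocyanins (0-2 ug/cm^2),
carbon-based constituents (0.001-0.01 g/cm^2), soil brightness (0-1), leaf
angle (30-70 deg) and hot spot (0.01-0.5); range-truncated Gaussians for
protein content (mean 0.0015, SD 0.0005, range 0.001-0.0025 g/cm^2) and
LAI (mean 3, SD 2, range 0.1-7); fixed geometry (sun zenith 30 deg, nadir
observer). Truncated Gaussians are drawn by rejection, so the marginals
are exactly the truncated laws (the test-suite checks them with
Kolmogorov-Smirnov tests at n = 1e5). The implied label range is 0.23-39.5
g/m^2.

Additive spectral noise is available (`noise_pct`) but **off by default**:
with diversity active learning tuning the pool against (noisy) validation
data, artificial noise on the simulations did not earn its place in the
default configuration.

## Radiative transfer: what is authored and what it stands on

No leaf/canopy RTM implementation is bundled with this toolchain's
dependencies, so both models are authored here from their published
formulations.

* The leaf model is a generalised plate model: interface transmissivities
  are computed by direct Gauss-Legendre quadrature of the unpolarised
  Fresnel transmittance (rather than a closed-form approximation), the
  elementary-layer transmission is `(1-k)e^{-k} + k^2 E_1(k)`, and the
  `N-1` homogeneous layers are stacked with the Stokes system, with the
  conservative-scattering limit handled explicitly.
* **The coefficient spectra are synthetic.** The refractive index and the
  specific absorption coefficients of chlorophyll, carotenoids,
  anthocyanins, water, protein and carbon-based constituents are
  parametric (Gaussian features at the canonical absorption wavelengths,
  magnitudes set so the sampling ranges above produce realistic
  vegetation spectra). They are *not* a published calibration; absolute
  reflectance values are those of a physically plausible synthetic leaf.
  Every property the package asserts about itself (energy conservation,
  absorber monotonicity, variance concentration, retrieval accuracy on
  synthetic scenes) is computed with these coefficients, and nothing is
  claimed about agreement with any laboratory calibration.
* The canopy model is the classical four-stream turbid-medium
  formulation: directional extinction/scattering coefficients integrated
  over a 13-class ellipsoidal (Campbell) leaf inclination distribution;
  the diffuse two-stream boundary value problem solved analytically (the
  derivation was re-done from the ODE system; the test-suite verifies the
  solution against an independent `deSolve` numerical solution of the
  same system to 1e-6); single scattering hot-spot-corrected with the
  20-step exponential quadrature; soil coupled by the adding method with
  `rho_soil = alpha_soil * soil_reference(lambda)`, a parametric dry-soil
  curve. Near-resonant forcing (`ks` ~ `m`) is regularised by a 1e-7
  shift, far below the model's physical fidelity.

The leaf inclination family (ellipsoidal) and the soil reference are
deliberate choices where the workflow specification only names a range or
a scaling factor; both are smooth in their parameters, and neither is
observable by the downstream regressor beyond the reflectance it shapes.

## Spectral cleaning chain

`preprocess_pixel()` composes, deterministically: spike masking ->
window exclusion -> restriction to the harmonized subset -> spline gap
filling.

* **Spike masking.** A band is masked when it is a local extremum whose
  prominence relative to *both* immediate neighbours exceeds 0.018
  reflectance units. Dips count as well as peaks: sensor artifacts
  undershoot as often as they overshoot. A strictly monotone spectrum is
  never touched.
* **Window exclusion.** Twelve noisy intervals
  (535-550, 755-780, 810-855, 885-970, 1015-1050, 1080-1165, 1225-1285,
  1330-1490, 1685-1700, 1725-1750, 1780-1960, 1990-2030 nm) are masked on
  band centers (closed intervals); FWHM overlap is intentionally ignored
  as the simplest defensible membership rule.
* **Gap filling.** The default fill inside `preprocess_pixel()` is a
  *natural cubic interpolating spline* through the valid bands, with
  valid bands keeping their observed values. This choice makes the whole
  chain exactly idempotent: points added on a natural spline reproduce
  the same spline, so re-cleaning a cleaned spectrum is a no-op. A GCV
  smoothing spline (the `spline_gapfill()` default when called directly)
  trades that exactness for noise suppression at the valid bands;
  `preprocess_config(fill_method = "smooth")` selects it.

The "blue visible" cut is implemented as centers < 470 nm; percent-scale
input spectra are detected (max > 1.5) and converted to fractions.

## Gaussian process regression

The kernel is the scaled Gaussian
`K(x_i, x_j) = nu * exp(-sum_b (x_ib - x_jb)^2 / (2 sigma_b^2)) + delta_ij sigma_n^2`,
isotropic (one shared `sigma_b`) inside the active-learning loop for
speed. For the final fit the kernel is selected *by validation RMSE*
between the isotropic and the automatic-relevance-determination (ARD)
form (`kernel_mode_final = "auto"`). The obvious alternative -- always
ARD -- fails under these study conditions: on the AL-selected,
NV-augmented training set the evidence-optimal ARD solution collapses
length-scales on low-variance components and, despite a clearly better
marginal likelihood, substantially degrades the validation RMSE
(evidence overfitting under model misspecification: validation spectra
sit slightly off the simulated manifold, and tiny length-scales on
low-variance components make them look far from all training data).
Selecting by validation RMSE applies the same decision criterion the
active-learning loop is built on. Targets are centered before fitting
(zero-mean prior); the offset is restored at prediction. The predictive self-similarity uses
`k** = nu`, i.e. the latent function is predicted;
`include_noise = TRUE` adds `sigma_n^2` for observation-level intervals.

Hyperparameters minimise the negative log marginal likelihood in
log-space with analytic gradients (L-BFGS-B). The evidence surface has a
*white-noise local optimum* at tiny length-scales, so the multi-start
policy spreads the length-scale start over octaves around the
median-pairwise-distance heuristic (`nu` starts at `var(y)`, `sigma_n` at
`0.1 sd(y)`; 5 restarts by default, 4 in the recovery experiment below).
Failed Cholesky factorisations retry with jitter escalating from
`1e-10 nu` to `1e-6 nu`.

The recovery experiment in the test-suite draws data from a known GP
(`nu = 1, sigma_b = 1, sigma_n = 0.1, N = 200`). The input design matters:
uniform designs leave the signal variance (or the noise SD) with a
sampling SD too large for a +/-0.3 log-accuracy check *regardless of the
estimator*. The experiment therefore uses a covariance-estimation design
-- 100 dispersed cluster centers, each paired with a second point at a lag
between 0.03 and 1.8 -- which identifies all three hyperparameters
simultaneously (tight pairs pin the noise, medium lags the length-scale,
dispersed clusters the variance).

## Diversity active learning

From the pool of 1000 labelled simulations (as 20-component scores), 10%
are drawn uniformly as the initial training set. Then, in a single pass
until the pool is exhausted, the candidate with the largest *maximin*
squared-Euclidean distance to the current training set is tentatively
added and kept only if the validation RMSE strictly decreases (ties
reject, so the recorded trace is strictly monotone). Rejected candidates
are permanently removed. R-squared is recorded alongside but never drives
acceptance -- it is the less reliable selection signal. Maximin
aggregation (rather than mean or sum, both available) guarantees a
duplicate of a training point is never selected while alternatives exist.
In-loop refits warm-start from the previous optimum with one start; the
final model is refit with full restarts and the ARD kernel.

Non-vegetated spectra are projected through the *existing* PCA -- the PCA
is fit once on the simulated database and never refit -- and labelled
0 g/m^2, the only physically coherent nitrogen content for bare soil,
water and man-made surfaces.

## Synthetic data: what it emulates, and what passing tests do not show

The field campaign, the non-vegetated library and the ground-truthed
scene stand in for unpublished field data and a real satellite
acquisition.

* `make_field_campaign()` draws wheat-like and corn-like parameter
  trajectories over growth stages (archetypes differ in leaf angle, LAI
  and protein trajectories; they are presets, not calibrated cultivars),
  simulates reflectance with the same RTM family as the training
  database, applies 3% multiplicative spectral noise and 1 g/m^2 label
  noise, and caps the implied CNC at 21 g/m^2, the envelope of typical
  leaves-plus-stalks measurements (field campaigns report roughly
  0.9-21.5 g/m^2).
* `make_scene()` tiles a 64 x 64 scene into 16-pixel patches: 30%
  non-vegetated (soil / water / man-made endmembers), the rest crop
  fields with field-level biochemistry and per-pixel LAI and soil
  variation, emitted on the raw 239-band sensor grid so mapping exercises
  the full cleaning chain.

Because validation and scene spectra come from the same model family as
the training database (plus noise), these benchmarks are *deliberately
optimistic*: they demonstrate the machinery end to end -- database, PCA,
active learning, augmentation, mapping, uncertainty masking -- but say
nothing about structural model error on real canopies (row structure,
non-turbid architecture, residues, atmospheric artifacts). Accuracies
measured on them must not be read as expected field accuracy.

## Numerical choices and degenerate inputs

* Band-center resampling weights are normalised to sum 1, so constants
  survive resampling exactly and the operation is linear to machine
  precision.
* PCA component signs are fixed (largest-magnitude loading positive) for
  reproducible serialization; requesting components beyond the matrix
  rank truncates with a warning.
* Predictive variances are clipped at zero; clipping beyond -1e-10
  raises a warning.
* Pixels with predictive mean <= 1e-6 g/m^2 (configurable) are flagged
  invalid rather than producing unbounded CV; masking at a CV threshold
  is idempotent and monotone in the threshold.
* Model bundles serialize to JSON with doubles encoded at 17 significant
  digits, which round-trips IEEE doubles exactly; restored bundles
  reproduce predictions bit-identically.
* All stochastic entry points take explicit seeds and restore the
  caller's RNG state; equal seeds give bit-identical databases, campaign
  sets, scenes and active-learning runs.

## Problem sizes used by the test-suite

The suite runs the study-scale objects once and caches them: one
1000-sample database (the size at which a dense GPR remains comfortable,
since training inverts an N x N matrix), a 30-record campaign, an
active-learning pass over the 900 remaining candidates, and one 64 x 64
scene; the remaining tests run on small purpose-built instances. The
acceptance script recomputes only the database-and-PCA stage.

## Known limitations

* Synthetic leaf coefficients (above): absolute spectra are plausible,
  not calibrated.
* The turbid-medium canopy assumption ignores row structure and clumping;
  no fluorescence, no thermal domain, no 3-D canopies.
* Cube IO is in-memory plus long-CSV; no geospatial raster formats, no
  georeferencing, no atmospheric correction -- inputs are assumed to be
  surface reflectance.
* The active-learning loop optimises against one validation set; with a
  narrow or noisy validation set the selection inherits its biases
  (acceptance decisions *are* validation-set overfitting, by design).
* Fruit nitrogen is invisible to reflectance; labels represent
  leaves-plus-stalks nitrogen only.
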