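#' Synthetic leaf optical coefficient set
#'
#' Returns the per-wavelength model constants used by [prospect_pro()]: the
#' leaf refractive index and the specific absorption coefficients of
#' chlorophyll a+b, carotenoids, anthocyanins, water, protein and carbon-based
#' constituents (CBC) on the native 1 nm grid from 400 to 2500 nm.
#'
#' This coefficient set is *synthetic*: it is generated from parametric
#' (Gaussian-feature) forms placed at the canonical absorption wavelengths of
#' each constituent (pigments in the visible, water at 970/1200/1450/1940 nm,
#' protein and dry-matter features through the SWIR), with magnitudes chosen
#' so that the Table-style input ranges produce realistic vegetation spectra.
#' It is not a published calibration, and absolute reflectance values from the
#' model should be read as those of a physically plausible synthetic leaf.
#'
#' @param wavelengths numeric vector of wavelengths in nm (default the native
#'   1 nm grid, 400--2500 nm).
#' @return A data frame with columns `wavelength`, `refractive_index`, and the
#'   specific absorption coefficients `k_cab` (cm^2/ug), `k_car` (cm^2/ug),
#'   `k_anth` (cm^2/ug), `k_water` (1/cm), `k_protein` (cm^2/g),
#'   `k_cbc` (cm^2/g).
#' @export
#' @examples
#' head(leaf_coefficients())
leaf_coefficients <- function(wavelengths = 400:2500) {
  assert_finite_numeric(wavelengths, "wavelengths")
  wl <- wavelengths
  g <- function(center, sd) exp(-(wl - center)^2 / (2 * sd^2))
  sig <- function(center, scale) 1 / (1 + exp(-(wl - center) / scale))

  refr <- 1.35 + 0.17 * exp(-(wl - 400) / 800)

  k_cab <- 0.030 * exp(-(wl - 400) / 60) + 0.065 * g(430, 35) +
    0.040 * g(460, 30) + 0.030 * g(640, 30) + 0.070 * g(670, 25)
  k_car <- 0.045 * exp(-(wl - 400) / 50) + 0.100 * g(445, 32) +
    0.060 * g(480, 28)
  k_anth <- 0.045 * g(550, 40) + 0.010 * g(520, 30)
  k_water <- 1.5 * g(970, 50) + 4.0 * g(1200, 70) + 32 * g(1450, 80) +
    85 * g(1940, 90) + 40 * g(2500, 250) + 0.8 * sig(1300, 200)
  k_protein <- 110 * g(1510, 60) + 90 * g(1730, 50) + 160 * g(1980, 70) +
    210 * g(2060, 60) + 180 * g(2180, 70) + 150 * g(2300, 80) +
    25 * g(910, 40) + 35 * g(1020, 40)
  k_cbc <- 15 * sig(900, 300) + 25 * g(1210, 80) + 60 * g(1730, 90) +
    70 * g(2100, 100) + 90 * g(2300, 120)

  data.frame(
    wavelength = wl, refractive_index = refr,
    k_cab = k_cab, k_car = k_car, k_anth = k_anth,
    k_water = k_water, k_protein = k_protein, k_cbc = k_cbc
  )
}

# memoised default-grid coefficients (model constants; computed once)
.cnc_cache <- new.env(parent = emptyenv())

default_leaf_coefficients <- function() {
  if (is.null(.cnc_cache$coef)) .cnc_cache$coef <- leaf_coefficients(400:2500)
  .cnc_cache$coef
}

#' Reference dry-soil reflectance
#'
#' A smooth synthetic dry-soil reflectance spectrum (brightening from the
#' visible into the SWIR with shallow water-absorption dips). The canopy
#' model scales it linearly by the soil scaling factor `alpha_soil`, i.e.
#' `rho_soil(lambda) = alpha_soil * soil_reference(lambda)`.
#'
#' @param wavelengths wavelengths in nm.
#' @return reflectance fraction per wavelength.
#' @export
soil_reference <- function(wavelengths = 400:2500) {
  wl <- wavelengths
  g <- function(center, sd) exp(-(wl - center)^2 / (2 * sd^2))
  r <- 0.12 + 0.28 / (1 + exp(-(wl - 900) / 450)) -
    0.05 * g(1450, 90) - 0.09 * g(1940, 120) - 0.03 * g(2250, 150)
  pmin(pmax(r, 0.02), 0.65)
}
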