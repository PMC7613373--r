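#' Sensor band grid
#'
#' A band grid is the spectral sampling of a sensor: strictly increasing band
#' centers (nm) with a positive full width at half maximum (FWHM, nm) per
#' band, defining the Gaussian spectral response of each band.
#'
#' @param centers band center wavelengths in nm, strictly increasing.
#' @param fwhm per-band FWHM in nm (recycled if scalar).
#' @return object of class `band_grid` (data frame with `center`, `fwhm`).
#' @export
#' @examples
#' g <- band_grid(seq(470, 2140, by = 10), fwhm = 10)
band_grid <- function(centers, fwhm) {
  assert_finite_numeric(centers, "centers")
  assert_finite_numeric(fwhm, "fwhm")
  if (length(fwhm) == 1) fwhm <- rep(fwhm, length(centers))
  if (length(fwhm) != length(centers)) {
    stop_domain("centers and fwhm must have the same length")
  }
  if (any(diff(centers) <= 0)) stop_domain("centers must be strictly increasing")
  if (any(fwhm <= 0)) stop_domain("fwhm must be positive")
  structure(data.frame(center = centers, fwhm = fwhm), class = c("band_grid", "data.frame"))
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf(
    "<band_grid> %d bands, %.1f-%.1f nm, median fwhm %.1f nm\n",
    nrow(x), min(x$center), max(x$center), stats::median(x$fwhm)
  ))
  invisible(x)
}

#' Nominal satellite band table
#'
#' Reads the 239-band nominal band table shipped with the package. The table
#' is a *synthetic* stand-in for the band list of a PRISMA-like VSWIR imaging
#' spectrometer (6--12 nm sampling over the exploited spectral ranges,
#' sparser sampling in the excluded blue, water-absorption and upper-SWIR
#' ranges); it is constructed so that [harmonized_grid()] retains exactly 207
#' bands between 470 and 2143 nm.
#'
#' @return a [band_grid()] with 239 bands.
#' @export
sensor_band_grid <- function() {
  path <- system.file("extdata", "synthetic_prisma_like_bands.csv",
    package = "cncmap", mustWork = TRUE
  )
  tab <- utils::read.csv(path)
  band_grid(tab$center_nm, tab$fwhm_nm)
}

#' Read a band grid from a two-column CSV
#'
#' @param path CSV file with columns `center_nm` and `fwhm_nm`.
#' @return a [band_grid()].
#' @export
read_band_grid <- function(path) {
  tab <- utils::read.csv(path)
  band_grid(tab$center_nm, tab$fwhm_nm)
}

#' Harmonized band subset
#'
#' Restricts a band grid to the spectral ranges exploited for nitrogen
#' retrieval: band centers in \[470, 2143\] nm, excluding the water-absorption
#' windows \[1345, 1510\] and \[1795, 2000\] nm. Idempotent.
#'
#' @param source a [band_grid()] covering the sensor range.
#' @return the retained [band_grid()].
#' @export
harmonized_grid <- function(source) {
  keep <- harmonized_band_mask(source)
  band_grid(source$center[keep], source$fwhm[keep])
}

# logical mask of harmonized bands within a source grid
harmonized_band_mask <- function(source) {
  ctr <- source$center
  ctr >= 470 & ctr <= 2143 &
    !(ctr >= 1345 & ctr <= 1510) &
    !(ctr >= 1795 & ctr <= 2000)
}

#' Gaussian spectral-response resampling
#'
#' Resamples a finely sampled spectrum to a sensor band grid: each output
#' band is the Gaussian-weighted average of the fine spectrum, with the
#' spectral response function centered at the band center and standard
#' deviation `fwhm / 2.3548`; weights are normalised to sum to one over the
#' fine grid, so constants are preserved exactly and the operation is linear.
#'
#' @param values fine-grid spectrum (vector) or matrix with one spectrum per
#'   row (columns = fine wavelengths).
#' @param fine_wavelengths wavelengths (nm) of the fine grid.
#' @param target a [band_grid()]; every band center must lie inside the fine
#'   grid's range.
#' @return resampled spectrum (vector) or matrix (rows = spectra,
#'   columns = target bands).
#' @export
gaussian_resample <- function(values, fine_wavelengths, target) {
  W <- srf_weights(fine_wavelengths, target)
  if (is.matrix(values)) {
    if (ncol(values) != length(fine_wavelengths)) {
      stop_domain("values columns must match the fine wavelength grid")
    }
    values %*% W
  } else {
    if (length(values) != length(fine_wavelengths)) {
      stop_domain("values must match the fine wavelength grid")
    }
    drop(matrix(values, nrow = 1) %*% W)
  }
}

# normalised Gaussian SRF weight matrix (fine wavelengths x target bands)
srf_weights <- function(fine_wavelengths, target) {
  wl <- fine_wavelengths
  if (any(target$center < min(wl)) || any(target$center > max(wl))) {
    stop_domain("target band centers outside the fine grid's coverage")
  }
  sd <- target$fwhm / 2.3548
  W <- vapply(seq_len(nrow(target)), function(j) {
    w <- stats::dnorm(wl, mean = target$center[j], sd = sd[j])
    w / sum(w)
  }, numeric(length(wl)))
  W
}
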