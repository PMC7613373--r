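#' Noisy-region window presets
#'
#' `prisma_noisy_windows()` returns the twelve wavelength intervals (nm)
#' systematically excluded from PRISMA-like spectra before spline gap
#' filling; `water_windows()` returns the two broad atmospheric
#' water-absorption regions that are removed from the final band set.
#'
#' @return a list of `c(lo, hi)` intervals in nm.
#' @export
prisma_noisy_windows <- function() {
  list(
    c(535, 550), c(755, 780), c(810, 855), c(885, 970),
    c(1015, 1050), c(1080, 1165), c(1225, 1285), c(1330, 1490),
    c(1685, 1700), c(1725, 1750), c(1780, 1960), c(1990, 2030)
  )
}

#' @rdname prisma_noisy_windows
#' @export
water_windows <- function() {
  list(c(1345, 1510), c(1795, 2000))
}

# validate + sort + merge overlapping [lo, hi] intervals
normalize_windows <- function(windows) {
  if (length(windows) == 0) {
    return(list())
  }
  for (w in windows) {
    if (length(w) != 2 || w[1] >= w[2]) stop_domain("windows must be c(lo, hi) with lo < hi")
  }
  m <- do.call(rbind, windows)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      last <- out[[length(out)]]
      if (m[i, 1] <= last[2]) {
        out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
      } else {
        out[[length(out) + 1]] <- m[i, ]
      }
    }
  }
  out
}

#' Masked spectrum
#'
#' A spectrum on a band grid together with a per-band validity mask.
#' Masked-out positions carry no value semantics.
#'
#' @param values reflectance fraction per band.
#' @param grid a [band_grid()].
#' @param valid logical per band (default all valid).
#' @return object of class `masked_spectrum`.
#' @export
masked_spectrum <- function(values, grid, valid = rep(TRUE, length(values))) {
  if (length(values) != nrow(grid)) stop_domain("values length must match grid")
  if (length(valid) != length(values)) stop_domain("valid length must match values")
  structure(list(values = values, grid = grid, valid = as.logical(valid)),
    class = "masked_spectrum"
  )
}

#' Spike removal by local-extremum prominence
#'
#' Masks out bands that are local extrema (peaks or dips) whose prominence
#' relative to both immediate neighbours exceeds `threshold` reflectance
#' units. Strictly monotone spectra are never touched.
#'
#' @param values reflectance per band (>= 3 bands).
#' @param grid a [band_grid()].
#' @param threshold prominence threshold in reflectance units
#'   (default 0.018).
#' @return a [masked_spectrum()] with spike bands invalid.
#' @export
despike <- function(values, grid, threshold = 0.018) {
  n <- length(values)
  if (n < 3) stop_domain("despike needs at least 3 bands")
  valid <- rep(TRUE, n)
  i <- 2:(n - 1)
  dl <- values[i] - values[i - 1]
  dr <- values[i] - values[i + 1]
  peak_prom <- pmin(dl, dr) # > 0 only at local maxima
  dip_prom <- pmin(-dl, -dr) # > 0 only at local minima
  valid[i] <- !(peak_prom > threshold | dip_prom > threshold)
  masked_spectrum(values, grid, valid)
}

#' Mask bands falling in exclusion windows
#'
#' Marks every band whose center lies inside any closed `[lo, hi]` interval
#' as invalid. The mask is monotone: bands already invalid stay invalid, so
#' the operation is idempotent.
#'
#' @param ms a [masked_spectrum()].
#' @param windows list of `c(lo, hi)` intervals in nm.
#' @return a [masked_spectrum()].
#' @export
exclude_windows <- function(ms, windows) {
  windows <- normalize_windows(windows)
  valid <- ms$valid
  ctr <- ms$grid$center
  for (w in windows) valid <- valid & !(ctr >= w[1] & ctr <= w[2])
  masked_spectrum(ms$values, ms$grid, valid)
}

#' Smoothing-spline gap filling
#'
#' Fits a smoothing cubic spline to the valid bands of a masked spectrum and
#' evaluates it at every band center, producing a gapless spectrum. The
#' smoothing level defaults to generalized cross-validation.
#'
#' @param ms a [masked_spectrum()] with at least 4 valid bands.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV. Ignored
#'   for `method = "interp"`.
#' @param replace_valid if `TRUE`, all bands take the spline value; if
#'   `FALSE` (default) only invalid bands are filled and valid bands keep
#'   their observed values.
#' @param method `"smooth"` (default): GCV smoothing spline;  `"interp"`:
#'   natural cubic interpolating spline through the valid bands. The
#'   interpolating variant makes the full cleaning chain exactly idempotent,
#'   because refitting after adding points that lie on a natural spline
#'   reproduces the same spline.
#' @return numeric vector of reflectance on the full grid.
#' @export
spline_gapfill <- function(ms, spar = NULL, replace_valid = FALSE,
                           method = c("smooth", "interp")) {
  method <- match.arg(method)
  ok <- ms$valid
  if (sum(ok) < 4) stop_domain("spline_gapfill needs at least 4 valid bands")
  x <- ms$grid$center[ok]
  y <- ms$values[ok]
  pred <- if (method == "interp") {
    stats::spline(x, y, xout = ms$grid$center, method = "natural")$y
  } else {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(x, y, cv = FALSE)
    } else {
      stats::smooth.spline(x, y, spar = spar)
    }
    stats::predict(fit, ms$grid$center)$y
  }
  if (replace_valid) {
    pred
  } else {
    out <- ms$values
    out[!ok] <- pred[!ok]
    out
  }
}

#' Preprocessing configuration
#'
#' @param spike_threshold prominence threshold for [despike()].
#' @param windows exclusion window list (default the twelve noisy regions of
#'   [prisma_noisy_windows()]).
#' @param fill_method gap-fill spline flavour, see [spline_gapfill()];
#'   the default `"interp"` keeps the chain exactly idempotent.
#' @param spar optional fixed smoothing parameter (only for
#'   `fill_method = "smooth"`).
#' @return a named list.
#' @export
preprocess_config <- function(spike_threshold = 0.018,
                              windows = prisma_noisy_windows(),
                              fill_method = "interp",
                              spar = NULL) {
  list(
    spike_threshold = spike_threshold, windows = windows,
    fill_method = fill_method, spar = spar
  )
}

#' Clean a raw sensor spectrum onto the harmonized grid
#'
#' Applies the full per-pixel cleaning chain: spike removal, exclusion of the
#' configured noisy windows, restriction to the harmonized band subset, and
#' smoothing-spline filling of the masked bands. Deterministic, and
#' idempotent on its own output.
#'
#' @param values reflectance per band of `grid`. Values given in percent
#'   (max > 1.5) are converted to fractions.
#' @param grid the raw sensor [band_grid()].
#' @param cfg a [preprocess_config()].
#' @return list with `values` (gapless reflectance on the harmonized grid)
#'   and `grid` (the harmonized [band_grid()]).
#' @export
preprocess_pixel <- function(values, grid, cfg = preprocess_config()) {
  if (max(values, na.rm = TRUE) > 1.5) values <- values / 100
  ms <- despike(values, grid, threshold = cfg$spike_threshold)
  ms <- exclude_windows(ms, cfg$windows)
  keep <- harmonized_band_mask(grid)
  hgrid <- band_grid(grid$center[keep], grid$fwhm[keep])
  ms <- masked_spectrum(ms$values[keep], hgrid, ms$valid[keep])
  filled <- spline_gapfill(ms,
    spar = cfg$spar,
    method = cfg$fill_method %||% "interp"
  )
  list(values = filled, grid = hgrid)
}
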