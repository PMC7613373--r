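#' Canopy nitrogen content from leaf protein and leaf area
#'
#' Upscales leaf protein content to aboveground canopy nitrogen content:
#' `CNC = LAI * Cp * 10000 / 4.43` in g/m^2, where 4.43 is the
#' protein-to-nitrogen conversion factor and the factor 10000 converts
#' per-cm^2 leaf protein to per-m^2.
#'
#' @param lai leaf area index (m^2/m^2, >= 0); vectorised.
#' @param cp leaf protein content (g/cm^2, >= 0); vectorised.
#' @return canopy nitrogen content in g/m^2; linear in each argument.
#' @export
#' @examples
#' compute_cnc(3, 0.0015) # 10.158 g/m2
compute_cnc <- function(lai, cp) {
  assert_finite_numeric(lai, "lai")
  assert_finite_numeric(cp, "cp")
  if (any(lai < 0) || any(cp < 0)) stop_domain("lai and cp must be >= 0")
  lai * cp * 10000 / 4.43
}

#' Sampling configuration of the simulated training database
#'
#' Per-variable ranges and distributions used to draw the leaf and canopy
#' inputs of the training database: uniform draws over the stated ranges for
#' most variables, range-truncated Gaussian draws for protein content
#' (mean 0.0015, SD 0.0005 g/cm^2) and leaf area index (mean 3, SD 2), and
#' fixed viewing geometry (sun zenith 30 deg, nadir observer).
#'
#' @return a named list of per-variable blocks
#'   `list(min, max, distribution, mean, sd)`; geometry entries carry a fixed
#'   `value`.
#' @export
database_config <- function() {
  u <- function(min, max) list(min = min, max = max, distribution = "uniform")
  g <- function(min, max, mean, sd) {
    list(min = min, max = max, distribution = "gaussian", mean = mean, sd = sd)
  }
  list(
    N_struct = u(1.0, 2.5),
    C_ab = u(0, 80),
    C_w = u(0.001, 0.02),
    C_xc = u(0, 15),
    C_anth = u(0, 2),
    C_p = g(0.001, 0.0025, 0.0015, 0.0005),
    CBC = u(0.001, 0.01),
    LAI = g(0.1, 7, 3, 2),
    alpha_soil = u(0, 1),
    ALA = u(30, 70),
    HotS = u(0.01, 0.5),
    SZA = list(value = 30),
    OZA = list(value = 0)
  )
}

#' Write / read a database configuration as YAML
#'
#' @param config a [database_config()]-shaped list.
#' @param path file path.
#' @return `read_database_config` returns the configuration list.
#' @export
write_database_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_database_config
#' @export
read_database_config <- function(path) {
  yaml::read_yaml(path)
}

# truncated-Gaussian draws by rejection within [min, max]
rtruncnorm_reject <- function(n, mean, sd, min, max) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= min & x <= max])
  }
  out[seq_len(n)]
}

#' Draw random model input parameter sets
#'
#' Draws `n` joint (leaf, canopy, geometry) parameter sets from the sampling
#' scheme of [database_config()]. Reproducible for a given seed.
#'
#' @param n number of parameter sets (>= 1).
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @param config sampling configuration, by default [database_config()].
#' @return a data frame with one row per sample and columns `N_struct`,
#'   `C_ab`, `C_w`, `C_xc`, `C_anth`, `C_p`, `CBC`, `LAI`, `alpha_soil`,
#'   `ALA`, `HotS`, `SZA`, `OZA`, `cnc` (g/m^2, from [compute_cnc()]).
#' @export
sample_parameters <- function(n, seed = NULL, config = database_config()) {
  if (!is.numeric(n) || n < 1) stop_domain("n must be >= 1")
  n <- as.integer(n)
  draw <- function(cfg) {
    if (!is.null(cfg$value)) {
      rep(cfg$value, n)
    } else if (identical(cfg$distribution, "uniform")) {
      stats::runif(n, cfg$min, cfg$max)
    } else if (identical(cfg$distribution, "gaussian")) {
      rtruncnorm_reject(n, cfg$mean, cfg$sd, cfg$min, cfg$max)
    } else {
      stop_domain("unknown distribution: ", cfg$distribution)
    }
  }
  with_seed_if(seed, {
    cols <- lapply(config, draw)
    out <- as.data.frame(cols)
    out$cnc <- compute_cnc(out$LAI, out$C_p)
    out
  })
}

#' Simulate the labelled training database
#'
#' Forward-simulates `n` canopy reflectance spectra with the coupled
#' leaf/canopy radiative transfer model on the native 1 nm grid, resamples
#' them to the requested sensor band grid through the Gaussian spectral
#' response, and labels each spectrum with its canopy nitrogen content.
#' Optional additive Gaussian noise (off by default) perturbs reflectance
#' only, never the labels.
#'
#' @param n number of samples (default 1000).
#' @param grid target [band_grid()]; default: the harmonized subset of the
#'   nominal sensor table.
#' @param seed integer seed for the parameter draws (and noise, if any).
#' @param noise_pct additive Gaussian noise SD as percent of reflectance
#'   (default 0 = no noise).
#' @param config sampling configuration, see [database_config()].
#' @return object of class `training_database`: list with `parameters`
#'   (data frame incl. `cnc`), `reflectance` (n x bands matrix), `grid`,
#'   `seed`, `noise_pct`, `config`.
#' @export
#' @examples
#' \donttest{
#' db <- build_training_database(25, seed = 1)
#' dim(db$reflectance)
#' }
build_training_database <- function(n = 1000, grid = NULL, seed = NULL,
                                    noise_pct = 0, config = database_config()) {
  if (is.null(grid)) grid <- harmonized_grid(sensor_band_grid())
  if (min(grid$center) < 400 || max(grid$center) > 2500) {
    stop_domain("band grid must lie within 400-2500 nm")
  }
  pars <- sample_parameters(n, seed = seed, config = config)
  wl <- 400:2500
  W <- srf_weights(wl, grid)
  soil_ref <- soil_reference(wl)
  refl <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  for (i in seq_len(n)) {
    leaf <- leaf_params(
      N_struct = pars$N_struct[i], C_ab = pars$C_ab[i], C_xc = pars$C_xc[i],
      C_anth = pars$C_anth[i], C_w = pars$C_w[i], C_p = pars$C_p[i],
      CBC = pars$CBC[i]
    )
    canopy <- canopy_params(
      LAI = pars$LAI[i], ALA = pars$ALA[i], HotS = pars$HotS[i],
      alpha_soil = pars$alpha_soil[i]
    )
    geom <- view_geometry(SZA = pars$SZA[i], OZA = pars$OZA[i])
    brf <- sail4(canopy, prospect_pro(leaf),
      soil_reflectance = canopy$alpha_soil * soil_ref, geometry = geom
    )
    refl[i, ] <- drop(matrix(brf, nrow = 1) %*% W)
  }
  if (noise_pct > 0) {
    noise_seed <- if (is.null(seed)) NULL else seed + 1L
    refl <- with_seed_if(noise_seed, {
      refl + matrix(
        stats::rnorm(length(refl), 0, noise_pct / 100 * abs(refl)),
        nrow = n
      )
    })
    refl <- pmin(pmax(refl, 0), 1)
  }
  structure(
    list(
      parameters = pars, reflectance = refl, grid = grid,
      seed = seed, noise_pct = noise_pct, config = config
    ),
    class = "training_database"
  )
}

#' @export
print.training_database <- function(x, ...) {
  cat(sprintf(
    "<training_database> %d samples x %d bands, CNC %.2f-%.2f g/m2%s\n",
    nrow(x$reflectance), ncol(x$reflectance),
    min(x$parameters$cnc), max(x$parameters$cnc),
    if (x$noise_pct > 0) sprintf(", %.1f%% noise", x$noise_pct) else ""
  ))
  invisible(x)
}

#' Export a training database to CSV files
#'
#' Writes two plain-text files: `<prefix>_parameters.csv` (inputs + CNC label)
#' and `<prefix>_spectra.csv` (first column wavelength, one column per
#' sample).
#'
#' @param db a [build_training_database()] result.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
export_training_database <- function(db, prefix) {
  ppath <- paste0(prefix, "_parameters.csv")
  spath <- paste0(prefix, "_spectra.csv")
  utils::write.csv(db$parameters, ppath, row.names = FALSE)
  spec <- data.frame(wavelength_nm = db$grid$center, t(db$reflectance))
  names(spec)[-1] <- paste0("sample_", seq_len(nrow(db$reflectance)))
  utils::write.csv(spec, spath, row.names = FALSE)
  invisible(c(ppath, spath))
}
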