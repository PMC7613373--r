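#' Crop archetype parameter trajectories
#'
#' Documentation-level presets describing how the leaf/canopy inputs of a
#' wheat-like and a corn-like crop evolve over a normalised growth stage
#' `g` in \[0, 1\]. The trajectories are designed so the implied CNC label
#' spans roughly 1-20 g/m^2 across the season -- the envelope of typical
#' leaves-plus-stalks field measurements -- and are not calibrated to real
#' cultivars.
#'
#' @param archetype `"wheat"` or `"corn"`.
#' @param g growth stage in \[0, 1\] (vectorised).
#' @return data frame of leaf and canopy parameters per stage.
#' @export
crop_archetype <- function(archetype = c("wheat", "corn"), g) {
  archetype <- match.arg(archetype)
  s <- sin(pi * pmin(pmax(g, 0), 1))
  if (archetype == "wheat") {
    data.frame(
      N_struct = 1.4 + 0.3 * g,
      C_ab = 15 + 50 * s,
      C_xc = 4 + 6 * s,
      C_anth = 0.3 + 0.6 * (1 - s),
      C_w = 0.004 + 0.012 * s,
      C_p = 0.0009 + 0.0011 * s,
      CBC = 0.003 + 0.004 * g,
      LAI = 0.3 + 5.2 * s^1.1,
      ALA = 55 + 10 * g,
      HotS = 0.05,
      alpha_soil = 0.55
    )
  } else {
    data.frame(
      N_struct = 1.5 + 0.4 * g,
      C_ab = 20 + 45 * s,
      C_xc = 5 + 7 * s,
      C_anth = 0.2 + 0.8 * (1 - s),
      C_w = 0.005 + 0.013 * s,
      C_p = 0.0011 + 0.0013 * s,
      CBC = 0.004 + 0.005 * g,
      LAI = 0.2 + 4.3 * s^0.9,
      ALA = 38 + 12 * g,
      HotS = 0.12,
      alpha_soil = 0.45
    )
  }
}

#' Field-campaign generator configuration
#'
#' @param n_records number of (spectrum, measured CNC) records (>= 2).
#' @param crop_archetypes archetypes sampled from, see [crop_archetype()].
#' @param noise multiplicative spectral noise SD in percent (default 3).
#' @param label_noise CNC measurement noise SD in g/m^2 (default 1).
#' @param seed integer seed.
#' @return a named list of class `campaign_config`.
#' @export
campaign_config <- function(n_records = 30, crop_archetypes = c("wheat", "corn"),
                            noise = 3, label_noise = 1, seed = NULL) {
  if (n_records < 2) stop_domain("n_records must be >= 2")
  if (noise < 0 || label_noise < 0) stop_domain("noise levels must be >= 0")
  structure(
    list(
      n_records = n_records, crop_archetypes = crop_archetypes,
      noise = noise, label_noise = label_noise, seed = seed
    ),
    class = "campaign_config"
  )
}

# simulate one parameter row to a sensor-grid spectrum (shared by the
# campaign and scene generators)
simulate_row_spectrum <- function(row, W, soil_ref, geometry) {
  leaf <- leaf_params(
    N_struct = row$N_struct, C_ab = row$C_ab, C_xc = row$C_xc,
    C_anth = row$C_anth, C_w = row$C_w, C_p = row$C_p, CBC = row$CBC
  )
  canopy <- canopy_params(
    LAI = row$LAI, ALA = row$ALA, HotS = row$HotS,
    alpha_soil = row$alpha_soil
  )
  brf <- sail4(canopy, prospect_pro(leaf),
    soil_reflectance = canopy$alpha_soil * soil_ref, geometry = geometry
  )
  drop(matrix(brf, nrow = 1) %*% W)
}

#' Synthetic field campaign
#'
#' Emulates a destructive-sampling field campaign: crop-archetype parameter
#' trajectories are drawn across growth stages with record-level jitter,
#' reflectance is simulated with the same radiative transfer family as the
#' training database, resampled to the sensor grid, restricted to the
#' harmonized band subset, and perturbed with multiplicative spectral noise;
#' CNC labels are computed from LAI and protein content *before* Gaussian
#' measurement noise is added (then clipped at 0). A deliberately
#' optimistic stand-in for unpublished campaign data: real canopies deviate
#' from the turbid-medium model far more than noise alone.
#'
#' @param cfg a [campaign_config()].
#' @param sensor the raw sensor [band_grid()].
#' @return list with `spectra` (m x harmonized-bands matrix), `grid`
#'   (harmonized [band_grid()]), `cnc` (noisy labels, g/m^2), `truth`
#'   (data frame of true parameters incl. noise-free `cnc_true`).
#' @export
make_field_campaign <- function(cfg = campaign_config(),
                                sensor = sensor_band_grid()) {
  wl <- 400:2500
  keep <- harmonized_band_mask(sensor)
  hgrid <- band_grid(sensor$center[keep], sensor$fwhm[keep])
  W <- srf_weights(wl, hgrid)
  soil_ref <- soil_reference(wl)
  geom <- view_geometry()
  with_seed_if(cfg$seed, {
    m <- cfg$n_records
    arch <- sample(cfg$crop_archetypes, m, replace = TRUE)
    stage <- stats::runif(m, 0.08, 0.97)
    spectra <- matrix(NA_real_, m, nrow(hgrid))
    truth <- NULL
    for (i in seq_len(m)) {
      row <- crop_archetype(arch[i], stage[i])
      # record-level biological variability around the trajectory
      row$LAI <- max(0.05, row$LAI * stats::rlnorm(1, 0, 0.15))
      row$C_p <- max(2e-4, row$C_p * stats::rlnorm(1, 0, 0.10))
      row$C_ab <- max(1, row$C_ab + stats::rnorm(1, 0, 5))
      row$alpha_soil <- min(1, max(0, row$alpha_soil + stats::rnorm(1, 0, 0.1)))
      # keep the implied CNC inside the leaves-plus-stalks field envelope
      # (~21 g/m2): very dense canopies with peak protein are not observed
      cnc_i <- compute_cnc(row$LAI, row$C_p)
      if (cnc_i > 21) row$LAI <- row$LAI * 21 / cnc_i
      spectra[i, ] <- simulate_row_spectrum(row, W, soil_ref, geom)
      truth <- rbind(truth, cbind(
        archetype = arch[i], stage = stage[i], row
      ))
    }
    truth$cnc_true <- compute_cnc(truth$LAI, truth$C_p)
    if (cfg$noise > 0) {
      spectra <- spectra * matrix(
        stats::rnorm(length(spectra), 1, cfg$noise / 100),
        nrow = m
      )
      spectra <- pmin(pmax(spectra, 0), 1)
    }
    cnc <- pmax(truth$cnc_true + stats::rnorm(m, 0, cfg$label_noise), 0)
    list(spectra = spectra, grid = hgrid, cnc = cnc, truth = truth)
  })
}

#' Synthetic non-vegetated spectral library
#'
#' Generates `k` pairwise-distinct smooth spectra of non-vegetated surfaces
#' -- scaled bare-soil curves, dark flat water-like curves (NIR/SWIR
#' reflectance below 0.05) and sloped bright man-made-surface curves -- with
#' small random perturbations, on the requested band grid.
#'
#' @param k number of spectra (default 24).
#' @param seed integer seed.
#' @param grid target [band_grid()] (default the harmonized sensor subset).
#' @return list with `spectra` (k x bands matrix), `grid`, `type`
#'   (character per spectrum).
#' @export
make_nonvegetated_library <- function(k = 24, seed = NULL,
                                      grid = harmonized_grid(sensor_band_grid())) {
  if (k < 1) stop_domain("k must be >= 1")
  wl <- 400:2500
  W <- srf_weights(wl, grid)
  soil_ref <- soil_reference(wl)
  with_seed_if(seed, {
    types <- rep(c("soil", "water", "manmade"), length.out = k)
    spectra <- matrix(NA_real_, k, nrow(grid))
    for (i in seq_len(k)) {
      base <- switch(types[i],
        soil = soil_ref * stats::runif(1, 0.35, 1.0) *
          (1 + stats::runif(1, -0.1, 0.1) * (wl - 1400) / 1000),
        water = 0.035 * exp(-(wl - 400) / stats::runif(1, 350, 600)) +
          stats::runif(1, 0.002, 0.008),
        manmade = stats::runif(1, 0.15, 0.45) +
          stats::runif(1, -0.08, 0.12) * (wl - 400) / 2100
      )
      base <- base + stats::rnorm(1, 0, 0.004) # brightness jitter
      spectra[i, ] <- drop(matrix(pmin(pmax(base, 0.001), 0.9), nrow = 1) %*% W)
    }
    list(spectra = spectra, grid = grid, type = types)
  })
}

#' Scene generator configuration
#'
#' @param rows,cols scene size in pixels (default 64 x 64).
#' @param field_patch_size side length of quadratic field patches (pixels).
#' @param fraction_nonvegetated fraction of patches assigned to
#'   non-vegetated surfaces, in \[0, 1\].
#' @param noise multiplicative spectral noise SD in percent.
#' @param seed integer seed.
#' @return a named list of class `scene_config`.
#' @export
scene_config <- function(rows = 64, cols = 64, field_patch_size = 16,
                         fraction_nonvegetated = 0.3, noise = 2, seed = NULL) {
  if (fraction_nonvegetated < 0 || fraction_nonvegetated > 1) {
    stop_domain("fraction_nonvegetated must be in [0, 1]")
  }
  structure(
    list(
      rows = rows, cols = cols, field_patch_size = field_patch_size,
      fraction_nonvegetated = fraction_nonvegetated, noise = noise,
      seed = seed
    ),
    class = "scene_config"
  )
}

#' Synthetic ground-truthed scene
#'
#' Builds a patchwork landscape: quadratic patches are assigned either a
#' crop archetype at a random growth stage (field-level leaf parameters,
#' per-pixel LAI and soil-background variation) or a non-vegetated surface
#' (truth CNC 0). Per-pixel spectra are simulated on the native grid,
#' resampled to the raw sensor grid and perturbed with multiplicative
#' noise, so the cube exercises the full cleaning chain.
#'
#' @param cfg a [scene_config()].
#' @param sensor the raw sensor [band_grid()].
#' @return list with `cube` (a [hypercube()] on the sensor grid), `truth`
#'   (rows x cols matrix of true CNC, g/m^2), `is_vegetated`
#'   (logical matrix).
#' @export
make_scene <- function(cfg = scene_config(), sensor = sensor_band_grid()) {
  wl <- 400:2500
  W <- srf_weights(wl, sensor)
  soil_ref <- soil_reference(wl)
  geom <- view_geometry()
  with_seed_if(cfg$seed, {
    rows <- cfg$rows
    cols <- cfg$cols
    p <- cfg$field_patch_size
    pr <- ceiling(rows / p)
    pc <- ceiling(cols / p)
    n_patch <- pr * pc
    nv_patch <- stats::runif(n_patch) < cfg$fraction_nonvegetated
    nv_lib <- make_nonvegetated_library(
      k = max(3, sum(nv_patch)),
      grid = sensor
    )
    vals <- array(NA_real_, c(rows, cols, nrow(sensor)))
    truth <- matrix(0, rows, cols)
    veg <- matrix(FALSE, rows, cols)
    patch_id <- 0
    for (ir in seq_len(pr)) {
      for (ic in seq_len(pc)) {
        patch_id <- patch_id + 1
        rsel <- ((ir - 1) * p + 1):min(ir * p, rows)
        csel <- ((ic - 1) * p + 1):min(ic * p, cols)
        if (nv_patch[patch_id]) {
          base <- nv_lib$spectra[1 + (patch_id %% nrow(nv_lib$spectra)), ]
          for (r in rsel) {
            for (c in csel) {
              vals[r, c, ] <- base * stats::rlnorm(1, 0, 0.03)
            }
          }
        } else {
          arch <- sample(c("wheat", "corn"), 1)
          stage <- stats::runif(1, 0.15, 0.95)
          field <- crop_archetype(arch, stage)
          field$C_p <- max(2e-4, field$C_p * stats::rlnorm(1, 0, 0.1))
          # leaf biochemistry is field-level: leaf optics computed once
          optics <- prospect_pro(leaf_params(
            N_struct = field$N_struct, C_ab = field$C_ab,
            C_xc = field$C_xc, C_anth = field$C_anth,
            C_w = field$C_w, C_p = field$C_p, CBC = field$CBC
          ))
          for (r in rsel) {
            for (c in csel) {
              lai <- max(0.05, field$LAI * stats::rlnorm(1, 0, 0.12))
              asoil <- min(1, max(
                0,
                field$alpha_soil + stats::rnorm(1, 0, 0.08)
              ))
              canopy <- canopy_params(
                LAI = lai, ALA = field$ALA,
                HotS = field$HotS, alpha_soil = asoil
              )
              brf <- sail4(canopy, optics,
                soil_reflectance = asoil * soil_ref, geometry = geom
              )
              vals[r, c, ] <- drop(matrix(brf, nrow = 1) %*% W)
              truth[r, c] <- compute_cnc(lai, field$C_p)
              veg[r, c] <- TRUE
            }
          }
        }
      }
    }
    if (cfg$noise > 0) {
      vals <- vals * array(
        stats::rnorm(length(vals), 1, cfg$noise / 100),
        dim(vals)
      )
      vals <- pmin(pmax(vals, 0), 1)
    }
    list(
      cube = hypercube(vals, sensor),
      truth = truth, is_vegetated = veg
    )
  })
}
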