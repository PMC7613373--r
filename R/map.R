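#' Hyperspectral image cube
#'
#' An in-memory reflectance cube: a `rows x cols x bands` array on a band
#' grid, with an optional per-pixel nodata mask. Plain-text (long CSV)
#' import/export is provided by [read_hypercube_csv()] /
#' [write_hypercube_csv()].
#'
#' @param values numeric array `rows x cols x bands` of reflectance
#'   fractions.
#' @param grid a [band_grid()] with `bands` entries.
#' @param nodata_mask logical `rows x cols` matrix, `TRUE` where the pixel
#'   carries no data (default none).
#' @return object of class `hypercube`.
#' @export
hypercube <- function(values, grid, nodata_mask = NULL) {
  d <- dim(values)
  if (length(d) != 3) stop_domain("values must be a rows x cols x bands array")
  if (d[3] != nrow(grid)) stop_domain("band count must match the grid")
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, d[1], d[2])
  if (!all(dim(nodata_mask) == d[1:2])) stop_domain("nodata_mask shape mismatch")
  valid_vals <- values[rep(!nodata_mask, d[3])]
  if (anyNA(valid_vals) || any(!is.finite(valid_vals))) {
    stop_domain("values must be finite where valid")
  }
  structure(
    list(
      values = values, grid = grid, nodata_mask = nodata_mask,
      rows = d[1], cols = d[2], bands = d[3]
    ),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), %d nodata\n",
    x$rows, x$cols, x$bands, min(x$grid$center), max(x$grid$center),
    sum(x$nodata_mask)
  ))
  invisible(x)
}

#' @rdname hypercube
#' @param cube a `hypercube`.
#' @param path CSV path; columns `row`, `col`, then one column per band
#'   (named `b<center>`), with a commented header carrying the band grid.
#' @export
write_hypercube_csv <- function(cube, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# centers_nm: ", paste(cube$grid$center, collapse = " ")), con)
  writeLines(paste0("# fwhm_nm: ", paste(cube$grid$fwhm, collapse = " ")), con)
  flat <- matrix(cube$values, nrow = cube$rows * cube$cols)
  df <- data.frame(
    row = rep(seq_len(cube$rows), cube$cols),
    col = rep(seq_len(cube$cols), each = cube$rows),
    nodata = as.integer(as.vector(cube$nodata_mask))
  )
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:3)] <- paste0("b", seq_len(cube$bands))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname hypercube
#' @export
read_hypercube_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  centers <- as.numeric(strsplit(sub("# centers_nm: ", "", hdr[1]), " ")[[1]])
  fwhm <- as.numeric(strsplit(sub("# fwhm_nm: ", "", hdr[2]), " ")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  rows <- max(df$row)
  cols <- max(df$col)
  grid <- band_grid(centers, fwhm)
  vals <- array(NA_real_, c(rows, cols, length(centers)))
  flat <- as.matrix(df[, -(1:3), drop = FALSE])
  ord <- order(df$col, df$row)
  vals[] <- flat[ord, ]
  nodata <- matrix(FALSE, rows, cols)
  nodata[cbind(df$row, df$col)] <- df$nodata == 1
  vals[is.na(vals)] <- 0
  hypercube(vals, grid, nodata)
}

#' Apply a trained model bundle to an image cube
#'
#' Runs the full retrieval chain per valid pixel -- cleaning onto the
#' harmonized grid (when the cube is on the raw sensor grid), PCA
#' projection, GP prediction -- and assembles per-pixel CNC mean, predictive
#' SD, coefficient of variation and a validity mask. Results are identical
#' to looping [predict_spectrum()] pixel by pixel.
#'
#' @param cube a [hypercube()] on the bundle's sensor grid, its harmonized
#'   grid, or the native 1 nm grid (resampled internally).
#' @param bundle a [model_bundle()].
#' @param cv_epsilon predictive means at or below this value (g/m^2) are
#'   flagged invalid instead of producing unbounded CV (default 1e-6).
#' @param include_noise use observation-level predictive variance
#'   (adds `sigma_n^2`); default `FALSE` (latent-function SD).
#' @return object of class `trait_map`: matrices `cnc_mean`, `cnc_sd`,
#'   `cv_pct`, logical `valid_mask`, plus the masking threshold applied (if
#'   any; see [mask_by_uncertainty()]).
#' @export
apply_model <- function(cube, bundle, cv_epsilon = 1e-6, include_noise = FALSE) {
  npix <- cube$rows * cube$cols
  # column-major pixel order throughout (matches matrix(v, rows, cols))
  spec_mat <- matrix(cube$values, nrow = npix) # npix x bands
  valid <- !as.vector(cube$nodata_mask)

  harm <- bundle$harmonized_grid
  X <- matrix(NA_real_, nrow = npix, ncol = nrow(harm))
  if (grids_equal(cube$grid, harm)) {
    X[valid, ] <- spec_mat[valid, , drop = FALSE]
  } else if (grids_equal(cube$grid, bundle$sensor_grid)) {
    for (j in which(valid)) {
      X[j, ] <- preprocess_pixel(spec_mat[j, ], cube$grid,
        cfg = bundle$preprocess
      )$values
    }
  } else if (all(diff(cube$grid$center) <= 1.5)) {
    W <- srf_weights(cube$grid$center, bundle$sensor_grid)
    for (j in which(valid)) {
      raw <- drop(matrix(spec_mat[j, ], nrow = 1) %*% W)
      X[j, ] <- preprocess_pixel(raw, bundle$sensor_grid,
        cfg = bundle$preprocess
      )$values
    }
  } else {
    stop_domain("cube band grid cannot be resolved to the bundle's grids")
  }

  mu <- rep(NA_real_, npix)
  sd_ <- rep(NA_real_, npix)
  # per-pixel prediction through the same single-spectrum path as
  # predict_spectrum(), so map results are bit-identical to a pixel loop
  for (j in which(valid)) {
    pr <- gpr_predict(bundle$gpr, project(bundle$pca, X[j, ]),
      include_noise = include_noise
    )
    mu[j] <- pr$mean
    sd_[j] <- sqrt(pr$variance)
  }
  shape <- function(v) matrix(v, nrow = cube$rows, ncol = cube$cols)
  tm <- structure(
    list(
      cnc_mean = shape(mu), cnc_sd = shape(sd_),
      cv_pct = NULL, valid_mask = shape(valid), cv_threshold = NULL
    ),
    class = "trait_map"
  )
  tm$cv_pct <- relative_uncertainty(tm, epsilon = cv_epsilon)
  degen <- tm$valid_mask & !is.na(tm$cnc_mean) & tm$cnc_mean <= cv_epsilon
  tm$valid_mask <- tm$valid_mask & !degen
  tm
}

grids_equal <- function(a, b) {
  nrow(a) == nrow(b) && all(abs(a$center - b$center) < 1e-6)
}

#' Per-pixel relative uncertainty (coefficient of variation)
#'
#' `100 * sd / mean` in percent. Pixels with mean at or below `epsilon` are
#' returned as `NA` (and flagged invalid by [apply_model()]) rather than
#' propagating unbounded values.
#'
#' @param map a `trait_map`.
#' @param epsilon degeneracy threshold on the mean (g/m^2).
#' @return matrix of CV in percent.
#' @export
relative_uncertainty <- function(map, epsilon = 1e-6) {
  cv <- 100 * map$cnc_sd / map$cnc_mean
  cv[!is.na(map$cnc_mean) & map$cnc_mean <= epsilon] <- NA_real_
  cv
}

#' Mask a trait map by relative uncertainty
#'
#' Invalidates pixels whose coefficient of variation exceeds the threshold
#' (20 percent by default, the Global Climate Observing System accuracy
#' goal). Idempotent, and monotone in the threshold.
#'
#' @param map a `trait_map` with `cv_pct` computed.
#' @param threshold_pct CV threshold in percent.
#' @return the masked `trait_map`.
#' @export
mask_by_uncertainty <- function(map, threshold_pct = 20) {
  drop_ <- !is.na(map$cv_pct) & map$cv_pct > threshold_pct
  map$valid_mask <- map$valid_mask & !drop_ & !is.na(map$cv_pct)
  map$cv_threshold <- threshold_pct
  map
}

#' @export
print.trait_map <- function(x, ...) {
  ok <- x$valid_mask
  cat(sprintf(
    "<trait_map> %d x %d pixels, %d valid; CNC %.2f-%.2f g/m2%s\n",
    nrow(ok), ncol(ok), sum(ok),
    suppressWarnings(min(x$cnc_mean[ok])),
    suppressWarnings(max(x$cnc_mean[ok])),
    if (!is.null(x$cv_threshold)) sprintf(" (CV mask %g%%)", x$cv_threshold) else ""
  ))
  invisible(x)
}
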