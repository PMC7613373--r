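#' Trained retrieval model bundle
#'
#' Packs everything needed to turn a raw sensor spectrum into a CNC
#' estimate: the sensor band grid, the preprocessing configuration, the PCA
#' compression model, the fitted GP regression model and provenance
#' (seeds, sizes, creation time).
#'
#' @param sensor_grid raw sensor [band_grid()].
#' @param preprocess a [preprocess_config()].
#' @param pca a [fit_pca()] model.
#' @param gpr a [gpr_fit()] model.
#' @param provenance named list of free-form provenance entries.
#' @return object of class `model_bundle`.
#' @export
model_bundle <- function(sensor_grid, preprocess, pca, gpr, provenance = list()) {
  harmonized <- harmonized_grid(sensor_grid)
  if (length(pca$mean) != nrow(harmonized)) {
    stop_domain("PCA band count does not match the harmonized grid")
  }
  structure(
    list(
      sensor_grid = sensor_grid, harmonized_grid = harmonized,
      preprocess = preprocess, pca = pca, gpr = gpr,
      provenance = c(provenance, list(package_version = "0.1.0"))
    ),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> %d sensor bands -> %d harmonized -> %d PCs -> GPR (N = %d, %s)\n",
    nrow(x$sensor_grid), nrow(x$harmonized_grid), x$pca$n_components,
    nrow(x$gpr$X_train), x$gpr$kernel_mode
  ))
  invisible(x)
}

#' Predict CNC for a single spectrum through a bundle
#'
#' @param bundle a [model_bundle()].
#' @param values reflectance per band of `grid`.
#' @param grid the spectrum's [band_grid()] (sensor or harmonized).
#' @param include_noise observation-level variance, see [gpr_predict()].
#' @return one-row data frame with `mean`, `variance`, `sd`, `cv_pct`.
#' @export
predict_spectrum <- function(bundle, values, grid, include_noise = FALSE) {
  if (grids_equal(grid, bundle$harmonized_grid)) {
    x <- values
  } else if (grids_equal(grid, bundle$sensor_grid)) {
    x <- preprocess_pixel(values, grid, cfg = bundle$preprocess)$values
  } else {
    stop_domain("spectrum grid matches neither the sensor nor harmonized grid")
  }
  pr <- gpr_predict(bundle$gpr, project(bundle$pca, x),
    include_noise = include_noise
  )
  pr$sd <- sqrt(pr$variance)
  pr$cv_pct <- ifelse(pr$mean > 1e-6, 100 * pr$sd / pr$mean, NA_real_)
  pr
}

# lossless double <-> text codecs: 17 significant digits round-trip any
# IEEE double exactly
enc_num <- function(x) {
  if (is.matrix(x)) {
    list(dim = dim(x), data = sprintf("%.17g", as.vector(x)))
  } else {
    sprintf("%.17g", as.vector(x))
  }
}
dec_num <- function(x) {
  if (is.list(x) && !is.null(x$dim)) {
    matrix(as.numeric(x$data), nrow = x$dim[1], ncol = x$dim[2])
  } else {
    as.numeric(unlist(x))
  }
}

#' Serialize a model bundle to JSON
#'
#' Floating-point arrays are encoded as 17-significant-digit strings, which
#' round-trip IEEE doubles exactly, so restoring a bundle leaves all
#' predictions bit-identical.
#'
#' @param bundle a [model_bundle()].
#' @param path JSON file path.
#' @return `read_bundle` returns the restored [model_bundle()].
#' @export
write_bundle <- function(bundle, path) {
  g <- bundle$gpr
  payload <- list(
    schema = "cncmap-bundle-1",
    sensor_grid = list(
      center = enc_num(bundle$sensor_grid$center),
      fwhm = enc_num(bundle$sensor_grid$fwhm)
    ),
    preprocess = list(
      spike_threshold = enc_num(bundle$preprocess$spike_threshold),
      windows = lapply(bundle$preprocess$windows, enc_num),
      fill_method = bundle$preprocess$fill_method %||% "interp",
      spar = if (is.null(bundle$preprocess$spar)) NULL else enc_num(bundle$preprocess$spar)
    ),
    pca = list(
      mean = enc_num(as.numeric(bundle$pca$mean)),
      loadings = enc_num(bundle$pca$loadings),
      explained_variance_ratio = enc_num(bundle$pca$explained_variance_ratio),
      n_components = bundle$pca$n_components
    ),
    gpr = list(
      X_train = enc_num(g$X_train), y_train = enc_num(g$y_train),
      y_offset = enc_num(g$y_offset),
      theta = lapply(g$theta, enc_num),
      kernel_mode = g$kernel_mode, nlml = enc_num(g$nlml)
    ),
    provenance = bundle$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor <- band_grid(dec_num(p$sensor_grid$center), dec_num(p$sensor_grid$fwhm))
  pre <- preprocess_config(
    spike_threshold = dec_num(p$preprocess$spike_threshold),
    windows = lapply(
      seq_len(NROW(p$preprocess$windows)),
      function(i) {
        w <- p$preprocess$windows
        if (is.matrix(w)) as.numeric(w[i, ]) else dec_num(w[[i]])
      }
    ),
    fill_method = p$preprocess$fill_method,
    spar = if (is.null(p$preprocess$spar)) NULL else dec_num(p$preprocess$spar)
  )
  pca <- structure(
    list(
      mean = dec_num(p$pca$mean), loadings = dec_num(p$pca$loadings),
      explained_variance_ratio = dec_num(p$pca$explained_variance_ratio),
      n_components = p$pca$n_components
    ),
    class = "pca_model"
  )
  theta <- list(
    nu = dec_num(p$gpr$theta$nu), sigma_b = dec_num(p$gpr$theta$sigma_b),
    sigma_n = dec_num(p$gpr$theta$sigma_n)
  )
  X <- dec_num(p$gpr$X_train)
  y <- dec_num(p$gpr$y_train)
  y_offset <- dec_num(p$gpr$y_offset)
  Kse <- kernel_matrix(theta, sqdist_features(X))
  L <- chol_with_jitter(Kse + diag(theta$sigma_n^2, nrow(X)), theta$nu)
  gpr <- structure(
    list(
      X_train = X, y_train = y, y_offset = y_offset,
      theta = theta, alpha = backsolve(L, forwardsolve(t(L), y - y_offset)),
      chol_factor = L, kernel_mode = p$gpr$kernel_mode,
      nlml = dec_num(p$gpr$nlml)
    ),
    class = "gpr_model"
  )
  model_bundle(sensor, pre, pca, gpr, provenance = as.list(p$provenance))
}
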