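# Shared fixtures, built lazily and cached for the whole test run. The
# heavier objects (the 1000-sample database, the active-learning run, the
# trained bundle) are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_db1000 <- function() {
  fixture("db1000", function() build_training_database(1000, seed = 42))
}

fx_campaign <- function() {
  fixture("campaign", function() {
    make_field_campaign(campaign_config(n_records = 30, seed = 5))
  })
}

fx_pca <- function() {
  fixture("pca", function() fit_pca(fx_db1000()$reflectance, 20))
}

fx_pool <- function() {
  fixture("pool", function() {
    db <- fx_db1000()
    labeled_pool(project(fx_pca(), db$reflectance), db$parameters$cnc)
  })
}

fx_val <- function() {
  fixture("val", function() {
    camp <- fx_campaign()
    validation_set(project(fx_pca(), camp$spectra), camp$cnc)
  })
}

fx_al <- function() {
  fixture("al", function() run_ebd_al(fx_pool(), fx_val(), seed = 11))
}

fx_full_model <- function() {
  fixture("full_model", function() {
    gpr_fit(fx_pool()$scores, fx_pool()$labels,
      kernel_mode = "isotropic",
      n_restarts = 2, seed = 3
    )
  })
}

# final bundle: AL-selected samples + 24 synthetic non-vegetated spectra,
# refit choosing the kernel by validation RMSE (as train_pipeline does)
fx_bundle <- function() {
  fixture("bundle", function() {
    al <- fx_al()
    pool <- fx_pool()
    idx <- match(al$selected_ids, pool$ids)
    training <- labeled_pool(
      pool$scores[idx, , drop = FALSE],
      pool$labels[idx], pool$ids[idx]
    )
    nv <- make_nonvegetated_library(24,
      seed = 7,
      grid = harmonized_grid(sensor_band_grid())
    )
    training <- augment_nonvegetated(training, nv$spectra, fx_pca())
    cand <- lapply(c("isotropic", "ard"), function(km) {
      gpr_fit(training$scores, training$labels,
        kernel_mode = km,
        n_restarts = 2, seed = 13
      )
    })
    rmses <- vapply(cand, function(m) {
      pr <- gpr_predict(m, fx_val()$scores)
      goodness_of_fit(pr$mean, fx_val()$cnc_measured)$rmse
    }, numeric(1))
    gpr <- cand[[which.min(rmses)]]
    model_bundle(sensor_band_grid(), preprocess_config(), fx_pca(), gpr)
  })
}

fx_scene <- function() {
  fixture("scene", function() make_scene(scene_config(seed = 21)))
}

# a GP model at user-fixed hyperparameters (no optimisation), for oracle
# comparisons
make_fixed_gpr <- function(X, y, theta, kernel_mode = "isotropic") {
  X <- as.matrix(X)
  yc <- y - mean(y)
  Kse <- cncmap:::kernel_matrix(theta, cncmap:::sqdist_features(X))
  L <- cncmap:::chol_with_jitter(Kse + diag(theta$sigma_n^2, nrow(X)), theta$nu)
  structure(
    list(
      X_train = X, y_train = y, y_offset = mean(y), theta = theta,
      alpha = backsolve(L, forwardsolve(t(L), yc)),
      chol_factor = L, kernel_mode = kernel_mode, nlml = NA_real_
    ),
    class = "gpr_model"
  )
}

# simple smooth synthetic canopy-like spectrum on an arbitrary grid
smooth_test_spectrum <- function(centers) {
  0.05 + 0.25 / (1 + exp(-(centers - 720) / 18)) +
    0.08 * exp(-(centers - 560)^2 / (2 * 40^2)) -
    0.12 / (1 + exp(-(centers - 1900) / 160))
}
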