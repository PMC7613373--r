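#' Pipeline configuration
#'
#' Single configuration object orchestrating the full training workflow.
#' The defaults reproduce the reference configuration: a 1000-sample
#' simulated database, 20 principal components, diversity active learning
#' seeded with 10 percent of the pool, 24 added non-vegetated spectra, and
#' a 20 percent coefficient-of-variation masking threshold.
#'
#' @param n_train training database size.
#' @param rtm sampling configuration, see [database_config()].
#' @param preprocessing a [preprocess_config()].
#' @param n_components PCA components retained.
#' @param kernel_mode_final kernel for the final fit: `"auto"` (default)
#'   fits both the isotropic and the ARD kernel and keeps the one with the
#'   lower validation RMSE -- the same decision criterion the
#'   active-learning loop uses; `"isotropic"` or `"ard"` force a kernel.
#' @param n_restarts restarts for the final fit.
#' @param al_enabled run the active-learning reduction.
#' @param init_frac initial fraction for active learning.
#' @param nv_enabled add non-vegetated spectra.
#' @param nv_count size of the synthetic non-vegetated library (used when
#'   no library is supplied to [train_pipeline()]).
#' @param cv_threshold masking threshold in percent for mapping.
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_train = 1000, rtm = database_config(),
                            preprocessing = preprocess_config(),
                            n_components = 20,
                            kernel_mode_final = "auto", n_restarts = 3,
                            al_enabled = TRUE, init_frac = 0.10,
                            nv_enabled = TRUE, nv_count = 24,
                            cv_threshold = 20, seed = 1L) {
  structure(
    list(
      n_train = n_train, rtm = rtm, preprocessing = preprocessing,
      n_components = n_components, kernel_mode_final = kernel_mode_final,
      n_restarts = n_restarts, al_enabled = al_enabled,
      init_frac = init_frac, nv_enabled = nv_enabled, nv_count = nv_count,
      cv_threshold = cv_threshold, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns the configuration.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg
}

#' Train a full retrieval model
#'
#' Runs the hybrid training workflow: simulate the labelled database on the
#' harmonized grid, compress it with centered PCA, optionally reduce the
#' pool by diversity active learning against the validation set, optionally
#' append non-vegetated spectra (label 0), and fit the final GP regression
#' model (ARD kernel, multi-start). With `al_enabled = FALSE` the model is
#' trained on the full pool; with `nv_enabled = FALSE` no non-vegetated
#' spectra are added.
#'
#' @param cfg a [pipeline_config()].
#' @param validation list with `spectra` (m x harmonized-bands) and `cnc`
#'   (g/m^2), e.g. from [make_field_campaign()].
#' @param sensor the raw sensor [band_grid()].
#' @param nv_spectra optional non-vegetated spectra matrix on the harmonized
#'   grid; by default a synthetic library of `cfg$nv_count` spectra.
#' @param verbose print stage progress.
#' @return list with `bundle` ([model_bundle()]), `al` ([run_ebd_al()]
#'   result or `NULL`), `metrics` (validation [goodness_of_fit()]),
#'   `database` (the training database).
#' @export
train_pipeline <- function(cfg, validation, sensor = sensor_band_grid(),
                           nv_spectra = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- cfg$seed

  say("stage 1/5: simulating %d-sample training database", cfg$n_train)
  hgrid <- harmonized_grid(sensor)
  db <- build_training_database(cfg$n_train,
    grid = hgrid, seed = seed,
    config = cfg$rtm
  )

  say("stage 2/5: PCA compression to %d components", cfg$n_components)
  pca <- fit_pca(db$reflectance, k = cfg$n_components)
  pool <- labeled_pool(project(pca, db$reflectance), db$parameters$cnc)
  val <- validation_set(project(pca, validation$spectra), validation$cnc)

  al <- NULL
  if (cfg$al_enabled) {
    say("stage 3/5: diversity active learning over %d candidates", cfg$n_train)
    al <- run_ebd_al(pool, val,
      init_frac = cfg$init_frac,
      seed = seed + 1L, verbose = verbose
    )
    idx <- match(al$selected_ids, pool$ids)
    training <- labeled_pool(
      pool$scores[idx, , drop = FALSE],
      pool$labels[idx], pool$ids[idx]
    )
  } else {
    say("stage 3/5: active learning disabled; using the full pool")
    training <- pool
  }

  if (cfg$nv_enabled) {
    if (is.null(nv_spectra)) {
      nv_spectra <- make_nonvegetated_library(cfg$nv_count,
        seed = seed + 2L,
        grid = hgrid
      )$spectra
    }
    say("stage 4/5: adding %d non-vegetated spectra", nrow(nv_spectra))
    training <- augment_nonvegetated(training, nv_spectra, pca)
  } else {
    say("stage 4/5: non-vegetated augmentation disabled")
  }

  say(
    "stage 5/5: final %s fit on %d samples", cfg$kernel_mode_final,
    nrow(training$scores)
  )
  val_rmse <- function(model) {
    pr <- gpr_predict(model, val$scores)
    goodness_of_fit(pr$mean, val$cnc_measured)$rmse
  }
  if (identical(cfg$kernel_mode_final, "auto")) {
    cand <- lapply(c("isotropic", "ard"), function(km) {
      gpr_fit(training$scores, training$labels,
        kernel_mode = km,
        n_restarts = cfg$n_restarts, seed = seed + 3L
      )
    })
    rmses <- vapply(cand, val_rmse, numeric(1))
    gpr <- cand[[which.min(rmses)]]
    say(
      "kernel selection by validation RMSE: isotropic %.3f, ard %.3f -> %s",
      rmses[1], rmses[2], gpr$kernel_mode
    )
  } else {
    gpr <- gpr_fit(training$scores, training$labels,
      kernel_mode = cfg$kernel_mode_final, n_restarts = cfg$n_restarts,
      seed = seed + 3L
    )
  }
  bundle <- model_bundle(sensor, cfg$preprocessing, pca, gpr,
    provenance = list(
      seed = seed, n_train = cfg$n_train,
      al_enabled = cfg$al_enabled, nv_enabled = cfg$nv_enabled,
      n_selected = length(training$labels), created = format(Sys.time())
    )
  )
  ev <- evaluate(bundle, validation)
  say(
    "validation: RMSE %.2f g/m2, NRMSE %.1f%%, R2 %.2f",
    ev$metrics$rmse, ev$metrics$nrmse, ev$metrics$r2
  )
  list(bundle = bundle, al = al, metrics = ev$metrics, database = db)
}

#' Evaluate a bundle against a validation set
#'
#' Predicts every validation record and reports pooled goodness-of-fit
#' statistics plus per-record scatter data for measured-vs-estimated plots
#' with uncertainty intervals.
#'
#' @param bundle a [model_bundle()].
#' @param validation list with `spectra` (on the harmonized grid) and `cnc`.
#' @return list with `metrics` ([goodness_of_fit()]) and `scatter`
#'   (data frame `measured`, `predicted`, `sd`).
#' @export
evaluate <- function(bundle, validation) {
  scores <- project(bundle$pca, validation$spectra)
  pr <- gpr_predict(bundle$gpr, scores)
  list(
    metrics = goodness_of_fit(pr$mean, validation$cnc),
    scatter = data.frame(
      measured = validation$cnc, predicted = pr$mean,
      sd = sqrt(pr$variance)
    )
  )
}
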