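#' Labeled sample pool for active learning
#'
#' @param scores n x B matrix of principal-component scores.
#' @param labels CNC labels in g/m^2 (length n).
#' @param ids stable sample identifiers (default `1:n`).
#' @return object of class `labeled_pool`.
#' @export
labeled_pool <- function(scores, labels, ids = seq_len(nrow(scores))) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(labels) || length(ids) != length(labels)) {
    stop_domain("scores, labels and ids must be row-aligned")
  }
  if (anyDuplicated(ids)) stop_domain("ids must be unique")
  structure(list(scores = scores, labels = labels, ids = ids),
    class = "labeled_pool"
  )
}

#' Validation set for active learning
#'
#' Paired (projected spectrum, measured CNC) records; must be produced by
#' the same preprocessing and PCA projection as the candidate pool.
#'
#' @param scores m x B score matrix.
#' @param cnc_measured measured CNC in g/m^2 (length m >= 2).
#' @return object of class `validation_set`.
#' @export
validation_set <- function(scores, cnc_measured) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(cnc_measured)) stop_domain("rows must match labels")
  if (nrow(scores) < 2) stop_domain("validation set needs m >= 2")
  structure(list(scores = scores, cnc_measured = cnc_measured),
    class = "validation_set"
  )
}

#' Diversity distance of a candidate to a training set
#'
#' Squared-Euclidean diversity criterion: the minimum over training rows of
#' `||x_u - x_l||^2` (maximin aggregation -- a candidate identical to any
#' training sample scores zero).
#'
#' @param candidate feature vector.
#' @param training matrix of training feature rows (non-empty).
#' @param aggregate `"min"` (default, maximin), `"mean"` or `"sum"`.
#' @return scalar distance.
#' @export
#' @examples
#' ebd_distance(c(0, 0), matrix(c(3, 4), nrow = 1)) # 25
ebd_distance <- function(candidate, training, aggregate = c("min", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  training <- as.matrix(training)
  if (nrow(training) == 0) stop_domain("training set must be non-empty")
  if (length(candidate) != ncol(training)) stop_domain("dimension mismatch")
  d2 <- colSums((t(training) - candidate)^2)
  switch(aggregate, min = min(d2), mean = mean(d2), sum = sum(d2))
}

# squared distances of many candidates (rows) to training rows: M x N matrix
cross_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Select the most diverse remaining candidate
#'
#' Returns the id of the remaining pool sample with the largest maximin
#' squared-Euclidean distance to the current training rows; ties are broken
#' by the smallest id.
#'
#' @param pool a [labeled_pool()].
#' @param remaining_ids ids still in the candidate set (non-empty).
#' @param training_scores matrix of current training feature rows.
#' @param aggregate distance aggregation, see [ebd_distance()].
#' @return the selected id.
#' @export
select_next <- function(pool, remaining_ids, training_scores,
                        aggregate = "min") {
  if (length(remaining_ids) == 0) stop_domain("remaining pool is empty")
  idx <- match(remaining_ids, pool$ids)
  cand <- pool$scores[idx, , drop = FALSE]
  d2 <- cross_sqdist(cand, as.matrix(training_scores))
  score <- switch(aggregate,
    min = apply(d2, 1, min),
    mean = rowMeans(d2),
    sum = rowSums(d2)
  )
  # ties -> smallest id
  best <- score >= max(score) - 0
  remaining_ids[best][which.min(remaining_ids[best])]
}

#' Euclidean-distance-based diversity active learning
#'
#' Builds a compact training set from a labelled candidate pool by iterative
#' diversity sampling with validation-driven acceptance: an initial random
#' subset (`init_frac` of the pool) seeds a GP regression model; then, until
#' the pool is exhausted (single pass), the candidate most remote from the
#' current training set (maximin squared-Euclidean distance) is tentatively
#' added, the model refit, and the candidate kept only if the validation
#' RMSE strictly decreases. The RMSE/R-squared trace per accepted subset
#' size is recorded; R-squared is recorded but never used for acceptance.
#'
#' @param pool a [labeled_pool()] (size >= 10).
#' @param val a [validation_set()].
#' @param init_frac fraction of the pool drawn (uniformly, without
#'   replacement) as the initial training set (default 0.10).
#' @param seed integer seed making the whole run reproducible.
#' @param kernel_mode kernel used for the in-loop refits (default
#'   `"isotropic"` for speed).
#' @param n_restarts_init restarts for the initial fit.
#' @param maxit optimiser iteration cap for in-loop warm-started refits.
#' @param max_iter optional cap on the number of candidate evaluations.
#' @param aggregate diversity aggregation, see [ebd_distance()].
#' @param verbose print progress every 100 candidates.
#' @return object of class `al_result`: `selected_ids` (initial subset then
#'   accepted ids, in order), `initial_ids`, `trace` (data frame `size`,
#'   `rmse`, `r2`; first row is the initial model), `model` (final
#'   [gpr_fit()] model), `seed`, `config`.
#' @export
run_ebd_al <- function(pool, val, init_frac = 0.10, seed = NULL,
                       kernel_mode = "isotropic", n_restarts_init = 3,
                       maxit = 60, max_iter = Inf, aggregate = "min",
                       verbose = FALSE) {
  n <- nrow(pool$scores)
  if (n < 10) stop_domain("pool size must be >= 10")
  n_init <- max(2, floor(init_frac * n))

  init_ids <- with_seed_if(seed, sample(pool$ids, n_init))
  sel <- sort(init_ids)
  remaining <- setdiff(pool$ids, sel)

  fit_on <- function(ids, init_theta = NULL, restarts = 1) {
    idx <- match(ids, pool$ids)
    gpr_fit(pool$scores[idx, , drop = FALSE], pool$labels[idx],
      kernel_mode = kernel_mode, n_restarts = restarts,
      seed = if (is.null(seed)) NULL else seed + 17L,
      init = init_theta, maxit = if (is.null(init_theta)) 100 else maxit
    )
  }
  # acceptance needs only the RMSE; R-squared is recorded defensively (NA
  # for a zero-variance validation target) so degenerate validation sets
  # cannot abort the loop
  val_metrics <- function(model) {
    pr <- gpr_predict(model, val$scores)
    obs <- val$cnc_measured
    ss_tot <- sum((obs - mean(obs))^2)
    list(
      rmse = sqrt(mean((pr$mean - obs)^2)),
      r2 = if (ss_tot > 0) 1 - sum((obs - pr$mean)^2) / ss_tot else NA_real_
    )
  }

  model <- fit_on(sel, restarts = n_restarts_init)
  gof <- val_metrics(model)
  trace <- data.frame(size = length(sel), rmse = gof$rmse, r2 = gof$r2)
  best_rmse <- gof$rmse

  it <- 0
  while (length(remaining) > 0 && it < max_iter) {
    it <- it + 1
    idx_tr <- match(sel, pool$ids)
    cand_id <- select_next(pool, remaining, pool$scores[idx_tr, , drop = FALSE],
      aggregate = aggregate
    )
    remaining <- setdiff(remaining, cand_id)
    cand_model <- tryCatch(
      fit_on(c(sel, cand_id), init_theta = model$theta),
      error = function(e) {
        warning("GPR fit failed for candidate ", cand_id, ": ",
          conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(cand_model)) next
    gof <- val_metrics(cand_model)
    if (gof$rmse < best_rmse) {
      sel <- c(sel, cand_id)
      model <- cand_model
      best_rmse <- gof$rmse
      trace <- rbind(trace, data.frame(
        size = length(sel), rmse = gof$rmse, r2 = gof$r2
      ))
    }
    if (verbose && it %% 100 == 0) {
      message(sprintf(
        "AL iteration %d: %d selected, best RMSE %.3f",
        it, length(sel), best_rmse
      ))
    }
  }
  structure(
    list(
      selected_ids = sel, initial_ids = sort(init_ids), trace = trace,
      model = model, seed = seed,
      config = list(
        init_frac = init_frac, kernel_mode = kernel_mode,
        aggregate = aggregate, max_iter = max_iter
      )
    ),
    class = "al_result"
  )
}

#' @export
print.al_result <- function(x, ...) {
  cat(sprintf(
    "<al_result> %d -> %d samples; validation RMSE %.3f -> %.3f g/m2\n",
    x$trace$size[1], utils::tail(x$trace$size, 1),
    x$trace$rmse[1], utils::tail(x$trace$rmse, 1)
  ))
  invisible(x)
}

#' Persist / restore an active-learning result as JSON
#'
#' @param x an [run_ebd_al()] result.
#' @param path JSON file path.
#' @return `read_al_result` returns a list with the ids, trace, seed and
#'   config (the fitted model is not serialised here; see
#'   [write_bundle()]).
#' @export
write_al_result <- function(x, path) {
  jsonlite::write_json(
    list(
      selected_ids = x$selected_ids, initial_ids = x$initial_ids,
      trace = x$trace, seed = x$seed, config = x$config
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_al_result
#' @export
read_al_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Augment a training pool with non-vegetated spectra
#'
#' Projects preprocessed non-vegetated spectra (bare soil, water, man-made
#' surfaces) through the already-fitted PCA -- the PCA is never refit -- and
#' appends them to the training pool with a CNC label of 0 g/m^2, the only
#' physically coherent label for non-vegetated surfaces. The caller refits
#' the regression model on the returned pool.
#'
#' @param selection a [labeled_pool()] holding the current training set.
#' @param nv_spectra matrix of non-vegetated spectra (rows) on the
#'   harmonized grid used to fit `pca`.
#' @param pca the [fit_pca()] model of the training database.
#' @return the augmented [labeled_pool()]; NV samples get ids
#'   `"nv_1", "nv_2", ...`.
#' @export
augment_nonvegetated <- function(selection, nv_spectra, pca) {
  if (is.null(nv_spectra) || nrow(nv_spectra) == 0) {
    return(selection)
  }
  nv_scores <- project(pca, nv_spectra)
  labeled_pool(
    rbind(selection$scores, nv_scores),
    c(selection$labels, rep(0, nrow(nv_scores))),
    c(selection$ids, paste0("nv_", seq_len(nrow(nv_scores))))
  )
}
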