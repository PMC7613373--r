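#' Fit a centered principal component analysis to spectra
#'
#' Centered (but unscaled) PCA of a spectra matrix, retaining `k` components.
#' Reflectance bands share units and scale, so no variance scaling is
#' applied -- unit-variance scaling would inflate the influence of noisy
#' bands. Component signs are fixed by making the largest-magnitude loading
#' entry of each component positive, for reproducible serialization.
#'
#' @param X numeric matrix, one spectrum per row (rows >= k, columns >= k).
#' @param k number of components to retain (default 20). If the matrix rank
#'   is below `k`, the available components are kept with a warning.
#' @return object of class `pca_model`: list with `mean` (per-band mean
#'   spectrum), `loadings` (bands x k, orthonormal columns),
#'   `explained_variance_ratio` (length k, non-increasing), `n_components`.
#' @export
fit_pca <- function(X, k = 20) {
  X <- as.matrix(X)
  if (nrow(X) < k || ncol(X) < k) {
    stop_domain("need at least k rows and k columns to fit ", k, " components")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  total <- sum(var_all)
  rank_eff <- sum(var_all > max(var_all) * 1e-12)
  if (rank_eff < k) {
    warning(sprintf(
      "matrix rank %d below requested %d components; retaining %d",
      rank_eff, k, rank_eff
    ))
    k <- rank_eff
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(
    list(
      mean = pc$center,
      loadings = unname(load),
      explained_variance_ratio = var_all[seq_len(k)] / total,
      n_components = k
    ),
    class = "pca_model"
  )
}

#' Project spectra into principal-component space
#'
#' Computes `scores = t(loadings) %*% (spectrum - mean)` for each spectrum;
#' linear in its input.
#'
#' @param m a [fit_pca()] model.
#' @param spectra vector (one spectrum) or matrix (one per row) on the grid
#'   used for fitting.
#' @return score matrix (rows = spectra, columns = components).
#' @export
project <- function(m, spectra) {
  if (!is.matrix(spectra)) spectra <- matrix(spectra, nrow = 1)
  if (ncol(spectra) != length(m$mean)) {
    stop_domain("spectra have ", ncol(spectra), " bands; model expects ", length(m$mean))
  }
  sweep(spectra, 2, m$mean) %*% m$loadings
}

#' Cumulative explained-variance fraction
#'
#' @param m a [fit_pca()] model.
#' @param j number of leading components (1 <= j <= n_components).
#' @return fraction of total variance explained by the first `j` components;
#'   non-decreasing in `j`.
#' @export
cumulative_variance <- function(m, j) {
  if (j < 1 || j > m$n_components) stop_domain("j must be in [1, n_components]")
  sum(m$explained_variance_ratio[seq_len(j)])
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d components over %d bands; cumvar(%d) = %.4f\n",
    x$n_components, length(x$mean), x$n_components,
    cumulative_variance(x, x$n_components)
  ))
  invisible(x)
}
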