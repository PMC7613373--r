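#' Scaled Gaussian (squared-exponential) kernel
#'
#' Evaluates `nu * exp(-sum_b (x_ib - x_jb)^2 / (2 sigma_b^2))`, plus
#' `sigma_n^2` when the two inputs are the same training point (Kronecker
#' delta on the index, not on the coordinates).
#'
#' @param xi,xj equal-length feature vectors.
#' @param theta list with `nu` (signal scale), `sigma_b` (length-scales,
#'   length 1 for an isotropic kernel or one per feature), `sigma_n`
#'   (noise SD); all strictly positive.
#' @param same_index `TRUE` iff `xi` and `xj` are the same training sample.
#' @return covariance scalar.
#' @export
gpr_kernel <- function(xi, xj, theta, same_index = FALSE) {
  check_theta(theta)
  if (length(xi) != length(xj)) stop_domain("xi and xj must have equal length")
  v <- theta$nu * exp(-sum((xi - xj)^2 / (2 * theta$sigma_b^2)))
  if (same_index) v <- v + theta$sigma_n^2
  v
}

check_theta <- function(theta) {
  if (any(c(theta$nu, theta$sigma_b, theta$sigma_n) <= 0)) {
    stop_domain("hyperparameters must be strictly positive")
  }
  invisible(theta)
}

# per-feature squared-difference cubes: list of B (n x m) matrices, or a
# single matrix of summed squares for the isotropic kernel
sqdist_features <- function(X, Z = NULL) {
  if (is.null(Z)) Z <- X
  B <- ncol(X)
  lapply(seq_len(B), function(b) outer(X[, b], Z[, b], "-")^2)
}

kernel_matrix <- function(theta, d2list) {
  s2 <- 2 * theta$sigma_b^2
  if (length(s2) == 1) s2 <- rep(s2, length(d2list))
  E <- -d2list[[1]] / s2[1]
  if (length(d2list) > 1) {
    for (b in 2:length(d2list)) E <- E - d2list[[b]] / s2[b]
  }
  theta$nu * exp(E)
}

# Cholesky of K + sigma_n^2 I with escalating jitter
chol_with_jitter <- function(Kn, nu) {
  jit <- 0
  for (expo in c(NA, 10:6)) {
    if (!is.na(expo)) jit <- nu * 10^(-expo)
    ch <- tryCatch(chol(Kn + diag(jit, nrow(Kn))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(ch)
    }
  }
  stop_domain("covariance matrix not positive definite even with jitter")
}

#' Negative log marginal likelihood of a GP regression model
#'
#' Computes `0.5 y' (K + sigma_n^2 I)^-1 y + 0.5 log|K + sigma_n^2 I|
#' + (N/2) log 2pi` through a Cholesky decomposition, together with analytic
#' gradients with respect to the log-hyperparameters. Targets are centered
#' internally (zero-mean prior).
#'
#' @param theta hyperparameter list (`nu`, `sigma_b`, `sigma_n`).
#' @param X feature matrix (N x B).
#' @param y targets (length N >= 1).
#' @param gradient if `TRUE`, attach attribute `"gradient"` (named vector on
#'   the log-theta scale: `log_nu`, `log_sigma_b[...]`, `log_sigma_n`).
#' @return the scalar NLML (optionally with gradient attribute).
#' @export
gpr_nlml <- function(theta, X, y, gradient = FALSE) {
  check_theta(theta)
  X <- as.matrix(X)
  yc <- y - mean(y)
  n <- length(yc)
  d2 <- sqdist_features(X)
  nlml_core(theta, d2, yc, n, gradient)
}

nlml_core <- function(theta, d2, yc, n, gradient = FALSE) {
  Kse <- kernel_matrix(theta, d2)
  Kn <- Kse + diag(theta$sigma_n^2, n)
  L <- chol_with_jitter(Kn, theta$nu)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  val <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  if (!gradient) {
    return(val)
  }
  Kinv <- chol2inv(L)
  M <- Kinv - tcrossprod(alpha) # d(nlml)/dK = 0.5 * M (trace pairing)
  g_nu <- 0.5 * sum(M * Kse)
  s2 <- theta$sigma_b^2
  iso <- length(s2) == 1
  if (iso) {
    D2 <- d2[[1]]
    if (length(d2) > 1) for (b in 2:length(d2)) D2 <- D2 + d2[[b]]
    g_sb <- 0.5 * sum(M * (Kse * D2 / s2))
  } else {
    g_sb <- vapply(seq_along(d2), function(b) {
      0.5 * sum(M * (Kse * d2[[b]] / s2[b]))
    }, numeric(1))
  }
  g_sn <- 0.5 * sum(diag(M)) * 2 * theta$sigma_n^2
  grad <- c(log_nu = g_nu, g_sb, log_sigma_n = g_sn)
  names(grad) <- c(
    "log_nu",
    if (iso) "log_sigma_b" else paste0("log_sigma_b", seq_along(g_sb)),
    "log_sigma_n"
  )
  attr(val, "gradient") <- grad
  val
}

theta_from_log <- function(par, B_ls) {
  list(
    nu = exp(par[1]),
    sigma_b = exp(par[1 + seq_len(B_ls)]),
    sigma_n = exp(par[length(par)])
  )
}

#' Fit a Gaussian process regression model by Type-II maximum likelihood
#'
#' Minimises the negative log marginal likelihood over log-hyperparameters
#' with multi-start gradient-based optimisation (L-BFGS-B with analytic
#' gradients). The first start uses the median-pairwise-distance heuristic
#' for the length-scale, `var(y)` for the signal scale and `0.1 sd(y)` for
#' the noise SD; further restarts perturb the start in log-space.
#' Deterministic for a given seed.
#'
#' @param X feature matrix (N x B), e.g. principal-component scores.
#' @param y targets, e.g. CNC in g/m^2 (length N >= 2).
#' @param kernel_mode `"isotropic"` (one shared length-scale; default) or
#'   `"ard"` (one length-scale per feature, automatic relevance
#'   determination).
#' @param n_restarts number of optimisation starts (default 5).
#' @param seed integer seed controlling the restart perturbations.
#' @param init optional hyperparameter list used as the first start
#'   (warm start).
#' @param maxit L-BFGS-B iteration cap per start.
#' @return object of class `gpr_model`: `X_train`, `y_train`, `y_offset`,
#'   `theta`, `alpha` (weights solving `(K + sigma_n^2 I) alpha = y - offset`),
#'   `chol_factor`, `kernel_mode`, `nlml`.
#' @export
gpr_fit <- function(X, y, kernel_mode = c("isotropic", "ard"),
                    n_restarts = 5, seed = NULL, init = NULL, maxit = 100) {
  kernel_mode <- match.arg(kernel_mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 || length(y) != n) stop_domain("need N >= 2 rows of X matching y")
  B <- ncol(X)
  B_ls <- if (kernel_mode == "ard") B else 1L
  yc <- y - mean(y)
  d2 <- sqdist_features(X)

  # heuristic first start
  D2 <- d2[[1]]
  if (B > 1) for (b in 2:B) D2 <- D2 + d2[[b]]
  med <- sqrt(stats::median(D2[upper.tri(D2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1e-3
  base <- c(log(max(stats::var(y), 1e-12)), rep(log(med), B_ls), log(0.1 * sdy))
  if (!is.null(init)) {
    sb <- init$sigma_b
    if (length(sb) != B_ls) sb <- rep(sb[1], B_ls)
    base <- c(log(init$nu), log(sb), log(init$sigma_n))
  }

  fn <- function(par) {
    as.numeric(nlml_core(theta_from_log(par, B_ls), d2, yc, n, gradient = FALSE))
  }
  gr <- function(par) {
    v <- nlml_core(theta_from_log(par, B_ls), d2, yc, n, gradient = TRUE)
    as.numeric(attr(v, "gradient"))
  }

  # restarts spread the length-scale start over octaves around the median
  # heuristic (the evidence surface has a white-noise local optimum at tiny
  # length-scales that a single large start can fall into), with mild jitter
  # on the remaining coordinates
  ls_offsets <- c(0, -1.5, 1.5, -3, 0.75, -2.25, 2.5, -0.75)
  starts <- with_seed_if(seed, {
    lapply(seq_len(max(1, n_restarts)), function(r) {
      if (r == 1) {
        return(base)
      }
      s <- base + stats::rnorm(length(base), 0, 0.3)
      off <- ls_offsets[1 + (r - 1) %% length(ls_offsets)]
      s[1 + seq_len(B_ls)] <- s[1 + seq_len(B_ls)] + off
      s
    })
  })
  best <- NULL
  fails <- character(0)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn, gr,
        method = "L-BFGS-B",
        lower = rep(-25, length(s)), upper = rep(25, length(s)),
        control = list(maxit = maxit)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop_domain(
      "all optimisation restarts failed: ",
      paste(unique(fails), collapse = "; ")
    )
  }
  theta <- theta_from_log(best$par, B_ls)
  Kse <- kernel_matrix(theta, d2)
  L <- chol_with_jitter(Kse + diag(theta$sigma_n^2, n), theta$nu)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(
    list(
      X_train = X, y_train = y, y_offset = mean(y), theta = theta,
      alpha = alpha, chol_factor = L, kernel_mode = kernel_mode,
      nlml = best$value
    ),
    class = "gpr_model"
  )
}

#' Predictive mean and variance of a fitted GP regression model
#'
#' Implements the analytic posterior: mean `k*' (K + sigma_n^2 I)^-1 y`
#' (offset restored) and variance `k** - k*' (K + sigma_n^2 I)^-1 k*`, where
#' the self-similarity `k** = nu` predicts the latent function; with
#' `include_noise = TRUE` the observation noise variance `sigma_n^2` is
#' added for observation-level intervals.
#'
#' @param m a [gpr_fit()] model.
#' @param X_star matrix of query feature rows (or a single vector).
#' @param include_noise add `sigma_n^2` to the predictive variance.
#' @return data frame with columns `mean` and `variance` (variance clipped
#'   at zero; a warning is raised if clipping exceeds numerical noise).
#' @export
gpr_predict <- function(m, X_star, include_noise = FALSE) {
  if (!is.matrix(X_star)) X_star <- matrix(X_star, nrow = 1)
  if (ncol(X_star) != ncol(m$X_train)) {
    stop_domain(
      "query has ", ncol(X_star), " features; model expects ",
      ncol(m$X_train)
    )
  }
  d2 <- sqdist_features(m$X_train, X_star)
  Ks <- kernel_matrix(m$theta, d2) # N x M
  mu <- drop(crossprod(Ks, m$alpha)) + m$y_offset
  v <- forwardsolve(t(m$chol_factor), Ks)
  var <- m$theta$nu - colSums(v^2)
  if (any(var < -1e-10)) {
    warning("predictive variance clipped at 0 beyond numerical tolerance")
  }
  var <- pmax(var, 0)
  if (include_noise) var <- var + m$theta$sigma_n^2
  data.frame(mean = mu, variance = var)
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> N = %d, B = %d, %s kernel; nu = %.3g, sigma_n = %.3g\n",
    nrow(x$X_train), ncol(x$X_train), x$kernel_mode, x$theta$nu,
    x$theta$sigma_n
  ))
  invisible(x)
}

#' Goodness-of-fit statistics
#'
#' Root mean square error (same units as the observations), range-normalised
#' RMSE in percent (`100 * rmse / (max(obs) - min(obs))`) and the coefficient
#' of determination `1 - SS_res / SS_tot`.
#'
#' @param predicted predicted values.
#' @param observed observed values (same length >= 2).
#' @return list with `rmse`, `nrmse` (percent), `r2`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1.1, 1.9, 3.2))
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2) {
    stop_domain("predicted and observed must share a length >= 2")
  }
  rng <- max(observed) - min(observed)
  if (rng <= 0) stop_domain("observed range is zero; NRMSE undefined")
  rmse <- sqrt(mean((predicted - observed)^2))
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(rmse = rmse, nrmse = 100 * rmse / rng, r2 = 1 - ss_res / ss_tot)
}
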