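test_that("kernel evaluates the scaled Gaussian form with index-wise noise", {
  th <- list(nu = 2, sigma_b = 1.5, sigma_n = 0.4)
  x <- c(1, 2, 3)
  expect_equal(gpr_kernel(x, x, th, same_index = TRUE), 2 + 0.16)
  expect_equal(gpr_kernel(x, x, th, same_index = FALSE), 2)
  expect_lt(gpr_kernel(x, x + 100, th), 1e-12)
  # ARD form with per-feature length-scales
  tha <- list(nu = 1, sigma_b = c(1, 10, 100), sigma_n = 0.1)
  d <- c(0.5, 0.5, 0.5)
  expect_equal(
    gpr_kernel(x, x + d, tha),
    exp(-sum(d^2 / (2 * c(1, 10, 100)^2)))
  )
  expect_error(gpr_kernel(x, x, list(nu = -1, sigma_b = 1, sigma_n = 1)), "positive")
  expect_error(gpr_kernel(x, c(1, 2), th), "equal length")
})

test_that("evidence matches closed form and a dense-matrix oracle", {
  th <- list(nu = 1.7, sigma_b = 0.9, sigma_n = 0.33)
  # single observation at the prior mean: closed form
  expect_equal(
    gpr_nlml(th, matrix(0, 1, 1), 0),
    0.5 * log(1.7 + 0.33^2) + 0.5 * log(2 * pi)
  )
  # random 5-point sets against explicit inverse/determinant arithmetic
  set.seed(12)
  for (i in 1:20) {
    X <- matrix(rnorm(5 * 3), 5, 3)
    y <- rnorm(5)
    yc <- y - mean(y)
    K <- outer(1:5, 1:5, Vectorize(function(a, b) {
      gpr_kernel(X[a, ], X[b, ], th, same_index = a == b)
    }))
    oracle <- 0.5 * drop(t(yc) %*% solve(K, yc)) +
      0.5 * determinant(K)$modulus[1] + 2.5 * log(2 * pi)
    expect_equal(as.numeric(gpr_nlml(th, X, y)), oracle, tolerance = 1e-10)
  }
})

test_that("evidence gradients match central finite differences", {
  set.seed(5)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12)
  for (mode in c("iso", "ard")) {
    sb <- if (mode == "iso") 1.1 else c(0.7, 1.3, 2.2, 0.9)
    th <- list(nu = 1.4, sigma_b = sb, sigma_n = 0.25)
    g <- attr(gpr_nlml(th, X, y, gradient = TRUE), "gradient")
    par <- log(c(th$nu, th$sigma_b, th$sigma_n))
    mk <- function(p) {
      list(
        nu = exp(p[1]), sigma_b = exp(p[2:(length(p) - 1)]),
        sigma_n = exp(p[length(p)])
      )
    }
    fd <- vapply(seq_along(par), function(i) {
      e <- 1e-6
      up <- par
      up[i] <- up[i] + e
      dn <- par
      dn[i] <- dn[i] - e
      (gpr_nlml(mk(up), X, y) - gpr_nlml(mk(dn), X, y)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("fitting honours its optimizer contract on degenerate and normal data", {
  set.seed(30)
  X <- matrix(runif(20 * 2, 0, 5), 20, 2)
  # constant targets reproduce the constant
  mc <- gpr_fit(X, rep(3.7, 20), n_restarts = 2, seed = 1)
  pr <- gpr_predict(mc, matrix(runif(10, 0, 5), 5, 2))
  expect_equal(pr$mean, rep(3.7, 5), tolerance = 1e-6)
  # returned optimum is at least as good as the heuristic start
  y <- sin(X[, 1]) + 0.1 * rnorm(20)
  m <- gpr_fit(X, y, n_restarts = 3, seed = 2)
  D2 <- as.matrix(dist(X))^2
  start <- list(
    nu = var(y), sigma_b = sqrt(median(D2[upper.tri(D2)])),
    sigma_n = 0.1 * sd(y)
  )
  expect_lte(m$nlml, as.numeric(gpr_nlml(start, X, y)) + 1e-8)
  # cached weights solve the linear system
  K <- cncmap:::kernel_matrix(m$theta, cncmap:::sqdist_features(X)) +
    diag(m$theta$sigma_n^2, 20)
  expect_lt(max(abs(K %*% m$alpha - (y - mean(y)))), 1e-8)
  expect_error(gpr_fit(X[1, , drop = FALSE], 1), "N >= 2")
})

test_that("posterior collapses onto training data and reverts to the prior far away", {
  set.seed(41)
  X <- matrix(runif(16, 0, 4), 8, 2)
  y <- rnorm(8, 10, 2)
  th <- list(nu = 4, sigma_b = 1, sigma_n = 1e-6)
  m <- make_fixed_gpr(X, y, th)
  at_train <- gpr_predict(m, X)
  expect_equal(at_train$mean, y, tolerance = 1e-4)
  expect_true(all(at_train$variance < 1e-4))
  far <- gpr_predict(m, matrix(1e3, 1, 2))
  expect_equal(far$mean, mean(y), tolerance = 1e-9)
  expect_equal(far$variance, th$nu, tolerance = 1e-9)
  # two-point hand oracle
  X2 <- matrix(c(0, 1), 2, 1)
  y2 <- c(1, 3)
  th2 <- list(nu = 2, sigma_b = 0.8, sigma_n = 0.3)
  m2 <- make_fixed_gpr(X2, y2, th2)
  k12 <- 2 * exp(-0.5 / 0.8^2)
  Km <- matrix(c(2 + 0.09, k12, k12, 2 + 0.09), 2)
  xs <- 0.4
  ks <- 2 * exp(-c(0.4^2, 0.6^2) / (2 * 0.8^2))
  mu_or <- drop(ks %*% solve(Km, y2 - 2)) + 2
  va_or <- 2 - drop(ks %*% solve(Km, ks))
  got <- gpr_predict(m2, matrix(xs, 1, 1))
  expect_equal(got$mean, mu_or, tolerance = 1e-12)
  expect_equal(got$variance, va_or, tolerance = 1e-12)
  expect_error(gpr_predict(m2, matrix(1, 1, 3)), "features")
})

test_that("predictive variance is bounded, monotone under duplication and permutation-consistent", {
  set.seed(55)
  X <- matrix(runif(30, 0, 3), 15, 2)
  y <- rnorm(15)
  th <- list(nu = 1.3, sigma_b = 0.9, sigma_n = 0.2)
  m <- make_fixed_gpr(X, y, th)
  Xq <- matrix(runif(40, -1, 4), 20, 2)
  pr <- gpr_predict(m, Xq)
  expect_true(all(pr$variance >= 0 & pr$variance <= th$nu + th$sigma_n^2 + 1e-12))
  # duplicating a training point with identical target never increases
  # variance anywhere
  md <- make_fixed_gpr(rbind(X, X[4, ]), c(y, y[4]), th)
  prd <- gpr_predict(md, Xq)
  expect_true(all(prd$variance <= pr$variance + 1e-9))
  # permuting features together with ARD length-scales leaves the posterior
  # unchanged
  tha <- list(nu = 1.3, sigma_b = c(0.5, 2), sigma_n = 0.2)
  ma <- make_fixed_gpr(X, y, tha, kernel_mode = "ard")
  thp <- list(nu = 1.3, sigma_b = c(2, 0.5), sigma_n = 0.2)
  mp <- make_fixed_gpr(X[, 2:1], y, thp, kernel_mode = "ard")
  expect_equal(gpr_predict(ma, Xq)$mean, gpr_predict(mp, Xq[, 2:1])$mean,
    tolerance = 1e-10
  )
  # observation-level intervals add the noise variance
  pn <- gpr_predict(m, Xq, include_noise = TRUE)
  expect_equal(pn$variance, pr$variance + th$sigma_n^2, tolerance = 1e-12)
})

test_that("posterior means agree with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  set.seed(66)
  X <- matrix(runif(40, 0, 5), 20, 2)
  y <- sin(X[, 1]) * cos(X[, 2])
  yc <- y - mean(y)
  th <- list(nu = 1, sigma_b = 1.2, sigma_n = 0.3)
  m <- make_fixed_gpr(X, yc, th)
  Xq <- matrix(runif(20, 0, 5), 10, 2)
  kl <- kernlab::gausspr(X, yc,
    scaled = FALSE, kernel = "rbfdot",
    kpar = list(sigma = 1 / (2 * 1.2^2)), var = 0.3^2, tol = 1e-8
  )
  expect_equal(gpr_predict(m, Xq)$mean,
    drop(kernlab::predict(kl, Xq)),
    tolerance = 1e-6
  )
})

test_that("goodness-of-fit statistics follow their definitions", {
  obs <- c(1, 4, 2, 8, 5)
  perfect <- goodness_of_fit(obs, obs)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  at_mean <- goodness_of_fit(rep(mean(obs), 5), obs)
  expect_equal(at_mean$r2, 0)
  g <- goodness_of_fit(c(1.5, 3.5, 2.5, 7, 6), obs)
  expect_equal(g$rmse, sqrt(mean(c(0.5, -0.5, 0.5, -1, 1)^2)))
  expect_equal(g$nrmse, 100 * g$rmse / 7)
  expect_error(goodness_of_fit(1:3, rep(2, 3)), "range")
  expect_error(goodness_of_fit(1:3, 1:4), "length")
})
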