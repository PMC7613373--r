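test_that("canopy nitrogen upscaling is exact and linear", {
  expect_equal(compute_cnc(3, 0.0015), 3 * 0.0015 * 10000 / 4.43)
  expect_equal(round(compute_cnc(3, 0.0015), 4), 10.1580)
  expect_identical(compute_cnc(0, 0.0025), 0)
  expect_equal(round(compute_cnc(7, 0.0025), 4), 39.5034)
  # linearity in each argument over many random pairs
  set.seed(1)
  lai <- runif(1e6, 0, 7)
  cp <- runif(1e6, 0, 0.0025)
  expect_true(all(abs(compute_cnc(lai, cp) - lai * cp * 10000 / 4.43) <=
    1e-12 * pmax(compute_cnc(lai, cp), 1e-300)))
  expect_equal(compute_cnc(2 * 1.3, 0.002), 2 * compute_cnc(1.3, 0.002))
  expect_error(compute_cnc(-1, 0.001), "must be")
  expect_error(compute_cnc(1, -0.001), "must be")
})

test_that("parameter sampler honours ranges, fixed geometry and distributions", {
  pars <- sample_parameters(5000, seed = 123)
  cfg <- database_config()
  for (v in c("N_struct", "C_ab", "C_w", "C_xc", "C_anth", "CBC", "alpha_soil", "ALA", "HotS")) {
    expect_true(all(pars[[v]] >= cfg[[v]]$min & pars[[v]] <= cfg[[v]]$max), info = v)
  }
  expect_true(all(pars$C_p >= 0.001 & pars$C_p <= 0.0025))
  expect_true(all(pars$LAI >= 0.1 & pars$LAI <= 7))
  expect_true(all(pars$SZA == 30))
  expect_true(all(pars$OZA == 0))
  # reproducibility
  expect_identical(sample_parameters(50, seed = 9), sample_parameters(50, seed = 9))
})

test_that("sampler marginals pass Kolmogorov-Smirnov against their laws", {
  pars <- sample_parameters(1e5, seed = 2024)
  # uniform marginals (ties warnings stem from the RNG's finite resolution
  # at n = 1e5 and are irrelevant to the asymptotic test)
  expect_gt(suppressWarnings(ks.test(pars$C_ab, "punif", 0, 80))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(pars$ALA, "punif", 30, 70))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(pars$alpha_soil, "punif", 0, 1))$p.value, 0.01)
  # truncated-Gaussian marginals: oracle CDF from the normal CDF restricted
  # to the sampling range
  ptrunc <- function(q, mean, sd, lo, hi) {
    (pnorm(q, mean, sd) - pnorm(lo, mean, sd)) /
      (pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
  }
  expect_gt(
    ks.test(pars$C_p, function(q) ptrunc(q, 0.0015, 0.0005, 0.001, 0.0025))$p.value,
    0.01
  )
  expect_gt(
    ks.test(pars$LAI, function(q) ptrunc(q, 3, 2, 0.1, 7))$p.value,
    0.01
  )
  # the truncated-Gaussian mean from the closed-form oracle: truncation to
  # [0.1, 7] removes more of the lower tail, shifting the mean up to ~3.19
  a <- (0.1 - 3) / 2
  b <- (7 - 3) / 2
  mean_oracle <- 3 + 2 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(pars$LAI) - mean_oracle), 0.03)
})

test_that("leaf model conserves energy and responds to absorbers", {
  # absorption-free limit: all incident light eventually leaves the leaf
  lo0 <- prospect_pro(leaf_params(
    N_struct = 1.5, C_ab = 0, C_xc = 0, C_anth = 0,
    C_w = 0, C_p = 0, CBC = 0
  ))
  expect_true(all(abs(lo0$reflectance + lo0$transmittance - 1) < 1e-9))
  # energy bounds for random valid leaves
  pars <- sample_parameters(200, seed = 31)
  for (i in seq_len(50)) {
    lo <- prospect_pro(leaf_params(
      N_struct = pars$N_struct[i], C_ab = pars$C_ab[i], C_xc = pars$C_xc[i],
      C_anth = pars$C_anth[i], C_w = pars$C_w[i], C_p = pars$C_p[i],
      CBC = pars$CBC[i]
    ))
    expect_true(all(lo$reflectance >= 0 & lo$reflectance <= 1))
    expect_true(all(lo$transmittance >= 0 & lo$transmittance <= 1))
    expect_true(all(lo$reflectance + lo$transmittance <= 1 + 1e-12))
  }
  # more protein absorbs more in the SWIR protein bands
  base <- leaf_params(C_p = 0.001)
  high <- leaf_params(C_p = 0.0025)
  r_base <- prospect_pro(base)$reflectance
  r_high <- prospect_pro(high)$reflectance
  swir <- 400:2500 >= 2000 & 400:2500 <= 2143
  expect_true(all(r_high[swir] <= r_base[swir] + 1e-12))
  expect_error(prospect_pro(leaf_params(N_struct = 0.5)), "N_struct")
  expect_error(prospect_pro(leaf_params(C_w = -0.1)), "non-negative")
})

test_that("canopy model reproduces soil at zero cover and stays bounded", {
  lo <- prospect_pro(leaf_params())
  soil <- 0.6 * soil_reference(400:2500)
  brf0 <- sail4(canopy_params(LAI = 1e-6, alpha_soil = 0.6), lo,
    soil_reflectance = soil
  )
  expect_lt(max(abs(brf0 - soil)), 1e-3)
  # bounds for random parameter draws
  pars <- sample_parameters(20, seed = 8)
  for (i in seq_len(10)) {
    brf <- sail4(
      canopy_params(
        LAI = pars$LAI[i], ALA = pars$ALA[i],
        HotS = pars$HotS[i], alpha_soil = pars$alpha_soil[i]
      ),
      prospect_pro(leaf_params(
        N_struct = pars$N_struct[i], C_ab = pars$C_ab[i],
        C_xc = pars$C_xc[i], C_anth = pars$C_anth[i], C_w = pars$C_w[i],
        C_p = pars$C_p[i], CBC = pars$CBC[i]
      ))
    )
    expect_true(all(brf >= 0 & brf <= 1))
  }
  # NIR saturation: reflectance response flattens at high leaf area
  black <- rep(0, 2101)
  at800 <- function(lai) {
    sail4(canopy_params(LAI = lai), lo, soil_reflectance = black)[401]
  }
  expect_lt(abs(at800(7) - at800(6.9)), abs(at800(1.1) - at800(1.0)))
  expect_error(
    sail4(canopy_params(), lo, soil_reflectance = c(0.1, 0.2)),
    "wavelength grid"
  )
})

test_that("two-stream solution matches an independent numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  # scalar single-wavelength comparison of the full canopy-only directional
  # reflectance (negligible hot spot) against a shooting solution of the
  # same two-stream system plus the observer integrals
  ode_total <- function(rho, tau, lai, ala, tts, tto, psi) {
    geo <- cncmap:::sail_geometry(ala, tts, tto, psi)
    ks <- geo$ks
    ko <- geo$ko
    bf <- geo$bf
    sigb <- 0.5 * (1 + bf) * rho + 0.5 * (1 - bf) * tau
    sigf <- 0.5 * (1 - bf) * rho + 0.5 * (1 + bf) * tau
    att <- 1 - sigf
    sb <- 0.5 * (ks + bf) * rho + 0.5 * (ks - bf) * tau
    sf <- 0.5 * (ks - bf) * rho + 0.5 * (ks + bf) * tau
    vb <- 0.5 * (ko + bf) * rho + 0.5 * (ko - bf) * tau
    vf <- 0.5 * (ko - bf) * rho + 0.5 * (ko + bf) * tau
    w <- geo$sob * rho + geo$sof * tau
    dyn <- function(x, y, parms) {
      list(c(
        -ks * y[1],
        sf * y[1] - att * y[2] + sigb * y[3],
        -sb * y[1] - sigb * y[2] + att * y[3],
        (vb * y[2] + vf * y[3]) * exp(-ko * x)
      ))
    }
    shoot <- function(u) {
      deSolve::ode(c(1, 0, u, 0), c(0, lai), dyn, NULL,
        method = "lsoda",
        rtol = 1e-11, atol = 1e-13
      )[2, -1]
    }
    u <- uniroot(function(u) shoot(u)[3], c(-5, 5), tol = 1e-13)$root
    rsod <- shoot(u)[4]
    rsos <- w * (1 - exp(-(ks + ko) * lai)) / (ks + ko)
    unname(rsod + rsos)
  }
  set.seed(99)
  for (i in 1:6) {
    rho <- runif(1, 0.02, 0.5)
    tau <- runif(1, 0.02, min(0.45, 0.95 - rho))
    lai <- runif(1, 0.3, 6.5)
    ala <- runif(1, 30, 70)
    # constant leaf optics across wavelength; black soil isolates the
    # canopy term
    optics <- list(
      wavelengths = 400:2500,
      reflectance = rep(rho, 2101), transmittance = rep(tau, 2101)
    )
    got <- sail4(
      canopy_params(LAI = lai, ALA = ala, HotS = 1e-9),
      optics,
      soil_reflectance = rep(0, 2101), geometry = view_geometry()
    )[1]
    expect_equal(got, ode_total(rho, tau, lai, ala, 30, 0, 0), tolerance = 1e-6)
  }
})

test_that("training database is reproducible, labelled by the exact formula and bounded", {
  db <- build_training_database(40, seed = 77)
  db2 <- build_training_database(40, seed = 77)
  expect_identical(db$reflectance, db2$reflectance)
  expect_identical(db$parameters, db2$parameters)
  expect_equal(db$parameters$cnc, with(db$parameters, LAI * C_p * 10000 / 4.43))
  # CNC envelope forced by the labelling formula at the sampling extrema
  expect_true(all(db$parameters$cnc >= 0.1 * 0.001 * 10000 / 4.43 - 1e-9))
  expect_true(all(db$parameters$cnc <= 7 * 0.0025 * 10000 / 4.43 + 1e-9))
  expect_true(all(db$reflectance >= 0 & db$reflectance <= 1))
  expect_equal(ncol(db$reflectance), 207)
  # noise perturbs spectra, never labels
  dbn <- build_training_database(40, seed = 77, noise_pct = 3)
  expect_identical(dbn$parameters$cnc, db$parameters$cnc)
  expect_false(identical(dbn$reflectance, db$reflectance))
})

test_that("database configuration round-trips through YAML and CSV export works", {
  cfg <- database_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_database_config(cfg, path)
  cfg2 <- read_database_config(path)
  expect_equal(cfg2$C_p$mean, 0.0015)
  expect_equal(cfg2$LAI$sd, 2)
  db <- build_training_database(5, seed = 1)
  prefix <- withr::local_tempfile()
  paths <- export_training_database(db, prefix)
  tab <- read.csv(paste0(prefix, "_parameters.csv"))
  expect_equal(nrow(tab), 5)
  spec <- read.csv(paste0(prefix, "_spectra.csv"))
  expect_equal(dim(spec), c(207, 6))
})
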