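test_that("band grids validate their invariants", {
  expect_error(band_grid(c(500, 500), 10), "strictly increasing")
  expect_error(band_grid(c(500, 600), c(10, -1)), "positive")
  expect_error(band_grid(c(500, 600), c(10, 10, 10)), "same length")
  g <- sensor_band_grid()
  expect_equal(nrow(g), 239)
  expect_true(all(diff(g$center) > 0))
})

test_that("Gaussian resampling preserves constants, is linear and matches quadrature", {
  wl <- 400:2500
  target <- band_grid(seq(500, 2400, by = 50), fwhm = 10)
  # normalised weights reproduce constants exactly
  expect_equal(gaussian_resample(rep(0.30, length(wl)), wl, target),
    rep(0.30, nrow(target)),
    tolerance = 1e-12
  )
  # single 1 nm spike at a band center equals the SRF weight of that sample
  # computed by direct quadrature
  spike <- as.numeric(wl == 1000)
  tg <- band_grid(1000, fwhm = 10)
  w_oracle <- dnorm(wl, 1000, 10 / 2.3548)
  expect_equal(gaussian_resample(spike, wl, tg),
    w_oracle[wl == 1000] / sum(w_oracle),
    tolerance = 1e-12
  )
  # identity limit: target = fine grid with vanishing fwhm
  s <- smooth_test_spectrum(wl)
  idg <- band_grid(wl, fwhm = 0.1)
  expect_lt(max(abs(gaussian_resample(s, wl, idg) - s)), 1e-6)
  # linearity to machine precision
  s2 <- soil_reference(wl)
  lhs <- gaussian_resample(2.5 * s - 1.3 * s2, wl, target)
  rhs <- 2.5 * gaussian_resample(s, wl, target) -
    1.3 * gaussian_resample(s2, wl, target)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  # matrix form agrees with row-wise application
  M <- rbind(s, s2)
  expect_equal(gaussian_resample(M, wl, target)[2, ],
    gaussian_resample(s2, wl, target),
    tolerance = 1e-15
  )
  expect_error(
    gaussian_resample(s, wl, band_grid(c(300, 500), 10)),
    "coverage"
  )
})

test_that("spike masking keys on prominence of local extrema only", {
  g <- band_grid(seq(500, 700, by = 10), fwhm = 10)
  n <- nrow(g)
  ramp <- seq(0.1, 0.4, length.out = n)
  expect_true(all(despike(ramp, g)$valid))
  # +0.05 spike above a smooth spectrum: exactly that band masked
  s <- smooth_test_spectrum(g$center)
  up <- s
  up[8] <- up[8] + 0.05
  expect_identical(which(!despike(up, g)$valid), 8L)
  # below-threshold bump retained
  lo <- s
  lo[8] <- lo[8] + 0.01
  expect_true(all(despike(lo, g)$valid))
  # dips are artifacts too
  dn <- s
  dn[12] <- dn[12] - 0.05
  expect_identical(which(!despike(dn, g)$valid), 12L)
  # strictly monotone spectra are never masked, whatever the threshold
  set.seed(4)
  for (i in 1:20) {
    mono <- cumsum(runif(n, 0, 0.05))
    expect_true(all(despike(mono, g, threshold = 0.001)$valid))
  }
  expect_error(despike(c(1, 2), band_grid(c(1, 2), 1)), "3 bands")
})

test_that("window exclusion equals brute-force interval membership and is idempotent", {
  g <- band_grid(seq(470, 2140, by = 10), fwhm = 10)
  s <- masked_spectrum(smooth_test_spectrum(g$center), g)
  expect_identical(exclude_windows(s, list())$valid, s$valid)
  w <- exclude_windows(s, list(c(1345, 1510)))
  expect_identical(!w$valid, g$center >= 1345 & g$center <= 1510)
  # random grids and windows against elementwise membership
  set.seed(11)
  for (i in 1:25) {
    ctr <- sort(sample(seq(400, 2500, by = 1), 80))
    gg <- band_grid(ctr, fwhm = 8)
    wins <- lapply(1:4, function(j) sort(runif(2, 400, 2500)))
    got <- exclude_windows(masked_spectrum(runif(80), gg), wins)
    want <- !Reduce(`|`, lapply(wins, function(w) ctr >= w[1] & ctr <= w[2]))
    expect_identical(got$valid, want)
  }
  # applying the preset twice changes nothing
  once <- exclude_windows(s, prisma_noisy_windows())
  twice <- exclude_windows(once, prisma_noisy_windows())
  expect_identical(once$valid, twice$valid)
  expect_error(exclude_windows(s, list(c(700, 600))), "lo < hi")
})

test_that("spline gap filling restores linear data and reduces corruption error", {
  g <- band_grid(seq(500, 800, by = 10), fwhm = 10)
  lin <- 0.1 + 0.001 * (g$center - 500)
  valid <- rep(TRUE, nrow(g))
  valid[12:16] <- FALSE
  filled <- spline_gapfill(masked_spectrum(lin, g, valid))
  expect_lt(max(abs(filled - lin)), 1e-8)
  # no gaps + near-zero smoothing: output ~ input
  s <- smooth_test_spectrum(g$center)
  out <- spline_gapfill(masked_spectrum(s, g), spar = 1e-8, replace_valid = TRUE)
  expect_lt(max(abs(out - s)), 1e-4)
  # interpolating fill reproduces a spectrum from its unmasked bands well
  sim <- fx_db1000()$reflectance[1, ]
  gh <- fx_db1000()$grid
  corrupt <- sim
  corrupt[c(30, 90, 150)] <- corrupt[c(30, 90, 150)] + 0.08
  ms <- despike(corrupt, gh)
  rec <- spline_gapfill(ms, method = "interp")
  expect_lt(
    sqrt(mean((rec - sim)^2)),
    sqrt(mean((corrupt - sim)^2))
  )
  expect_error(
    spline_gapfill(masked_spectrum(lin, g, c(rep(TRUE, 3), rep(FALSE, 28)))),
    "4 valid"
  )
})

test_that("harmonized subset retains 207 bands of the nominal table", {
  g <- sensor_band_grid()
  h <- harmonized_grid(g)
  expect_equal(nrow(h), 207)
  expect_true(all(h$center >= 470 & h$center <= 2143))
  expect_true(!any(h$center >= 1345 & h$center <= 1510))
  expect_true(!any(h$center >= 1795 & h$center <= 2000))
  # brute-force interval filter on a synthetic uniform grid
  gg <- band_grid(seq(400, 2500, by = 10), fwhm = 10)
  ctr <- gg$center
  want <- ctr[ctr >= 470 & ctr <= 2143 &
    !(ctr >= 1345 & ctr <= 1510) & !(ctr >= 1795 & ctr <= 2000)]
  expect_equal(harmonized_grid(gg)$center, want)
  # idempotence
  expect_equal(harmonized_grid(h)$center, h$center)
})

test_that("the full cleaning chain is deterministic, gapless and idempotent", {
  g <- sensor_band_grid()
  db <- fx_db1000()
  # a clean simulated spectrum on the raw sensor grid
  pars <- db$parameters[3, ]
  lo <- prospect_pro(leaf_params(
    N_struct = pars$N_struct, C_ab = pars$C_ab, C_xc = pars$C_xc,
    C_anth = pars$C_anth, C_w = pars$C_w, C_p = pars$C_p, CBC = pars$CBC
  ))
  brf <- sail4(
    canopy_params(
      LAI = pars$LAI, ALA = pars$ALA, HotS = pars$HotS,
      alpha_soil = pars$alpha_soil
    ), lo,
    soil_reflectance = pars$alpha_soil * soil_reference(400:2500)
  )
  raw <- gaussian_resample(brf, 400:2500, g)
  out <- preprocess_pixel(raw, g)
  expect_equal(nrow(out$grid), 207)
  expect_true(all(is.finite(out$values)))
  # bands untouched by the mask pass through exactly; bands bridged across
  # the exclusion windows stay within 5% (interpolation flattens genuine
  # shallow absorption dips inside the windows)
  ref <- raw[cncmap:::harmonized_band_mask(g)]
  hctr <- out$grid$center
  in_window <- Reduce(`|`, lapply(
    prisma_noisy_windows(),
    function(w) hctr >= w[1] & hctr <= w[2]
  ))
  expect_identical(out$values[!in_window], ref[!in_window])
  expect_lt(max(abs(out$values - ref) / pmax(ref, 0.01)), 0.05)
  # corrupted bands are replaced; output still gapless on 207 bands
  corrupt <- raw
  corrupt[c(20, 100, 180)] <- corrupt[c(20, 100, 180)] + 0.06
  outc <- preprocess_pixel(corrupt, g)
  expect_equal(length(outc$values), 207)
  expect_lt(
    sqrt(mean((outc$values - ref)^2)),
    sqrt(mean((corrupt[cncmap:::harmonized_band_mask(g)] - ref)^2))
  )
  # determinism and idempotence on its own output
  expect_identical(preprocess_pixel(corrupt, g)$values, outc$values)
  again <- preprocess_pixel(outc$values, outc$grid)
  expect_lt(max(abs(again$values - outc$values)), 1e-9)
  # percent-scale input is converted
  expect_equal(preprocess_pixel(raw * 100, g)$values, out$values,
    tolerance = 1e-12
  )
})
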