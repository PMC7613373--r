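rd <- pi / 180

#' Canopy parameter record
#'
#' @param LAI leaf area index (m^2/m^2, >= 0).
#' @param ALA average leaf inclination angle (degrees); drives an ellipsoidal
#'   (Campbell-type) leaf inclination distribution.
#' @param HotS hot spot parameter (leaf size / canopy height ratio, m/m).
#' @param alpha_soil soil scaling factor in \[0, 1\] multiplying the reference
#'   dry-soil spectrum.
#' @return named list of class `canopy_params`.
#' @export
canopy_params <- function(LAI = 3, ALA = 50, HotS = 0.1, alpha_soil = 0.5) {
  vals <- c(LAI = LAI, ALA = ALA, HotS = HotS, alpha_soil = alpha_soil)
  assert_finite_numeric(vals, "canopy parameters")
  if (LAI < 0) stop_domain("LAI must be >= 0")
  if (ALA <= 0 || ALA >= 90) stop_domain("ALA must be in (0, 90) degrees")
  if (HotS < 0) stop_domain("HotS must be >= 0")
  if (alpha_soil < 0 || alpha_soil > 1) stop_domain("alpha_soil must be in [0, 1]")
  structure(as.list(vals), class = "canopy_params")
}

#' Sun/observer geometry record
#'
#' @param SZA sun zenith angle (degrees, \[0, 90)).
#' @param OZA observer zenith angle (degrees, \[0, 90)).
#' @param rel_azimuth relative azimuth between sun and observer (degrees).
#'   With a nadir observer it has no effect.
#' @return named list of class `view_geometry`.
#' @export
view_geometry <- function(SZA = 30, OZA = 0, rel_azimuth = 0) {
  vals <- c(SZA = SZA, OZA = OZA, rel_azimuth = rel_azimuth)
  assert_finite_numeric(vals, "view geometry")
  if (SZA < 0 || SZA >= 90 || OZA < 0 || OZA >= 90) {
    stop_domain("zenith angles must be in [0, 90) degrees")
  }
  structure(as.list(vals), class = "view_geometry")
}

# ellipsoidal (Campbell) leaf inclination frequencies over the 13 standard bins
campbell_lidf <- function(ala) {
  tx1 <- c(10, 20, 30, 40, 50, 60, 70, 80, 82, 84, 86, 88, 90)
  tx2 <- c(0, 10, 20, 30, 40, 50, 60, 70, 80, 82, 84, 86, 88)
  tl1 <- tx1 * rd
  tl2 <- tx2 * rd
  excent <- exp(-1.6184e-5 * ala^3 + 2.1145e-3 * ala^2 - 1.2390e-1 * ala + 3.2491)
  x1 <- excent / sqrt(1 + excent^2 * tan(tl1)^2)
  x2 <- excent / sqrt(1 + excent^2 * tan(tl2)^2)
  if (abs(excent - 1) < 1e-9) {
    freq <- abs(cos(tl1) - cos(tl2))
  } else {
    alpha <- excent / sqrt(abs(1 - excent^2))
    alpha2 <- alpha^2
    if (excent > 1) {
      alpx1 <- sqrt(alpha2 + x1^2)
      alpx2 <- sqrt(alpha2 + x2^2)
      freq <- abs((x1 * alpx1 + alpha2 * log(x1 + alpx1)) -
        (x2 * alpx2 + alpha2 * log(x2 + alpx2)))
    } else {
      almx1 <- sqrt(alpha2 - x1^2)
      almx2 <- sqrt(alpha2 - x2^2)
      freq <- abs((x1 * almx1 + alpha2 * asin(x1 / alpha)) -
        (x2 * almx2 + alpha2 * asin(x2 / alpha)))
    }
  }
  freq / sum(freq)
}

# geometric factors of a leaf inclination class (Verhoef's volume-scattering
# geometry): fractions of intercepted direct/observed radiation and the
# bidirectional scattering integrals
volscatt <- function(tts, tto, psi, ttl) {
  cts <- cos(tts * rd); cto <- cos(tto * rd)
  sts <- sin(tts * rd); sto <- sin(tto * rd)
  cospsi <- cos(psi * rd); psir <- psi * rd
  cttl <- cos(ttl * rd); sttl <- sin(ttl * rd)
  cs <- cttl * cts; co <- cttl * cto
  ss <- sttl * sts; so <- sttl * sto
  cosbts <- if (abs(ss) > 1e-6) -cs / ss else 5
  cosbto <- if (abs(so) > 1e-6) -co / so else 5
  if (abs(cosbts) < 1) { bts <- acos(cosbts); ds <- ss } else { bts <- pi; ds <- cs }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)
  if (abs(cosbto) < 1) {
    bto <- acos(cosbto); do_ <- so
  } else if (tto < 90) {
    bto <- pi; do_ <- co
  } else {
    bto <- 0; do_ <- -co
  }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)
  btran1 <- abs(bts - bto)
  btran2 <- 2 * pi - bts - bto
  if (psir <= btran1) {
    bt1 <- psir; bt2 <- btran1; bt3 <- btran2
  } else if (psir <= btran2) {
    bt1 <- btran1; bt2 <- psir; bt3 <- btran2
  } else {
    bt1 <- btran1; bt2 <- btran2; bt3 <- psir
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- if (bt2 > 0) sin(bt2) * (2 * ds * do_ + ss * so * cos(bt1) * cos(bt3)) else 0
  denom <- 2 * pi^2
  c(
    chi_s = chi_s, chi_o = chi_o,
    frho = max(((pi - bt2) * t1 + t2) / denom, 0),
    ftau = max((-bt2 * t1 + t2) / denom, 0)
  )
}

# directional extinction/scattering coefficients for a given leaf angle
# distribution and geometry (wavelength-independent)
sail_geometry <- function(ala, tts, tto, psi) {
  litab <- c(5, 15, 25, 35, 45, 55, 65, 75, 81, 83, 85, 87, 89)
  lidf <- campbell_lidf(ala)
  cts <- cos(tts * rd); cto <- cos(tto * rd)
  ctscto <- cts * cto
  ks <- ko <- bf <- sob <- sof <- 0
  for (i in seq_along(litab)) {
    v <- volscatt(tts, tto, psi, litab[i])
    ks <- ks + v[["chi_s"]] / cts * lidf[i]
    ko <- ko + v[["chi_o"]] / cto * lidf[i]
    sob <- sob + v[["frho"]] * pi / ctscto * lidf[i]
    sof <- sof + v[["ftau"]] * pi / ctscto * lidf[i]
    bf <- bf + cos(litab[i] * rd)^2 * lidf[i]
  }
  list(ks = ks, ko = ko, bf = bf, sob = sob, sof = sof,
       tants = tan(tts * rd), tanto = tan(tto * rd), cospsi = cos(psi * rd))
}

# hot-spot-corrected single-scattering integral (Kuusk-style exponential
# quadrature in 20 steps); returns sum-integral and the joint gap fraction
hotspot_integral <- function(ks, ko, lai, hspot, dso) {
  tss <- exp(-ks * lai)
  if (hspot <= 0 || dso > 0) {
    alf <- if (hspot > 0) (dso / hspot) * 2 / (ks + ko) else 1e8
    alf <- min(alf, 1e8) # large alf = hotspot off; bounded for stability
    fhot <- lai * sqrt(ko * ks)
    x1 <- 0; y1 <- 0; f1 <- 1
    fint <- (1 - exp(-alf)) * 0.05
    sumint <- 0
    for (i in 1:20) {
      x2 <- if (i < 20) -log(1 - i * fint) / alf else 1
      y2 <- -(ko + ks) * lai * x2 + fhot * (1 - exp(-alf * x2)) / alf
      f2 <- exp(y2)
      sumint <- sumint + if (abs(y2 - y1) > 1e-12) {
        (f2 - f1) * (x2 - x1) / (y2 - y1)
      } else {
        f1 * (x2 - x1)
      }
      x1 <- x2; y1 <- y2; f1 <- f2
    }
    list(sumint = sumint, tsstoo = f1)
  } else {
    # exact hot spot direction
    list(sumint = (1 - tss) / (ks * lai), tsstoo = tss)
  }
}

#' Four-stream canopy bidirectional reflectance (SAIL family)
#'
#' Computes the canopy bidirectional reflectance factor from leaf reflectance
#' and transmittance, a soil background spectrum and sun/observer geometry,
#' using the classical four-stream turbid-medium formulation with an
#' ellipsoidal leaf inclination distribution and a hot-spot correction of the
#' single-scattering term. The diffuse two-stream system is solved
#' analytically (verified in the test-suite against an independent numerical
#' ODE solution of the same system).
#'
#' @param canopy a [canopy_params()] list (`LAI`, `ALA`, `HotS`, `alpha_soil`).
#' @param optics leaf optics as returned by [prospect_pro()] (`wavelengths`,
#'   `reflectance`, `transmittance`).
#' @param soil_reflectance soil background reflectance on the same wavelength
#'   grid as `optics`; by default `alpha_soil * soil_reference(wavelengths)`.
#' @param geometry a [view_geometry()] list.
#' @return numeric vector: bidirectional reflectance factor per wavelength,
#'   in \[0, 1\].
#' @export
#' @examples
#' lo <- prospect_pro(leaf_params())
#' brf <- sail4(canopy_params(LAI = 3), lo, geometry = view_geometry())
sail4 <- function(canopy, optics, soil_reflectance = NULL,
                  geometry = view_geometry()) {
  rho <- optics$reflectance
  tau <- optics$transmittance
  if (is.null(soil_reflectance)) {
    soil_reflectance <- canopy$alpha_soil * soil_reference(optics$wavelengths)
  }
  if (length(soil_reflectance) != length(rho)) {
    stop_domain("soil and leaf optics must share one wavelength grid")
  }
  lai <- canopy$LAI
  if (lai <= 1e-9) {
    return(soil_reflectance)
  }

  geo <- sail_geometry(canopy$ALA, geometry$SZA, geometry$OZA,
                       geometry$rel_azimuth)
  ks <- geo$ks; ko <- geo$ko; bf <- geo$bf
  sdb <- 0.5 * (ks + bf); sdf <- 0.5 * (ks - bf)
  dob <- 0.5 * (ko + bf); dof <- 0.5 * (ko - bf)
  ddb <- 0.5 * (1 + bf); ddf <- 0.5 * (1 - bf)

  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  att <- 1 - sigf
  m <- sqrt(pmax((att + sigb) * (att - sigb), 1e-30))
  sb <- sdb * rho + sdf * tau
  sf <- sdf * rho + sdb * tau
  vb <- dob * rho + dof * tau
  vf <- dof * rho + dob * tau
  w <- geo$sob * rho + geo$sof * tau

  e1 <- exp(-m * lai)
  e2 <- e1^2
  sigb_s <- pmax(sigb, 1e-12)
  rinf <- (att - m) / sigb_s
  denom <- 1 - rinf^2 * e2
  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)

  # diffuse-diffuse and solar-excited diffuse terms from the analytic
  # solution of the two-stream boundary value problem
  rdd <- rinf * (1 - e2) / denom
  tdd <- (1 - rinf^2) * e1 / denom

  ks_s <- ifelse(abs(m - ks) < 1e-7, ks + 1e-7, ks) # avoid resonant forcing
  D <- m^2 - ks_s^2
  p <- (sf * (att + ks_s) + sb * sigb) / D
  q <- (sb * (att - ks_s) + sf * sigb) / D
  tss_s <- exp(-ks_s * lai)
  A <- (rinf * e1 * q * tss_s - p) / denom
  B <- rinf * e1 * (p * rinf * e1 - q * tss_s) / denom
  rsd <- rinf * A + B / rinf + q
  tsd <- A * e1 + B / e1 + p * tss_s

  # observer-direction integrals of exp(-(ko + s) x) over the canopy depth
  Im <- (1 - exp(-(ko + m) * lai)) / (ko + m)
  dif <- ko - m
  Imm <- ifelse(abs(dif) * lai > 1e-4,
    (1 - exp(-dif * lai)) / dif,
    lai * (1 - dif * lai / 2 + (dif * lai)^2 / 6)
  )
  Iks <- (1 - exp(-(ko + ks_s) * lai)) / (ko + ks_s)
  rsod <- (vb + vf * rinf) * A * Im + (vb + vf / rinf) * B * Imm +
    (vb * p + vf * q) * Iks

  Ad <- 1 / denom
  Bd <- -rinf^2 * e2 / denom
  rdo <- (vb + vf * rinf) * Ad * Im + (vb + vf / rinf) * Bd * Imm
  # diffuse-to-observer transmission via the J-function closed forms
  J1ko <- jfunc1(ko, m, lai)
  J2ko <- (1 - exp(-(ko + m) * lai)) / (ko + m)
  Pv <- (vf + vb * rinf) * J1ko
  Qv <- (vf * rinf + vb) * J2ko
  re <- rinf * e1
  tdo <- (Pv - re * Qv) / denom

  # single scattering with hot spot
  dso <- sqrt(geo$tants^2 + geo$tanto^2 - 2 * geo$tants * geo$tanto * geo$cospsi)
  hs <- hotspot_integral(ks, ko, lai, canopy$HotS, dso)
  rsos <- w * lai * hs$sumint
  tsstoo <- hs$tsstoo

  # couple with the soil background (adding method)
  rs <- soil_reflectance
  dn <- 1 - rs * rdd
  rso <- rsos + rsod + tsstoo * rs +
    ((tss + tsd) * tdo + (tsd + tss * rs * rdd) * too) * rs / dn

  pmin(pmax(rso, 0), 1)
}

jfunc1 <- function(k, l, t) {
  d <- (k - l) * t
  ifelse(abs(d) > 1e-3,
    (exp(-l * t) - exp(-k * t)) / (k - l),
    0.5 * t * (exp(-k * t) + exp(-l * t)) * (1 - d * d / 12)
  )
}
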