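#' @keywords internal
# Average transmissivity of a dielectric interface over a cone of incidence
# angles [0, alpha_deg], for refractive index n (vectorised over n). Computed
# by Gauss-Legendre quadrature of the unpolarised Fresnel transmittance
# weighted by sin(theta)cos(theta).
tav <- function(alpha_deg, n) {
  if (alpha_deg <= 0) {
    return(4 * n / (n + 1)^2)
  }
  amax <- alpha_deg * pi / 180
  quad <- pracma::gaussLegendre(64, 0, amax)
  th <- quad$x
  w <- quad$w
  out <- numeric(length(n))
  sw <- sin(th) * cos(th)
  norm <- sum(w * sw)
  for (i in seq_along(n)) {
    ni <- n[i]
    st <- sin(th) / ni
    ct <- sqrt(pmax(1 - st^2, 0))
    ci <- cos(th)
    rs <- ((ci - ni * ct) / (ci + ni * ct))^2
    rp <- ((ni * ci - ct) / (ni * ci + ct))^2
    tfres <- 1 - 0.5 * (rs + rp)
    out[i] <- sum(w * sw * tfres) / norm
  }
  out
}

# memoised interface transmissivities on the default refractive-index spectrum
default_tav <- function() {
  if (is.null(.cnc_cache$tav)) {
    n <- default_leaf_coefficients()$refractive_index
    .cnc_cache$tav <- list(t40 = tav(40, n), t90 = tav(90, n))
  }
  .cnc_cache$tav
}

# transmission of an elementary absorbing layer with absorption k >= 0
layer_transmission <- function(k) {
  out <- rep(1, length(k))
  pos <- k > 1e-12
  kp <- k[pos]
  out[pos] <- (1 - kp) * exp(-kp) + kp^2 * pracma::expint_E1(kp)
  pmin(pmax(out, 0), 1)
}

#' Leaf optical properties (protein-resolving plate model)
#'
#' Simulates directional-hemispherical leaf reflectance and transmittance on
#' the native 1 nm grid (400--2500 nm) with a generalised plate model in
#' which leaf dry matter is split into protein content and carbon-based
#' constituents (CBC), so that nitrogen-related absorption is explicitly
#' represented in the SWIR. Uses the synthetic coefficient set of
#' [leaf_coefficients()].
#'
#' @param leaf a list (or [leaf_params()] result) with elements `N_struct`
#'   (leaf structure parameter, >= 1), `C_ab` (chlorophyll a+b, ug/cm^2),
#'   `C_xc` (carotenoids, ug/cm^2), `C_anth` (anthocyanins, ug/cm^2),
#'   `C_w` (equivalent water thickness, cm), `C_p` (protein, g/cm^2),
#'   `CBC` (carbon-based constituents, g/cm^2).
#' @return list with `wavelengths` (nm), `reflectance`, `transmittance`
#'   (fractions; `r + t <= 1` at every wavelength).
#' @export
#' @examples
#' lo <- prospect_pro(leaf_params(C_ab = 40, C_w = 0.01, C_p = 0.0015))
#' stopifnot(all(lo$reflectance + lo$transmittance <= 1))
prospect_pro <- function(leaf) {
  leaf <- leaf_params(
    N_struct = leaf$N_struct, C_ab = leaf$C_ab, C_xc = leaf$C_xc,
    C_anth = leaf$C_anth, C_w = leaf$C_w, C_p = leaf$C_p, CBC = leaf$CBC
  )
  cf <- default_leaf_coefficients()
  n <- cf$refractive_index
  N <- leaf$N_struct

  k <- (leaf$C_ab * cf$k_cab + leaf$C_xc * cf$k_car +
    leaf$C_anth * cf$k_anth + leaf$C_w * cf$k_water +
    leaf$C_p * cf$k_protein + leaf$CBC * cf$k_cbc) / N
  theta <- layer_transmission(k)

  tv <- default_tav()
  talf <- tv$t40
  ralf <- 1 - talf
  t12 <- tv$t90
  r12 <- 1 - t12
  t21 <- t12 / n^2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * theta^2
  Ta <- talf * theta * t21 / denom
  Ra <- ralf + r21 * theta * Ta
  tl <- t12 * theta * t21 / denom
  rl <- r12 + r21 * theta * tl

  # Stokes system for the remaining N-1 layers
  D <- sqrt(pmax((1 + rl + tl) * (1 + rl - tl) * (1 - rl + tl) * (1 - rl - tl), 0))
  rq <- rl^2
  tq <- tl^2
  a <- (1 + rq - tq + D) / (2 * rl)
  b <- (1 - rq + tq + D) / (2 * tl)
  bNm1 <- b^(N - 1)
  bN2 <- bNm1^2
  a2 <- a^2
  denom2 <- a2 * bN2 - 1
  Rsub <- a * (bN2 - 1) / denom2
  Tsub <- bNm1 * (a2 - 1) / denom2
  # conservative-scattering limit (no absorption): a,b -> 1
  degen <- rl + tl >= 1 - 1e-12 | !is.finite(Rsub) | !is.finite(Tsub)
  if (any(degen)) {
    Tsub[degen] <- tl[degen] / (tl[degen] + (1 - tl[degen]) * (N - 1))
    Rsub[degen] <- 1 - Tsub[degen]
  }

  dnm <- 1 - Rsub * rl
  tran <- Ta * Tsub / dnm
  refl <- Ra + Ta * Rsub * tl / dnm

  list(
    wavelengths = cf$wavelength,
    reflectance = pmin(pmax(refl, 0), 1),
    transmittance = pmin(pmax(tran, 0), 1)
  )
}

#' Leaf parameter record
#'
#' Validates and assembles the leaf-model inputs. All contents must be
#' non-negative and the structure parameter at least 1.
#'
#' @param N_struct leaf structure parameter (unitless, >= 1).
#' @param C_ab chlorophyll a+b content (ug/cm^2).
#' @param C_xc carotenoid content (ug/cm^2).
#' @param C_anth anthocyanin content (ug/cm^2).
#' @param C_w equivalent water thickness (cm).
#' @param C_p protein content (g/cm^2).
#' @param CBC carbon-based constituents (g/cm^2).
#' @return named list of class `leaf_params`.
#' @export
leaf_params <- function(N_struct = 1.5, C_ab = 40, C_xc = 8, C_anth = 1,
                        C_w = 0.01, C_p = 0.0015, CBC = 0.005) {
  vals <- c(
    N_struct = N_struct, C_ab = C_ab, C_xc = C_xc, C_anth = C_anth,
    C_w = C_w, C_p = C_p, CBC = CBC
  )
  assert_finite_numeric(vals, "leaf parameters")
  if (any(vals < 0)) stop_domain("leaf parameters must be non-negative")
  if (N_struct < 1) stop_domain("N_struct must be >= 1")
  structure(as.list(vals), class = "leaf_params")
}
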