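#' Construct a surface pixel
#'
#' One ocean-colour grid cell's surface state: everything any of the six NPP
#' algorithms needs. Units follow the ocean-colour conventions: chl mg m-3,
#' bbp/aph/adg/kd490 m-1, par mol photons m-2 day-1, sst degC, mld/zno3 m.
#'
#' @param chl chlorophyll-a (mg m-3).
#' @param sst sea surface temperature (degC).
#' @param par daily photosynthetically active radiation (mol photons m-2 day-1).
#' @param lat latitude (degrees).
#' @param doy day of year.
#' @param kd490 diffuse attenuation at 490 nm (m-1).
#' @param mld mixed-layer depth (m).
#' @param bbp particulate backscattering at the reference wavelength (m-1).
#' @param eta spectral slope of backscattering (dimensionless).
#' @param aph phytoplankton absorption at 443 nm (m-1).
#' @param adg detrital + coloured dissolved absorption at 443 nm (m-1).
#' @param zno3 nitracline depth (m), where nitrate + nitrite reaches 0.5 uM.
#' @param sss sea surface salinity.
#' @return a list of class `surface_pixel`.
#' @export
surface_pixel <- function(chl, sst, par, lat, doy, kd490 = 0.08, mld = 40,
                          bbp = 0.002, eta = 1.0, aph = 0.02, adg = 0.01,
                          zno3 = 60, sss = 34) {
  px <- list(chl = chl, sst = sst, par = par, lat = lat, doy = doy,
             kd490 = kd490, mld = mld, bbp = bbp, eta = eta, aph = aph,
             adg = adg, zno3 = zno3, sss = sss)
  if (any(c(chl, kd490, par) < 0, na.rm = TRUE) ||
      any(c(mld, zno3) <= 0, na.rm = TRUE) ||
      abs(lat) > 90 || doy < 1 || doy > 366) {
    stop("invalid surface pixel", call. = FALSE)
  }
  structure(px, class = "surface_pixel")
}

npp_result <- function(npp, algorithm, ...) {
  diag <- list(...)
  structure(list(npp = npp, algorithm = algorithm, diagnostics = diag),
            class = "npp_result")
}

#' Euphotic depth from surface chlorophyll (Morel case-I)
#'
#' Column-integrated chlorophyll is estimated from surface chlorophyll with
#' the two-branch power law, and the 1%-light depth from its power-law
#' inverse, switching relations for depths greater than 102 m.
#'
#' @param chl surface chlorophyll-a (mg m-3), vectorised.
#' @param coeffs an [npp_coefficients()] set.
#' @return euphotic depth (m); `NA` where `chl <= 0`.
#' @export
euphotic_depth <- function(chl, coeffs = npp_coefficients()) {
  m <- coeffs$morel
  ctot <- ifelse(chl < 1,
                 m$ctot_a_low * chl^m$ctot_b_low,
                 m$ctot_a_high * chl^m$ctot_b_high)
  zeu <- m$zeu_a * ctot^m$zeu_b
  zeu <- ifelse(zeu > m$z_switch, m$zeu_a2 * ctot^m$zeu_b2, zeu)
  ifelse(is.na(chl) | chl <= 0, NA_real_, zeu)
}

#' Optimal chlorophyll-normalised photosynthetic rate
#'
#' Temperature dependence of PBopt, either the 7th-order polynomial with its
#' low/high temperature clamps (`"behrenfeld"`) or the exponential
#' (`"eppley"`) form.
#'
#' @param sst sea surface temperature (degC), vectorised.
#' @param variant `"behrenfeld"` or `"eppley"`.
#' @param coeffs an [npp_coefficients()] set.
#' @return PBopt in mg C (mg Chl)-1 h-1.
#' @export
pb_opt <- function(sst, variant = c("behrenfeld", "eppley"),
                   coeffs = npp_coefficients()) {
  variant <- match.arg(variant)
  if (variant == "eppley") {
    e <- coeffs$eppley
    return(e$a * 10^(e$b * sst - e$c))
  }
  b <- coeffs$behrenfeld
  pows <- outer(sst, 0:7, `^`)
  pb <- as.numeric(pows %*% b$poly)
  pb[sst < b$t_lo] <- b$pb_lo
  pb[sst > b$t_hi] <- b$pb_hi
  pb
}

#' Vertically generalised production model (VGPM)
#'
#' NPP = scale * PBopt(SST) * PAR/(PAR + e_sat) * chl * Zeu * daylength.
#'
#' @param pixel a [surface_pixel()].
#' @param variant temperature function, `"behrenfeld"` or `"eppley"`.
#' @param coeffs an [npp_coefficients()] set.
#' @return an `npp_result` with NPP in mg C m-2 day-1 and diagnostics
#'   (`z_eu`, `pb_opt`, `daylength`).
#' @export
vgpm <- function(pixel, variant = c("behrenfeld", "eppley"),
                 coeffs = npp_coefficients()) {
  variant <- match.arg(variant)
  if (any(is.na(c(pixel$chl, pixel$par, pixel$sst)))) {
    return(npp_result(NA_real_, paste0("vgpm-", substr(variant, 1, 1))))
  }
  dl <- day_length(pixel$lat, pixel$doy)
  zeu <- euphotic_depth(pixel$chl, coeffs)
  pb <- pb_opt(pixel$sst, variant, coeffs)
  v <- coeffs$vgpm
  npp <- if (pixel$chl == 0) 0 else {
    v$scale * pb * pixel$par / (pixel$par + v$e_sat) * pixel$chl * zeu * dl
  }
  npp_result(npp, paste0("vgpm-", substr(variant, 1, 1)),
             z_eu = zeu, pb_opt = pb, daylength = dl)
}

#' Median mixed-layer light
#'
#' Hourly irradiance at the mid-point of the mixed layer,
#' Ig = (PAR/daylength) * exp(-kd490 * MLD / 2), the growth irradiance of the
#' CbPM growth law.
#'
#' @param par daily PAR (mol photons m-2 day-1).
#' @param kd490 attenuation (m-1), > 0.
#' @param mld mixed-layer depth (m), > 0.
#' @param daylength photoperiod (h).
#' @return Ig in mol photons m-2 h-1 (0 when `daylength` is 0).
#' @export
median_ml_light <- function(par, kd490, mld, daylength) {
  stopifnot(all(kd490 > 0), all(mld > 0))
  ifelse(daylength <= 0, 0, par / daylength * exp(-kd490 * mld / 2))
}

# CbPM growth law: mu(theta, I) with photoacclimated theta_max(I)
cbpm_mu <- function(theta, ig, coeffs) {
  cb <- coeffs$cbpm
  theta_max <- cb$theta_lo + (cb$theta_hi - cb$theta_lo) * exp(-cb$k_theta * ig)
  acclim <- clamp((theta - cb$theta_min) / (theta_max - cb$theta_min), 0, 1)
  cb$mu_max * acclim * (1 - exp(-cb$k_i * ig))
}

#' Phytoplankton carbon from particulate backscattering
#'
#' Affine conversion Cphyto = s_bbp * (bbp - b_dark), floored at zero.
#' @param bbp particulate backscattering (m-1) at the CbPM reference
#'   wavelength.
#' @param coeffs an [npp_coefficients()] set.
#' @return Cphyto in mg C m-3.
#' @export
cphyto_from_bbp <- function(bbp, coeffs = npp_coefficients()) {
  pmax(coeffs$cbpm$s_bbp * (bbp - coeffs$cbpm$b_dark), 0)
}

#' Carbon-based production model, surface (mixed-layer) form
#'
#' Phytoplankton carbon from backscattering, growth rate from the Chl:C
#' photoacclimation state and median mixed-layer light, and
#' NPP = mu * Cphyto * Zeu.
#'
#' @inheritParams vgpm
#' @return an `npp_result` (mg C m-2 day-1) with diagnostics `mu`, `cphyto`,
#'   `theta`, `i_g`, `z_eu`.
#' @export
cbpm_surface <- function(pixel, coeffs = npp_coefficients()) {
  if (any(is.na(c(pixel$chl, pixel$bbp, pixel$par)))) {
    return(npp_result(NA_real_, "cbpm-b"))
  }
  dl <- day_length(pixel$lat, pixel$doy)
  ig <- median_ml_light(pixel$par, pixel$kd490, pixel$mld, dl)
  cph <- cphyto_from_bbp(pixel$bbp, coeffs)
  if (cph <= 0) {
    return(npp_result(0, "cbpm-b", flag = "cphyto<=0", cphyto = cph))
  }
  theta <- pixel$chl / cph
  mu <- cbpm_mu(theta, ig, coeffs)
  zeu <- euphotic_depth(max(pixel$chl, 1e-6), coeffs)
  npp_result(mu * cph * zeu, "cbpm-b",
             mu = mu, cphyto = cph, theta = theta, i_g = ig, z_eu = zeu,
             daylength = dl)
}

#' Construct a depth-resolved environment
#'
#' @param z depth grid (m), strictly increasing from the surface.
#' @param chl,cphyto,par,temp profiles on `z` (mg m-3, mg C m-3, mol photons
#'   m-2 day-1, degC).
#' @return a list of class `depth_environment`.
#' @export
depth_environment <- function(z, chl, cphyto, par, temp) {
  n <- length(z)
  if (n < 2L || any(diff(z) <= 0)) {
    stop("depth grid must be strictly increasing", call. = FALSE)
  }
  if (any(lengths(list(chl, cphyto, par, temp)) != n)) {
    stop("profile arrays must match the depth grid", call. = FALSE)
  }
  structure(list(z = z, chl = chl, cphyto = cphyto, par = par, temp = temp),
            class = "depth_environment")
}

#' Reconstruct a depth-resolved environment from a surface pixel
#'
#' Builds the vertical structure the depth-resolved CbPM needs from surface
#' fields: chlorophyll and phytoplankton carbon uniform within the mixed
#' layer; below the deeper of the mixed layer and the nitracline the Chl:C
#' ratio relaxes linearly in optical depth towards the photoacclimation
#' optimum theta_max(E(z)) at the euphotic depth; Cphyto is held constant to
#' Zeu and attenuated exponentially below it; PAR decays as
#' exp(-kd490 * z); temperature is mixed-layer SST with a weak decrease below.
#'
#' @param pixel a [surface_pixel()].
#' @param coeffs an [npp_coefficients()] set.
#' @param z depth grid (m), default 0..200 m at 1 m.
#' @return a [depth_environment()].
#' @export
reconstruct_profile <- function(pixel, coeffs = npp_coefficients(),
                                z = seq(0, 200, by = 1)) {
  cb <- coeffs$cbpm
  par_z <- pixel$par * exp(-pixel$kd490 * z)
  cph0 <- cphyto_from_bbp(pixel$bbp, coeffs)
  zeu <- euphotic_depth(max(pixel$chl, 1e-6), coeffs)
  cph <- ifelse(z <= zeu, cph0, cph0 * exp(-(z - zeu) / cb$cphyto_efold))
  theta0 <- if (cph0 > 0) pixel$chl / cph0 else cb$theta_min
  # light available for acclimation uses hourly irradiance at depth
  dl <- day_length(pixel$lat, pixel$doy)
  ig_z <- if (dl > 0) par_z / dl else par_z * 0
  theta_max_z <- cb$theta_lo + (cb$theta_hi - cb$theta_lo) *
    exp(-cb$k_theta * ig_z)
  # relaxation active only below both the mixed layer and the nitracline
  z_start <- max(pixel$mld, pixel$zno3)
  tau <- pixel$kd490 * z                     # optical depth
  tau_start <- pixel$kd490 * z_start
  tau_eu <- max(pixel$kd490 * zeu, tau_start + 1e-9)
  w <- clamp((tau - tau_start) / (tau_eu - tau_start), 0, 1)
  theta <- (1 - w) * theta0 + w * theta_max_z
  chl <- theta * cph
  temp <- ifelse(z <= pixel$mld, pixel$sst,
                 pixel$sst - 0.02 * (z - pixel$mld))
  depth_environment(z, chl, cph, par_z, temp)
}

#' Depth-resolved carbon-based production model
#'
#' Applies the CbPM growth law at every depth using local PAR and local
#' Chl:C, giving volumetric NPP mu(z) * Cphyto(z) (mg C m-3 day-1), then
#' integrates to `z_max` by the trapezoidal rule. In
#' `"satellite_reconstructed"` mode the profile is first built from a surface
#' pixel via [reconstruct_profile()]; in `"float_measured"` mode the supplied
#' [depth_environment()] is used as is.
#'
#' @param env a [depth_environment()] (ignored in satellite mode if `pixel`
#'   given).
#' @param mode `"float_measured"` or `"satellite_reconstructed"`.
#' @param coeffs an [npp_coefficients()] set.
#' @param z_max integration depth (m), must not exceed `max(env$z)`.
#' @param pixel surface pixel for satellite mode.
#' @param daylength photoperiod (h) used to convert daily PAR to hourly
#'   growth irradiance; computed from `pixel` when supplied.
#' @return list with `npp_z` (volumetric profile) and `result` (integrated
#'   `npp_result`, mg C m-2 day-1).
#' @export
cbpm_depth_resolved <- function(env = NULL,
                                mode = c("float_measured",
                                         "satellite_reconstructed"),
                                coeffs = npp_coefficients(), z_max = 200,
                                pixel = NULL, daylength = NULL) {
  mode <- match.arg(mode)
  if (mode == "satellite_reconstructed") {
    stopifnot(!is.null(pixel))
    env <- reconstruct_profile(pixel, coeffs,
                               z = seq(0, z_max, by = 1))
    daylength <- day_length(pixel$lat, pixel$doy)
  }
  if (any(diff(env$z) <= 0)) stop("non-monotone depth grid", call. = FALSE)
  if (z_max > max(env$z) + 1e-9) {
    stop("z_max exceeds the sampled depth range", call. = FALSE)
  }
  dl <- daylength %||% 12
  ig_z <- if (dl > 0) env$par / dl else env$par * 0
  theta <- ifelse(env$cphyto > 0, env$chl / env$cphyto, 0)
  mu_z <- cbpm_mu(theta, ig_z, coeffs)
  npp_z <- mu_z * pmax(env$cphyto, 0)
  keep <- env$z <= z_max & is.finite(npp_z)
  integral <- trapz_int(env$z[keep], npp_z[keep])
  list(npp_z = npp_z,
       result = npp_result(integral, if (mode == "float_measured")
         "cbpm-w-float" else "cbpm-w", z_max = z_max, daylength = dl))
}

#' Depth-resolved (volumetric) VGPM for float profiles
#'
#' Volumetric reading of the VGPM for measured profiles:
#' npp(z) = scale * PBopt(T(z)) * chl(z) * daylength * E(z)/(E(z) + e_sat),
#' integrated to `z_max`.
#'
#' @inheritParams cbpm_depth_resolved
#' @param variant temperature function, `"behrenfeld"` or `"eppley"`.
#' @return list with `npp_z` and integrated `result`.
#' @export
vgpm_depth_resolved <- function(env, variant = c("behrenfeld", "eppley"),
                                coeffs = npp_coefficients(), z_max = 200,
                                daylength = 12) {
  variant <- match.arg(variant)
  v <- coeffs$vgpm
  pb_z <- pb_opt(env$temp, variant, coeffs)
  npp_z <- v$scale * pb_z * pmax(env$chl, 0) * daylength *
    env$par / (env$par + v$e_sat)
  keep <- env$z <= z_max & is.finite(npp_z)
  integral <- trapz_int(env$z[keep], npp_z[keep])
  list(npp_z = npp_z,
       result = npp_result(integral, paste0("vgpm-", substr(variant, 1, 1),
                                            "-float"),
                           z_max = z_max, daylength = daylength))
}

#' Absorption-based production models (AbPM and CAFE forms)
#'
#' Absorbed photon flux AQ(z) = aph * PAR * exp(-kd490 * z) (spectrally
#' integrated), converted to carbon with an irradiance-dependent quantum
#' yield phi(E) and integrated over depth:
#' NPP = 12 g mol-1 * sum_z phi(E(z)) * AQ(z) * dz, reported in mg C m-2
#' day-1. The AbPM form uses phi(E) = phi_max * Ek/(Ek + E); the CAFE form
#' phi(E) = phi_max * (Ek/E) * (1 - exp(-E/Ek)) with Ek acclimated to the
#' daily-equivalent median mixed-layer light. Both are bounded by the
#' analytic limit 12 * phi_max * aph * PAR / kd490.
#'
#' @inheritParams vgpm
#' @param variant `"abpm"` or `"cafe"`.
#' @param dz quadrature step (m); default from `coeffs$absorption$dz`.
#' @return an `npp_result` (mg C m-2 day-1) with diagnostics `e_k`, `i_g`,
#'   `z_grid_max`.
#' @export
absorption_npp <- function(pixel, variant = c("abpm", "cafe"),
                           coeffs = npp_coefficients(), dz = NULL) {
  variant <- match.arg(variant)
  ab <- coeffs$absorption
  dz <- dz %||% ab$dz
  if (any(is.na(c(pixel$aph, pixel$kd490, pixel$par)))) {
    return(npp_result(NA_real_, variant))
  }
  if (pixel$aph <= 0 || pixel$par <= 0) {
    return(npp_result(0, variant))
  }
  dl <- day_length(pixel$lat, pixel$doy)
  ig <- median_ml_light(pixel$par, pixel$kd490, pixel$mld, dl)
  ek <- max(ab$ek_floor, ig * dl)   # daily-equivalent saturation irradiance
  z_top <- min(500, ceiling(6 / pixel$kd490))  # e^-6 light floor
  z <- seq(0, z_top, by = dz)
  e_z <- pixel$par * exp(-pixel$kd490 * z)
  phi <- if (variant == "abpm") {
    ab$phi_max * ek / (ek + e_z)
  } else {
    ab$phi_max * (ek / e_z) * (1 - exp(-e_z / ek))
  }
  aq <- pixel$aph * e_z
  npp <- 12 * 1000 * trapz_int(z, phi * aq)   # g mol-1 -> mg C m-2 day-1
  npp_result(npp, variant, e_k = ek, i_g = ig, z_grid_max = z_top,
             daylength = dl)
}

#' Spectral translation of particulate backscattering
#'
#' bbp(target) = bbp(ref) * (lambda_target / lambda_ref)^(-eta).
#'
#' @param bbp_ref backscattering at `lambda_ref` (m-1).
#' @param lambda_ref,lambda_target wavelengths (nm), > 0.
#' @param eta spectral slope (dimensionless).
#' @return bbp at the target wavelength (m-1).
#' @examples
#' bbp_spectral(0.001, 700, 470, 0.78)  # x1.3644
#' @export
bbp_spectral <- function(bbp_ref, lambda_ref, lambda_target, eta) {
  stopifnot(all(lambda_ref > 0), all(lambda_target > 0))
  bbp_ref * (lambda_target / lambda_ref)^(-eta)
}

#' Compute NPP for a pixel with a named algorithm
#'
#' Dispatcher over the six algorithm identifiers: `"vgpm-b"`, `"vgpm-e"`,
#' `"cbpm-b"` (surface carbon-based), `"cbpm-w"` (depth-resolved, profile
#' reconstructed from the pixel), `"abpm"`, `"cafe"`.
#'
#' @param pixel a [surface_pixel()].
#' @param algorithm one of the six identifiers.
#' @param coeffs an [npp_coefficients()] set.
#' @return an `npp_result`.
#' @export
compute_npp <- function(pixel,
                        algorithm = c("vgpm-b", "vgpm-e", "cbpm-b", "cbpm-w",
                                      "abpm", "cafe"),
                        coeffs = npp_coefficients()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    "vgpm-b" = vgpm(pixel, "behrenfeld", coeffs),
    "vgpm-e" = vgpm(pixel, "eppley", coeffs),
    "cbpm-b" = cbpm_surface(pixel, coeffs),
    "cbpm-w" = cbpm_depth_resolved(mode = "satellite_reconstructed",
                                   coeffs = coeffs, pixel = pixel)$result,
    "abpm" = absorption_npp(pixel, "abpm", coeffs),
    "cafe" = absorption_npp(pixel, "cafe", coeffs)
  )
}

#' All supported algorithm identifiers
#' @return character vector.
#' @export
npp_algorithms <- function() c("vgpm-b", "vgpm-e", "cbpm-b", "cbpm-w",
                               "abpm", "cafe")
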