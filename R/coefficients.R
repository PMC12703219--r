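#' Default coefficient set for the NPP algorithms
#'
#' All tunable constants of the six production algorithms live in one named,
#' versioned list so that results can be reproduced bit-for-bit from a
#' serialized coefficient set. Defaults follow the standard published values
#' of each algorithm family: the VGPM scale factor and light-saturation
#' constant, the Eppley exponential temperature function, the Morel case-I
#' euphotic-depth relation, CbPM photoacclimation bounds, and an
#' absorption-family quantum-yield model.
#'
#' @param ... named overrides, e.g. `npp_coefficients(cbpm = list(mu_max = 1.8))`.
#'   Overrides are merged element-wise into the default nested list.
#'
#' @return an object of class `npp_coefficients`: a nested list with elements
#'   `vgpm`, `eppley`, `behrenfeld`, `morel`, `cbpm`, `absorption`, `version`.
#'
#' @details Components:
#' \describe{
#'   \item{vgpm}{`scale` (0.66125, dimensionless), `e_sat` (4.1, mol photons
#'     m-2 day-1) in the light term PAR/(PAR + e_sat).}
#'   \item{eppley}{`a` (1.54), `b` (0.0275 per degC), `c` (0.07):
#'     PBopt = a * 10^(b*T - c) in mg C (mg Chl)-1 h-1.}
#'   \item{behrenfeld}{7th-order polynomial coefficients `poly` in SST and the
#'     clamps `t_lo`/`pb_lo` (below -1 degC -> 1.13) and `t_hi`/`pb_hi`
#'     (above 28.5 degC -> 4.0).}
#'   \item{morel}{case-I euphotic depth from chlorophyll: column-integrated
#'     chlorophyll Ctot = 38 chl^0.425 (chl < 1) else 40.2 chl^0.547; Zeu =
#'     568.2 Ctot^-0.746, replaced by 200 Ctot^-0.293 when deeper than 102 m.}
#'   \item{cbpm}{`mu_max` (2 day-1), Chl:C bounds `theta_min` (3e-4),
#'     `theta_lo` (0.022), `theta_hi` (0.045), light constants `k_theta` (3)
#'     and `k_i` (5) (both per mol photons m-2 h-1), and the phytoplankton
#'     carbon rule Cphyto = `s_bbp` * (bbp - `b_dark`) with s_bbp = 13000 mg C
#'     m-2, b_dark = 0.00035 m-1.}
#'   \item{absorption}{`phi_max` (0.05 mol C per mol photons), `ek_floor`
#'     (1 mol photons m-2 day-1) for the light-acclimated saturation
#'     irradiance, and `dz` (1 m) default quadrature step.}
#' }
#'
#' @examples
#' co <- npp_coefficients()
#' co$vgpm$scale
#' @export
npp_coefficients <- function(...) {
  co <- list(
    vgpm = list(scale = 0.66125, e_sat = 4.1),
    eppley = list(a = 1.54, b = 0.0275, c = 0.07),
    behrenfeld = list(
      poly = c(1.2956, 2.749e-1, 6.17e-2, -2.05e-2, 2.462e-3,
               -1.348e-4, 3.4132e-6, -3.27e-8),
      t_lo = -1, pb_lo = 1.13, t_hi = 28.5, pb_hi = 4.0
    ),
    morel = list(
      ctot_a_low = 38.0, ctot_b_low = 0.425,
      ctot_a_high = 40.2, ctot_b_high = 0.547,
      zeu_a = 568.2, zeu_b = -0.746,
      zeu_a2 = 200.0, zeu_b2 = -0.293, z_switch = 102.0
    ),
    cbpm = list(
      mu_max = 2.0, theta_min = 3e-4, theta_lo = 0.022, theta_hi = 0.045,
      k_theta = 3.0, k_i = 5.0, s_bbp = 13000, b_dark = 0.00035,
      cphyto_efold = 100  # e-folding depth (m) of Cphyto below Zeu in
                          # reconstructed profiles
    ),
    absorption = list(phi_max = 0.05, ek_floor = 1.0, dz = 1.0),
    version = "sonpp-coeffs-1"
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(co[[nm]])) {
      co[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      co[[nm]] <- ov[[nm]]
    }
  }
  bad <- vapply(unlist(co[setdiff(names(co), "version")]), function(x) {
    !is.finite(x)
  }, logical(1))
  if (any(bad)) stop("non-finite algorithm coefficients", call. = FALSE)
  structure(co, class = "npp_coefficients")
}

#' Stable hash of a coefficient set (provenance)
#' @param coeffs an `npp_coefficients` object.
#' @return character hash.
#' @export
coefficients_hash <- function(coeffs) rlang::hash(unclass(coeffs))
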