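#' Standard vertical grid for processed float profiles
#'
#' 1 m resolution from 1 to 300 m, 10 m resolution from 310 to 1000 m.
#' @return numeric depth vector (m).
#' @export
standard_grid <- function() c(seq(1, 300, by = 1), seq(310, 1000, by = 10))

#' Select samples by quality-control flag
#'
#' Masks every sample whose QC flag is not in `keep_flags` (default
#' \{1, 2, 5, 8\}) for every flagged variable, and drops profiles left with no
#' valid sample in any flagged variable.
#'
#' @param profiles a list of float profiles (each a list with data vectors
#'   and a `qc` list of integer flag vectors named after the variables).
#' @param keep_flags integer flags regarded as good.
#' @return the filtered profile list; dropped profiles are recorded in
#'   attribute `"dropped"` with reasons.
#' @export
select_qc <- function(profiles, keep_flags = c(1, 2, 5, 8)) {
  dropped <- character(0)
  out <- list()
  for (p in profiles) {
    if (is.null(p$qc) || !length(p$qc)) {
      dropped <- c(dropped, paste0(p$id %||% "?", ": missing QC flags"))
      next
    }
    any_valid <- FALSE
    for (v in names(p$qc)) {
      bad <- !(p$qc[[v]] %in% keep_flags)
      p[[v]][bad] <- NA_real_
      if (any(!bad & is.finite(p[[v]]))) any_valid <- TRUE
    }
    if (any_valid) out[[length(out) + 1L]] <- p
    else dropped <- c(dropped, paste0(p$id %||% "?", ": no valid samples"))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Regrid a raw profile onto the standard vertical grid
#'
#' Shape-preserving (monotone) piecewise-cubic Hermite interpolation with no
#' extrapolation: grid nodes outside the observed depth range are missing;
#' raw samples coinciding with grid nodes are reproduced exactly.
#'
#' @param raw_z raw sample depths (m).
#' @param values raw sample values (may contain `NA`).
#' @param grid target depth grid, default [standard_grid()].
#' @return values on `grid`, `NA` outside the sampled range; attribute
#'   `"flag"` set to `"insufficient"` when fewer than 2 valid samples.
#' @export
regrid_profile <- function(raw_z, values, grid = standard_grid()) {
  ok <- is.finite(raw_z) & is.finite(values)
  if (sum(ok) < 2L) {
    out <- rep(NA_real_, length(grid))
    attr(out, "flag") <- "insufficient"
    return(out)
  }
  x <- raw_z[ok]; y <- values[ok]
  o <- order(x); x <- x[o]; y <- y[o]
  dup <- duplicated(x); x <- x[!dup]; y <- y[!dup]
  if (length(x) < 2L) {
    out <- rep(NA_real_, length(grid))
    attr(out, "flag") <- "insufficient"
    return(out)
  }
  inside <- grid >= x[1] & grid <= x[length(x)]
  out <- rep(NA_real_, length(grid))
  if (any(inside)) out[inside] <- pracma::pchip(x, y, grid[inside])
  out
}

#' Correct daytime fluorescence quenching (mixed-layer maximum extrapolation)
#'
#' Daytime non-photochemical quenching suppresses fluorescence near the
#' surface. Following the mixed-layer-maximum scheme, the fluorescence
#' maximum within the mixed layer is located and every value shallower than
#' that depth is replaced by the maximum. Night profiles are returned
#' unchanged.
#'
#' @param fchl fluorescence-chlorophyll profile (mg m-3) on grid `z`.
#' @param z depth grid (m).
#' @param mld mixed-layer depth (m).
#' @param is_day logical: was the profile taken in daylight?
#' @return corrected profile; attribute `"corrected"` TRUE when the
#'   correction fired, `"flag"` when no valid value lay within the mixed
#'   layer.
#' @export
correct_quenching <- function(fchl, z, mld, is_day) {
  out <- fchl
  attr(out, "corrected") <- FALSE
  if (!isTRUE(is_day)) return(out)
  in_ml <- which(z <= mld & is.finite(fchl))
  if (!length(in_ml)) {
    attr(out, "flag") <- "no valid values in mixed layer"
    return(out)
  }
  imax <- in_ml[which.max(fchl[in_ml])]
  # replace only sampled values: no extrapolation beyond the raw range
  shallower <- which(z < z[imax] & is.finite(fchl))
  if (length(shallower)) {
    out[shallower] <- fchl[imax]
    attr(out, "corrected") <- TRUE
  }
  out
}

#' Convert fluorescence to chlorophyll
#'
#' Applies the factory-calibration slope adjustment: chl = fchl / `factor`
#' with the standard factor of 2.
#' @param fchl quenching-corrected fluorescence-chlorophyll (mg m-3).
#' @param factor slope adjustment factor.
#' @return chlorophyll-a (mg m-3).
#' @export
fluor_to_chl <- function(fchl, factor = 2) fchl / factor

#' Clean a particulate backscattering profile
#'
#' Masks negative samples, rejects profiles whose median absolute successive
#' difference exceeds `noise_mult` times the profile-set median of that
#' statistic ("noisy"), and rejects profiles whose median bbp below 700 m
#' exceeds `deep_mult` times the set's deep median ("anomalous deep").
#'
#' @param bbp backscattering profile (m-1) on grid `z`.
#' @param z depth grid (m).
#' @param context list with set-level statistics `median_msd` (median over
#'   profiles of the median absolute successive difference) and
#'   `deep_median` (median over profiles of median bbp below 700 m); build it
#'   with [bbp_set_context()].
#' @param noise_mult,deep_mult rejection multiples (defaults 5 and 3).
#' @return cleaned profile, or `NULL` with attribute `"reason"` on the
#'   context list not applicable; rejection is signalled by returning an
#'   object of class `bbp_rejection` carrying the reason code.
#' @export
clean_bbp <- function(bbp, z, context, noise_mult = 5, deep_mult = 3) {
  out <- bbp
  out[out < 0] <- NA_real_
  if (!any(is.finite(out))) {
    return(structure(list(reason = "all masked"), class = "bbp_rejection"))
  }
  msd <- stats::median(abs(diff(out)), na.rm = TRUE)
  if (is.finite(msd) && is.finite(context$median_msd) &&
      context$median_msd > 0 && msd > noise_mult * context$median_msd) {
    return(structure(list(reason = "noisy"), class = "bbp_rejection"))
  }
  deep <- stats::median(out[z > 700], na.rm = TRUE)
  if (is.finite(deep) && is.finite(context$deep_median) &&
      context$deep_median > 0 && deep > deep_mult * context$deep_median) {
    return(structure(list(reason = "anomalous deep"), class = "bbp_rejection"))
  }
  out
}

#' Profile-set context statistics for backscatter cleaning
#' @param bbp_list list of regridded bbp profiles.
#' @param z depth grid.
#' @return list with `median_msd` and `deep_median`.
#' @export
bbp_set_context <- function(bbp_list, z) {
  msds <- vapply(bbp_list, function(b) {
    b[b < 0] <- NA_real_
    stats::median(abs(diff(b)), na.rm = TRUE)
  }, numeric(1))
  deeps <- vapply(bbp_list, function(b) {
    b[b < 0] <- NA_real_
    stats::median(b[z > 700], na.rm = TRUE)
  }, numeric(1))
  list(median_msd = stats::median(msds, na.rm = TRUE),
       deep_median = stats::median(deeps, na.rm = TRUE))
}

#' Despike a series with a running median
#'
#' Centered running median of odd `window` length; at the edges the window is
#' truncated to the available samples. Series shorter than 3 are returned
#' unchanged.
#'
#' @param series numeric vector (may contain `NA`; medians ignore them).
#' @param window odd window length, default 11.
#' @return filtered series.
#' @export
despike <- function(series, window = 11) {
  stopifnot(window %% 2 == 1)
  n <- length(series)
  if (n < 3L) return(series)
  half <- (window - 1L) / 2L
  # missing samples stay missing: filtering must not fill gaps
  vapply(seq_len(n), function(i) {
    if (is.na(series[i])) return(NA_real_)
    w <- series[max(1L, i - half):min(n, i + half)]
    stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

#' Convert backscattering at 700 nm to phytoplankton carbon
#'
#' Removes the non-algal baseline (per-profile median bbp in 850-1000 m,
#' floored at zero), translates the residual to 470 nm with a spectral slope
#' of magnitude 0.78, and converts with the slope factor 12128:
#' Cphyto = 12128 * max(bbp700 - baseline, 0) * (470/700)^(-0.78).
#'
#' @param bbp700 cleaned, despiked backscattering at 700 nm (m-1) on `z`.
#' @param z depth grid (m).
#' @param set_deep_median fallback baseline when the profile has no 850-1000 m
#'   samples (profile-set deep median).
#' @param slope_factor carbon conversion slope (mg C m-2).
#' @param eta magnitude of the spectral slope.
#' @return Cphyto profile (mg C m-3); attributes `"baseline"` and, when the
#'   fallback fired, `"flag"`.
#' @export
to_cphyto <- function(bbp700, z, set_deep_median = NA_real_,
                      slope_factor = 12128, eta = 0.78) {
  deep <- is.finite(bbp700) & z >= 850 & z <= 1000
  flag <- NULL
  if (any(deep)) {
    baseline <- stats::median(bbp700[deep])
  } else {
    baseline <- set_deep_median
    flag <- "baseline from profile set"
  }
  if (!is.finite(baseline)) baseline <- 0
  b_phyto <- pmax(bbp700 - baseline, 0)
  out <- slope_factor * bbp_spectral(b_phyto, 700, 470, eta)
  attr(out, "baseline") <- baseline
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

#' Potential density from a linear equation of state
#'
#' Documented linear equation of state
#' rho = rho0 * (1 - alpha (T - T0) + beta (S - S0)) with rho0 = 1025 kg m-3,
#' alpha = 2e-4 per degC, beta = 7.6e-4 per salinity unit, T0 = 10, S0 = 35.
#' Adequate for mixed-layer-depth detection; a full thermodynamic equation of
#' state can be injected wherever a density function is accepted.
#'
#' @param temp,sal temperature (degC) and salinity.
#' @return potential density (kg m-3).
#' @export
linear_eos <- function(temp, sal) {
  1025 * (1 - 2e-4 * (temp - 10) + 7.6e-4 * (sal - 35))
}

#' Mixed-layer depth from a potential-density threshold
#'
#' Shallowest depth at which potential density exceeds its value at the 10 m
#' reference depth by `criterion` (default 0.03 kg m-3).
#'
#' @param temp,sal profiles on `z`.
#' @param z depth grid (m).
#' @param criterion density threshold (kg m-3).
#' @param ref_depth reference depth (m); the nearest available sample is used
#'   (flagged when not at 10 m).
#' @param eos density function of (temp, sal).
#' @return MLD (m); attribute `"flag"` set to `"no threshold crossing"` when
#'   the profile is homogeneous (deepest valid level returned) or to
#'   `"reference not at 10 m"` when the reference sample was elsewhere.
#' @export
mld_density <- function(temp, sal, z, criterion = 0.03, ref_depth = 10,
                        eos = linear_eos) {
  rho <- eos(temp, sal)
  ok <- is.finite(rho)
  if (!any(ok)) return(structure(NA_real_, flag = "no density data"))
  zi <- z[ok]; ri <- rho[ok]
  iref <- which.min(abs(zi - ref_depth))
  flag <- NULL
  if (abs(zi[iref] - ref_depth) > 2) flag <- "reference not at 10 m"
  below <- which(zi > zi[iref] & ri >= ri[iref] + criterion)
  if (!length(below)) {
    return(structure(max(zi), flag = "no threshold crossing"))
  }
  structure(zi[min(below)], flag = flag)
}

#' Upper-ocean trapezoidal integral
#'
#' Integrates a profile from the surface to `z_max`: the shallowest sample is
#' extended to 0 m, interior gaps are linearly interpolated, and the value at
#' `z_max` interpolated when sampled levels straddle it. Returns `NA` when
#' more than half of the grid levels in range are missing.
#'
#' @param values profile on `z`.
#' @param z depth grid (m), increasing.
#' @param z_max integration depth (m), `<= max(z)`.
#' @return the integral in `units(values) * m`.
#' @export
integrate_upper <- function(values, z, z_max) {
  stopifnot(all(diff(z) > 0), z_max <= max(z) + 1e-9)
  in_range <- z <= z_max
  if (mean(!is.finite(values[in_range])) > 0.5) return(NA_real_)
  ok <- is.finite(values)
  if (sum(ok) < 2L) return(NA_real_)
  zi <- z[ok]; vi <- values[ok]
  # surface extension + gap filling + exact endpoint
  zq <- sort(unique(c(0, zi[zi <= z_max], z_max)))
  vq <- stats::approx(zi, vi, xout = zq, rule = 2)$y
  trapz_int(zq, vq)
}

#' Ratio of two upper-ocean inventories
#'
#' Divides the integrals of two co-located profiles over the same depth
#' range, after optional unit conversion to moles (e.g. a dissolved Mn to Fe
#' molar ratio over the upper 100 m).
#'
#' @param num,den numerator and denominator profiles on `z`.
#' @param z depth grid (m).
#' @param z_max integration depth (m).
#' @param num_to_mol,den_to_mol multiplicative conversions to molar units.
#' @return dimensionless molar ratio.
#' @export
integrate_ratio <- function(num, den, z, z_max, num_to_mol = 1,
                            den_to_mol = 1) {
  a <- integrate_upper(num * num_to_mol, z, z_max)
  b <- integrate_upper(den * den_to_mol, z, z_max)
  if (!is.finite(a) || !is.finite(b) || b == 0) return(NA_real_)
  a / b
}

#' Process one raw float profile through the full chain
#'
#' Fixed, audited order: QC masking (done upstream by [select_qc()]) ->
#' vertical regridding -> fluorescence branch (quenching correction, slope
#' factor 2, despike) and backscatter branch (clean, despike, carbon
#' conversion) -> mixed-layer depth. Returns the processed profile with its
#' audit trail.
#'
#' @param profile a raw profile (after [select_qc()]).
#' @param context backscatter set context from [bbp_set_context()] computed
#'   on regridded profiles.
#' @param grid standard vertical grid.
#' @param coeffs an [npp_coefficients()] set (unused here but carried for
#'   provenance).
#' @return a list of class `processed_profile` with elements `z`, `chl`,
#'   `cphyto`, `par`, `temp`, `sal`, `mld`, `audit`, plus the profile
#'   metadata; or `NULL` when the backscatter branch rejected the profile.
#' @export
process_profile <- function(profile, context, grid = standard_grid(),
                            coeffs = npp_coefficients()) {
  audit <- character(0)
  temp <- regrid_profile(profile$z, profile$temp, grid)
  sal  <- regrid_profile(profile$z, profile$sal, grid)
  par  <- regrid_profile(profile$z, profile$par, grid)
  fchl <- regrid_profile(profile$z, profile$fchl, grid)
  bbp  <- regrid_profile(profile$z, profile$bbp700, grid)
  audit <- c(audit, "regrid")
  mld0 <- mld_density(temp, sal, grid)
  fchl_q <- correct_quenching(fchl, grid, as.numeric(mld0), profile$is_day)
  if (isTRUE(attr(fchl_q, "corrected"))) audit <- c(audit, "quench")
  chl <- despike(fluor_to_chl(fchl_q))
  audit <- c(audit, "fchl/2", "despike_chl")
  bbp_c <- clean_bbp(bbp, grid, context)
  if (inherits(bbp_c, "bbp_rejection")) {
    return(structure(NULL, reason = bbp_c$reason))
  }
  audit <- c(audit, "clean_bbp")
  bbp_d <- despike(bbp_c)
  cphyto <- to_cphyto(bbp_d, grid, set_deep_median = context$deep_median)
  audit <- c(audit, "despike_bbp", "to_cphyto")
  temp <- despike(temp); sal <- despike(sal); par <- despike(par)
  audit <- c(audit, "despike_physics", "mld")
  structure(list(
    id = profile$id, time = profile$time, lat = profile$lat,
    lon = profile$lon, is_day = profile$is_day,
    z = grid, chl = as.numeric(chl), cphyto = as.numeric(cphyto),
    par = as.numeric(par), temp = as.numeric(temp), sal = as.numeric(sal),
    mld = as.numeric(mld0), audit = audit
  ), class = "processed_profile")
}

#' Process a float profile set and compute per-profile NPP
#'
#' Runs [select_qc()] and [process_profile()] over a set and computes
#' integrated 0-200 m NPP with the requested float algorithms.
#'
#' @param profiles list of raw profiles.
#' @param algorithms subset of `c("vgpm-b", "vgpm-e", "cbpm-w")`.
#' @param grid standard grid.
#' @param coeffs an [npp_coefficients()] set.
#' @return data.frame with one row per retained profile: id, time, lat, lon,
#'   mld and one NPP column (mg C m-2 day-1) per algorithm; the processed
#'   profiles in attribute `"profiles"`.
#' @export
process_float_set <- function(profiles,
                              algorithms = c("vgpm-b", "vgpm-e", "cbpm-w"),
                              grid = standard_grid(),
                              coeffs = npp_coefficients()) {
  kept <- select_qc(profiles)
  bbp_list <- lapply(kept, function(p) regrid_profile(p$z, p$bbp700, grid))
  context <- bbp_set_context(bbp_list, grid)
  rows <- list()
  procs <- list()
  for (p in kept) {
    pp <- process_profile(p, context, grid, coeffs)
    if (is.null(pp)) next
    env_ok <- is.finite(pp$chl) & is.finite(pp$cphyto) & is.finite(pp$par) &
      is.finite(pp$temp) & pp$z <= 210
    if (sum(env_ok) < 10) next
    env <- depth_environment(pp$z[env_ok], pp$chl[env_ok], pp$cphyto[env_ok],
                             pp$par[env_ok], pp$temp[env_ok])
    dl <- day_length(pp$lat, round(365 * (pp$time %% 1)) + 1)
    zm <- min(200, max(env$z))
    row <- list(id = pp$id, time = pp$time, lat = pp$lat, lon = pp$lon,
                mld = pp$mld)
    for (alg in algorithms) {
      val <- switch(alg,
        "cbpm-w" = cbpm_depth_resolved(env, "float_measured", coeffs,
                                       z_max = zm, daylength = dl)$result$npp,
        "vgpm-b" = vgpm_depth_resolved(env, "behrenfeld", coeffs, zm,
                                       dl)$result$npp,
        "vgpm-e" = vgpm_depth_resolved(env, "eppley", coeffs, zm,
                                       dl)$result$npp,
        stop("unknown float algorithm: ", alg))
      row[[paste0("npp_", gsub("-", "_", alg))]] <- val
    }
    rows[[length(rows) + 1L]] <- row
    procs[[length(procs) + 1L]] <- pp
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  attr(df, "profiles") <- procs
  df
}
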