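#' Depth-integrate phytoplankton carbon
#'
#' Trapezoidal integral of a phyc(z) profile from the surface to `depth`
#' (default 100 m): the shallowest level is extended to 0 m and the value at
#' `depth` is linearly interpolated when levels straddle it.
#'
#' @param phyc carbon concentration profile (mol C m-3).
#' @param z level depths (m), increasing.
#' @param depth integration depth (m).
#' @return column inventory (mol C m-2); `NA` when no levels lie above
#'   `depth`.
#' @export
integrate_phyc <- function(phyc, z, depth = 100) {
  ok <- is.finite(phyc) & is.finite(z)
  if (!any(ok & z <= depth)) return(NA_real_)
  zi <- z[ok]; vi <- phyc[ok]
  zq <- sort(unique(c(0, zi[zi <= depth], min(depth, max(zi)))))
  vq <- stats::approx(zi, vi, xout = zq, rule = 2)$y
  trapz_int(zq, vq)
}

#' Biomass-weighted growth limitation
#'
#' Combines per-functional-type limitation terms into a community value by
#' weighting with each type's share of total surface biomass:
#' sum(lim_i * b_i) / sum(b_i). The result is bounded by the smallest and
#' largest component limitation.
#'
#' @param lim per-PFT limitation values in \[0, 1\] (vector, or array with the
#'   PFT dimension last).
#' @param biomass per-PFT surface biomass (same shape), >= 0.
#' @return weighted limitation; `NA` where total biomass is zero.
#' @export
weight_limitation <- function(lim, biomass) {
  if (any(biomass < 0, na.rm = TRUE)) {
    stop("negative biomass", call. = FALSE)
  }
  if (is.null(dim(lim))) {
    tot <- sum(biomass)
    if (!is.finite(tot) || tot == 0) return(NA_real_)
    return(sum(lim * biomass) / tot)
  }
  nd <- length(dim(lim))
  tot <- apply(biomass, seq_len(nd - 1), sum)
  out <- apply(lim * biomass, seq_len(nd - 1), sum) / tot
  out[!is.finite(out)] <- NA_real_
  out
}

#' Conservative 1-degree regridding of a rectilinear field
#'
#' Area-weighted conservative binning from a rectilinear native grid to a
#' regular 1-degree grid: each target cell's value is the overlap-area
#' weighted mean of the native cells it intersects, with spherical weights
#' (overlap in longitude times overlap in sin latitude). Target cells not
#' fully covered by the native domain are masked, so the area-weighted
#' domain mean is preserved.
#'
#' @param field matrix (lon, lat) on the native grid.
#' @param lon_bnds,lat_bnds native cell boundary vectors (length n+1,
#'   increasing).
#' @param res target resolution in degrees (default 1).
#' @return list with `field` (matrix on the target grid), `lon`, `lat`
#'   (target centres), `lon_bnds`, `lat_bnds`.
#' @export
regrid_1deg <- function(field, lon_bnds, lat_bnds, res = 1) {
  if (is.null(dim(field)) ||
      nrow(field) != length(lon_bnds) - 1L ||
      ncol(field) != length(lat_bnds) - 1L) {
    stop("field does not match the rectilinear cell bounds; curvilinear ",
         "grids are not supported", call. = FALSE)
  }
  t_lon <- seq(floor(min(lon_bnds)), ceiling(max(lon_bnds)), by = res)
  t_lat <- seq(floor(min(lat_bnds)), ceiling(max(lat_bnds)), by = res)
  # overlap matrices: native cell x target cell
  ov <- function(src_bnds, tgt_bnds, weight_fun = identity) {
    ns <- length(src_bnds) - 1L; nt <- length(tgt_bnds) - 1L
    m <- matrix(0, ns, nt)
    for (i in seq_len(ns)) {
      lo <- pmax(src_bnds[i], tgt_bnds[-length(tgt_bnds)])
      hi <- pmin(src_bnds[i + 1], tgt_bnds[-1])
      m[i, ] <- pmax(weight_fun(hi) - weight_fun(lo), 0) *
        (hi > lo)
    }
    m
  }
  w_lon <- ov(lon_bnds, t_lon)                      # degrees overlap
  w_lat <- ov(lat_bnds, t_lat, function(x) sin(x * pi / 180))
  num <- t(w_lon) %*% ifelse(is.finite(field), field, 0) %*% w_lat
  den <- t(w_lon) %*% (is.finite(field) * 1) %*% w_lat
  # full-coverage test against the target cell's own spherical area
  full <- outer(diff(t_lon), diff(sin(t_lat * pi / 180)))
  out <- num / den
  out[den < full * (1 - 1e-9)] <- NA_real_
  list(field = out,
       lon = (t_lon[-length(t_lon)] + t_lon[-1]) / 2,
       lat = (t_lat[-length(t_lat)] + t_lat[-1]) / 2,
       lon_bnds = t_lon, lat_bnds = t_lat)
}

#' intpp unit conversion
#'
#' CMIP archives intpp in mol C m-2 s-1 while day-based analyses use mol C
#' m-2 day-1; conversion is by the declared unit attribute.
#' @param intpp array of values.
#' @param units declared units string.
#' @return values in mol C m-2 day-1.
#' @export
intpp_to_per_day <- function(intpp, units = attr(intpp, "units") %||%
                               "mol m-2 d-1") {
  if (grepl("s-1|s\\^-1|/s", units)) {
    out <- intpp * 86400
  } else {
    out <- intpp
  }
  attr(out, "units") <- "mol m-2 d-1"
  out
}

period_mean <- function(arr, years, months, sel_years, summer_only = FALSE) {
  if (summer_only) {
    # DJF convention: December belongs to the following year's summer
    season_year <- years + (months == 12)
    keep <- season_year %in% sel_years & months %in% c(12, 1, 2)
  } else {
    keep <- years %in% sel_years
  }
  if (!any(keep)) stop("no months in the requested period", call. = FALSE)
  # check coverage
  need <- if (summer_only) 3 * length(sel_years) else 12 * length(sel_years)
  have <- sum(keep)
  if (have < need - (if (summer_only) 3 else 12)) {
    stop(sprintf("incomplete period coverage: %d of %d months", have, need),
         call. = FALSE)
  }
  apply(arr[, , keep, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
}

#' Scenario-minus-historical change fields
#'
#' Per-cell differences Delta = mean(future period) - mean(historical
#' period) for NPP, depth-integrated phytoplankton carbon, and the
#' biomass-weighted Fe and light limitation terms, on the common 1-degree
#' grid. With `summer_only` the means use austral summer (DJF, December
#' assigned to the following year) months only.
#'
#' @param hist,future `esm_member` objects (see [gen_esm_ensemble()]) for
#'   the historical and scenario runs of the same model.
#' @param hist_period,future_period year ranges to average (defaults
#'   1995-2014 and 2081-2100).
#' @param summer_only restrict to DJF.
#' @param regrid regrid the deltas to 1 degree (default TRUE).
#' @return list of class `delta_fields` with matrices `dnpp` (mol C m-2
#'   day-1), `dcphyto` (mol C m-2), `dlimfe`, `dlimirr`, plus `lon`, `lat`,
#'   `areas` and period metadata.
#' @export
delta_fields <- function(hist, future, hist_period = 1995:2014,
                         future_period = 2081:2100, summer_only = FALSE,
                         regrid = TRUE) {
  stopifnot(inherits(hist, "esm_member"), inherits(future, "esm_member"))
  one <- function(member, per) {
    yr <- member$years; mo <- member$months
    npp <- period_mean(intpp_to_per_day(member$intpp, member$intpp_units),
                       yr, mo, per, summer_only)
    shape_int <- trapz_int(member$phyc_shape$z, member$phyc_shape$f)
    cph <- period_mean(member$phyc_surface, yr, mo, per, summer_only) *
      shape_int
    wlim <- function(lim4) {
      # biomass-weighted over the PFT dimension (3rd), per time, then period
      nt <- dim(lim4)[4]
      out <- array(NA_real_, c(dim(lim4)[1], dim(lim4)[2], nt))
      for (k in seq_len(nt)) {
        out[, , k] <- weight_limitation(
          aperm(lim4[, , , k, drop = FALSE], c(1, 2, 3, 4))[, , , 1],
          member$pft_biomass)
      }
      period_mean(out, yr, mo, per, summer_only)
    }
    list(npp = npp, cph = cph, limfe = wlim(member$limfe),
         limirr = wlim(member$limirr))
  }
  h <- one(hist, hist_period)
  f <- one(future, future_period)
  d <- list(dnpp = f$npp - h$npp, dcphyto = f$cph - h$cph,
            dlimfe = f$limfe - h$limfe, dlimirr = f$limirr - h$limirr)
  lon <- hist$lon; lat <- hist$lat
  if (regrid) {
    rg <- lapply(d, function(m) regrid_1deg(m, hist$lon_bnds, hist$lat_bnds))
    lon <- rg[[1]]$lon; lat <- rg[[1]]$lat
    lat_bnds <- rg[[1]]$lat_bnds
    d <- lapply(rg, `[[`, "field")
  } else {
    lat_bnds <- hist$lat_bnds
  }
  areas <- area_weights(lat_bnds, abs(diff(lon[1:2])))$area_m2
  structure(c(d, list(lon = lon, lat = lat, areas = areas,
                      hist_period = range(hist_period),
                      future_period = range(future_period),
                      summer_only = summer_only)),
            class = "delta_fields")
}

#' Regression of NPP change on a driver change
#'
#' Ordinary least squares of Delta NPP on a Delta driver across grid cells
#' (optionally area-weighted), the spatial driver-attribution regression.
#'
#' @param delta a [delta_fields()] object.
#' @param driver one of `"dcphyto"`, `"dlimfe"`, `"dlimirr"`.
#' @param area_weighted weight cells by pixel area.
#' @return list of class `driver_regression` with `driver`, `slope`, `r`,
#'   `n`; slope/r are `NA` (flagged) when the driver is constant.
#' @export
driver_regression <- function(delta, driver = c("dcphyto", "dlimfe",
                                                "dlimirr"),
                              area_weighted = FALSE) {
  driver <- match.arg(driver)
  x <- as.numeric(delta[[driver]])
  y <- as.numeric(delta$dnpp)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("fewer than 10 valid cells", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(structure(list(driver = driver, slope = NA_real_, r = NA_real_,
                          n = length(x), flag = "constant driver"),
                     class = "driver_regression"))
  }
  w <- if (area_weighted) {
    aw <- matrix(delta$areas, nrow = length(delta$lon),
                 ncol = length(delta$lat), byrow = TRUE)
    as.numeric(aw)[ok]
  } else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  r <- stats::cov.wt(cbind(x, y), wt = w, cor = TRUE)$cor[1, 2]
  structure(list(driver = driver, slope = unname(stats::coef(fit)[2]),
                 r = r, n = length(x)),
            class = "driver_regression")
}

#' Annual regional NPP series of an ESM member
#'
#' Calendar-year means of intpp (converted to mg C m-2 day-1) integrated
#' with spherical pixel areas to Pg C yr-1.
#'
#' @param member an `esm_member`.
#' @param years optional year subset.
#' @return data.frame with `year`, `npp_pg`.
#' @export
esm_regional_series <- function(member, years = NULL) {
  intpp <- intpp_to_per_day(member$intpp, member$intpp_units)
  mg <- intpp * C_MOLAR_MASS * 1000          # mol C m-2 d-1 -> mg C m-2 d-1
  yrs <- sort(unique(member$years))
  if (!is.null(years)) yrs <- intersect(yrs, years)
  areas <- area_weights(member$lat_bnds, abs(diff(member$lon[1:2])))$area_m2
  npp <- vapply(yrs, function(y) {
    fld <- apply(mg[, , member$years == y, drop = FALSE], c(1, 2), mean)
    regional_integral(fld, areas)
  }, numeric(1))
  data.frame(year = yrs, npp_pg = npp)
}

#' Cumulative regional NPP change relative to a baseline period
#'
#' Each year's regional NPP minus the baseline-period mean, per member, with
#' the equal-weight multi-model mean and standard deviation across members.
#'
#' @param series_list list of data.frames (`year`, `npp_pg`), one per
#'   ensemble member.
#' @param baseline baseline years (default 1995:2014); every member must
#'   cover them.
#' @return list with `per_member` (data.frame year x member change, Pg C),
#'   `mean`, `sd` (vectors by year), `years`.
#' @export
cumulative_npp_change <- function(series_list, baseline = 1995:2014) {
  changes <- lapply(series_list, function(s) {
    if (!all(baseline %in% s$year)) {
      stop("baseline period not fully covered", call. = FALSE)
    }
    base <- mean(s$npp_pg[s$year %in% baseline])
    data.frame(year = s$year, change = s$npp_pg - base)
  })
  years <- sort(unique(unlist(lapply(changes, `[[`, "year"))))
  mat <- vapply(changes, function(ch) {
    ch$change[match(years, ch$year)]
  }, numeric(length(years)))
  mat <- matrix(mat, nrow = length(years))
  list(per_member = data.frame(year = years, mat),
       mean = rowMeans(mat, na.rm = TRUE),
       sd = apply(mat, 1, stats::sd, na.rm = TRUE),
       years = years)
}

#' Regional NPP trend of an ESM member
#'
#' Delegates to the same normality-routed trend machinery used for remote
#' sensing: annual regional NPP (Pg C) over the requested period, then
#' [pixel_trend()].
#'
#' @param member an `esm_member` covering the period.
#' @param period `"contemporary"` (1998-2024), `"future"` (2051-2100), or a
#'   numeric year vector.
#' @return a `trend_estimate`; slope in Pg C yr-1 per year (multiply by 1e6
#'   for Gg C yr-2, see [convert_trend_units()]).
#' @export
esm_trends <- function(member, period = c("contemporary", "future")) {
  yrs <- if (is.numeric(period)) period else
    switch(match.arg(period), contemporary = 1998:2024, future = 2051:2100)
  s <- esm_regional_series(member, yrs)
  if (!all(yrs %in% s$year)) {
    stop("member does not cover the requested period", call. = FALSE)
  }
  pixel_trend(s$npp_pg, s$year)
}

#' Concatenate a historical and a scenario member in time
#' @param hist,scen `esm_member` objects on the same grid.
#' @return combined `esm_member`.
#' @export
concat_members <- function(hist, scen) {
  stopifnot(identical(hist$lon, scen$lon), identical(hist$lat, scen$lat))
  out <- hist
  out$scenario <- paste(hist$scenario, scen$scenario, sep = "+")
  out$years <- c(hist$years, scen$years)
  out$months <- c(hist$months, scen$months)
  bind3 <- function(a, b) {
    arr <- array(c(a, b), dim = c(dim(a)[1], dim(a)[2],
                                  dim(a)[3] + dim(b)[3]))
    attr(arr, "units") <- attr(a, "units")
    arr
  }
  out$intpp <- bind3(hist$intpp, scen$intpp)
  out$phyc_surface <- bind3(hist$phyc_surface, scen$phyc_surface)
  abind4 <- function(a, b) array(c(a, b),
                                 dim = c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
  out$limfe <- abind4(hist$limfe, scen$limfe)
  out$limirr <- abind4(hist$limirr, scen$limirr)
  out
}
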