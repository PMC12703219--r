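#' Configuration for the synthetic data generators
#'
#' One nested configuration object drives all three generators (gridded
#' ocean-colour fields, float profile sets, ESM-like ensembles). Defaults
#' emulate the study conditions: a Southern Ocean domain south of 40 S, an
#' 8-day ocean-colour record over 1998-2024, a 2014-2024 float archive, and
#' a historical + three-scenario model ensemble through 2100.
#'
#' @param lat_range latitude range (degrees), default c(-78, -40).
#' @param lon_range longitude range (degrees).
#' @param grid_res grid resolution (degrees), > 0.
#' @param years ocean-colour years.
#' @param cadence `"8day"` or `"monthly"`.
#' @param vars per-variable specs: named list of lists with `baseline`,
#'   `seasonal` (amplitude), `trend` (per year), `rho` (AR(1) coefficient,
#'   0 <= rho < 1), `sd` (innovation sd), `min` (physical floor, optional).
#'   Defaults cover the 11 ocean-colour/physics variables plus a synthetic
#'   `npp` field with a declining trend.
#' @param float float-archive parameters: `count`, `profiles_per_float`,
#'   `years`, `quench_factor` (daytime fluorescence multiplied by this above
#'   the quench depth; in (0, 1\]), `spike_rate` (spikes per profile),
#'   `negative_rate`, `bad_flag_frac`, `npp_rel_trend` (fractional biomass
#'   change per year), `mld` (true mixed-layer depth, m), `dz_range` (raw
#'   sampling spacing, m).
#' @param esm model-ensemble parameters: `n_models`, `n_pft`, `alpha`,
#'   `beta`, `gamma` (driver coefficients of the NPP change construction),
#'   `noise_sd` (cell-level sd of the NPP change residual), `ar_sd` (monthly
#'   noise), `scenarios`, `scenario_mult` (trend multiplier per scenario),
#'   `cumulative_change_pg` (prescribed regional change by 2081-2100, Pg C,
#'   per scenario), `hist_years`, `scen_years`, `grid_res` (native lon/lat
#'   resolution, non-1-degree by default), `delta_sd` (spatial sd of each
#'   imposed driver-change pattern).
#' @param seed default seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(lat_range = c(-78, -40), lon_range = c(0, 20),
                             grid_res = 1, years = 1998:2024,
                             cadence = "8day",
                             vars = NULL, float = NULL, esm = NULL,
                             seed = 1L) {
  default_vars <- list(
    chl   = list(baseline = 0.4, seasonal = 0.2, trend = 0.002, rho = 0.3,
                 sd = 0.04, min = 0.001),
    bbp   = list(baseline = 0.002, seasonal = 5e-4, trend = 0, rho = 0.3,
                 sd = 1e-4, min = 1e-5),
    aph   = list(baseline = 0.02, seasonal = 0.005, trend = 0, rho = 0.3,
                 sd = 0.002, min = 1e-4),
    adg   = list(baseline = 0.01, seasonal = 0.002, trend = 0, rho = 0.3,
                 sd = 0.001, min = 1e-4),
    kd490 = list(baseline = 0.08, seasonal = 0.01, trend = 0, rho = 0.3,
                 sd = 0.005, min = 0.01),
    eta   = list(baseline = 1.0, seasonal = 0.1, trend = 0, rho = 0.3,
                 sd = 0.05, min = 0),
    par   = list(baseline = 30, seasonal = 20, trend = 0, rho = 0.3,
                 sd = 2, min = 0),
    sst   = list(baseline = 4, seasonal = 2, trend = 0.02, rho = 0.3,
                 sd = 0.3, min = -2),
    mld   = list(baseline = 60, seasonal = -30, trend = 0, rho = 0.3,
                 sd = 5, min = 5),
    zno3  = list(baseline = 60, seasonal = 10, trend = 0, rho = 0.3,
                 sd = 5, min = 5),
    sss   = list(baseline = 34, seasonal = 0.2, trend = 0, rho = 0.3,
                 sd = 0.05, min = 20),
    npp   = list(baseline = 300, seasonal = 150, trend = -1.5, rho = 0.3,
                 sd = 30, min = 0)
  )
  if (!is.null(vars)) {
    for (nm in names(vars)) {
      if (nm %in% names(default_vars)) {
        default_vars[[nm]][names(vars[[nm]])] <- vars[[nm]]
      } else default_vars[[nm]] <- vars[[nm]]
    }
  }
  default_float <- list(count = 12, profiles_per_float = 10,
                        years = c(2014, 2024), quench_factor = 0.6,
                        spike_rate = 1, negative_rate = 0.01,
                        bad_flag_frac = 0.05, npp_rel_trend = -0.05,
                        mld = 55, dz_range = c(2, 8), max_depth = 1000,
                        day_frac = 0.5)
  if (!is.null(float)) default_float[names(float)] <- float
  default_esm <- list(n_models = 5, n_pft = 3,
                      alpha = 0.02, beta = 0.01, gamma = 0.015,
                      noise_sd = 0, ar_sd = 5e-4,
                      scenarios = c("ssp245", "ssp370", "ssp585"),
                      scenario_mult = c(ssp245 = 0.8, ssp370 = 1,
                                        ssp585 = 1.2),
                      cumulative_change_pg = c(ssp245 = 0.3, ssp370 = 0.5,
                                               ssp585 = 0.5),
                      hist_years = 1995:2014, scen_years = 2015:2100,
                      grid_res = c(1.5, 1.25), delta_sd = 0.1)
  if (!is.null(esm)) default_esm[names(esm)] <- esm
  cfg <- list(lat_range = lat_range, lon_range = lon_range,
              grid_res = grid_res, years = years, cadence = cadence,
              vars = default_vars, float = default_float, esm = default_esm,
              seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Validate a synthetic configuration
#' @param cfg a configuration list.
#' @return `TRUE` invisibly; stops with a message on invalid values.
#' @export
validate_synthetic_config <- function(cfg) {
  if (!is.finite(cfg$grid_res) || cfg$grid_res <= 0) {
    stop("grid_res must be > 0", call. = FALSE)
  }
  for (nm in names(cfg$vars)) {
    v <- cfg$vars[[nm]]
    if (!all(is.finite(unlist(v[c("baseline", "seasonal", "trend", "rho",
                                  "sd")])))) {
      stop(sprintf("non-finite config for variable '%s'", nm), call. = FALSE)
    }
    if (v$rho < 0 || v$rho >= 1) {
      stop(sprintf("AR(1) rho for '%s' must be in [0, 1)", nm),
           call. = FALSE)
    }
    if (v$sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  }
  fl <- cfg$float
  if (fl$quench_factor <= 0 || fl$quench_factor > 1) {
    stop("quench_factor must be in (0, 1]", call. = FALSE)
  }
  if (fl$spike_rate < 0 || fl$negative_rate < 0 || fl$bad_flag_frac < 0) {
    stop("artifact rates must be >= 0", call. = FALSE)
  }
  if (cfg$esm$n_pft < 1) stop("PFT count must be >= 1", call. = FALSE)
  if (!all(is.finite(c(cfg$esm$alpha, cfg$esm$beta, cfg$esm$gamma)))) {
    stop("driver coefficients must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

# AR(1) series with stationary start; columns = independent series
ar1_noise <- function(n, rho, sd, ncol = 1) {
  if (sd == 0) return(matrix(0, n, ncol))
  eps <- matrix(stats::rnorm(n * ncol, 0, sd), n, ncol)
  if (rho == 0) return(eps)
  out <- eps
  out[1, ] <- eps[1, ] / sqrt(1 - rho^2)
  for (i in 2:n) out[i, ] <- rho * out[i - 1, ] + eps[i, ]
  out
}

#' Generate gridded ocean-colour-like fields with known trends
#'
#' Each variable's pixel series is baseline + trend * (t - t0) + seasonal *
#' sin(2 pi doy / 365 + phase) + AR(1) noise, clipped at its physical floor.
#' The austral seasonal phase peaks in January. The returned truth record
#' carries the imposed per-variable trends.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param vars subset of variable names to generate (default: all
#'   configured).
#' @return list with `grid` (class `rs_grid`: `lon`, `lat`, `time` decimal
#'   years, `doy`, `vars` list of (lon, lat, time) arrays) and `truth`
#'   (class `truth_record`: imposed trends, regional NPP trend in Pg C yr-1
#'   per year where `npp` is generated).
#' @export
gen_rs_fields <- function(cfg = synthetic_config(), seed = cfg$seed,
                          vars = names(cfg$vars)) {
  validate_synthetic_config(cfg)
  set.seed(seed)
  lat <- seq(cfg$lat_range[1] + cfg$grid_res / 2, cfg$lat_range[2],
             by = cfg$grid_res)
  lon <- seq(cfg$lon_range[1] + cfg$grid_res / 2, cfg$lon_range[2],
             by = cfg$grid_res)
  step_days <- if (cfg$cadence == "8day") 8 else 365 / 12
  doy_steps <- seq(1, 365, by = step_days)
  doy <- rep(doy_steps, times = length(cfg$years))
  year <- rep(cfg$years, each = length(doy_steps))
  time <- decimal_year(year, doy)
  t_rel <- time - time[1]
  nt <- length(time); np <- length(lon) * length(lat)
  out_vars <- list()
  for (nm in vars) {
    v <- cfg$vars[[nm]]
    seas <- v$seasonal * sin(2 * pi * doy / 365 + pi / 2)  # austral peak ~Jan
    base <- v$baseline + v$trend * t_rel + seas
    noise <- ar1_noise(nt, v$rho, v$sd, np)
    m <- matrix(base, nt, np) + noise
    if (!is.null(v$min)) m <- pmax(m, v$min)
    out_vars[[nm]] <- array(t(m), dim = c(length(lon), length(lat), nt))
  }
  grid <- structure(list(lon = lon, lat = lat, time = time, doy = doy,
                         vars = out_vars),
                    class = "rs_grid")
  trends <- vapply(cfg$vars[vars], `[[`, numeric(1), "trend")
  truth <- structure(list(trends = trends), class = "truth_record")
  if ("npp" %in% vars) {
    edges <- c(lat - cfg$grid_res / 2, lat[length(lat)] + cfg$grid_res / 2)
    aw <- area_weights(edges, cfg$grid_res)
    fld <- matrix(trends[["npp"]], length(lon), length(lat))
    truth$regional_npp_trend_pg <- regional_integral(fld, aw$area_m2)
  }
  list(grid = grid, truth = truth)
}

# true chlorophyll profile: mixed-layer plateau + Gaussian deep maximum
true_chl_profile <- function(z, mld, chl0, deep_max_frac = 0.6,
                             deep_depth = NULL, deep_width = 15) {
  deep_depth <- deep_depth %||% (mld + 30)
  plateau <- ifelse(z <= mld, chl0, chl0 * exp(-(z - mld) / 40))
  plateau + deep_max_frac * chl0 * exp(-((z - deep_depth) / deep_width)^2)
}

#' Generate a synthetic float profile set with instrument artifacts
#'
#' Profiles carry a two-layer temperature/salinity structure with a known
#' mixed-layer depth, a chlorophyll profile with a mixed-layer plateau and a
#' Gaussian deep maximum, proportional phytoplankton carbon, and exponential
#' PAR. Raw fluorescence is 2 x true chlorophyll (the slope-factor
#' convention); raw backscattering encodes true carbon through the 470 nm
#' spectral translation and slope factor 12128 plus a non-algal deep
#' baseline. Artifacts: daytime fluorescence multiplied by `quench_factor`
#' above the quench depth (the shallower of half the mixed layer and 20 m),
#' isolated backscatter spikes, occasional negatives, and a configured
#' fraction of bad QC flags. A multiplicative biomass factor
#' (1 + npp_rel_trend * (t - t0)) imposes a known NPP trend.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `profiles` (raw profile list) and `truth` (per-profile
#'   artifact-free chl/cphyto on the raw depths, true MLD, quench depth,
#'   spike indices, biomass scale).
#' @export
gen_float_dataset <- function(cfg = synthetic_config(), seed = cfg$seed) {
  validate_synthetic_config(cfg)
  set.seed(seed)
  fl <- cfg$float
  if (fl$profiles_per_float == 0) {
    warning("profiles_per_float is 0: empty float set")
    return(list(profiles = list(), truth = structure(list(profiles = list()),
                                                     class = "truth_record")))
  }
  profiles <- list(); truths <- list()
  t0 <- fl$years[1]
  for (fi in seq_len(fl$count)) {
    f_lat <- stats::runif(1, cfg$lat_range[1] + 2, cfg$lat_range[2] - 2)
    f_lon <- stats::runif(1, cfg$lon_range[1], cfg$lon_range[2])
    times <- sort(stats::runif(fl$profiles_per_float, fl$years[1],
                               fl$years[2] + 1))
    for (pi in seq_len(fl$profiles_per_float)) {
      tm <- times[pi]
      z <- cumsum(stats::runif(400, fl$dz_range[1], fl$dz_range[2]))
      z <- z[z <= fl$max_depth]
      scale_f <- 1 + fl$npp_rel_trend * (tm - t0)
      chl0 <- 0.8 * scale_f
      mld <- fl$mld
      chl_true <- true_chl_profile(z, mld, chl0)
      cph_true <- 25 * scale_f *
        true_chl_profile(z, mld, 1, deep_max_frac = 0.4)
      temp <- ifelse(z <= mld, 5, 5 - 2.5 * (1 - exp(-(z - mld) / 50)))
      sal <- ifelse(z <= mld, 33.8, 33.8 + 0.4 * (1 - exp(-(z - mld) / 80)))
      par0 <- 35
      par <- par0 * exp(-0.08 * z)
      is_day <- stats::runif(1) < fl$day_frac
      # backscatter encodes cphyto through the processing chain conventions
      b_base <- 4e-4
      bbp <- cph_true / 12128 / bbp_spectral(1, 700, 470, 0.78) + b_base
      fchl <- 2 * chl_true
      # --- artifacts ---
      quench_depth <- min(0.5 * mld, 20)
      if (is_day && fl$quench_factor < 1) {
        fchl[z < quench_depth] <- fchl[z < quench_depth] * fl$quench_factor
      }
      n_spike <- round(fl$spike_rate)
      spike_idx <- if (n_spike > 0 && length(z) > 2) {
        sort(sample(seq_along(z), min(n_spike, length(z))))
      } else integer(0)
      bbp[spike_idx] <- bbp[spike_idx] * stats::runif(length(spike_idx), 5, 20)
      neg_idx <- which(stats::runif(length(z)) < fl$negative_rate)
      bbp[neg_idx] <- -abs(bbp[neg_idx]) * 0.1
      qc_of <- function(n) {
        flags <- sample(c(1, 2, 5, 8), n, replace = TRUE,
                        prob = c(0.85, 0.1, 0.03, 0.02))
        bad <- stats::runif(n) < fl$bad_flag_frac
        flags[bad] <- sample(c(3, 4), sum(bad), replace = TRUE)
        flags
      }
      nz <- length(z)
      prof <- list(id = sprintf("F%02d", fi), time = tm, lat = f_lat,
                   lon = f_lon, is_day = is_day, z = z, temp = temp,
                   sal = sal, fchl = fchl, bbp700 = bbp, par = par,
                   qc = list(temp = qc_of(nz), sal = qc_of(nz),
                             fchl = qc_of(nz), bbp700 = qc_of(nz),
                             par = qc_of(nz)))
      profiles[[length(profiles) + 1L]] <- prof
      truths[[length(truths) + 1L]] <- list(
        id = prof$id, time = tm, lat = f_lat, is_day = is_day, z = z,
        chl = chl_true, cphyto = cph_true, par = par, temp = temp,
        mld = mld, quench_depth = quench_depth, spike_idx = spike_idx,
        scale = scale_f)
    }
  }
  truth <- structure(list(profiles = truths, mld = fl$mld,
                          npp_rel_trend = fl$npp_rel_trend),
                     class = "truth_record")
  list(profiles = profiles, truth = truth)
}

# orthogonalise columns of m (centered), preserving each column's sd target
orthogonal_patterns <- function(n, k, sd_target) {
  m <- matrix(stats::rnorm(n * k), n, k)
  m <- scale(m, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))
  q <- scale(q, center = TRUE, scale = TRUE)
  sweep(q, 2, sd_target, `*`)
}

#' Generate a CMIP6-like model ensemble with a prescribed NPP change
#' construction
#'
#' Monthly historical and scenario members on a non-1-degree rectilinear
#' grid. Each model's change in NPP between the historical (1995-2014) and
#' future (2081-2100) periods is constructed per cell as alpha * dCphyto +
#' beta * dLimFe + gamma * dLimIrr + Gaussian noise, where the three driver
#' change patterns are mutually orthogonal random fields ramped linearly in
#' time between the two period midpoints; a spatially uniform term adjusts
#' the regional change to the prescribed cumulative value per scenario.
#' Per-PFT surface biomass fractions sum to one; limitation terms are
#' clipped to \[0, 1\].
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `members` (list per model of list(historical = member,
#'   <scenario> = member, ...)) and `truth` (alpha/beta/gamma, per-model
#'   driver patterns, prescribed cumulative changes). Each member is an
#'   `esm_member`: lon/lat centres and bounds, `years`, `months`, `intpp`
#'   (mol C m-2 day-1), `phyc_surface` (mol C m-3), `phyc_shape` (separable
#'   depth structure), `pft_biomass` fractions, `limfe`/`limirr`
#'   (lon, lat, pft, time).
#' @export
gen_esm_ensemble <- function(cfg = synthetic_config(), seed = cfg$seed) {
  validate_synthetic_config(cfg)
  set.seed(seed)
  es <- cfg$esm
  lon_bnds <- seq(cfg$lon_range[1], cfg$lon_range[2], by = es$grid_res[1])
  lat_bnds <- seq(cfg$lat_range[1], cfg$lat_range[2], by = es$grid_res[2])
  lon <- (lon_bnds[-length(lon_bnds)] + lon_bnds[-1]) / 2
  lat <- (lat_bnds[-length(lat_bnds)] + lat_bnds[-1]) / 2
  nx <- length(lon); ny <- length(lat); nc <- nx * ny
  z_shape <- seq(0, 150, by = 10)
  f_shape <- exp(-z_shape / 80)
  shape_int <- trapz_int(z_shape, f_shape)
  areas <- area_weights(lat_bnds, es$grid_res[1])$area_m2
  area_m <- matrix(areas, nx, ny, byrow = TRUE)
  hist_mid <- mean(range(es$hist_years)) + 0.5
  fut_mid <- mean(c(2081, 2100)) + 0.5
  month_time <- function(years) {
    yr <- rep(years, each = 12)
    mo <- rep(1:12, times = length(years))
    list(years = yr, months = mo, dec = yr + (mo - 0.5) / 12)
  }
  members <- list(); truth_models <- list()
  for (mi in seq_len(es$n_models)) {
    base_npp <- matrix(0.02 + 0.005 * stats::rnorm(nc), nx, ny)   # mol C m-2 d-1
    base_npp <- pmax(base_npp, 0.005)
    base_cph_int <- matrix(pmax(0.8 + 0.2 * stats::rnorm(nc), 0.2), nx, ny)
    base_limfe <- matrix(stats::runif(nc, 0.3, 0.6), nx, ny)
    base_limirr <- matrix(stats::runif(nc, 0.4, 0.7), nx, ny)
    pat <- orthogonal_patterns(nc, 3, c(es$delta_sd * 2, es$delta_sd * 0.5,
                                        es$delta_sd * 0.5))
    d_cph <- matrix(pat[, 1], nx, ny)       # mol C m-2
    d_fe <- matrix(pat[, 2], nx, ny)        # dimensionless
    d_irr <- matrix(pat[, 3], nx, ny)
    eps <- matrix(stats::rnorm(nc, 0, es$noise_sd), nx, ny)
    frac <- stats::runif(es$n_pft); frac <- frac / sum(frac)
    pft_b <- array(rep(frac, each = nc), c(nx, ny, es$n_pft))
    truth_models[[mi]] <- list(d_cph = d_cph, d_fe = d_fe, d_irr = d_irr,
                               eps = eps)
    build <- function(scenario, years, mult, uniform_offset) {
      tt <- month_time(years)
      nt <- length(tt$dec)
      ramp <- (tt$dec - hist_mid) / (fut_mid - hist_mid) * mult
      seas <- 0.3 * sin(2 * pi * (tt$months - 1) / 12 + pi / 2)
      dnpp_cell <- es$alpha * d_cph + es$beta * d_fe + es$gamma * d_irr +
        eps + uniform_offset
      arr3 <- function(base, delta, rel_seas = 0) {
        a <- array(0, c(nx, ny, nt))
        for (k in seq_len(nt)) {
          a[, , k] <- base + delta * ramp[k] + base * rel_seas * seas[k]
        }
        a
      }
      intpp <- arr3(base_npp, dnpp_cell, rel_seas = 1)
      if (es$ar_sd > 0) {
        noise <- ar1_noise(nt, 0.3, es$ar_sd, nc)
        intpp <- intpp + array(t(noise), c(nx, ny, nt))
      }
      intpp <- pmax(intpp, 0)
      attr(intpp, "units") <- "mol m-2 d-1"
      cph_int <- arr3(base_cph_int, d_cph)
      phyc_surface <- cph_int / shape_int
      lim4 <- function(base, delta) {
        a <- array(0, c(nx, ny, es$n_pft, nt))
        for (k in seq_len(nt)) {
          sl <- clamp(base + delta * ramp[k], 0, 1)
          for (p in seq_len(es$n_pft)) a[, , p, k] <- sl
        }
        a
      }
      limfe <- lim4(base_limfe, d_fe)
      limirr <- lim4(base_limirr, d_irr)
      structure(list(model = sprintf("model%02d", mi), scenario = scenario,
                     lon = lon, lat = lat, lon_bnds = lon_bnds,
                     lat_bnds = lat_bnds, years = tt$years,
                     months = tt$months, intpp = intpp,
                     intpp_units = "mol m-2 d-1",
                     phyc_surface = phyc_surface,
                     phyc_shape = list(z = z_shape, f = f_shape),
                     pft_biomass = pft_b, limfe = limfe, limirr = limirr),
                class = "esm_member")
    }
    mod <- list(historical = build("historical", es$hist_years, 1, 0))
    for (sc in es$scenarios) {
      mult <- unname(es$scenario_mult[sc])
      # uniform offset so the prescribed regional cumulative change holds:
      # prescribed = sum((dnpp_struct + u) * area) * 365 * 12.011e3 / 1e18
      dnpp_struct <- (es$alpha * d_cph + es$beta * d_fe +
                        es$gamma * d_irr + eps) * mult
      struct_pg <- sum(dnpp_struct * area_m) * 365 * C_MOLAR_MASS * 1000 /
        1e18
      target <- unname(es$cumulative_change_pg[sc])
      u <- (target - struct_pg) * 1e18 /
        (365 * C_MOLAR_MASS * 1000 * sum(area_m)) / mult
      mod[[sc]] <- build(sc, es$scen_years, mult, u)
    }
    members[[sprintf("model%02d", mi)]] <- mod
  }
  truth <- structure(list(alpha = es$alpha, beta = es$beta, gamma = es$gamma,
                          noise_sd = es$noise_sd,
                          cumulative_change_pg = es$cumulative_change_pg,
                          scenario_mult = es$scenario_mult,
                          models = truth_models),
                     class = "truth_record")
  list(members = members, truth = truth)
}
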