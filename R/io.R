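#' Write a gridded dataset to plain-text files
#'
#' Serialises an `rs_grid` as one CSV per variable (rows = time steps,
#' columns = pixels in lon-major order) plus a JSON sidecar holding the
#' coordinates, units and missing-value convention. The round trip through
#' [read_grid()] restores values, coordinates and missing masks exactly.
#'
#' @param grid an `rs_grid` (see [gen_rs_fields()]).
#' @param path directory to create/write into.
#' @param units optional named character vector of unit strings per variable.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, units = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(lon = grid$lon, lat = grid$lat, time = grid$time,
               doy = grid$doy, variables = names(grid$vars),
               units = as.list(units %||% character(0)),
               missing_value = "NA")
  jsonlite::write_json(meta, file.path(path, "coords.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(grid$vars)) {
    arr <- grid$vars[[nm]]
    # rows = time, columns = pixel (lon varying fastest)
    m <- t(matrix(arr, ncol = dim(arr)[3]))
    utils::write.csv(m, file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a gridded dataset written by [write_grid()]
#'
#' @param path directory containing `coords.json` and per-variable CSVs.
#' @return an `rs_grid`. Variables whose declared units are per second are
#'   flagged for automatic conversion with attribute `"convert_per_day"`.
#' @export
read_grid <- function(path) {
  meta_file <- file.path(path, "coords.json")
  if (!file.exists(meta_file)) {
    stop("schema error: missing coords.json sidecar", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (need in c("lon", "lat", "time")) {
    if (is.null(meta[[need]])) {
      stop(sprintf("schema error: missing coordinate variable '%s'", need),
           call. = FALSE)
    }
  }
  vars <- list()
  for (nm in meta$variables) {
    m <- as.matrix(utils::read.csv(file.path(path, paste0(nm, ".csv"))))
    # rows = time, columns = pixel (lon fastest): invert the write layout
    arr <- aperm(array(as.numeric(m),
                       dim = c(length(meta$time), length(meta$lon),
                               length(meta$lat))),
                 c(2, 3, 1))
    u <- meta$units[[nm]]
    if (!is.null(u) && grepl("s-1|s\\^-1|/s", u)) {
      attr(arr, "convert_per_day") <- TRUE
      attr(arr, "units") <- u
    }
    vars[[nm]] <- arr
  }
  structure(list(lon = meta$lon, lat = meta$lat, time = meta$time,
                 doy = meta$doy, vars = vars),
            class = "rs_grid")
}

#' Write a float profile set as a flat CSV + JSON truth sidecar
#'
#' One long-format CSV: a row per (profile, depth) with the raw variables
#' and QC flags; profile metadata repeated per row.
#'
#' @param profiles list of raw profiles.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_profiles <- function(profiles, file) {
  rows <- lapply(profiles, function(p) {
    data.frame(id = p$id, time = p$time, lat = p$lat, lon = p$lon,
               is_day = p$is_day, z = p$z, temp = p$temp, sal = p$sal,
               fchl = p$fchl, bbp700 = p$bbp700, par = p$par,
               qc_temp = p$qc$temp, qc_sal = p$qc$sal, qc_fchl = p$qc$fchl,
               qc_bbp700 = p$qc$bbp700, qc_par = p$qc$par)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read a float profile set from the flat CSV written by [write_profiles()]
#' @param file CSV path.
#' @return list of raw profiles.
#' @export
read_profiles <- function(file) {
  df <- utils::read.csv(file)
  split_keys <- interaction(df$id, df$time, drop = TRUE)
  lapply(split(df, split_keys), function(d) {
    list(id = d$id[1], time = d$time[1], lat = d$lat[1], lon = d$lon[1],
         is_day = as.logical(d$is_day[1]), z = d$z, temp = d$temp,
         sal = d$sal, fchl = d$fchl, bbp700 = d$bbp700, par = d$par,
         qc = list(temp = d$qc_temp, sal = d$qc_sal, fchl = d$qc_fchl,
                   bbp700 = d$qc_bbp700, par = d$qc_par))
  })
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the known schema before any stage runs:
#' unknown keys and unknown algorithm names are rejected.
#'
#' @param config named list; recognised keys: `region_lat` (boundary
#'   latitude, default -40), `algorithms` (subset of [npp_algorithms()]),
#'   `seed`, `out_dir`, `stages` (subset of c("simulate", "npp", "argo",
#'   "trends", "esm")), `synthetic` (overrides for [synthetic_config()]).
#' @return the completed config, invisibly; stops with a validation error
#'   otherwise.
#' @export
validate_pipeline_config <- function(config) {
  known <- c("region_lat", "algorithms", "seed", "out_dir", "stages",
             "synthetic")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("validation error: unknown config keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  config$region_lat <- config$region_lat %||% -40
  config$algorithms <- config$algorithms %||% npp_algorithms()
  bad <- setdiff(config$algorithms, npp_algorithms())
  if (length(bad)) {
    stop("validation error: unknown algorithm name: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("simulate", "npp", "argo", "trends",
                                        "esm")
  bad_st <- setdiff(config$stages, c("simulate", "npp", "argo", "trends",
                                     "esm"))
  if (length(bad_st)) {
    stop("validation error: unknown stage: ", paste(bad_st, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

#' Demonstration pipeline configuration
#'
#' A small, fast configuration exercising every stage: a 6 x 8 pixel
#' ocean-colour grid over 8 years, 30 float profiles, and a 2-model,
#' 1-scenario ensemble.
#' @param seed integer seed.
#' @return config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    region_lat = -40,
    algorithms = c("vgpm-e", "cbpm-b"),
    seed = as.integer(seed),
    stages = c("simulate", "npp", "argo", "trends", "esm"),
    synthetic = list(
      lat_range = c(-60, -44), lon_range = c(0, 6), grid_res = 1,
      years = 2005:2024,
      float = list(count = 6, profiles_per_float = 5),
      esm = list(n_models = 2, scenarios = "ssp370",
                 scen_years = 2015:2100,
                 grid_res = c(1.5, 1.25))
    )
  )
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Chains the stages simulate -> npp -> argo -> trends -> esm on generated
#' data, deterministically for a given seed, and returns a run manifest
#' recording configuration and coefficient hashes, per-stage record counts
#' and timings, and headline results.
#'
#' @param config a configuration accepted by [validate_pipeline_config()].
#' @param coeffs an [npp_coefficients()] set.
#' @return a list of class `run_manifest`: `config_hash`, `coeffs_hash`,
#'   `seed`, `stages` (per-stage record counts), `results` (regional trend
#'   table, float trends, ESM summary), `warnings`, `timings_s`. All fields
#'   except `timings_s` are reproducible bit-for-bit for a fixed config.
#' @export
run_pipeline <- function(config = demo_config(), coeffs = npp_coefficients()) {
  config <- validate_pipeline_config(config)
  syn <- config$synthetic %||% list()
  cfg <- do.call(synthetic_config, c(syn, list(seed = config$seed)))
  manifest <- list(config_hash = rlang::hash(config),
                   coeffs_hash = coefficients_hash(coeffs),
                   seed = config$seed, stages = list(), results = list(),
                   warnings = character(0), timings_s = list())
  tic <- function() proc.time()[["elapsed"]]
  # --- simulate ---
  t0 <- tic()
  rs <- gen_rs_fields(cfg, seed = config$seed)
  fd <- gen_float_dataset(cfg, seed = config$seed + 1L)
  es <- if ("esm" %in% config$stages) {
    gen_esm_ensemble(cfg, seed = config$seed + 2L)
  } else NULL
  manifest$stages$simulate <- list(
    pixels = length(rs$grid$lon) * length(rs$grid$lat),
    times = length(rs$grid$time), profiles = length(fd$profiles),
    esm_members = if (is.null(es)) 0 else length(es$members))
  manifest$timings_s$simulate <- tic() - t0
  # --- npp (satellite algorithms on the grid's mean state) ---
  if ("npp" %in% config$stages) {
    t0 <- tic()
    mid <- which.min(abs(rs$grid$time - stats::median(rs$grid$time)))
    px_mean <- surface_pixel(
      chl = mean(rs$grid$vars$chl[, , mid]),
      sst = mean(rs$grid$vars$sst[, , mid]),
      par = mean(rs$grid$vars$par[, , mid]),
      lat = mean(rs$grid$lat), doy = rs$grid$doy[mid],
      kd490 = mean(rs$grid$vars$kd490[, , mid]),
      mld = mean(rs$grid$vars$mld[, , mid]),
      bbp = mean(rs$grid$vars$bbp[, , mid]),
      eta = mean(rs$grid$vars$eta[, , mid]),
      aph = mean(rs$grid$vars$aph[, , mid]),
      adg = mean(rs$grid$vars$adg[, , mid]),
      zno3 = mean(rs$grid$vars$zno3[, , mid]),
      sss = mean(rs$grid$vars$sss[, , mid]))
    manifest$results$npp_mean_state <- lapply(
      stats::setNames(config$algorithms, config$algorithms),
      function(a) compute_npp(px_mean, a, coeffs)$npp)
    manifest$stages$npp <- list(algorithms = length(config$algorithms))
    manifest$timings_s$npp <- tic() - t0
  }
  # --- argo ---
  if ("argo" %in% config$stages) {
    t0 <- tic()
    fnpp <- process_float_set(fd$profiles, algorithms = "cbpm-w",
                              coeffs = coeffs)
    ft <- float_trend(fnpp$time, fnpp$npp_cbpm_w, fnpp$lat,
                      config$region_lat)
    manifest$stages$argo <- list(profiles_in = length(fd$profiles),
                                 profiles_out = nrow(fnpp))
    manifest$results$float_trend <- list(slope = ft$slope,
                                         method = ft$method, n = ft$n)
    manifest$timings_s$argo <- tic() - t0
  }
  # --- trends ---
  if ("trends" %in% config$stages) {
    t0 <- tic()
    reg <- regional_series(rs$grid, "npp")
    jk <- tryCatch(jackknife_windows(reg$year, reg$npp_pg,
                                     window_years = min(20, nrow(reg) - 1)),
                   error = function(e) NULL)
    manifest$stages$trends <- list(years = nrow(reg))
    manifest$results$regional_trend <- list(
      mean_pg = if (is.null(jk)) NA_real_ else jk$mean_trend,
      sd_pg = if (is.null(jk)) NA_real_ else jk$sd_trend,
      true_pg = rs$truth$regional_npp_trend_pg)
    manifest$timings_s$trends <- tic() - t0
  }
  # --- esm ---
  if ("esm" %in% config$stages) {
    t0 <- tic()
    sc <- cfg$esm$scenarios[1]
    series <- lapply(es$members, function(mod) {
      esm_regional_series(concat_members(mod$historical, mod[[sc]]))
    })
    cum <- cumulative_npp_change(series, baseline = cfg$esm$hist_years)
    fin <- cum$years >= 2081 & cum$years <= 2100
    manifest$stages$esm <- list(models = length(es$members))
    manifest$results$esm_cumulative_change <- list(
      mean_pg = mean(cum$mean[fin]), sd_pg = mean(cum$sd[fin]),
      prescribed_pg = unname(cfg$esm$cumulative_change_pg[sc]))
    manifest$timings_s$esm <- tic() - t0
  }
  structure(manifest, class = "run_manifest")
}

#' Strip volatile fields from a run manifest
#'
#' Drops wall-clock timings so two manifests from identical (config, seed)
#' runs compare identical.
#' @param manifest a `run_manifest`.
#' @return the manifest without `timings_s`.
#' @export
manifest_fingerprint <- function(manifest) {
  manifest$timings_s <- NULL
  unclass(manifest)
}
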