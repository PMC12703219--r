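#' D'Agostino-Pearson K2 omnibus normality test
#'
#' Combines the standard normal transformations of the sample skewness and
#' kurtosis statistics into K2 = Zs^2 + Zk^2, chi-squared with 2 degrees of
#' freedom under normality. Requires n >= 20 for the kurtosis approximation
#' to be reliable.
#'
#' @param x numeric vector, `NA` removed.
#' @return list with `statistic` (K2) and `p.value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) return(list(statistic = NA_real_, p.value = NA_real_))
  # skewness z-score (D'Agostino)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z-score (Anscombe-Glynn)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (term1 - term2) / sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Mann-Kendall trend test with Theil-Sen slope
#'
#' Nonparametric monotonic-trend test: S is the sum of signs over all sample
#' pairs, its variance is tie-corrected, and the two-sided p-value uses the
#' continuity-corrected normal approximation. The accompanying slope is the
#' Theil-Sen estimator, the median of all pairwise slopes.
#'
#' @param y values.
#' @param t time axis (defaults to 1..n); pairs with equal `t` are skipped
#'   for the slope.
#' @return list with `s`, `var_s`, `z`, `p.value`, `sen_slope`, `intercept`
#'   (median of `y - slope * t`), `n`.
#' @export
mann_kendall <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 3) return(list(s = NA, var_s = NA, z = NA, p.value = NA,
                         sen_slope = NA_real_, intercept = NA_real_, n = n))
  dy <- outer(y, y, `-`)       # dy[i, j] = y[i] - y[j]
  dt <- outer(t, t, `-`)
  upper <- upper.tri(dy)       # j > i pairs as (later - earlier)
  s <- sum(sign(-dy[upper]))   # sign(y_j - y_i) for j > i
  ties <- table(y)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (var_s <= 0) 0 else if (s > 0) (s - 1) / sqrt(var_s) else
    if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- if (var_s <= 0) 1 else 2 * stats::pnorm(-abs(z))
  slopes <- (-dy[upper]) / (-dt[upper])
  slopes <- slopes[is.finite(slopes)]
  sen <- if (length(slopes)) stats::median(slopes) else NA_real_
  list(s = s, var_s = var_s, z = z, p.value = p, sen_slope = sen,
       intercept = stats::median(y - sen * t), n = n)
}

#' Huber robust trend
#'
#' M-estimated linear trend with the Huber loss (epsilon = 1.35 by default)
#' via iteratively reweighted least squares. Outliers are the samples whose
#' final robust weight falls below 1, i.e. whose scaled residual exceeds
#' epsilon. A series whose OLS residual scale is (numerically) zero is an
#' exact line, where the Huber and OLS estimates coincide by construction.
#'
#' @param y values.
#' @param t time axis.
#' @param epsilon Huber tuning constant.
#' @return list with `slope`, `intercept`, `outlier_frac`, `p.value` (slope
#'   t-test), `se`, `n`.
#' @export
huber_trend <- function(y, t = seq_along(y), epsilon = 1.35) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  fit0 <- stats::lm(y ~ t)
  res_scale <- stats::mad(stats::residuals(fit0))
  if (!is.finite(res_scale) || res_scale < 1e-10 * max(stats::sd(y), 1e-300)) {
    # exact line: summary.lm warns about a perfect fit by design here
    sm <- suppressWarnings(summary(fit0))$coefficients
    return(list(slope = unname(stats::coef(fit0)[2]),
                intercept = unname(stats::coef(fit0)[1]),
                outlier_frac = 0,
                p.value = if (nrow(sm) > 1) sm[2, 4] else NA_real_,
                se = if (nrow(sm) > 1) sm[2, 2] else NA_real_, n = n))
  }
  fit <- MASS::rlm(y ~ t, psi = MASS::psi.huber, k = epsilon, maxit = 100)
  sm <- summary(fit)$coefficients
  se <- sm[2, 2]
  tval <- sm[2, 3]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       outlier_frac = mean(fit$w < 1),
       p.value = 2 * stats::pt(-abs(tval), df = n - 2),
       se = se, n = n)
}

trend_estimate <- function(slope = NA_real_, intercept = NA_real_,
                           method = "none", normality_p = NA_real_,
                           outlier_frac = NA_real_, p.value = NA_real_,
                           se = NA_real_, n = 0L, reason = NULL) {
  structure(list(slope = slope, intercept = intercept, method = method,
                 normality_p = normality_p, outlier_frac = outlier_frac,
                 p.value = p.value, se = se, n = n, reason = reason),
            class = "trend_estimate")
}

#' Normality-routed robust trend of one pixel series
#'
#' The trend procedure applied per pixel: series with less than
#' `min_available` of the nominal time axis present get no trend; series
#' passing the D'Agostino-Pearson normality test (alpha = 0.05, requiring
#' n >= 20 for the test's validity) get a Huber-regression trend (epsilon
#' 1.35), with no trend reported when more than half the samples are flagged
#' as outliers; all other series get a Mann-Kendall test with the Theil-Sen
#' slope. Constant series report a zero Mann-Kendall slope with p = 1.
#'
#' @param values series values (NA = missing).
#' @param t nominal time axis (same length), e.g. decimal years.
#' @param min_available minimum available fraction (default 0.5).
#' @param alpha normality test level.
#' @param epsilon Huber tuning constant.
#' @param normality_min_n below this n the normality test is not attempted
#'   and the series routes to Mann-Kendall.
#' @return a `trend_estimate`: slope/intercept in units per unit of `t`,
#'   `method` in \{"huber", "mann_kendall", "none"\}.
#' @export
pixel_trend <- function(values, t = seq_along(values), min_available = 0.5,
                        alpha = 0.05, epsilon = 1.35, normality_min_n = 20) {
  avail <- mean(is.finite(values))
  if (avail < min_available) {
    return(trend_estimate(method = "none", reason = "availability",
                          n = sum(is.finite(values))))
  }
  ok <- is.finite(values) & is.finite(t)
  y <- values[ok]; tt <- t[ok]
  n <- length(y)
  if (n < 3) return(trend_estimate(method = "none", reason = "too short",
                                   n = n))
  if (stats::sd(y) == 0) {
    return(trend_estimate(slope = 0, intercept = y[1],
                          method = "mann_kendall", p.value = 1, n = n))
  }
  norm_p <- if (n >= normality_min_n) dagostino_pearson(y)$p.value else
    NA_real_
  if (is.finite(norm_p) && norm_p > alpha) {
    h <- huber_trend(y, tt, epsilon)
    if (h$outlier_frac > 0.5) {
      return(trend_estimate(method = "none", normality_p = norm_p,
                            outlier_frac = h$outlier_frac,
                            reason = "outliers", n = n))
    }
    return(trend_estimate(h$slope, h$intercept, "huber", norm_p,
                          h$outlier_frac, h$p.value, h$se, n))
  }
  mk <- mann_kendall(y, tt)
  trend_estimate(mk$sen_slope, mk$intercept, "mann_kendall", norm_p,
                 NA_real_, mk$p.value, NA_real_, n)
}

#' Pixel areas on a regular latitude-longitude grid
#'
#' Spherical pixel area A = R^2 * dlambda * (sin(phi2) - sin(phi1)) per
#' latitude band.
#'
#' @param lat_edges latitude band edges (degrees), increasing.
#' @param lon_res longitude resolution (degrees).
#' @return data.frame with `lat` (band centre) and `area_m2` (one pixel).
#' @export
area_weights <- function(lat_edges, lon_res) {
  phi <- lat_edges * pi / 180
  dlam <- lon_res * pi / 180
  a <- EARTH_RADIUS_M^2 * dlam * diff(sin(phi))
  data.frame(lat = (lat_edges[-length(lat_edges)] + lat_edges[-1]) / 2,
             area_m2 = a)
}

#' Area-weighted regional NPP integral
#'
#' Converts a per-pixel NPP field (mg C m-2 day-1) to an annual regional
#' total in Pg C yr-1: sum(value * area) * 365 / 1e18. Missing pixels are
#' excluded.
#'
#' @param field matrix of per-pixel values, dimensions (lon, lat).
#' @param areas vector of pixel areas (m2) per latitude band, length
#'   `ncol(field)`, or a full matrix conformable with `field`.
#' @return regional total (Pg C yr-1), `NA` if all pixels missing.
#' @export
regional_integral <- function(field, areas) {
  a <- if (is.matrix(areas)) areas else
    matrix(areas, nrow = nrow(field), ncol = ncol(field), byrow = TRUE)
  v <- field * a
  if (!any(is.finite(v))) return(NA_real_)
  sum(v, na.rm = TRUE) * 365 / 1e18
}

#' Moving-window jackknife of a regional trend
#'
#' Slope of every contiguous `window_years`-long sub-window of an annual
#' regional series, each estimated with the same normality-routed procedure
#' as pixel trends, summarised as mean +/- standard deviation.
#'
#' @param years annual time axis.
#' @param values annual regional values (e.g. Pg C).
#' @param window_years window length (default 20).
#' @return list of class `jackknife_summary` with `windows` (data.frame
#'   start, end, slope, method), `mean_trend`, `sd_trend`.
#' @export
jackknife_windows <- function(years, values, window_years = 20) {
  n <- length(years)
  stopifnot(length(values) == n)
  if (n < window_years) {
    stop("series shorter than the jackknife window", call. = FALSE)
  }
  n_win <- n - window_years + 1L
  rows <- lapply(seq_len(n_win), function(i) {
    idx <- i:(i + window_years - 1L)
    tr <- pixel_trend(values[idx], years[idx])
    data.frame(start = years[i], end = years[i + window_years - 1L],
               slope = tr$slope %||% NA_real_, method = tr$method)
  })
  win <- do.call(rbind, rows)
  structure(list(windows = win,
                 mean_trend = mean(win$slope, na.rm = TRUE),
                 sd_trend = stats::sd(win$slope)),
            class = "jackknife_summary")
}

#' Float NPP trend from annual means
#'
#' Ordinary least-squares trend of calendar-year mean NPP for float records
#' south of the region boundary. Years with no profiles are skipped.
#'
#' @param time decimal-year timestamps of profiles.
#' @param npp per-profile NPP values.
#' @param lat profile latitudes; profiles north of `lat_max` are excluded.
#' @param lat_max region boundary latitude (default -40).
#' @return a `trend_estimate` with method `"ols"` (slope per year), or
#'   method `"none"` with fewer than 3 annual means.
#' @export
float_trend <- function(time, npp, lat = NULL, lat_max = -40) {
  ok <- is.finite(time) & is.finite(npp)
  if (!is.null(lat)) ok <- ok & lat <= lat_max
  time <- time[ok]; npp <- npp[ok]
  yr <- floor(time)
  means <- tapply(npp, yr, mean)
  yrs <- as.numeric(names(means))
  if (length(means) < 3) {
    return(trend_estimate(method = "none", reason = "fewer than 3 years",
                          n = length(means)))
  }
  fit <- stats::lm(means ~ yrs)
  sm <- suppressWarnings(summary(fit))$coefficients
  trend_estimate(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                 "ols", p.value = sm[2, 4], se = sm[2, 2],
                 n = length(means))
}

#' Per-pixel trend map of a gridded series
#'
#' Applies [pixel_trend()] to each pixel of a (lon, lat, time) array, by
#' default after reducing to calendar-year annual means (deseasonalising by
#' construction).
#'
#' @param grid an `rs_grid` (see [gen_rs_fields()]).
#' @param var variable name within `grid$vars`.
#' @param annual reduce to annual means first (default TRUE).
#' @return list with matrices `slope`, `p`, `outlier_frac`, character matrix
#'   `method`, and the annual series array in `annual_values` when `annual`.
#' @export
trend_map <- function(grid, var, annual = TRUE) {
  arr <- grid$vars[[var]]
  if (annual) {
    yr <- floor(grid$time)
    yrs <- sort(unique(yr))
    ann <- array(NA_real_, c(dim(arr)[1], dim(arr)[2], length(yrs)))
    for (k in seq_along(yrs)) {
      ann[, , k] <- apply(arr[, , yr == yrs[k], drop = FALSE], c(1, 2),
                          mean, na.rm = TRUE)
    }
    arr <- ann
    taxis <- yrs
  } else {
    taxis <- grid$time
  }
  d <- dim(arr)
  slope <- p <- of <- matrix(NA_real_, d[1], d[2])
  method <- matrix("none", d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    tr <- pixel_trend(arr[i, j, ], taxis)
    slope[i, j] <- tr$slope
    p[i, j] <- tr$p.value
    of[i, j] <- tr$outlier_frac
    method[i, j] <- tr$method
  }
  list(slope = slope, p = p, outlier_frac = of, method = method,
       annual_values = if (annual) arr else NULL, time = taxis)
}

#' Annual regional series from a gridded NPP field
#'
#' Calendar-year mean NPP per pixel, integrated with latitude-dependent
#' pixel areas to annual regional totals (Pg C yr-1).
#'
#' @param grid an `rs_grid` carrying an NPP variable (mg C m-2 day-1).
#' @param var variable name.
#' @return data.frame with `year` and `npp_pg` columns.
#' @export
regional_series <- function(grid, var = "npp") {
  arr <- grid$vars[[var]]
  res <- abs(diff(grid$lat[1:2]))
  edges <- c(grid$lat - res / 2, grid$lat[length(grid$lat)] + res / 2)
  aw <- area_weights(edges, abs(diff(grid$lon[1:2])))
  yr <- floor(grid$time)
  yrs <- sort(unique(yr))
  npp <- vapply(yrs, function(y) {
    fld <- apply(arr[, , yr == y, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    regional_integral(fld, aw$area_m2)
  }, numeric(1))
  data.frame(year = yrs, npp_pg = npp)
}

#' Convert a regional trend between Pg C yr-2 and Gg C yr-2
#'
#' Basin-integrated trends are reported either in Pg C per year of change
#' (slope of an annual Pg C series) or, as often printed, in Gg C year-1.
#' 1 Pg = 1e6 Gg.
#' @param x trend value.
#' @param from,to `"pg"` or `"gg"`.
#' @return converted value.
#' @export
convert_trend_units <- function(x, from = "pg", to = "gg") {
  f <- c(pg = 1e6, gg = 1)[c(from, to)]
  x * f[[1]] / f[[2]]
}
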