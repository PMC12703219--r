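# Shared fixtures and independent oracles used across the suite.

# small, fast synthetic configuration for module tests; float overrides are
# merged into the small defaults
small_config <- function(..., float = NULL) {
  fl <- list(count = 3, profiles_per_float = 4)
  if (!is.null(float)) fl[names(float)] <- float
  synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 5),
                   years = 2010:2015, float = fl, ...)
}

# random but physically plausible surface pixel
random_pixel <- function() {
  surface_pixel(
    chl = stats::runif(1, 0.01, 5), sst = stats::runif(1, -2, 20),
    par = stats::runif(1, 1, 60), lat = stats::runif(1, -75, -40),
    doy = sample(1:365, 1), kd490 = stats::runif(1, 0.02, 0.3),
    mld = stats::runif(1, 10, 150), bbp = stats::runif(1, 5e-4, 0.01),
    eta = stats::runif(1, 0, 2), aph = stats::runif(1, 1e-3, 0.1),
    adg = stats::runif(1, 1e-3, 0.05), zno3 = stats::runif(1, 20, 150),
    sss = stats::runif(1, 33, 35))
}

# brute-force all-pairs Mann-Kendall S and Theil-Sen slope (loop oracle)
brute_mann_kendall <- function(y, t = seq_along(y)) {
  n <- length(y)
  s <- 0
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(y[j] - y[i])
    if (t[j] != t[i]) slopes <- c(slopes, (y[j] - y[i]) / (t[j] - t[i]))
  }
  list(s = s, sen = stats::median(slopes))
}

# brute-force truncated-window running median (second implementation)
brute_running_median <- function(x, window) {
  half <- (window - 1) / 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    out[i] <- stats::median(x[lo:hi], na.rm = TRUE)
  }
  out
}

# artifact-free truth NPP for a synthetic float profile (depth-resolved CbPM
# on the generator's true profiles)
truth_cbpm_npp <- function(tp, z_max = 200) {
  env <- depth_environment(tp$z, tp$chl, tp$cphyto, tp$par, tp$temp)
  doy <- round(365 * (tp$time %% 1)) + 1
  dl <- day_length(tp$lat, doy)
  cbpm_depth_resolved(env, "float_measured", z_max = min(z_max, max(tp$z)),
                      daylength = dl)$result$npp
}
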