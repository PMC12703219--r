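test_that("phytoplankton carbon depth-integration matches closed forms", {
  z <- seq(0, 200, by = 5)
  # constant 0.5 mol m-3 over 100 m -> 50 mol m-2
  expect_equal(integrate_phyc(rep(0.5, length(z)), z, 100), 50,
               tolerance = 1e-12)
  # linear profile: exact trapezoid equals the closed form
  v <- 1 - 0.004 * z
  expect_equal(integrate_phyc(v, z, 100), 100 * 1 - 0.004 * 100^2 / 2,
               tolerance = 1e-9)
  # coarse model levels vs 0.1 m quadrature within 1 %
  zl <- c(2.5, 10, 20, 35, 55, 80, 110, 150)
  prof <- 0.8 * exp(-zl / 60)
  fine_z <- seq(0, 100, by = 0.1)
  fine <- stats::approx(c(0, zl), c(prof[1], prof), xout = fine_z)$y
  expect_equal(integrate_phyc(prof, zl, 100),
               pracma::trapz(fine_z, fine), tolerance = 0.01)
  # no levels above the horizon -> missing
  expect_true(is.na(integrate_phyc(c(1, 2), c(150, 200), 100)))
})

test_that("biomass weighting of limitation terms is a proper convex combination", {
  # identical limitations are invariant to the biomass mix
  expect_equal(weight_limitation(c(0.5, 0.5, 0.5), c(1, 7, 0.1)), 0.5)
  # 3:1 biomass with limits 0.4/0.8 -> 0.5
  expect_equal(weight_limitation(c(0.4, 0.8), c(3, 1)), 0.5)
  # single type unchanged
  expect_equal(weight_limitation(0.73, 2), 0.73)
  # zero biomass -> missing
  expect_true(is.na(weight_limitation(c(0.2, 0.4), c(0, 0))))
  # negative biomass rejected
  expect_error(weight_limitation(c(0.2), c(-1)), "negative biomass")
  # array form: bounded by component limits everywhere
  set.seed(13)
  lim <- array(runif(4 * 5 * 3), c(4, 5, 3))
  bio <- array(runif(4 * 5 * 3), c(4, 5, 3))
  w <- weight_limitation(lim, bio)
  lo <- apply(lim, c(1, 2), min); hi <- apply(lim, c(1, 2), max)
  expect_true(all(w >= lo - 1e-12 & w <= hi + 1e-12))
})

test_that("conservative regridding preserves constants and area-weighted means", {
  # constant field -> constant field
  lonb <- seq(0, 15, by = 1.5); latb <- seq(-60, -50, by = 1.25)
  f <- matrix(3.7, length(lonb) - 1, length(latb) - 1)
  rg <- regrid_1deg(f, lonb, latb)
  expect_true(all(abs(rg$field[is.finite(rg$field)] - 3.7) < 1e-12))
  # area-weighted mean preserved within 0.1 % over random fields
  set.seed(19)
  wmean <- function(field, lonb, latb) {
    a <- outer(diff(lonb), diff(sin(latb * pi / 180)))
    sum(field * a, na.rm = TRUE) / sum(a[is.finite(field)])
  }
  for (k in 1:20) {
    f <- matrix(rnorm((length(lonb) - 1) * (length(latb) - 1)),
                length(lonb) - 1, length(latb) - 1)
    rg <- regrid_1deg(f, lonb, latb)
    m1 <- wmean(f, lonb, latb)
    m2 <- wmean(rg$field, rg$lon_bnds, rg$lat_bnds)
    expect_equal(m2, m1, tolerance = 1e-3)
  }
  # 1.5-degree checkerboard against a brute-force overlap computation
  nx <- length(lonb) - 1; ny <- length(latb) - 1
  cb <- outer(1:nx, 1:ny, function(i, j) (-1)^(i + j))
  rg <- regrid_1deg(cb, lonb, latb)
  brute_cell <- function(li, lj) {
    lon0 <- rg$lon_bnds[li]; lon1 <- rg$lon_bnds[li + 1]
    lat0 <- rg$lat_bnds[lj]; lat1 <- rg$lat_bnds[lj + 1]
    num <- 0; den <- 0
    for (i in 1:nx) for (j in 1:ny) {
      dl <- max(0, min(lon1, lonb[i + 1]) - max(lon0, lonb[i]))
      ds <- max(0, sin(min(lat1, latb[j + 1]) * pi / 180) -
                  sin(max(lat0, latb[j]) * pi / 180))
      num <- num + cb[i, j] * dl * ds
      den <- den + dl * ds
    }
    num / den
  }
  for (li in c(1, 5, 9)) for (lj in c(2, 6)) {
    if (is.finite(rg$field[li, lj])) {
      expect_equal(rg$field[li, lj], brute_cell(li, lj), tolerance = 1e-10)
    }
  }
  # shape mismatch (proxy for unsupported curvilinear input) -> error
  expect_error(regrid_1deg(matrix(1, 3, 3), lonb, latb), "rectilinear")
})

test_that("intpp unit handling converts per-second archives exactly once", {
  x <- array(1e-6, c(2, 2, 3))
  per_day <- intpp_to_per_day(x, "mol m-2 s-1")
  expect_equal(as.numeric(per_day[1]), 86400e-6)
  same <- intpp_to_per_day(per_day, attr(per_day, "units"))
  expect_equal(as.numeric(same), as.numeric(per_day))
  # pre-converted field yields the same regional integral
  expect_equal(as.numeric(intpp_to_per_day(x * 86400, "mol m-2 d-1")),
               as.numeric(per_day), tolerance = 1e-9)
})

test_that("delta fields difference the right periods and recover the construction", {
  cfg <- synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 15),
                          esm = list(n_models = 1, scenarios = "ssp370",
                                     scen_years = 2015:2100, noise_sd = 0,
                                     ar_sd = 0))
  ee <- gen_esm_ensemble(cfg, seed = 5)
  m <- ee$members$model01
  # identical periods -> all deltas zero
  d0 <- delta_fields(m$historical, m$historical, hist_period = 1995:2014,
                     future_period = 1995:2014, regrid = FALSE)
  expect_true(all(abs(d0$dnpp) < 1e-12))
  expect_true(all(abs(d0$dlimfe) < 1e-12))
  # uniform shift: future = hist + 2
  shifted <- m$historical
  shifted$intpp <- m$historical$intpp + 2
  attr(shifted$intpp, "units") <- "mol m-2 d-1"
  d2 <- delta_fields(m$historical, shifted, hist_period = 1995:2014,
                     future_period = 1995:2014, regrid = FALSE)
  expect_true(all(abs(d2$dnpp - 2) < 1e-12))
  # noise-free construction: dnpp equals alpha*dC + beta*dFe + gamma*dIrr
  d <- delta_fields(m$historical, m$ssp370, regrid = FALSE)
  tm <- ee$truth$models[[1]]
  mult <- unname(cfg$esm$scenario_mult["ssp370"])
  pred <- cfg$esm$alpha * mult * tm$d_cph + cfg$esm$beta * mult * tm$d_fe +
    cfg$esm$gamma * mult * tm$d_irr
  resid <- d$dnpp - pred
  expect_lt(stats::sd(as.numeric(resid)), 1e-9)  # uniform offset only
  expect_equal(d$dcphyto, mult * tm$d_cph, tolerance = 1e-9)
  # exact linear construction: regression returns each coefficient, r -> 1
  # when the other drivers vanish
  cfg1 <- synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 15),
                           esm = list(n_models = 1, scenarios = "ssp370",
                                      scen_years = 2015:2100, noise_sd = 0,
                                      ar_sd = 0, beta = 0, gamma = 0))
  e1 <- gen_esm_ensemble(cfg1, seed = 6)
  d1 <- delta_fields(e1$members$model01$historical,
                     e1$members$model01$ssp370, regrid = FALSE)
  r1 <- driver_regression(d1, "dcphyto")
  expect_equal(r1$slope, cfg1$esm$alpha, tolerance = 1e-6)
  expect_equal(abs(r1$r), 1, tolerance = 1e-9)
})

test_that("driver regression flags constant drivers and sees no signal in null fields", {
  d <- structure(list(dnpp = matrix(rnorm(100), 10, 10),
                      dcphyto = matrix(1, 10, 10),
                      dlimfe = matrix(rnorm(100), 10, 10),
                      dlimirr = matrix(rnorm(100), 10, 10),
                      lon = 1:10 - 0.5, lat = seq(-55, -46),
                      areas = rep(1, 10)), class = "delta_fields")
  rc <- driver_regression(d, "dcphyto")
  expect_true(is.na(rc$slope))
  expect_equal(rc$flag, "constant driver")
  # independent Gaussian fields: |r| < 0.05 for most seeds at n = 5000
  set.seed(37)
  hits <- vapply(1:40, function(i) {
    dn <- structure(list(dnpp = matrix(rnorm(5000), 100, 50),
                         dcphyto = matrix(rnorm(5000), 100, 50),
                         lon = seq(0.5, 99.5), lat = seq(-64.5, -15.5),
                         areas = rep(1, 50)), class = "delta_fields")
    abs(driver_regression(dn, "dcphyto")$r) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("cumulative NPP change is zero on baseline and tracks prescribed steps", {
  years <- 1995:2100
  flat <- data.frame(year = years, npp_pg = 7)
  cc <- cumulative_npp_change(list(flat))
  expect_true(all(abs(cc$mean) < 1e-12))
  # +0.5 step from 2050
  stepped <- flat
  stepped$npp_pg[years >= 2050] <- 7.5
  cc2 <- cumulative_npp_change(list(stepped))
  expect_true(all(abs(cc2$mean[cc2$years >= 2050] - 0.5) < 1e-12))
  expect_true(all(abs(cc2$mean[cc2$years < 2050]) < 1e-12))
  # ensemble of five members with prescribed changes -> mean 0.5, sd 0.158
  mems <- lapply(c(0.3, 0.4, 0.5, 0.6, 0.7), function(ch) {
    s <- flat; s$npp_pg[years >= 2081] <- 7 + ch; s
  })
  cc3 <- cumulative_npp_change(mems)
  fin <- cc3$years >= 2081
  expect_equal(mean(cc3$mean[fin]), 0.5, tolerance = 1e-12)
  expect_equal(mean(cc3$sd[fin]), sd(c(0.3, 0.4, 0.5, 0.6, 0.7)),
               tolerance = 1e-12)
  # incomplete baseline -> error
  expect_error(cumulative_npp_change(list(flat[flat$year > 2000, ])),
               "baseline")
})

test_that("prescribed regional cumulative changes are recovered from the ensemble", {
  cfg <- synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 15),
                          esm = list(n_models = 2, scenarios = "ssp370",
                                     scen_years = 2015:2100, noise_sd = 0,
                                     ar_sd = 0))
  ee <- gen_esm_ensemble(cfg, seed = 9)
  series <- lapply(ee$members, function(mod) {
    esm_regional_series(concat_members(mod$historical, mod$ssp370))
  })
  cc <- cumulative_npp_change(series, baseline = 1995:2014)
  fin <- cc$years >= 2081 & cc$years <= 2100
  expect_equal(mean(cc$mean[fin]),
               unname(cfg$esm$cumulative_change_pg["ssp370"]),
               tolerance = 1e-6)
})

test_that("ESM trends delegate to the routed trend machinery", {
  cfg <- synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 15),
                          esm = list(n_models = 1, scenarios = "ssp370",
                                     scen_years = 2015:2100, ar_sd = 0,
                                     noise_sd = 0))
  ee <- gen_esm_ensemble(cfg, seed = 12)
  m <- concat_members(ee$members$model01$historical,
                      ee$members$model01$ssp370)
  # noiseless ramp construction: future slope matches the regional NPP ramp
  tr <- esm_trends(m, "future")
  s <- esm_regional_series(m, 2051:2100)
  ols <- unname(coef(lm(s$npp_pg ~ s$year))[2])
  expect_equal(tr$slope, ols, tolerance = 0.02)
  # flat member: zero slope
  flat <- m
  flat$intpp <- array(0.02, dim(m$intpp))
  attr(flat$intpp, "units") <- "mol m-2 d-1"
  tr0 <- esm_trends(flat, "future")
  expect_equal(tr0$slope, 0)
  expect_error(esm_trends(ee$members$model01$historical, "future"),
               "cover")
})

test_that("PFT biomass fractions sum to one at every cell", {
  cfg <- synthetic_config(lat_range = c(-60, -50), lon_range = c(0, 15),
                          esm = list(n_models = 2, scenarios = "ssp370",
                                     scen_years = 2015:2030))
  ee <- gen_esm_ensemble(cfg, seed = 14)
  for (mod in ee$members) {
    tot <- apply(mod$historical$pft_biomass, c(1, 2), sum)
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})
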