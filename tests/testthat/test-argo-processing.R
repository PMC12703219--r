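test_that("QC selection keeps exactly the good-flag samples", {
  mk_prof <- function(flags) {
    n <- length(flags)
    list(id = "T1", time = 2020, lat = -50, lon = 0, is_day = FALSE,
         z = seq(5, by = 5, length.out = n), temp = rnorm(n, 5),
         sal = rnorm(n, 34), fchl = runif(n), bbp700 = runif(n, 0, 0.01),
         par = runif(n, 0, 30),
         qc = list(temp = flags, sal = flags, fchl = flags,
                   bbp700 = flags, par = flags))
  }
  # all flags 4 -> empty set
  out <- select_qc(list(mk_prof(rep(4, 5))))
  expect_length(out, 0)
  # mixed flags: {1,4,8,3,5} keeps 3 samples
  out <- select_qc(list(mk_prof(c(1, 4, 8, 3, 5))))
  expect_length(out, 1)
  expect_equal(sum(is.finite(out[[1]]$fchl)), 3)
  # all good -> identity
  p <- mk_prof(rep(1, 5))
  out <- select_qc(list(p))
  expect_identical(out[[1]]$fchl, p$fchl)
  # missing QC -> dropped with reason
  p2 <- p; p2$qc <- NULL
  out <- select_qc(list(p2))
  expect_length(out, 0)
  expect_match(attr(out, "dropped"), "missing QC")
})

test_that("monotone Hermite regridding is exact on lines, shape-preserving, and never extrapolates", {
  g <- standard_grid()
  # exact on linear data at all covered nodes
  z <- c(2, 7.5, 20, 100, 400, 990)
  v <- 3 + 0.1 * z
  out <- regrid_profile(z, v, g)
  covered <- g >= min(z) & g <= max(z)
  expect_equal(out[covered], 3 + 0.1 * g[covered], tolerance = 1e-10)
  expect_true(all(is.na(out[!covered])))
  # no values outside the sampled range
  expect_true(all(is.na(out[g < 2 | g > 990])))
  # monotone input -> no overshoot beyond neighbour range
  set.seed(3)
  z2 <- sort(runif(30, 1, 300)); v2 <- cumsum(abs(rnorm(30)))
  out2 <- regrid_profile(z2, v2, g)
  ok <- !is.na(out2)
  expect_true(all(out2[ok] >= min(v2) - 1e-12 & out2[ok] <= max(v2) + 1e-12))
  expect_true(all(diff(out2[ok]) >= -1e-9))  # monotone preserved
  # coincident nodes reproduced exactly
  z3 <- c(4.3, 9.7, 15, 22.1, 30.5); v3 <- c(1, 2, 2.5, 2.6, 4)
  out3 <- regrid_profile(z3, v3, g)
  expect_equal(out3[g == 15], 2.5)
  # independent monotone-cubic oracle (different Fritsch-Carlson variant)
  oracle <- stats::splinefun(z3, v3, method = "monoH.FC")
  expect_equal(out3[g == 7], oracle(7), tolerance = 0.05)
  # fewer than 2 samples -> all missing with flag
  out4 <- regrid_profile(c(10), c(1), g)
  expect_true(all(is.na(out4)))
  expect_equal(attr(out4, "flag"), "insufficient")
})

test_that("quenching correction extrapolates the mixed-layer maximum on day profiles only", {
  z <- 1:100
  fchl <- rep(1, 100); fchl[z >= 15 & z <= 40] <- 2
  fchl[z < 15] <- 0.7  # quenched surface
  # night -> identity
  night <- correct_quenching(fchl, z, mld = 40, is_day = FALSE)
  expect_equal(as.numeric(night), fchl)
  # day -> surface restored to the mixed-layer maximum value
  day <- correct_quenching(fchl, z, mld = 40, is_day = TRUE)
  expect_true(all(day[z < 15] == 2))
  expect_true(attr(day, "corrected"))
  # maximum already at the surface -> identity
  fs <- rev(sort(runif(100, 0.5, 2)))
  expect_equal(as.numeric(correct_quenching(fs, z, 40, TRUE)), fs)
  # generator truth: quench factor restored exactly for the plateau case
  cfg <- small_config(float = list(count = 2, profiles_per_float = 4,
                                   quench_factor = 0.5, spike_rate = 0,
                                   negative_rate = 0, bad_flag_frac = 0))
  fd <- gen_float_dataset(cfg, seed = 8)
  day_idx <- which(vapply(fd$profiles, `[[`, logical(1), "is_day"))
  skip_if(length(day_idx) == 0)
  p <- fd$profiles[[day_idx[1]]]
  tp <- fd$truth$profiles[[day_idx[1]]]
  corr <- correct_quenching(p$fchl, p$z, tp$mld, TRUE)
  # everything above the mixed-layer maximum takes the maximum's value
  in_ml <- p$z <= tp$mld
  zq <- p$z[in_ml][which.max(corr[in_ml])]
  expect_equal(as.numeric(corr[p$z < zq]),
               rep(max(p$fchl[in_ml]), sum(p$z < zq)))
  # quenched surface restored close to truth (plateau + weak deep tail)
  ratio <- corr / (2 * tp$chl)
  expect_true(all(abs(ratio[p$z < tp$quench_depth] - 1) < 0.15))
  # below the mixed layer the profile is untouched
  deep <- p$z > tp$mld & p$z < 200
  expect_equal(as.numeric(corr[deep]), p$fchl[deep])
})

test_that("fluorescence-to-chlorophyll conversion applies the factor-2 slope", {
  expect_equal(fluor_to_chl(1.0), 0.5)
  expect_equal(fluor_to_chl(0), 0)
  expect_equal(fluor_to_chl(c(2, 4)), c(1, 2))
})

test_that("backscatter cleaning masks negatives and rejects noisy/deep-anomalous profiles", {
  g <- standard_grid()
  set.seed(5)
  mk_bbp <- function(scale = 1, noise = 1e-5) {
    0.002 * exp(-g / 300) * scale + 4e-4 + rnorm(length(g), 0, noise)
  }
  profs <- replicate(8, mk_bbp(), simplify = FALSE)
  ctx <- bbp_set_context(profs, g)
  # clean profile -> identity
  b <- profs[[1]]
  expect_equal(clean_bbp(b, g, ctx), b)
  # one negative -> masked, profile kept
  b2 <- b; b2[50] <- -1e-4
  out <- clean_bbp(b2, g, ctx)
  expect_true(is.na(out[50]))
  expect_equal(out[-50], b[-50])
  # deep median 10x the set's -> rejected
  b3 <- b; b3[g > 700] <- 10 * ctx$deep_median
  expect_s3_class(clean_bbp(b3, g, ctx), "bbp_rejection")
  expect_equal(clean_bbp(b3, g, ctx)$reason, "anomalous deep")
  # very noisy -> rejected
  b4 <- b + rnorm(length(g), 0, 20 * ctx$median_msd)
  expect_s3_class(clean_bbp(b4, g, ctx), "bbp_rejection")
})

test_that("running-median despiking removes isolated spikes and matches brute force", {
  x <- rep(2, 50); x[25] <- 100
  expect_equal(despike(x), rep(2, 50))
  expect_equal(despike(rep(3, 20)), rep(3, 20))
  set.seed(11)
  y <- rnorm(200)
  expect_equal(despike(y, 11), brute_running_median(y, 11))
  expect_equal(despike(y, 5), brute_running_median(y, 5))
  # interior agrees with the standard running median
  rm11 <- stats::runmed(y, 11, endrule = "keep")
  expect_equal(despike(y, 11)[6:195], as.numeric(rm11)[6:195])
  expect_equal(despike(y[1:2]), y[1:2])  # too short -> identity
})

test_that("carbon conversion applies the deep baseline, spectral slope and slope factor", {
  g <- standard_grid()
  base <- 5e-4
  # bbp equal to baseline everywhere -> zero carbon
  out <- to_cphyto(rep(base, length(g)), g)
  expect_true(all(out == 0))
  expect_equal(attr(out, "baseline"), base)
  # hand evaluation of the stated chain: excess 0.001 -> 12128*0.001*1.3644
  b <- rep(base, length(g)); b[g <= 200] <- base + 0.001
  out2 <- to_cphyto(b, g)
  expect_equal(out2[1], 12128 * 0.001 * (470 / 700)^(-0.78),
               tolerance = 1e-9)
  expect_equal(out2[1], 16.547, tolerance = 1e-4)
  # no deep samples -> set fallback, flagged
  shallow_g <- 1:200
  out3 <- to_cphyto(rep(base + 0.001, 200), shallow_g,
                    set_deep_median = base)
  expect_equal(attr(out3, "flag"), "baseline from profile set")
  expect_equal(out3[1], 12128 * 0.001 * (470 / 700)^(-0.78),
               tolerance = 1e-9)
  # generator truth round trip: artifact-free profile recovers Cphyto within 1 %
  cfg <- small_config(float = list(count = 1, profiles_per_float = 2,
                                   quench_factor = 1, spike_rate = 0,
                                   negative_rate = 0, bad_flag_frac = 0))
  fd <- gen_float_dataset(cfg, seed = 2)
  p <- fd$profiles[[1]]; tp <- fd$truth$profiles[[1]]
  bbp_g <- regrid_profile(p$z, p$bbp700, g)
  cph <- to_cphyto(bbp_g, g)
  cph_true <- regrid_profile(tp$z, tp$cphyto, g)
  sel <- which(g < 150 & is.finite(cph) & is.finite(cph_true) &
                 cph_true > 1)
  expect_gt(length(sel), 50)
  expect_lt(stats::median(abs(cph[sel] / cph_true[sel] - 1)), 0.01)
})

test_that("density-threshold MLD finds constructed layer steps and behaves monotonically", {
  z <- seq(1, 300)
  # two-layer: density step of +0.05 at 55 m via salinity
  sal <- ifelse(z < 55, 34, 34 + 0.05 / (1025 * 7.6e-4))
  temp <- rep(5, length(z))
  mld <- mld_density(temp, sal, z)
  expect_lt(abs(as.numeric(mld) - 55), 1.5)
  # homogeneous -> deepest level, flagged
  mld2 <- mld_density(rep(5, 300), rep(34, 300), z)
  expect_equal(as.numeric(mld2), 300)
  expect_equal(attr(mld2, "flag"), "no threshold crossing")
  # raising the criterion never shoals the MLD
  sal3 <- 34 + cumsum(runif(300, 0, 0.002))
  m03 <- as.numeric(mld_density(temp, sal3, z, criterion = 0.03))
  m05 <- as.numeric(mld_density(temp, sal3, z, criterion = 0.05))
  expect_gte(m05, m03)
  # generator truth: constructed float MLD recovered
  fd <- gen_float_dataset(small_config(), seed = 4)
  p <- fd$profiles[[1]]
  g <- standard_grid()
  tg <- regrid_profile(p$z, p$temp, g); sg <- regrid_profile(p$z, p$sal, g)
  mldr <- as.numeric(mld_density(tg, sg, g))
  expect_lt(abs(mldr - fd$truth$mld), 10)
})

test_that("upper-ocean integration is exact for constants and linear profiles", {
  z <- seq(1, 300)
  expect_equal(integrate_upper(rep(2.5, 300), z, 200), 500, tolerance = 1e-12)
  # linear a + b z sampled on a 1 m grid from the surface: 100a + 5000b
  z0 <- seq(0, 300)
  a <- 0.3; b <- 0.01
  expect_equal(integrate_upper(a + b * z0, z0, 100), 100 * a + 5000 * b,
               tolerance = 1e-9)
  # constant molar ratio
  expect_equal(integrate_ratio(rep(0.2, 300), rep(0.1, 300), z, 100), 2.0,
               tolerance = 1e-12)
  # > 50 % missing in range -> missing
  v <- rep(1, 300); v[1:160] <- NA
  expect_true(is.na(integrate_upper(v, z, 200)))
})

test_that("the full chain processes profiles in the audited order without extrapolation", {
  cfg <- small_config()
  fd <- gen_float_dataset(cfg, seed = 21)
  res <- process_float_set(fd$profiles)
  expect_gt(nrow(res), 0)
  pp <- attr(res, "profiles")[[1]]
  expect_equal(pp$audit[1], "regrid")
  expect_true(which(pp$audit == "quench" |
                      pp$audit == "fchl/2")[1] <
                which(pp$audit == "despike_chl"))
  expect_lt(which(pp$audit == "clean_bbp"), which(pp$audit == "to_cphyto"))
  # no extrapolation: nothing outside the raw sampled range
  raw <- fd$profiles[[1]]
  g <- standard_grid()
  outside <- g < min(raw$z) | g > max(raw$z)
  expect_true(all(is.na(pp$chl[outside])))
  # NPP columns present and positive
  expect_true(all(res$npp_cbpm_w > 0))
  expect_true(all(res$npp_vgpm_b > 0))
})

test_that("end-to-end float recovery: processed NPP within 10 % of artifact-free truth", {
  # all artifacts at their default rates, >= 100 profiles
  cfg <- synthetic_config(float = list(count = 11, profiles_per_float = 10))
  fd <- gen_float_dataset(cfg, seed = 17)
  expect_gte(length(fd$profiles), 100)
  res <- process_float_set(fd$profiles, algorithms = "cbpm-w")
  truth_map <- vapply(fd$truth$profiles, function(tp) {
    paste(tp$id, signif(tp$time, 10))
  }, character(1))
  ratios <- vapply(seq_len(nrow(res)), function(i) {
    k <- match(paste(res$id[i], signif(res$time[i], 10)), truth_map)
    truth <- truth_cbpm_npp(fd$truth$profiles[[k]])
    if (truth <= 0) NA_real_ else res$npp_cbpm_w[i] / truth  # polar night
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  expect_gte(length(ratios), 100)
  expect_lt(abs(stats::median(ratios) - 1), 0.10)
})
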