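# R2* fitting, concentration and dose mapping, dose-limit conversions.

test_that("noiseless mono-exponential decays are recovered exactly", {
  # S(TE) = 1000 * exp(-0.1 * TE[ms]) -> R2* = 100 1/s
  te <- default_echo_times()
  arr <- array(0, dim = c(2, 2, 2, 10))
  for (e in 1:10) arr[, , , e] <- 1000 * exp(-0.1 * te[e])
  fit <- fit_r2star(multi_echo_series(arr, te))
  expect_true(all(fit$valid))
  expect_equal(fit$r2star$values, array(100, c(2, 2, 2)), tolerance = 1e-9)
  expect_equal(fit$s0$values, array(1000, c(2, 2, 2)), tolerance = 1e-6)
  expect_equal(fit$fit_quality$values, array(1, c(2, 2, 2)), tolerance = 1e-9)
})

test_that("a holmium-loaded voxel's decay rate is recovered to machine precision", {
  conc <- volume_grid(array(1, dim = c(2, 2, 1)))  # 1 mg/mL, r2* = 90
  s <- synthesize_multiecho(conc, r2star0 = 35, noise_sd = 0)
  fit <- fit_r2star(s)
  expect_equal(fit$r2star$values[1, 1, 1], 125, tolerance = 1e-9)
})

test_that("R2* bias stays below 2% at Rician SNR 50 over 500 voxels", {
  conc <- volume_grid(array(65 / 90, dim = c(500, 1, 1)))  # R2* = 100 1/s
  s <- synthesize_multiecho(conc, noise_sd = 1000 / 50, seed = 42)
  fit <- fit_r2star(s)
  est <- fit$r2star$values[fit$valid]
  expect_gt(sum(fit$valid), 450)
  expect_lt(abs(mean(est) - 100) / 100, 0.02)
})

test_that("unusable voxels are flagged invalid, never zeroed", {
  te <- default_echo_times()
  arr <- array(5, dim = c(1, 1, 1, 10))  # all echoes below floor
  fit <- fit_r2star(multi_echo_series(arr, te), noise_floor = 10)
  expect_false(fit$valid[1, 1, 1])
  expect_true(is.na(fit$r2star$values[1, 1, 1]))
  expect_identical(fit$n_invalid, 1L)
  expect_error(fit_r2star(multi_echo_series(array(1, c(1, 1, 1, 2)), 1:2)),
               "3 echoes")
})

test_that("concentration map applies the delta-R2* law with clamping and QC", {
  te <- default_echo_times()
  mk <- function(r2s) {
    arr <- array(0, dim = c(2, 1, 1, 10))
    for (e in 1:10) arr[, , , e] <- 1000 * exp(-r2s / 1000 * te[e])
    fit_r2star(multi_echo_series(arr, te))
  }
  post <- mk(c(125, 20))   # voxel 2 BELOW baseline
  base <- mk(c(35, 35))
  cm <- concentration_map(post, base)
  expect_equal(cm$values[1, 1, 1], 1, tolerance = 1e-9)  # 90/90 = 1 mg/mL
  expect_identical(cm$values[2, 1, 1], 0)                # clamped
  expect_identical(attr(cm, "n_negative_delta"), 1L)
  bad <- mk(35)
  bad$r2star$spacing <- c(9, 9, 9)
  expect_error(concentration_map(post, bad), "geometry mismatch")
})

test_that("phantom round-trip truth -> synthesis -> fit -> concentration is exact", {
  ph <- test_phantom(seed = 3)
  truth <- simulate_deposition(ph$labels, ph$trees, scaled_schedule(ph$labels),
                               flow_condition("medium"), seed = 2)
  C <- truth$true_concentration[[5]]
  pre <- fit_r2star(synthesize_multiecho(
    volume_grid(array(0, dim(C$values)), C$spacing), noise_sd = 0))
  post <- fit_r2star(synthesize_multiecho(C, noise_sd = 0))
  rec <- concentration_map(post, pre)
  expect_lt(max(abs(rec$values - C$values)), 1e-6)
})

test_that("the voxel dose law and its inverse reproduce the printed conversions", {
  k <- dosimetry_constants()
  conc <- volume_grid(array(0.3277, dim = c(1, 1, 1)))
  dm <- dose_map(conc, k)
  expect_equal(dm$dose$values[1, 1, 1], 60, tolerance = 1e-3)
  expect_identical(dose_map(volume_grid(array(0, c(1, 1, 1))),
                            k)$dose$values[1, 1, 1], 0)
  # linearity in specific activity
  k2 <- dosimetry_constants(specific_activity = 24)
  expect_equal(dose_map(conc, k2)$dose$values, 2 * dm$dose$values)
  # printed dose-limit correspondences, 2 d.p.
  expect_identical(round(concentration_for_dose(60, k), 2), 0.33)
  expect_identical(round(concentration_for_dose(300, k), 2), 1.64)
  # exact inverse property
  for (C in c(0.05, 1, 7.3)) {
    d <- dose_map(volume_grid(array(C, c(1, 1, 1))), k)$dose$values[1]
    expect_equal(concentration_for_dose(d, k), C, tolerance = 1e-12)
  }
  expect_error(concentration_for_dose(0), "> 0")
})

test_that("noiseless end-to-end dose scales linearly with administered mass", {
  ph <- test_phantom(seed = 3)
  base <- scaled_schedule(ph$labels)
  double <- fraction_schedule(base$fractions * 2)
  t1 <- simulate_deposition(ph$labels, ph$trees, base,
                            flow_condition("medium"), seed = 3)
  t2 <- simulate_deposition(ph$labels, ph$trees, double,
                            flow_condition("medium"), seed = 3)
  d1 <- dose_map(t1$true_concentration[[5]])$dose$values
  d2 <- dose_map(t2$true_concentration[[5]])$dose$values
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("lobe dose summaries satisfy the mass-accounting oracle and additivity", {
  ph <- test_phantom(seed = 3)
  truth <- simulate_deposition(ph$labels, ph$trees, scaled_schedule(ph$labels),
                               flow_condition("medium"), seed = 2)
  k <- dosimetry_constants()
  dm <- dose_map(truth$true_concentration[[5]], k)
  tab <- lobe_dose_summary(dm, ph$labels)
  v <- lobe_volumes(ph$labels)
  # lobe mean dose = SA*k/rho * lobe mass / lobe volume (2%: rasterisation)
  analytic <- k$specific_activity * k$dose_factor / k$tissue_density *
    deposited_mass_by_lobe(truth) / v$volume_ml
  expect_equal(tab$mean_gy, analytic, tolerance = 0.02)
  # partition additivity: sum(mean * volume) over lobes = liver mean * volume
  mask <- ph$labels$labels > 0
  expect_equal(sum(tab$mean_gy * tab$volume_ml),
               mean(dm$dose$values[mask]) * sum(v$volume_ml),
               tolerance = 1e-9)
  # uniform map: every lobe mean is the value itself
  u <- lobe_dose_summary(uniform_dose(10, dim(ph$labels$labels)), ph$labels)
  expect_equal(u$mean_gy, rep(10, 5))
  expect_equal(u$d2_gy, rep(10, 5))
})

test_that("empty lobes yield flagged NaN rows without aborting", {
  labs <- array(0L, dim = c(6, 6, 4))
  labs[1:2, , ] <- 1L; labs[3, , ] <- 2L; labs[4, , ] <- 3L; labs[5, , ] <- 4L
  lab <- lobe_label_map(labs, spacing = c(2, 2, 2))  # lobe 5 empty
  expect_warning(tab <- lobe_dose_summary(uniform_dose(5, dim(labs)), lab),
                 "lobe 5")
  expect_true(is.nan(tab$mean_gy[5]))
  expect_equal(tab$mean_gy[1:4], rep(5, 4))
})
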