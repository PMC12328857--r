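# Microsphere counting, Pearson correlation and bins, hemodynamic utilities.

test_that("microsphere counts follow the per-sphere mass formula", {
  # uniform 1 mg/mL over a 1,000 mL liver -> 5.05e7 spheres
  labs <- array(0L, dim = c(25, 25, 25))
  labs[1:25, 1:25, 1:25] <- rep(1:5, each = 25 * 25 * 5)
  lab <- lobe_label_map(labs, spacing = c(4, 4, 4))  # 15625 voxels = 1000 mL
  conc <- volume_grid(array(1, dim = dim(labs)), lab$spacing)
  tab <- microsphere_counts(conc, lab)
  expect_equal(sum(tab$count), 5.05e7, tolerance = 1e-2)
  expect_equal(sum(tab$mass_mg), 1000)
  zero <- microsphere_counts(volume_grid(array(0, dim(labs)), lab$spacing),
                             lab)
  expect_identical(zero$count, rep(0, 5))
})

test_that("Pearson r agrees with the covariance-formula oracle to 1e-12", {
  oracle_r <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(7)
  for (i in 1:20) {
    x <- runif(5); y <- runif(5)
    tab <- correlate_perfusion_deposition(x / sum(x), y)
    expect_equal(attr(tab, "r"), oracle_r(x / sum(x), y / sum(y)),
                 tolerance = 1e-12)
  }
})

test_that("proportional counts give r = 1 'perfect'; signed negatives are out-of-bin", {
  pf <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  tab <- correlate_perfusion_deposition(pf, pf * 5.05e4 * 100)
  expect_equal(attr(tab, "r"), 1, tolerance = 1e-12)
  expect_identical(attr(tab, "category"), "perfect")
  anti <- correlate_perfusion_deposition(pf, rev(pf) * 1e4)
  expect_lt(attr(anti, "r"), 0)
  expect_identical(attr(anti, "category"), "out-of-bin (negative)")
  expect_error(correlate_perfusion_deposition(pf, rep(1, 5)), "zero variance")
  expect_error(correlate_perfusion_deposition(pf[1:2], 1:2), ">= 3")
})

test_that("correlation bins match the printed intervals with upward boundaries", {
  expect_identical(classify_correlation(0.611), "moderate")
  expect_identical(classify_correlation(0.977), "very strong")
  expect_identical(classify_correlation(0.6), "moderate")
  expect_identical(classify_correlation(0.05), "none")
  expect_identical(classify_correlation(0.1), "poor")
  expect_identical(classify_correlation(0.3), "fair")
  expect_identical(classify_correlation(0.8), "very strong")
  expect_identical(classify_correlation(1), "perfect")
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("flow-to-velocity reproduces the printed worked examples", {
  inj <- flow_to_velocity(32, 0.6)
  expect_identical(inj$cm_per_s_int, 188)
  expect_equal(inj$cm_per_s, 188.6, tolerance = 1e-3)
  low <- flow_to_velocity(51, 5)
  expect_identical(low$cm_per_s_int, 4)
  expect_equal(low$cm_per_s, 4.33, tolerance = 1e-2)
  # doubling the diameter quarters the velocity
  expect_equal(flow_to_velocity(32, 1.2)$cm_per_s, inj$cm_per_s / 4,
               tolerance = 1e-12)
  expect_error(flow_to_velocity(0, 1), "> 0")
})

test_that("flow normalisation and pump settings are consistent inverses", {
  expect_equal(normalize_flow(52.7, 2637), 0.02, tolerance = 1e-2)
  # 0.22 mL/min/g x 2,637 g within the printed high-condition pump band
  expect_equal(flow_setting(0.22, 2637), 583, tolerance = 15.28 / 583)
  expect_equal(normalize_flow(flow_setting(0.15, 2500), 2500), 0.15,
               tolerance = 1e-12)
  expect_error(normalize_flow(10, 0), "> 0")
})

test_that("high-mixing phantoms give strong perfusion-deposition correlation", {
  ph <- test_phantom(seed = 3)
  hits <- sapply(1:10, function(s) {
    truth <- simulate_deposition(ph$labels, ph$trees, fraction_schedule(),
                                 flow_condition("high"), seed = s)
    tab <- correlate_perfusion_deposition(
      truth$lobe_perfusion_fraction,
      deposited_mass_by_lobe(truth) * spheres_per_mg(truth$spheres))
    attr(tab, "r") >= 0.8
  })
  expect_gte(mean(hits), 0.9)
})
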