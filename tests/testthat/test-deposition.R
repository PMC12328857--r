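# Deposition simulator: conservation, flow-proportional routing at perfect
# mixing, proximal lodging at poor mixing, monotone mixing effects.

test_that("deposited mass is conserved exactly for every seed and condition", {
  ph <- test_phantom(seed = 3)
  for (cond in c("low", "high")) {
    for (seed in c(1, 9)) {
      sch <- fraction_schedule(residual_fraction = if (seed == 9) 0.1 else 0)
      truth <- simulate_deposition(ph$labels, ph$trees, sch,
                                   flow_condition(cond), seed = seed)
      total <- sum(vapply(truth$deposited_mass, sum, numeric(1)))
      expect_lt(abs(total - delivered_mass(sch)), 1e-9)
      # rasterised concentration carries the same mass
      vv <- voxel_volume_ml(ph$labels)
      last <- truth$true_concentration[[length(sch$fractions)]]
      expect_equal(sum(last$values) * vv, delivered_mass(sch),
                   tolerance = 1e-9)
      expect_true(all(last$values >= 0))
    }
  }
})

test_that("perfect mixing without proximal lodging deposits by lobe flow fraction", {
  ph <- test_phantom(seed = 3)
  cond <- flow_condition("high", mixing = 1)
  truth <- simulate_deposition(ph$labels, ph$trees, fraction_schedule(),
                               cond, seed = 4, lambda = 0)
  frac <- deposited_mass_by_lobe(truth) / delivered_mass(truth$schedule)
  F <- truth$lobe_perfusion_fraction
  # binomial 99.9% envelope on n = 5e4 packets per lobe fraction
  n <- 5e4
  expect_true(all(abs(frac - F) < 3.3 * sqrt(F * (1 - F) / n) + 1e-12))
})

test_that("low flow lodges more mass proximally (generations 1-3) than high flow", {
  ph <- test_phantom(seed = 3)
  sch <- fraction_schedule()
  for (seed in c(2, 5)) {
    lo <- simulate_deposition(ph$labels, ph$trees, sch,
                              flow_condition("low"), seed = seed)
    hi <- simulate_deposition(ph$labels, ph$trees, sch,
                              flow_condition("high"), seed = seed)
    expect_gt(mass_fraction_in_generations(lo, 1:3),
              mass_fraction_in_generations(hi, 1:3))
  }
})

test_that("mean lodged generation increases with mixing", {
  ph <- test_phantom(seed = 3)
  sch <- fraction_schedule()
  gens <- sapply(c(0.1, 0.5, 0.9), function(m) {
    mean(sapply(1:4, function(s) {
      mean_lodged_generation(simulate_deposition(
        ph$labels, ph$trees, sch, flow_condition("low", mixing = m),
        seed = s))
    }))
  })
  expect_true(all(diff(gens) > 0))
})

test_that("mean homogeneity index strictly decreases across mixing levels", {
  ph <- test_phantom(seed = 3)
  sch <- fraction_schedule()
  mask <- ph$labels$labels > 0
  mix <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mean_hi <- sapply(mix, function(m) {
    mean(sapply(1:10, function(s) {
      truth <- simulate_deposition(ph$labels, ph$trees, sch,
                                   flow_condition("low", mixing = m),
                                   seed = s)
      homogeneity_index(dose_map(truth$true_concentration[[5]]),
                        mask = mask)$hi
    }))
  })
  expect_true(all(diff(mean_hi) < 0))  # Spearman rho = -1 on the 5 means
})

test_that("simulated HI lands in the study's qualitative bands per condition", {
  sch <- fraction_schedule()
  hi_for <- function(cond) {
    mean(sapply(1:5, function(s) {
      ph <- test_phantom(seed = s)
      truth <- simulate_deposition(ph$labels, ph$trees, sch,
                                   flow_condition(cond), seed = s)
      homogeneity_index(dose_map(truth$true_concentration[[5]]),
                        mask = ph$labels$labels > 0)$hi
    }))
  }
  expect_gt(hi_for("low"), 3.5)
  expect_lt(hi_for("low"), 5.0)
  expect_gt(hi_for("high"), 1.5)
  expect_lt(hi_for("high"), 2.5)
})

test_that("deposition is a pure function of seed and inputs", {
  ph <- test_phantom(seed = 3)
  a <- simulate_deposition(ph$labels, ph$trees, fraction_schedule(),
                           flow_condition("medium"), seed = 6)
  b <- simulate_deposition(ph$labels, ph$trees, fraction_schedule(),
                           flow_condition("medium"), seed = 6)
  expect_identical(a$deposited_mass, b$deposited_mass)
  expect_identical(a$true_concentration[[5]]$values,
                   b$true_concentration[[5]]$values)
})

test_that("tight segment capacity pushes mass upstream or raises stasis", {
  ph <- test_phantom(seed = 3)
  sch <- fraction_schedule(1000)
  expect_error(
    simulate_deposition(ph$labels, ph$trees, sch, flow_condition("low"),
                        seed = 1, capacity_coeff = 1e-9),
    "stasis")
})
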