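# DVH percentiles, homogeneity index, trajectories, micro-CT segmentation.

# Brute-force Dp% oracle: sort doses, interpolate linearly between order
# statistics at rank h = (n - 1) * (100 - p) / 100 + 1.
oracle_dp <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * (100 - p) / 100 + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

test_that("D2% follows the stated interpolation rule (1..100 Gy gives 98.02)", {
  dm <- volume_grid(array(1:100, dim = c(10, 10, 1)), role = "dose")
  expect_equal(dose_percentile(dm, p = 2), 98.02)
  expect_equal(dose_percentile(dm, p = 98), 2.98)
  u <- uniform_dose(10)
  expect_equal(dose_percentile(u, p = 2), 10)
  expect_equal(dose_percentile(u, p = 98), 10)
  expect_error(dose_percentile(u, p = 0), "p must be")
})

test_that("percentiles agree exactly with the brute-force oracle on random maps", {
  set.seed(81)
  for (rep in 1:5) {
    n <- sample(50:10000, 1)
    d <- c(n, 1, 1)
    x <- rgamma(n, shape = 0.8) * 40
    x[sample(n, n %/% 10)] <- 0  # zero-dose voxels included
    dm <- volume_grid(array(x, dim = d), role = "dose")
    for (p in c(2, 50, 98)) {
      expect_equal(dose_percentile(dm, p = p), oracle_dp(x, p),
                   tolerance = 1e-12)
    }
    expect_gte(dose_percentile(dm, p = 2), dose_percentile(dm, p = 50))
    expect_gte(dose_percentile(dm, p = 50), dose_percentile(dm, p = 98))
  }
})

test_that("homogeneity index: uniform map 0, two-level 10/30 map 1.0, scale-invariant", {
  expect_identical(homogeneity_index(uniform_dose(10))$hi, 0)
  two <- volume_grid(array(c(rep(10, 50), rep(30, 50)), dim = c(100, 1, 1)),
                     role = "dose")
  st <- homogeneity_index(two)
  expect_equal(st$d2, 30)
  expect_equal(st$d98, 10)
  expect_equal(st$dmean, 20)
  expect_equal(st$hi, 1.0)
  # HI(alpha * dose) = HI(dose)
  set.seed(4)
  x <- rgamma(500, 1.2)
  a <- homogeneity_index(volume_grid(array(x, c(500, 1, 1))))$hi
  b <- homogeneity_index(volume_grid(array(7.3 * x, c(500, 1, 1))))$hi
  expect_equal(a, b, tolerance = 1e-12)
  # degenerate all-zero map: flagged undefined
  z <- homogeneity_index(uniform_dose(0))
  expect_true(z$undefined)
  expect_true(is.nan(z$hi))
})

test_that("pooling lobes into the whole-liver mask raises HI on low flow", {
  # between-lobe dose differences add heterogeneity: the whole-organ HI
  # exceeds the typical (volume-weighted mean) single-lobe HI
  ph <- test_phantom(seed = 3)
  for (s in c(2, 6)) {
    truth <- simulate_deposition(ph$labels, ph$trees, fraction_schedule(),
                                 flow_condition("low"), seed = s)
    dm <- dose_map(truth$true_concentration[[5]])
    whole <- homogeneity_index(dm, mask = ph$labels$labels > 0)$hi
    v <- lobe_volumes(ph$labels)$volume_ml
    lobe_his <- sapply(1:5, function(l) {
      homogeneity_index(dm, mask = ph$labels$labels == l)$hi
    })
    expect_gt(whole, sum(lobe_his * v) / sum(v))
  }
})

test_that("HI trajectory maps schedule mass to mg/mL and validates inputs", {
  sch <- fraction_schedule()  # 5 x 250 mg
  maps <- lapply(1:5, function(i) uniform_dose(i))
  traj <- hi_trajectory(maps, sch, liver_volume_ml = 1250)
  expect_equal(traj$mg_per_ml, c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(traj$hi, rep(0, 5))
  expect_error(hi_trajectory(maps[1], fraction_schedule(250), 1250),
               ">= 2 points")
  bad <- c(maps[1:4], list(uniform_dose(1, dim = c(3, 3, 3))))
  expect_error(hi_trajectory(bad, sch, 1250), "inconsistent geometry")
})

test_that("threshold segmentation is exact and tolerates empty masks", {
  arr <- array(0, dim = c(8, 8, 4))
  arr[2:3, 2:3, 2] <- 500
  v <- volume_grid(arr, spacing = c(0.03, 0.03, 0.03), role = "hu")
  seg <- segment_microct(v, microct_params(350))
  expect_identical(seg$mask, arr == 500)
  expect_identical(nrow(seg$components), 1L)
  empty <- segment_microct(volume_grid(arr, role = "hu"),
                           microct_params(1000))
  expect_identical(sum(empty$mask), 0L)
  expect_identical(nrow(empty$components), 0L)
})

test_that("a synthetic cylinder's radius is recovered by the distance transform", {
  # radius 0.09 mm = 3 voxels at 0.03 mm
  d <- c(30, 30, 40)
  sp <- c(0.03, 0.03, 0.03)
  arr <- array(0, dim = d)
  cx <- (d[1] / 2) * sp[1]; cy <- (d[2] / 2) * sp[2]
  for (z in 5:35) {
    for (x in 1:d[1]) for (y in 1:d[2]) {
      r <- sqrt(((x - 1) * sp[1] - cx)^2 + ((y - 1) * sp[2] - cy)^2)
      if (r <= 0.09) arr[x, y, z] <- 800
    }
  }
  seg <- segment_microct(volume_grid(arr, sp, role = "hu"))
  expect_identical(nrow(seg$components), 1L)
  expect_equal(seg$components$radius_mm, 0.09, tolerance = 0.03 / 0.09)
  # separate blobs at 26-connectivity stay separate when fully disjoint
  arr2 <- array(0, dim = c(10, 10, 4))
  arr2[2:3, 2:3, 2] <- 500
  arr2[7:8, 7:8, 2] <- 500
  seg2 <- segment_microct(volume_grid(arr2, sp, role = "hu"))
  expect_identical(nrow(seg2$components), 2L)
})
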