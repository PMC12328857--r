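# Time-intensity curves, the printed percent-enhancement convention,
# maximum wash-in slope, relative perfusion recovery.

mk_tic <- function(s_t, s0 = NULL, interval = 0.86, baseline = 10L) {
  structure(
    list(lobe = 1L, s0_lobe = s0 %||% mean(s_t[seq_len(baseline)]),
         s_t = s_t, times = (seq_along(s_t) - 1) * interval,
         frame_interval = interval, baseline_frames = baseline),
    class = "time_intensity_curve")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the PE transform uses the printed post-injection denominator", {
  tic <- mk_tic(c(rep(100, 10), 200, 400, 100, -5), s0 = 100)
  pe <- percent_enhancement(tic)
  expect_equal(pe$pe_t[11], 50)   # 100*(200-100)/200
  expect_equal(pe$pe_t[12], 75)   # NOT the conventional 300
  expect_equal(pe$pe_t[13], 0)    # s = s0
  expect_true(is.na(pe$pe_t[14])) # non-positive signal flagged
  conv <- percent_enhancement(tic, denominator = "baseline")
  expect_equal(conv$pe_t[12], 300)
  # PE invariant under global signal scaling
  pe2 <- percent_enhancement(mk_tic(7 * tic$s_t, s0 = 700))
  expect_equal(pe2$pe_t[11:13], pe$pe_t[11:13])
})

test_that("constant series give s_t identical to s0 and zero slope flagged", {
  lab <- test_phantom(seed = 3)$labels
  d <- dim(lab$labels)
  ds <- dynamic_series(array(500, dim = c(d, 30)), 0.86, lab$spacing)
  tics <- extract_tic(ds, lab)
  for (tc in tics) expect_equal(tc$s_t, rep(tc$s0_lobe, 30))
  fit <- max_washin_slope(percent_enhancement(tics[[1]]))
  expect_identical(fit$max_slope, 0)
  expect_identical(fit$flag, "non-enhancing")
})

test_that("extract_tic validates inputs and names empty lobes", {
  lab <- test_phantom(seed = 3)$labels
  d <- dim(lab$labels)
  ds <- dynamic_series(array(1, dim = c(d, 20)), 0.86)
  expect_error(extract_tic(ds, lab, baseline_frames = 20), "< n_frames")
  labs2 <- lab$labels
  labs2[labs2 == 5L] <- 0L
  lab2 <- lobe_label_map(labs2, lab$spacing)
  expect_error(extract_tic(ds, lab2), "lobe 5.*caudate")
})

test_that("a linear PE ramp yields its exact slope; time rescaling doubles it", {
  pe <- structure(list(pe_t = 2 * (0:59) * 0.86, times = (0:59) * 0.86,
                       frame_interval = 0.86, lobe = 1), class = "pe_curve")
  expect_equal(max_washin_slope(pe)$max_slope, 2, tolerance = 1e-12)
  # same samples at half the frame interval -> double the slope
  expect_equal(max_washin_slope(pe$pe_t, frame_interval = 0.43)$max_slope,
               4, tolerance = 1e-12)
})

test_that("logistic wash-in slope estimates stay within 5% of the analytic maximum", {
  interval <- 0.86
  t <- (0:199) * interval
  for (tau in c(3, 5)) {
    A <- 60
    pe_t <- A / (1 + exp(-(t - 60) / tau))
    est <- max_washin_slope(pe_t, frame_interval = interval)$max_slope
    expect_equal(est, dce_analytic_max_slope(A, tau), tolerance = 0.05)
  }
})

test_that("relative perfusion normalises slopes and rejects degenerate input", {
  expect_equal(relative_perfusion(rep(1, 5)), rep(0.2, 5))
  expect_equal(relative_perfusion(c(2, 1, 1, 0, 0)),
               c(0.5, 0.25, 0.25, 0, 0))
  expect_error(relative_perfusion(rep(0, 5)), "all slopes are zero")
  expect_error(relative_perfusion(c(-1, 2)), "non-negative")
})

test_that("noiseless DCE analysis recovers ground-truth perfusion fractions", {
  lab <- test_phantom(seed = 3)$labels
  # equal fractions -> exactly 0.2 each by symmetry
  ds_eq <- synthesize_dce(labels = lab, perfusion_fractions = rep(0.2, 5),
                          noise_sd = 0)
  res_eq <- analyze_perfusion(ds_eq, lab)
  expect_equal(res_eq$relative_perfusion, rep(0.2, 5), tolerance = 1e-6)
  # skewed fractions recovered within 1e-3
  pf <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  ds <- synthesize_dce(labels = lab, perfusion_fractions = pf, noise_sd = 0)
  res <- analyze_perfusion(ds, lab)
  expect_equal(res$relative_perfusion, pf, tolerance = 1e-3)
  # doubling one lobe's perfusion parameter doubles its analytic max slope
  tr <- attr(ds, "dce_truth")
  tr2 <- attr(synthesize_dce(labels = lab,
                             perfusion_fractions = pf * c(2, 1, 1, 1, 1),
                             noise_sd = 0), "dce_truth")
  expect_equal(tr2$analytic_max_slope[1] / tr$analytic_max_slope[1], 2,
               tolerance = 1e-12)
})

test_that("noisy DCE (2% of S0) recovers fractions within 0.02", {
  lab <- test_phantom(seed = 3)$labels
  pf <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  err <- sapply(1:8, function(s) {
    ds <- synthesize_dce(labels = lab, perfusion_fractions = pf,
                         noise_sd = 20, seed = s)
    max(abs(analyze_perfusion(ds, lab)$relative_perfusion - pf))
  })
  expect_lt(mean(err), 0.02)
})

test_that("delayed reduced-perfusion lobes wash in later and less steeply", {
  lab <- test_phantom(seed = 3)$labels
  ds <- synthesize_dce(labels = lab, perfusion_fractions = rep(0.2, 5),
                       reduced_lobes = 2L, noise_sd = 0)
  tr <- attr(ds, "dce_truth")
  expect_gt(tr$t0[2], tr$t0[1])
  expect_lt(tr$analytic_max_slope[2], tr$analytic_max_slope[1])
})
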