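# Image synthesis from phantom ground truth: multi-echo T2*-weighted
# magnitude series, DCE wash-in series, and micro-CT vessel volumes.

#' Synthesise a multi-echo gradient-echo series from a concentration map
#'
#' The noiseless magnitude signal is
#' `S(TE) = s0 * exp(-(r2star0 + relaxivity * C) * TE)` with `TE` in ms and
#' relaxation rates in 1/s; holmium concentration `C` (mg/mL) elevates R2*
#' linearly through the `relaxivity` constant. Rician noise (the magnitude
#' noise model) of parameter `noise_sd` is applied per echo when
#' `noise_sd > 0`.
#'
#' @param concentration A `volume_grid` of Ho concentration, mg/mL, `>= 0`.
#' @param echo_times Echo times, ms (default the 10-echo protocol,
#'   TE1 = 1.7 ms, spacing 1.35 ms).
#' @param s0 Baseline signal, a.u.
#' @param r2star0 Tissue baseline R2*, 1/s.
#' @param constants A `dosimetry_constants` (supplies the relaxivity).
#' @param noise_sd Rician noise parameter, a.u.
#' @param seed Integer seed (noise substream).
#' @return A `multi_echo_series`.
#' @export
synthesize_multiecho <- function(concentration,
                                 echo_times = default_echo_times(),
                                 s0 = 1000, r2star0 = 35,
                                 constants = dosimetry_constants(),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(concentration, "volume_grid"))
  C <- concentration$values
  if (any(C < 0, na.rm = TRUE)) stopf("concentration must be >= 0")
  r2s <- r2star0 + constants$relaxivity * C  # 1/s
  d <- dim(C)
  data <- array(0, dim = c(d, length(echo_times)))
  for (e in seq_along(echo_times)) {
    data[, , , e] <- s0 * exp(-r2s * echo_times[e] / 1000)
  }
  if (noise_sd > 0) {
    with_seed(substream_seed(seed, "noise"), {
      n <- length(data)
      data <- sqrt((data + stats::rnorm(n, 0, noise_sd))^2 +
                     stats::rnorm(n, 0, noise_sd)^2)
      data <- array(data, dim = c(d, length(echo_times)))
    })
  }
  multi_echo_series(data, echo_times, concentration$spacing,
                    concentration$origin)
}

#' Analytic maximum percent-enhancement slope of a synthetic wash-in curve
#'
#' The DCE generator prescribes each lobe's percent-enhancement curve as
#' `PE(t) = A * logistic((t - t0) / tau)`, whose maximum derivative is
#' `A / (4 * tau)` %/s.
#'
#' @param pe_amplitude Plateau percent enhancement `A`, percent.
#' @param tau Logistic time constant, s.
#' @return Maximum PE slope, %/s.
#' @export
dce_analytic_max_slope <- function(pe_amplitude, tau) pe_amplitude / (4 * tau)

#' Synthesise a DCE-MRI series with perfusion-encoded wash-in curves
#'
#' Each lobe's enhancement is prescribed in percent-enhancement (PE) domain
#' as `PE_l(t) = A_l * logistic((t - t0_l) / tau)` with amplitude
#' `A_l = pe_per_unit_perfusion * perfusion_fraction_l` (capped at 90%), so
#' the analytic maximum PE slope `A_l / (4 * tau)` is exactly proportional
#' to the lobe's ground-truth perfusion rate. The signal follows from the
#' printed PE convention with the post-injection denominator:
#' `S_l(t) = s0 / (1 - PE_l(t) / 100)`. Optional reduced-perfusion lobes get
#' a delayed onset and damped amplitude (delayed, less steep wash-in).
#' Gaussian temporal noise of SD `noise_sd` is added per voxel-frame.
#'
#' @param truth A `phantom_truth` (supplies perfusion fractions), or `NULL`
#'   when `perfusion_fractions` is given.
#' @param labels A `lobe_label_map`; defaults to `truth$label_map`.
#' @param perfusion_fractions Optional explicit per-lobe perfusion rates.
#'   Used as given (not renormalised), so doubling one lobe's value doubles
#'   that lobe's PE amplitude and analytic maximum slope.
#' @param n_frames Number of frames (default 200).
#' @param frame_interval Frame interval, s (default 0.86).
#' @param s0 Baseline signal, a.u.
#' @param t0 Wash-in midpoint, s.
#' @param tau Logistic time constant, s.
#' @param pe_per_unit_perfusion PE amplitude per unit perfusion fraction, %.
#' @param reduced_lobes Optional integer vector of lobes with reduced
#'   perfusion (delayed `t0` by `reduced_delay`, amplitude damped by
#'   `reduced_damping`).
#' @param reduced_delay Delay added to `t0` for reduced lobes, s.
#' @param reduced_damping Amplitude multiplier for reduced lobes.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param seed Integer seed (dce substream).
#' @return A `dynamic_series`; the generating parameters are attached as
#'   attribute `"dce_truth"` (per-lobe amplitude, t0, tau, analytic max
#'   slope).
#' @export
synthesize_dce <- function(truth = NULL, labels = NULL,
                           perfusion_fractions = NULL,
                           n_frames = 200L, frame_interval = 0.86,
                           s0 = 1000, t0 = 60, tau = 3,
                           pe_per_unit_perfusion = 100,
                           reduced_lobes = integer(0), reduced_delay = 20,
                           reduced_damping = 0.4,
                           noise_sd = 0, seed = 1L) {
  if (is.null(labels)) {
    if (is.null(truth)) stopf("need 'labels' (or a phantom_truth)")
    labels <- truth$label_map
  }
  stopifnot(inherits(labels, "lobe_label_map"))
  pf <- perfusion_fractions %||% truth$lobe_perfusion_fraction
  if (is.null(pf)) stopf("lobe perfusion fractions unknown")

  A <- pe_per_unit_perfusion * pf
  t0_l <- rep(t0, 5)
  if (length(reduced_lobes)) {
    A[reduced_lobes] <- A[reduced_lobes] * reduced_damping
    t0_l[reduced_lobes] <- t0_l[reduced_lobes] + reduced_delay
  }
  if (any(A <= 0)) stopf("PE amplitude must be > 0 for every lobe")
  A <- pmin(A, 90)

  d <- dim(labels$labels)
  times <- (seq_len(n_frames) - 1) * frame_interval
  data <- array(s0 * 0.3, dim = c(d, n_frames))  # non-liver background
  lab <- labels$labels
  for (l in 1:5) {
    sel <- lab == l
    if (!any(sel)) next
    pe <- A[l] / (1 + exp(-(times - t0_l[l]) / tau))
    sig <- s0 / (1 - pe / 100)
    for (k in seq_len(n_frames)) {
      frame <- data[, , , k]
      frame[sel] <- sig[k]
      data[, , , k] <- frame
    }
  }
  if (noise_sd > 0) {
    with_seed(substream_seed(seed, "dce"), {
      data <- data + array(stats::rnorm(length(data), 0, noise_sd),
                           dim = dim(data))
    })
  }
  out <- dynamic_series(data, frame_interval, labels$spacing, labels$origin)
  attr(out, "dce_truth") <- list(
    pe_amplitude = A, t0 = t0_l, tau = tau,
    analytic_max_slope = dce_analytic_max_slope(A, tau),
    perfusion_fractions = pf / sum(pf))
  out
}

#' Synthesise a micro-CT volume of microsphere-filled vessels
#'
#' Emulates a fixed tissue block imaged at 30 um voxels: parenchyma is
#' Gaussian background (default N(40, 15) HU) and microsphere-filled vessel
#' lumina are rendered as bright cylinders (>= 600 HU). Filled-vessel radii
#' are drawn from the deposition truth of the sampled lobe's tree: segments
#' are sampled with probability proportional to their deposited mass, and
#' each is rendered at its Murray radius scaled by `radius_scale` to the
#' calibre range visible in a micro-CT block. With no deposited mass in the
#' subtree, a background-only volume is returned.
#'
#' @param truth A `phantom_truth`.
#' @param lobe Which lobe's subtree to sample (1-5).
#' @param region_mm Edge length of the cubic sample, mm (`<= 20`, the
#'   physical tissue-block size).
#' @param spacing_mm Isotropic voxel size, mm (default 0.03 = 30 um).
#' @param n_vessels Number of filled vessels to render.
#' @param radius_scale Scale from tree segment radius (mm) to rendered lumen
#'   radius (mm).
#' @param bg_mean,bg_sd Background parenchyma HU distribution.
#' @param vessel_hu Mean HU of filled lumina.
#' @param seed Integer seed (microct substream).
#' @return A `volume_grid` (HU) with attribute `"vessel_radii_mm"` giving
#'   the rendered true radii.
#' @export
synthesize_microct <- function(truth, lobe = 1L, region_mm = 5,
                               spacing_mm = 0.03, n_vessels = 10L,
                               radius_scale = 0.4, bg_mean = 40, bg_sd = 15,
                               vessel_hu = 900, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (region_mm > 20) stopf("sample region must be <= 20 mm (tissue block)")
  tr <- truth$trees[[lobe]]
  seg <- tr$segments
  if (!nrow(seg)) stopf("empty subtree: lobe %d has no segments", lobe)
  mass <- rowSums(truth$deposited_mass[[lobe]])

  n <- max(8L, round(region_mm / spacing_mm))
  d <- c(n, n, n)

  with_seed(substream_seed(seed, "microct"), {
    vol <- array(stats::rnorm(prod(d), bg_mean, bg_sd), dim = d)
    radii <- numeric(0)
    if (sum(mass) > 0 && n_vessels > 0) {
      pick <- sample.int(nrow(seg), n_vessels, replace = TRUE,
                         prob = mass / sum(mass))
      radii <- pmin(seg$radius[pick] * radius_scale, region_mm / 4)
      ext <- (d - 1) * spacing_mm
      half_len <- region_mm / 2
      for (v in seq_along(pick)) {
        centre <- stats::runif(3, 0.2, 0.8) * ext
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        # evaluate only the cylinder's bounding box
        reach <- half_len + radii[v]
        lo <- pmax(1L, floor((centre - reach) / spacing_mm) + 1L)
        hi <- pmin(d, ceiling((centre + reach) / spacing_mm) + 1L)
        gx <- (lo[1]:hi[1] - 1) * spacing_mm - centre[1]
        gy <- (lo[2]:hi[2] - 1) * spacing_mm - centre[2]
        gz <- (lo[3]:hi[3] - 1) * spacing_mm - centre[3]
        bd <- c(length(gx), length(gy), length(gz))
        along <- outer(outer(gx * u[1], gy * u[2], `+`), gz * u[3], `+`)
        r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`) - along^2
        inside <- r2 <= radii[v]^2 & abs(along) <= half_len
        if (any(inside)) {
          sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
          sub[inside] <- pmax(600, vessel_hu +
                                stats::rnorm(sum(inside), 0, 40))
          vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
        }
      }
    }
    out <- volume_grid(vol, rep(spacing_mm, 3), role = "hu")
    attr(out, "vessel_radii_mm") <- radii
    out
  })
}
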