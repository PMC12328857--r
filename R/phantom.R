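# Synthetic liver phantom: flow conditions, administration schedule,
# microsphere properties and the five-lobe label-map generator.

#' Hepatic-arterial flow condition
#'
#' The three investigated conditions use HA flow rates of 0.02 (low), 0.15
#' (medium) and 0.22 (high) mL/min/g liver tissue, with portal-vein flow
#' maintained at exactly three times the HA flow. Each condition carries a
#' dimensionless `mixing` parameter in \[0, 1\] describing how completely
#' microspheres homogenise with blood before each bifurcation; the default
#' mapping (low 0.25, medium 0.65, high 0.90) is a named free parameter of
#' the simulator, calibrated only to qualitative homogeneity bands, and is
#' strictly increasing in HA flow.
#'
#' @param name `"low"`, `"medium"` or `"high"`.
#' @param ha_flow_per_gram Optional custom HA flow, mL/min/g; defaults to the
#'   condition's standard value.
#' @param mixing Optional custom mixing in \[0, 1\]; defaults to a monotone
#'   interpolation of the standard mapping at `ha_flow_per_gram`.
#' @return An object of class `flow_condition`.
#' @export
flow_condition <- function(name = c("low", "medium", "high"),
                           ha_flow_per_gram = NULL, mixing = NULL) {
  name <- match.arg(name)
  std_ha <- c(low = 0.02, medium = 0.15, high = 0.22)
  std_mix <- c(low = 0.25, medium = 0.65, high = 0.90)
  ha <- ha_flow_per_gram %||% std_ha[[name]]
  if (!is.finite(ha) || ha <= 0) stopf("HA flow must be > 0")
  if (is.null(mixing)) {
    mixing <- stats::approx(unname(std_ha), unname(std_mix), xout = ha,
                            rule = 2)$y
  }
  if (mixing < 0 || mixing > 1) stopf("mixing must be in [0, 1]")
  structure(
    list(name = name, ha_flow_per_gram = ha,
         pv_flow_per_gram = 3 * ha, mixing = mixing),
    class = "flow_condition"
  )
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf(
    "<flow_condition> %s: HA %.3g mL/min/g, PV %.3g mL/min/g, mixing %.2f\n",
    x$name, x$ha_flow_per_gram, x$pv_flow_per_gram, x$mixing))
  invisible(x)
}

#' Microsphere administration schedule
#'
#' The study schedule is five fractions of 250 mg, optionally followed by
#' four fractions of 1,000 mg (high-dosage arm). Residual mass retained in
#' the delivery vial is modelled as a fixed fraction of each administered
#' fraction.
#'
#' @param fractions Ordered fraction masses, mg.
#' @param residual_fraction Fraction of each mass retained in the vial.
#' @param extended If `TRUE` and `fractions` is missing, append the four
#'   1,000 mg fractions.
#' @return An object of class `fraction_schedule`.
#' @export
fraction_schedule <- function(fractions = NULL, residual_fraction = 0,
                              extended = FALSE) {
  if (is.null(fractions)) {
    fractions <- c(rep(250, 5), if (extended) rep(1000, 4))
  }
  fractions <- as.numeric(fractions)
  if (!length(fractions) || any(!is.finite(fractions)) || any(fractions <= 0)) {
    stopf("fraction masses must be positive")
  }
  if (residual_fraction < 0 || residual_fraction >= 1) {
    stopf("residual_fraction must be in [0, 1)")
  }
  structure(
    list(fractions = fractions, residual_fraction = residual_fraction),
    class = "fraction_schedule"
  )
}

#' Delivered mass of a schedule (mg)
#' @param schedule A `fraction_schedule`.
#' @return Total delivered mass, mg.
#' @export
delivered_mass <- function(schedule) {
  sum(schedule$fractions) * (1 - schedule$residual_fraction)
}

#' Microsphere physical specification
#'
#' Defaults: 30.0 um diameter, 1.4 g/mL density.
#'
#' @param diameter_um Sphere diameter, micrometres.
#' @param density_g_ml Sphere density, g/mL.
#' @return An object of class `microsphere_spec`.
#' @export
microsphere_spec <- function(diameter_um = 30.0, density_g_ml = 1.4) {
  if (diameter_um <= 0 || density_g_ml <= 0) {
    stopf("diameter and density must be > 0")
  }
  structure(list(diameter_um = diameter_um, density_g_ml = density_g_ml),
            class = "microsphere_spec")
}

#' Number of microspheres per milligram
#' @param spheres A `microsphere_spec`.
#' @return Spheres per mg (about 5.05e4 for the default spec).
#' @export
spheres_per_mg <- function(spheres = microsphere_spec()) {
  d_cm <- spheres$diameter_um * 1e-4
  mass_mg <- spheres$density_g_ml * pi * d_cm^3 / 6 * 1000
  1 / mass_mg
}

# ---- label-map generator ---------------------------------------------------

# Smooth random bump field on the unit ellipsoid coordinates: a handful of
# low-frequency cosine modes, giving a seed-dependent irregular boundary.
.bump_field <- function(u, n_modes = 6, amplitude = 0.08) {
  b <- numeric(nrow(u))
  for (k in seq_len(n_modes)) {
    w <- stats::rnorm(3)
    w <- w / sqrt(sum(w^2)) * stats::runif(1, 1.5, 3.5)
    phase <- stats::runif(1, 0, 2 * pi)
    b <- b + amplitude / n_modes * cos(u %*% w + phase)
  }
  as.numeric(b)
}

#' Build a five-lobe liver phantom label map
#'
#' Generates a smooth, seed-dependent liver envelope (a perturbed ellipsoid)
#' and partitions it into five disjoint lobes with configurable volume
#' fractions using an additively-weighted (power-diagram) nearest-seed
#' assignment whose weights are iterated until the realised fractions match
#' the targets.
#'
#' @param shape Lattice dimensions, e.g. `c(96, 96, 64)`.
#' @param spacing Voxel edge lengths, mm.
#' @param volume_fractions Target lobe volume fractions, length 5, summing
#'   to 1. Default `c(0.30, 0.20, 0.20, 0.22, 0.08)`.
#' @param seed Integer seed.
#' @param axis_scale Envelope semi-axes as a fraction of the half-extent.
#' @param frac_tol Relative tolerance on realised volume fractions.
#' @return A `lobe_label_map`.
#' @export
build_liver_phantom <- function(shape = c(96, 96, 64), spacing = c(2, 2, 2),
                                volume_fractions = c(0.30, 0.20, 0.20, 0.22, 0.08),
                                seed = 1L, axis_scale = 0.96, frac_tol = 0.03) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  volume_fractions <- volume_fractions / sum(volume_fractions)
  if (length(volume_fractions) != 5L) stopf("need 5 volume fractions")

  with_seed(substream_seed(seed, "phantom"), {
    ext <- (shape - 1) * spacing
    centre <- ext / 2
    semi <- pmax(ext / 2 * axis_scale, spacing)
    co <- voxel_coords(shape, spacing)
    u <- sweep(sweep(co, 2, centre), 2, semi, "/")  # unit-ellipsoid coords
    r2 <- rowSums(u^2)
    inside <- r2 + .bump_field(u) < 1
    n_in <- sum(inside)
    if (n_in < 50L) stopf("shape too small to host 5 lobes")

    pts <- co[inside, , drop = FALSE]
    # Spread 5 lobe seeds: greedy farthest-point from random candidates.
    first <- sample.int(n_in, 1)
    seeds <- matrix(NA_real_, 5, 3)
    seeds[1, ] <- pts[first, ]
    d2min <- colSums((t(pts) - seeds[1, ])^2)
    for (l in 2:5) {
      cand <- sample.int(n_in, min(n_in, 400L))
      pick <- cand[which.max(d2min[cand] * stats::runif(length(cand), 0.6, 1))]
      seeds[l, ] <- pts[pick, ]
      d2min <- pmin(d2min, colSums((t(pts) - seeds[l, ])^2))
    }

    d2 <- sapply(1:5, function(l) colSums((t(pts) - seeds[l, ])^2))
    w <- numeric(5)
    lr <- stats::median(d2)  # weight step scale, mm^2
    lab_in <- max.col(-(sweep(d2, 2, w)), ties.method = "first")
    for (it in seq_len(120L)) {
      frac <- tabulate(lab_in, 5) / n_in
      if (all(frac > 0) &&
          max(abs(frac - volume_fractions) / volume_fractions) < frac_tol) break
      w <- w + lr * 0.35 * log(volume_fractions / pmax(frac, 1 / n_in))
      w <- w - mean(w)
      lab_in <- max.col(-(sweep(d2, 2, w)), ties.method = "first")
    }
    frac <- tabulate(lab_in, 5) / n_in
    if (any(tabulate(lab_in, 5) < 10L)) {
      stopf("shape too small to host 5 lobes (a lobe has < 10 voxels)")
    }

    labels <- array(0L, dim = shape)
    labels[inside] <- lab_in
    lobe_label_map(labels, spacing)
  })
}

#' Lobe volumes of a label map
#' @param labels A `lobe_label_map`.
#' @return Data frame with lobe, name, n_voxel and volume_ml.
#' @export
lobe_volumes <- function(labels) {
  stopifnot(inherits(labels, "lobe_label_map"))
  n <- tabulate(labels$labels[labels$labels > 0], 5)
  data.frame(lobe = 1:5, name = unname(lobe_names()), n_voxel = n,
             volume_ml = n * voxel_volume_ml(labels))
}

# ---- separable 3-D Gaussian blur ------------------------------------------

# Zero-padded separable Gaussian convolution; sigma in voxels per axis.
# Used to spread lodged microsphere mass over terminal territories.
gaussian_blur3 <- function(arr, sigma = 1) {
  if (all(sigma <= 0)) return(arr)
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    m <- max(1L, ceiling(3 * s))
    k <- exp(-((-m):m)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim = d)
    for (j in (-m):m) {
      wgt <- k[j + m + 1]
      src <- seq_len(d[ax])
      keep <- src + j >= 1 & src + j <= d[ax]
      src_idx <- src[keep]
      dst_idx <- src_idx + j
      if (ax == 1) {
        out[dst_idx, , ] <- out[dst_idx, , ] + wgt * arr[src_idx, , ]
      } else if (ax == 2) {
        out[, dst_idx, ] <- out[, dst_idx, ] + wgt * arr[, src_idx, ]
      } else {
        out[, , dst_idx] <- out[, , dst_idx] + wgt * arr[, , src_idx]
      }
    }
    arr <- out
  }
  arr
}
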