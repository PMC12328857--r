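# MRI-voxel-based dosimetry: R2* mapping from multi-echo decays, holmium
# concentration maps, fictive absorbed-dose maps and per-lobe summaries.

#' Dosimetry constants
#'
#' Constants of the fictive dosimetry chain. The fictive specific activity
#' assigned to the nonradioactive spheres is 12 MBq/mg. The dose factor is
#' the 166Ho local-deposition value 15.87 Gy.kg/GBq (each voxel's decay
#' energy absorbed locally over full decay); tissue density defaults to
#' 1.04 g/mL. The R2* relaxivity of the spheres (1/s per mg/mL at 1.5 T)
#' defaults to 90 and is shared between synthesis and analysis; only its
#' order of magnitude matters when both sides use the same value, and a
#' mis-specified analysis relaxivity biases concentrations linearly.
#'
#' @param specific_activity MBq/mg.
#' @param relaxivity 1/s per mg/mL.
#' @param dose_factor Gy.kg/GBq.
#' @param tissue_density g/mL.
#' @return An object of class `dosimetry_constants`.
#' @export
dosimetry_constants <- function(specific_activity = 12, relaxivity = 90,
                                dose_factor = 15.87, tissue_density = 1.04) {
  v <- c(specific_activity, relaxivity, dose_factor, tissue_density)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stopf("all dosimetry constants must be positive")
  }
  structure(
    list(specific_activity = specific_activity, relaxivity = relaxivity,
         dose_factor = dose_factor, tissue_density = tissue_density),
    class = "dosimetry_constants")
}

#' Voxel-wise R2* estimation from a multi-echo series
#'
#' Per-voxel weighted least squares on `ln S` versus TE with weights
#' proportional to `S^2` (the first-order variance weighting for
#' log-transformed magnitude data); echoes at or below `noise_floor` are
#' excluded. Voxels with fewer than 3 usable echoes are marked invalid,
#' never silently zeroed. R2* is clipped to `[0, r2star_max]` as a
#' signal-void guard.
#'
#' @param series A `multi_echo_series` with at least 3 echoes.
#' @param noise_floor Signal level (a.u.) at or below which an echo is
#'   excluded from the fit.
#' @param r2star_max Upper clip, 1/s.
#' @param mask Optional logical array restricting the fit.
#' @return An object of class `r2star_map` with `volume_grid` fields
#'   `r2star` (1/s), `s0` (a.u.), `fit_quality` (weighted R^2), a logical
#'   `valid` lattice and a count `n_invalid`.
#' @export
fit_r2star <- function(series, noise_floor = 0, r2star_max = 2000,
                       mask = NULL) {
  stopifnot(inherits(series, "multi_echo_series"))
  te <- series$echo_times  # ms
  if (length(te) < 3L) stopf("need at least 3 echoes to fit R2*")
  d <- dim(series$data)[1:3]
  nv <- prod(d)
  S <- matrix(series$data, nrow = nv)
  if (!is.null(mask)) {
    fit_idx <- which(as.logical(mask))
  } else {
    fit_idx <- seq_len(nv)
  }
  Sf <- S[fit_idx, , drop = FALSE]

  w <- Sf^2
  w[Sf <= noise_floor] <- 0
  usable <- rowSums(w > 0)
  y <- log(pmax(Sf, .Machine$double.xmin))

  sw <- rowSums(w)
  swx <- as.numeric(w %*% te)
  swy <- rowSums(w * y)
  swxx <- as.numeric(w %*% te^2)
  swxy <- rowSums(w * sweep(y, 2, te, `*`))
  den <- sw * swxx - swx^2
  valid <- usable >= 3L & den > .Machine$double.eps * pmax(swxx, 1)
  slope <- rep(NA_real_, length(fit_idx))
  icept <- rep(NA_real_, length(fit_idx))
  slope[valid] <- (sw * swxy - swx * swy)[valid] / den[valid]
  icept[valid] <- (swy[valid] - slope[valid] * swx[valid]) / sw[valid]

  r2s <- -slope * 1000  # 1/ms -> 1/s
  r2s[valid] <- pmin(pmax(r2s[valid], 0), r2star_max)
  s0 <- exp(icept)

  # weighted R^2 of the log-linear fit
  ybar <- swy / pmax(sw, .Machine$double.xmin)
  yhat_res <- y - (icept + outer(slope, te))
  ss_res <- rowSums(w * yhat_res^2)
  ss_tot <- rowSums(w * (y - ybar)^2)
  fitq <- ifelse(valid & ss_tot > 0, 1 - ss_res / ss_tot,
                 ifelse(valid, 1, NA_real_))

  full <- function(vals) {
    a <- array(NA_real_, dim = d)
    a[fit_idx] <- vals
    a
  }
  valid_full <- array(FALSE, dim = d)
  valid_full[fit_idx] <- valid

  structure(
    list(r2star = volume_grid(full(r2s), series$spacing, series$origin,
                              role = "r2star"),
         s0 = volume_grid(full(s0), series$spacing, series$origin,
                          role = "signal"),
         fit_quality = volume_grid(full(fitq), series$spacing, series$origin),
         valid = valid_full,
         n_invalid = sum(!valid)),
    class = "r2star_map")
}

#' @export
print.r2star_map <- function(x, ...) {
  v <- x$r2star$values[x$valid]
  cat(sprintf("<r2star_map> %d valid voxels (%d invalid), R2* [%.3g, %.3g] 1/s\n",
              sum(x$valid), x$n_invalid,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Holmium concentration map from pre/post R2* maps
#'
#' `C = max(0, R2*_post - R2*_baseline) / relaxivity`. Noise-induced
#' negative deltas are clamped to zero and counted (`n_negative_delta` QC
#' attribute); voxels invalid in either input are invalid (NA) in the
#' output.
#'
#' @param post,baseline `r2star_map`s on identical geometry (post- and
#'   pre-administration).
#' @param constants A `dosimetry_constants`.
#' @return A `volume_grid` (mg/mL) with attributes `n_negative_delta` and
#'   `valid`.
#' @export
concentration_map <- function(post, baseline,
                              constants = dosimetry_constants()) {
  stopifnot(inherits(post, "r2star_map"), inherits(baseline, "r2star_map"))
  if (!identical(dim(post$r2star$values), dim(baseline$r2star$values)) ||
      !isTRUE(all.equal(post$r2star$spacing, baseline$r2star$spacing))) {
    stopf("geometry mismatch between post and baseline maps")
  }
  delta <- post$r2star$values - baseline$r2star$values
  valid <- post$valid & baseline$valid
  n_neg <- sum(delta < 0 & valid, na.rm = TRUE)
  C <- array(pmax(delta, 0) / constants$relaxivity, dim = dim(delta))
  C[!valid] <- NA_real_
  out <- volume_grid(C, post$r2star$spacing, post$r2star$origin,
                     role = "concentration")
  attr(out, "n_negative_delta") <- n_neg
  attr(out, "valid") <- valid
  out
}

#' Fictive absorbed-dose map from a concentration map
#'
#' Voxel activity is `a = C * SA` (MBq/mL); under the local-deposition model
#' the voxel dose is `D = k_Ho * a / rho` Gy (activity per tissue mass
#' `a / rho` in GBq/kg times the full-decay dose factor in Gy.kg/GBq). The
#' map is linear in concentration by construction.
#'
#' @param concentration A `volume_grid`, mg/mL, `>= 0` (NA = invalid).
#' @param constants A `dosimetry_constants`.
#' @param cumulative_fraction_index Optional provenance index.
#' @return An object of class `dose_map` (fields `dose` `volume_grid` in Gy,
#'   `constants`, `cumulative_fraction_index`).
#' @export
dose_map <- function(concentration, constants = dosimetry_constants(),
                     cumulative_fraction_index = NA_integer_) {
  stopifnot(inherits(concentration, "volume_grid"))
  C <- concentration$values
  if (any(C < 0, na.rm = TRUE)) stopf("concentration must be >= 0")
  D <- constants$dose_factor * (C * constants$specific_activity) /
    constants$tissue_density
  structure(
    list(dose = volume_grid(D, concentration$spacing, concentration$origin,
                            mask = concentration$mask, role = "dose"),
         constants = constants,
         cumulative_fraction_index = cumulative_fraction_index),
    class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  v <- x$dose$values[is.finite(x$dose$values)]
  cat(sprintf("<dose_map> mean %.3g Gy, max %.3g Gy\n", mean(v), max(v)))
  invisible(x)
}

#' Microsphere concentration corresponding to a target absorbed dose
#'
#' Exact inverse of the voxel dose law: `C = D * rho / (k_Ho * SA)`. Under
#' the default constants, 60 Gy corresponds to 0.33 mg/mL (the whole-liver
#' dose limit) and 300 Gy to 1.64 mg/mL (superselective single-lobe limit).
#'
#' @param target_dose Absorbed dose, Gy, `> 0`.
#' @param constants A `dosimetry_constants`.
#' @return Concentration, mg/mL.
#' @export
concentration_for_dose <- function(target_dose,
                                   constants = dosimetry_constants()) {
  if (any(!is.finite(target_dose)) || any(target_dose <= 0)) {
    stopf("target dose must be > 0")
  }
  target_dose * constants$tissue_density /
    (constants$dose_factor * constants$specific_activity)
}

#' Per-lobe dose summary
#'
#' One row per lobe 1-5 with mean dose, near-maximum D2%, near-minimum
#' D98% and lobe volume. An empty lobe yields a flagged NaN row and the run
#' continues.
#'
#' @param dose A `dose_map` (or dose `volume_grid`).
#' @param labels A `lobe_label_map` on the same geometry.
#' @return Data frame with columns lobe, name, n_voxel, volume_ml,
#'   mean_gy, d2_gy, d98_gy.
#' @export
lobe_dose_summary <- function(dose, labels) {
  dv <- if (inherits(dose, "dose_map")) dose$dose else dose
  stopifnot(inherits(dv, "volume_grid"), inherits(labels, "lobe_label_map"))
  if (!identical(dim(dv$values), dim(labels$labels))) {
    stopf("geometry mismatch between dose map and labels")
  }
  vv <- voxel_volume_ml(labels)
  rows <- lapply(1:5, function(l) {
    sel <- labels$labels == l
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("lobe %d is empty; summary flagged NaN", l),
              call. = FALSE)
      return(data.frame(lobe = l, name = unname(lobe_names()[l]),
                        n_voxel = 0L, volume_ml = 0,
                        mean_gy = NaN, d2_gy = NaN, d98_gy = NaN))
    }
    x <- dv$values[sel]
    x <- x[is.finite(x)]
    data.frame(lobe = l, name = unname(lobe_names()[l]), n_voxel = n,
               volume_ml = n * vv, mean_gy = mean(x),
               d2_gy = dose_percentile_values(x, 2),
               d98_gy = dose_percentile_values(x, 98))
  })
  do.call(rbind, rows)
}
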