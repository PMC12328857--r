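# Volumetric containers shared by all stages, plus NIfTI-1 I/O.
#
# Geometry convention: 0-based voxel indexing, axis order (x, y, z),
# voxel-center coordinates; `spacing` are voxel edge lengths in mm and
# `origin` is the physical position (mm) of voxel (0, 0, 0).

#' Construct a 3-D scalar volume
#'
#' `volume_grid` is the common currency of the pipeline: a 3-D scalar field
#' with voxel spacing, physical origin and an optional mask. The `role` tag
#' records what the values mean (`"signal"` a.u., `"dose"` Gy,
#' `"concentration"` mg/mL, `"r2star"` 1/s, `"hu"` HU).
#'
#' @param values Numeric 3-D array.
#' @param spacing Voxel edge lengths in mm, length 3, all `> 0`.
#' @param origin Physical offset (mm) of the first voxel, length 3.
#' @param mask Optional logical array of the same shape.
#' @param role Optional unit tag (character scalar).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        mask = NULL, role = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("'values' must be a 3-D array (got %s dims)",
          length(dim(values) %||% dim(as.array(values))))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("'spacing' must be three positive finite values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stopf("'origin' must be three finite values")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values))) {
      stopf("'mask' shape must equal 'values' shape")
    }
    mask <- array(as.logical(mask), dim = dim(values))
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         mask = mask, role = role),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %dx%dx%d voxels, spacing %s mm%s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              if (is.null(x$role)) "" else paste0(", role=", x$role)))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
  }
  if (!is.null(x$mask)) cat(sprintf("  mask: %d voxels\n", sum(x$mask)))
  invisible(x)
}

#' Volume of one voxel in millilitres
#' @param x A `volume_grid` or `lobe_label_map`.
#' @return Voxel volume in mL.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Five-lobe liver label map
#'
#' Integer labels 0 (background) and 1-5 for the porcine liver lobes:
#' 1 left lateral, 2 left medial, 3 right medial, 4 right lateral, 5 caudate.
#'
#' @param labels Integer 3-D array with values in `0:5`.
#' @param spacing,origin Geometry, as for [volume_grid()].
#' @return An object of class `lobe_label_map`.
#' @export
lobe_label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stopf("'labels' must be a 3-D array")
  }
  u <- sort(unique(as.integer(labels)))
  if (any(!u %in% 0:5)) {
    stopf("labels must be integers in 0..5 (found %s)",
          paste(setdiff(u, 0:5), collapse = ", "))
  }
  structure(
    list(labels = array(as.integer(labels), dim = dim(labels)),
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         names = lobe_names()),
    class = "lobe_label_map"
  )
}

#' Standard lobe numbering
#' @return Named character vector mapping label 1..5 to lobe name.
#' @export
lobe_names <- function() {
  c(`1` = "left lateral", `2` = "left medial", `3` = "right medial",
    `4` = "right lateral", `5` = "caudate")
}

#' @export
print.lobe_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lobe_label_map> %dx%dx%d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x")))
  vv <- voxel_volume_ml(x)
  for (l in 1:5) {
    n <- sum(x$labels == l)
    cat(sprintf("  lobe %d (%s): %d voxels, %.1f mL\n",
                l, x$names[[as.character(l)]], n, n * vv))
  }
  invisible(x)
}

#' Multi-echo gradient-echo series
#'
#' An echo-resolved stack of co-registered magnitude volumes. The default
#' acquisition has 10 echoes with TE1 = 1.7 ms and an echo spacing of
#' 1.35 ms.
#'
#' @param data Numeric 4-D array `(x, y, z, echo)`.
#' @param echo_times Echo times in ms, strictly increasing, one per echo.
#' @param spacing,origin Geometry, as for [volume_grid()].
#' @return An object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(data, echo_times, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stopf("'data' must be a 4-D array (x, y, z, echo)")
  }
  echo_times <- as.numeric(echo_times)
  if (dim(data)[4] != length(echo_times)) {
    stopf("echo-count mismatch: %d volumes but %d echo times",
          dim(data)[4], length(echo_times))
  }
  if (length(echo_times) && any(diff(echo_times) <= 0)) {
    stopf("echo times must be strictly increasing")
  }
  structure(
    list(data = data, echo_times = echo_times,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "multi_echo_series"
  )
}

#' Default multi-echo echo times (ms)
#' @param n_echoes Number of echoes.
#' @param te1 First echo time, ms.
#' @param delta_te Echo spacing, ms.
#' @return Numeric vector of echo times.
#' @export
default_echo_times <- function(n_echoes = 10L, te1 = 1.7, delta_te = 1.35) {
  te1 + delta_te * (seq_len(n_echoes) - 1)
}

#' Extract one echo of a multi-echo series as a volume
#' @param series A `multi_echo_series`.
#' @param i Echo index.
#' @return A `volume_grid` (signal, a.u.).
#' @export
get_echo <- function(series, i) {
  stopifnot(inherits(series, "multi_echo_series"))
  if (i < 1 || i > dim(series$data)[4]) stopf("echo index out of range")
  volume_grid(series$data[, , , i, drop = TRUE], series$spacing,
              series$origin, role = "signal")
}

#' @export
print.multi_echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_echo_series> %dx%dx%d voxels, %d echoes, TE %s ms\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$echo_times, 4), collapse = ", ")))
  invisible(x)
}

#' Dynamic (time-resolved) series
#'
#' A DCE-MRI frame stack; the default acquisition is 200 frames at a frame
#' interval of 0.86 s.
#'
#' @param data Numeric 4-D array `(x, y, z, frame)`.
#' @param frame_interval Frame interval in seconds, `> 0`.
#' @param spacing,origin Geometry, as for [volume_grid()].
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, frame_interval = 0.86, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stopf("'data' must be a 4-D array (x, y, z, frame)")
  }
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stopf("'frame_interval' must be > 0")
  }
  structure(
    list(data = data, frame_interval = as.numeric(frame_interval),
         n_frames = dim(data)[4],
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "dynamic_series"
  )
}

#' Frame acquisition times of a dynamic series
#'
#' Frame k is acquired at `(k - 1) * frame_interval` seconds, so the series
#' duration is `(n_frames - 1) * frame_interval` (171.14 s for 200 frames at
#' 0.86 s).
#'
#' @param series A `dynamic_series`.
#' @return Numeric vector of times in seconds.
#' @export
frame_times <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  (seq_len(series$n_frames) - 1) * series$frame_interval
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %dx%dx%d voxels, %d frames at %.3g s (duration %.2f s)\n",
    d[1], d[2], d[3], d[4], x$frame_interval, (d[4] - 1) * x$frame_interval))
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

.nifti_geometry <- function(img, ndim_expected) {
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  sp <- as.numeric(pd[seq_len(min(3L, length(pd)))])
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stopf("non-positive voxel spacing in NIfTI header: %s",
          paste(signif(sp, 4), collapse = ", "))
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  or <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  list(dim = d, spacing = sp, origin = or)
}

.as_nifti <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(spacing, rep(1, nd - 3L))
  RNifti::pixdim(img) <- pd
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(m, code = 2L))
}

#' Read a 3-D volume from a NIfTI file
#'
#' @param path Path to a NIfTI-1/2 file.
#' @param role Optional unit tag recorded on the returned volume
#'   (e.g. `"dose"`, `"concentration"`, `"hu"`).
#' @return A `volume_grid`.
#' @export
read_volume <- function(path, role = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stopf("expected 3-D volume, got %d-D payload in %s", length(dim(img)), path)
  }
  g <- .nifti_geometry(img, 3L)
  volume_grid(array(as.numeric(img), dim = g$dim), g$spacing, g$origin,
              role = role)
}

#' Write a volume (or label map) to a NIfTI file
#' @param x A `volume_grid` or `lobe_label_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "lobe_label_map")) x$labels else x$values
  RNifti::writeNifti(.as_nifti(arr, x$spacing, x$origin), path)
  invisible(path)
}

#' Read a lobe label map from a NIfTI file
#' @param path Path to a NIfTI file with integer labels 0..5.
#' @return A `lobe_label_map`.
#' @export
read_label_map <- function(path) {
  v <- read_volume(path, role = "labels")
  lobe_label_map(round(v$values), v$spacing, v$origin)
}

.read_sidecar <- function(sidecar) {
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  jsonlite::read_json(sidecar, simplifyVector = TRUE)
}

#' Read a multi-echo series (4-D NIfTI + JSON sidecar)
#'
#' The sidecar must contain `echo_times_ms`, one strictly increasing value
#' per volume along the 4th dimension.
#'
#' @param path_4d Path to the 4-D NIfTI file.
#' @param sidecar Path to the JSON sidecar.
#' @return A `multi_echo_series`.
#' @export
read_multiecho <- function(path_4d, sidecar) {
  if (!file.exists(path_4d)) stopf("file not found: %s", path_4d)
  img <- RNifti::readNifti(path_4d)
  if (length(dim(img)) != 4L) stopf("expected 4-D multi-echo payload")
  meta <- .read_sidecar(sidecar)
  te <- as.numeric(meta$echo_times_ms)
  if (length(te) != dim(img)[4]) {
    stopf("echo-count mismatch: file has %d volumes, sidecar %d echo times",
          dim(img)[4], length(te))
  }
  g <- .nifti_geometry(img, 4L)
  multi_echo_series(array(as.numeric(img), dim = g$dim), te, g$spacing, g$origin)
}

#' Write a multi-echo series (4-D NIfTI + JSON sidecar)
#' @param series A `multi_echo_series`.
#' @param path_4d Output NIfTI path.
#' @param sidecar Output JSON sidecar path (default: `path_4d` with `.json`).
#' @return `path_4d`, invisibly.
#' @export
write_multiecho <- function(series, path_4d,
                            sidecar = sub("\\.nii(\\.gz)?$", ".json", path_4d)) {
  RNifti::writeNifti(.as_nifti(series$data, series$spacing, series$origin),
                     path_4d)
  jsonlite::write_json(list(echo_times_ms = series$echo_times), sidecar,
                       digits = NA)
  invisible(path_4d)
}

#' Read a dynamic series (4-D NIfTI + JSON sidecar)
#'
#' The sidecar must contain `frame_interval_s`.
#'
#' @param path_4d Path to the 4-D NIfTI file.
#' @param sidecar Path to the JSON sidecar.
#' @return A `dynamic_series`.
#' @export
read_dynamic <- function(path_4d, sidecar) {
  if (!file.exists(path_4d)) stopf("file not found: %s", path_4d)
  img <- RNifti::readNifti(path_4d)
  if (length(dim(img)) != 4L) stopf("expected 4-D dynamic payload")
  meta <- .read_sidecar(sidecar)
  g <- .nifti_geometry(img, 4L)
  dynamic_series(array(as.numeric(img), dim = g$dim),
                 as.numeric(meta$frame_interval_s), g$spacing, g$origin)
}

#' Write a dynamic series (4-D NIfTI + JSON sidecar)
#' @param series A `dynamic_series`.
#' @param path_4d Output NIfTI path.
#' @param sidecar Output JSON sidecar path (default: `path_4d` with `.json`).
#' @return `path_4d`, invisibly.
#' @export
write_dynamic <- function(series, path_4d,
                          sidecar = sub("\\.nii(\\.gz)?$", ".json", path_4d)) {
  RNifti::writeNifti(.as_nifti(series$data, series$spacing, series$origin),
                     path_4d)
  jsonlite::write_json(list(frame_interval_s = series$frame_interval), sidecar,
                       digits = NA)
  invisible(path_4d)
}
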