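# Dose-distribution statistics (DVH percentiles, homogeneity index,
# HI-vs-cumulative-mass trajectories) and micro-CT vessel segmentation.

# Dp% on a plain numeric vector of masked doses: the dose exceeded by
# exactly p% of the voxels, i.e. the (100 - p)th percentile with linear
# interpolation between order statistics (stats::quantile type 7). All
# masked voxels, including zero dose, are included.
dose_percentile_values <- function(x, p) {
  if (!length(x)) stopf("empty mask")
  if (p <= 0 || p >= 100) stopf("p must be in (0, 100)")
  unname(stats::quantile(x, probs = (100 - p) / 100, type = 7, names = FALSE))
}

#' DVH dose percentile Dp%
#'
#' `Dp%` is the dose received by the hottest `p`% of the masked volume: the
#' `(100 - p)`th percentile of the masked voxel doses, with linear
#' interpolation between order statistics. All in-mask voxels enter,
#' zero-dose voxels included.
#'
#' @param dose A `dose_map` or dose `volume_grid`.
#' @param mask Optional logical array; defaults to the dose volume's own
#'   mask, else all finite voxels.
#' @param p Percent volume, in (0, 100); `p = 2` is the near-maximum D2%,
#'   `p = 98` the near-minimum D98%.
#' @return Dose in Gy.
#' @export
dose_percentile <- function(dose, mask = NULL, p = 2) {
  dv <- if (inherits(dose, "dose_map")) dose$dose else dose
  stopifnot(inherits(dv, "volume_grid"))
  mask <- mask %||% dv$mask
  x <- if (is.null(mask)) dv$values else dv$values[mask]
  x <- x[is.finite(x)]
  dose_percentile_values(x, p)
}

#' Dose statistics and homogeneity index
#'
#' Computes D2% (near maximum), D98% (near minimum), the mean dose and the
#' homogeneity index `HI = (D2% - D98%) / Dmean`. A lower HI represents a
#' more homogeneous dose distribution; HI is invariant under dose scaling.
#' A zero mean dose leaves HI undefined (NaN, flagged).
#'
#' @param dose A `dose_map` or dose `volume_grid`.
#' @param mask Optional logical array; defaults to the volume's own mask.
#' @return An object of class `dose_stats`: list with `d2`, `d98`, `dmean`,
#'   `hi`, `n_voxel`, `undefined`.
#' @export
homogeneity_index <- function(dose, mask = NULL) {
  dv <- if (inherits(dose, "dose_map")) dose$dose else dose
  stopifnot(inherits(dv, "volume_grid"))
  mask <- mask %||% dv$mask
  x <- if (is.null(mask)) dv$values else dv$values[mask]
  x <- x[is.finite(x)]
  if (!length(x)) stopf("empty mask")
  d2 <- dose_percentile_values(x, 2)
  d98 <- dose_percentile_values(x, 98)
  dmean <- mean(x)
  undefined <- dmean == 0
  hi <- if (undefined) NaN else (d2 - d98) / dmean
  structure(
    list(d2 = d2, d98 = d98, dmean = dmean, hi = hi,
         n_voxel = length(x), undefined = undefined),
    class = "dose_stats")
}

#' @export
print.dose_stats <- function(x, ...) {
  cat(sprintf(
    "<dose_stats> D2%% %.3g Gy, D98%% %.3g Gy, Dmean %.3g Gy, HI %.3g (n=%d)\n",
    x$d2, x$d98, x$dmean, x$hi, x$n_voxel))
  invisible(x)
}

#' Homogeneity-index trajectory over cumulative administered mass
#'
#' For a sequence of cumulative dose maps (one per administered fraction),
#' returns the administered microsphere concentration (cumulative delivered
#' mass per mL liver) against the HI of each cumulative map.
#'
#' @param dose_maps List of `dose_map`s (or dose `volume_grid`s), one per
#'   cumulative fraction, on identical geometry; at least 2.
#' @param schedule The `fraction_schedule` that produced them.
#' @param liver_volume_ml Liver volume, mL.
#' @param mask Optional logical array for the HI computation.
#' @return Data frame with columns mg_per_ml, hi, d2_gy, d98_gy, dmean_gy.
#' @export
hi_trajectory <- function(dose_maps, schedule, liver_volume_ml, mask = NULL) {
  if (length(dose_maps) < 2L) stopf("trajectory needs >= 2 points")
  stopifnot(inherits(schedule, "fraction_schedule"))
  if (length(dose_maps) != length(schedule$fractions)) {
    stopf("need one cumulative map per schedule fraction")
  }
  dims <- lapply(dose_maps, function(m) {
    dv <- if (inherits(m, "dose_map")) m$dose else m
    dim(dv$values)
  })
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stopf("inconsistent geometry across dose maps")
  }
  cum_mass <- cumsum(schedule$fractions) * (1 - schedule$residual_fraction)
  rows <- lapply(seq_along(dose_maps), function(i) {
    st <- homogeneity_index(dose_maps[[i]], mask = mask)
    data.frame(mg_per_ml = cum_mass[i] / liver_volume_ml, hi = st$hi,
               d2_gy = st$d2, d98_gy = st$d98, dmean_gy = st$dmean)
  })
  do.call(rbind, rows)
}

# ---- micro-CT segmentation -------------------------------------------------

#' Micro-CT segmentation parameters
#' @param threshold_hu Segmentation threshold, HU (default 350).
#' @param connectivity Neighbourhood order: 6, 18 or 26 (default 26, the
#'   standard choice for thin tubular structures).
#' @return An object of class `microct_params`.
#' @export
microct_params <- function(threshold_hu = 350, connectivity = 26L) {
  if (!is.finite(threshold_hu)) stopf("threshold must be finite")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stopf("connectivity must be 6, 18 or 26")
  }
  structure(list(threshold_hu = threshold_hu,
                 connectivity = as.integer(connectivity)),
            class = "microct_params")
}

.neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  if (connectivity == 6L) off <- off[ord == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[ord <= 2, , drop = FALSE]
  off
}

# Maximum Euclidean distance (mm) from a component's voxels to the nearest
# background voxel. A chamfer min-plus propagation on the padded bounding
# box gives a tight upper bound in O(radius) vectorised sweeps; the exact
# Euclidean maximum is then recovered by brute-force refinement of the
# near-maximal candidate voxels against the background surface set. Voxels
# outside the array count as background (samples are cut blocks).
.component_max_edt <- function(coord, mask, spacing) {
  d <- dim(mask)
  lo <- pmax(apply(coord, 2, min) - 1L, 1L)
  hi <- pmin(apply(coord, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sd3 <- dim(sub)
  pd <- sd3 + 2L                     # one-voxel background pad on all sides
  fg <- array(FALSE, dim = pd)
  fg[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- sub
  off <- .neighbour_offsets(26L)
  w <- sqrt(colSums((t(off) * spacing)^2))

  shift_min <- function(dist, o, wk) {
    s1 <- pmax(1L, 1L - o[1]):pmin(pd[1], pd[1] - o[1])
    s2 <- pmax(1L, 1L - o[2]):pmin(pd[2], pd[2] - o[2])
    s3 <- pmax(1L, 1L - o[3]):pmin(pd[3], pd[3] - o[3])
    dist[s1 + o[1], s2 + o[2], s3 + o[3]] <-
      pmin(dist[s1 + o[1], s2 + o[2], s3 + o[3]], dist[s1, s2, s3] + wk)
    dist
  }
  dist <- array(0, dim = pd)
  dist[fg] <- Inf
  repeat {
    prev <- dist
    for (k in seq_len(nrow(off))) dist <- shift_min(dist, off[k, ], w[k])
    if (all(prev[fg] == dist[fg])) break
  }

  # component voxel positions inside the padded box
  cpos <- sweep(coord, 2, lo - 2L)
  cd <- dist[cpos]
  best_chamfer <- max(cd)
  if (!is.finite(best_chamfer) || best_chamfer == 0) return(best_chamfer)

  # exact refinement: only candidates whose chamfer bound could still win
  cand <- cpos[cd >= 0.9 * best_chamfer, , drop = FALSE]
  near_fg <- array(FALSE, dim = pd)
  for (k in seq_len(nrow(off))) {
    o <- off[k, ]
    s1 <- pmax(1L, 1L - o[1]):pmin(pd[1], pd[1] - o[1])
    s2 <- pmax(1L, 1L - o[2]):pmin(pd[2], pd[2] - o[2])
    s3 <- pmax(1L, 1L - o[3]):pmin(pd[3], pd[3] - o[3])
    near_fg[s1 + o[1], s2 + o[2], s3 + o[3]] <-
      near_fg[s1 + o[1], s2 + o[2], s3 + o[3]] | fg[s1, s2, s3]
  }
  surf <- which(!fg & near_fg, arr.ind = TRUE)
  if (!nrow(surf)) return(best_chamfer)
  cand_mm <- sweep(cand, 2, spacing, `*`)
  surf_mm <- sweep(surf, 2, spacing, `*`)
  d2 <- outer(rowSums(cand_mm^2), rowSums(surf_mm^2), `+`) -
    2 * cand_mm %*% t(surf_mm)
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}

#' Threshold segmentation of a micro-CT volume
#'
#' Applies the HU threshold (`mask = volume >= threshold`), labels connected
#' components at the stated connectivity, and estimates a radius per
#' component as the maximum of the Euclidean distance transform (distance to
#' the nearest background voxel, in mm).
#'
#' @param volume A `volume_grid` in HU.
#' @param params A `microct_params`.
#' @param min_voxels Discard components smaller than this (noise specks).
#' @return List with `mask` (logical array), `labels` (integer array of
#'   component ids) and `components` (data frame: component, n_voxel,
#'   volume_mm3, radius_mm). An empty mask yields an empty table, no error.
#' @export
segment_microct <- function(volume, params = microct_params(),
                            min_voxels = 2L) {
  stopifnot(inherits(volume, "volume_grid"))
  mask <- volume$values >= params$threshold_hu
  d <- dim(mask)
  labs <- array(0L, dim = d)
  comp_tab <- data.frame(component = integer(0), n_voxel = integer(0),
                         volume_mm3 = numeric(0), radius_mm = numeric(0))
  fg <- which(mask)
  if (length(fg)) {
    # connected components: igraph over the foreground adjacency
    pos <- arrayInd(fg, .dim = d)
    lut <- array(0L, dim = d)
    lut[fg] <- seq_along(fg)
    off <- .neighbour_offsets(params$connectivity)
    edges <- list()
    for (k in seq_len(nrow(off))) {
      nb <- sweep(pos, 2, off[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(ok)) next
      nb_id <- lut[nb[ok, , drop = FALSE]]
      src <- seq_along(fg)[ok]
      keep <- nb_id > 0 & nb_id > src   # each edge once
      if (any(keep)) edges[[length(edges) + 1L]] <- cbind(src[keep], nb_id[keep])
    }
    g <- igraph::graph_from_edgelist(
      if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    cl <- igraph::components(g)$membership
    labs[fg] <- cl

    vv_mm3 <- prod(volume$spacing)
    keep_ids <- which(tabulate(cl) >= min_voxels)
    rows <- lapply(keep_ids, function(id) {
      coord <- pos[cl == id, , drop = FALSE]
      data.frame(component = id, n_voxel = nrow(coord),
                 volume_mm3 = nrow(coord) * vv_mm3,
                 radius_mm = .component_max_edt(coord, mask, volume$spacing))
    })
    if (length(rows)) comp_tab <- do.call(rbind, rows)
  }
  list(mask = mask, labels = labs, components = comp_tab)
}
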