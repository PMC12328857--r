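# Arterial-tree growth and flow-rate-dependent microsphere deposition.
#
# The tree is a mechanistic stand-in for the hepatic artery's division into
# five lobar branches: each lobe gets a space-filling binary tree grown by
# recursive bisection of its voxel set, with Murray-type radii
# (r_parent^3 = sum r_child^3) and flow fractions proportional to r^3.

#' Grow a space-filling arterial tree inside a lobe
#'
#' Recursively bisects the lobe's voxel cloud (2-means) down to the requested
#' number of generations. Child radii follow a Murray-type rule
#' `r_child = r_parent * f^(1/3)` where `f` is the child's flow fraction
#' (its share of downstream voxels), so flow fractions at each bifurcation
#' are proportional to `r^3` and sum to 1. Terminal territories are the
#' nearest-terminal (Euclidean) partition of the lobe mask.
#'
#' @param lobe_mask Logical 3-D array selecting the lobe's voxels.
#' @param spacing Voxel edge lengths, mm.
#' @param generations Number of generations (root segment is generation 1);
#'   a complete tree has `2^(generations - 1)` terminals. Must be `>= 2`.
#' @param seed Integer seed.
#' @param root_radius_mm Radius of the lobar root segment, mm.
#' @param entry_point Physical point (mm) the root enters from; defaults to
#'   the lobe boundary voxel nearest the grid centre (a hilum stand-in).
#' @param min_terminal_voxels Stop splitting below this territory size;
#'   branches that stop early reduce the local generation count (warning).
#' @return An object of class `arterial_tree` with `segments` (data frame),
#'   `territories` (list of voxel index vectors per terminal segment id),
#'   and `terminal_flow` (path flow fraction per terminal).
#' @export
grow_arterial_tree <- function(lobe_mask, spacing = c(2, 2, 2),
                               generations = 7L, seed = 1L,
                               root_radius_mm = 1.0, entry_point = NULL,
                               min_terminal_voxels = 4L) {
  if (generations < 2L) stopf("generations must be >= 2")
  idx <- which(lobe_mask)
  if (length(idx) < 2L * min_terminal_voxels) {
    stopf("lobe mask too small to grow a tree")
  }
  d <- dim(lobe_mask)
  co <- voxel_coords(d, spacing, mask = lobe_mask)

  with_seed(substream_seed(seed, "tree"), {
    if (is.null(entry_point)) entry_point <- (d - 1) * spacing / 2
    root_start <- co[which.min(colSums((t(co) - entry_point)^2)), ]

    env <- new.env()
    env$rows <- list()
    env$truncated <- FALSE

    grow <- function(sub, gen, parent, start, radius, flow_frac) {
      id <- length(env$rows) + 1L
      endp <- colMeans(co[sub, , drop = FALSE])
      n <- length(sub)
      can_split <- gen < generations && n >= 2L * min_terminal_voxels &&
        nrow(unique(co[sub, , drop = FALSE])) >= 2L
      if (!can_split && gen < generations) env$truncated <- TRUE
      env$rows[[id]] <- data.frame(
        id = id, parent = parent, gen = gen, radius = radius,
        flow_frac = flow_frac, terminal = !can_split,
        sx = start[1], sy = start[2], sz = start[3],
        ex = endp[1], ey = endp[2], ez = endp[3], n_voxel = n)
      if (can_split) {
        km <- suppressWarnings(
          stats::kmeans(co[sub, , drop = FALSE], centers = 2L,
                        nstart = 2L, iter.max = 25L))
        s1 <- sub[km$cluster == 1L]
        s2 <- sub[km$cluster == 2L]
        if (!length(s1) || !length(s2)) {
          env$rows[[id]]$terminal <- TRUE
          return(invisible(id))
        }
        f1 <- length(s1) / n
        grow(s1, gen + 1L, id, endp, radius * f1^(1 / 3), f1)
        grow(s2, gen + 1L, id, endp, radius * (1 - f1)^(1 / 3), 1 - f1)
      }
      invisible(id)
    }
    grow(seq_along(idx), 1L, 0L, root_start, root_radius_mm, 1)
    if (env$truncated) {
      warning("lobe too small for requested generations; some branches stop early",
              call. = FALSE)
    }
    seg <- do.call(rbind, env$rows)

    term <- seg[seg$terminal, ]
    tp <- as.matrix(term[, c("ex", "ey", "ez")])
    # nearest-terminal partition of the lobe mask
    nearest <- max.col(-sapply(seq_len(nrow(tp)),
                               function(k) colSums((t(co) - tp[k, ])^2)),
                       ties.method = "first")
    territories <- split(idx, factor(term$id[nearest], levels = term$id))

    # path flow fraction of each terminal = product of conditional fractions
    pf <- function(i) {
      f <- 1
      while (i != 0L) {
        f <- f * seg$flow_frac[i]
        i <- seg$parent[i]
      }
      f
    }
    terminal_flow <- vapply(term$id, pf, numeric(1))
    names(terminal_flow) <- term$id

    children <- split(seg$id, factor(seg$parent, levels = seg$id))

    structure(
      list(segments = seg, territories = territories,
           terminal_flow = terminal_flow, children = children,
           dim = d, spacing = spacing, voxel_idx = idx),
      class = "arterial_tree")
  })
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat(sprintf(
    "<arterial_tree> %d segments, %d terminals, max generation %d\n",
    nrow(x$segments), sum(x$segments$terminal), max(x$segments$gen)))
  invisible(x)
}

# Voxel linear indices along a segment's centreline (start -> end), snapped
# to the grid; used to paint non-terminal lodged mass.
segment_centreline_idx <- function(tree, seg_row) {
  p0 <- c(seg_row$sx, seg_row$sy, seg_row$sz)
  p1 <- c(seg_row$ex, seg_row$ey, seg_row$ez)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / min(tree$spacing) * 2))
  t <- seq(0, 1, length.out = n)
  pts <- outer(t, p1 - p0) + rep(p0, each = n)
  ijk <- round(sweep(pts, 2, tree$spacing, "/")) + 1
  ijk[, 1] <- pmin(pmax(ijk[, 1], 1), tree$dim[1])
  ijk[, 2] <- pmin(pmax(ijk[, 2], 1), tree$dim[2])
  ijk[, 3] <- pmin(pmax(ijk[, 3], 1), tree$dim[3])
  unique((ijk[, 3] - 1) * tree$dim[1] * tree$dim[2] +
           (ijk[, 2] - 1) * tree$dim[1] + ijk[, 1])
}

# Mixing/streamline-bias child-selection probabilities at one bifurcation.
# f: flow fractions of the children (sum 1); gamma: streamline-bias exponent.
.routing_probs <- function(f, mixing, gamma) {
  g <- f^gamma
  g <- g / sum(g)
  p <- mixing * f + (1 - mixing) * g
  p / sum(p)
}

#' Simulate flow-dependent microsphere deposition
#'
#' Routes packets of microspheres from a common root through the five lobar
#' trees. At every bifurcation (including the root split into lobes) a packet
#' takes child `c` with probability `mixing * f_c + (1 - mixing) * g_c`,
#' where `f_c` is the child's flow fraction and `g_c = f_c^gamma / sum f^gamma`
#' is a streamline-bias term concentrating poorly mixed spheres in
#' high-flow branches. Before each bifurcation the packet lodges in the
#' current segment with probability
#' `lambda * (1 - mixing) * exp(-gen / tau_g)`; packets reaching a terminal
#' lodge there. Lodged mass is rasterised to a voxel concentration map:
#' terminal mass is spread over the terminal's territory and blurred
#' (Gaussian, `blur_sigma` voxels), non-terminal mass is painted along the
#' segment centreline; total mass inside the liver mask is conserved exactly
#' per fraction.
#'
#' Packets are routed with binomial/multinomial draws (distributionally
#' identical to independent per-packet walks), so mass conservation is exact
#' by construction.
#'
#' @param labels A `lobe_label_map`.
#' @param trees List of five `arterial_tree`s (lobes 1-5).
#' @param schedule A `fraction_schedule`.
#' @param condition A `flow_condition` (supplies `mixing`).
#' @param spheres A `microsphere_spec`.
#' @param seed Integer seed.
#' @param lobe_perfusion_fraction Ground-truth lobe flow fractions (length 5,
#'   sums to 1); default proportional to lobe volumes.
#' @param n_packets Packets per fraction.
#' @param gamma Streamline-bias exponent.
#' @param lambda Proximal-lodging rate scale.
#' @param tau_g Generation decay constant of proximal lodging.
#' @param capacity_coeff Per-segment capacity in mg per mm^3 of `radius^3`;
#'   `Inf` (default) disables capacity. Overflow is redistributed upstream;
#'   overflow at a lobar root raises a stasis error.
#' @param blur_sigma Gaussian blur of terminal mass, voxels.
#' @param territory_tau_mm Length scale (mm) of the within-territory
#'   deposition-density gradient: voxel weights fall as
#'   `exp(-distance to the feeding terminal / territory_tau_mm)`, emulating
#'   denser sphere trapping near the feeding arteriole than at the
#'   territory periphery. `Inf` spreads terminal mass uniformly.
#' @return An object of class `phantom_truth`.
#' @export
simulate_deposition <- function(labels, trees, schedule, condition,
                                spheres = microsphere_spec(), seed = 1L,
                                lobe_perfusion_fraction = NULL,
                                n_packets = 10000L, gamma = 3, lambda = 0.35,
                                tau_g = 2, capacity_coeff = Inf,
                                blur_sigma = 1, territory_tau_mm = 1.5) {
  stopifnot(inherits(labels, "lobe_label_map"),
            inherits(schedule, "fraction_schedule"),
            inherits(condition, "flow_condition"))
  if (length(trees) != 5L || !all(vapply(trees, inherits, TRUE, "arterial_tree"))) {
    stopf("trees must be a list of five arterial_tree objects (lobes 1-5)")
  }
  vols <- lobe_volumes(labels)$n_voxel
  if (any(vols == 0)) stopf("trees must cover all 5 lobes (a lobe is empty)")
  F_lobe <- lobe_perfusion_fraction %||% (vols / sum(vols))
  if (length(F_lobe) != 5L || any(F_lobe < 0)) {
    stopf("lobe_perfusion_fraction must be 5 non-negative values")
  }
  F_lobe <- F_lobe / sum(F_lobe)
  mixing <- condition$mixing
  d <- dim(labels$labels)
  liver <- labels$labels > 0L
  vv_ml <- voxel_volume_ml(labels)
  n_frac <- length(schedule$fractions)

  # per-lobe segment count and lodged-count matrices
  counts <- lapply(trees, function(tr) {
    matrix(0, nrow = nrow(tr$segments), ncol = n_frac)
  })
  centrelines <- lapply(trees, function(tr) {
    seg <- tr$segments
    lapply(seq_len(nrow(seg)), function(i) {
      if (seg$terminal[i]) NULL else segment_centreline_idx(tr, seg[i, ])
    })
  })
  # within-territory deposition-density weights (sum 1 per territory)
  territory_w <- lapply(trees, function(tr) {
    seg <- tr$segments
    co_all <- voxel_coords(tr$dim, tr$spacing)
    lapply(names(tr$territories), function(id) {
      vox <- tr$territories[[id]]
      if (!is.finite(territory_tau_mm)) {
        return(rep(1 / length(vox), length(vox)))
      }
      i <- match(as.integer(id), seg$id)
      endp <- c(seg$ex[i], seg$ey[i], seg$ez[i])
      dmm <- sqrt(colSums((t(co_all[vox, , drop = FALSE]) - endp)^2))
      w <- exp(-dmm / territory_tau_mm)
      w / sum(w)
    })
  })

  route_lobe <- function(tr, n_in, cnt) {
    # iterative depth-first routing with stack of (segment id, packets)
    seg <- tr$segments
    stack <- list(c(1L, n_in))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- top[1]; n <- top[2]
      if (n <= 0) next
      if (seg$terminal[i]) {
        cnt[i] <- cnt[i] + n
        next
      }
      p_lodge <- min(1, lambda * (1 - mixing) * exp(-seg$gen[i] / tau_g))
      n_lodge <- stats::rbinom(1L, n, p_lodge)
      cnt[i] <- cnt[i] + n_lodge
      n_go <- n - n_lodge
      if (n_go <= 0) next
      kids <- tr$children[[as.character(seg$id[i])]]
      f <- seg$flow_frac[kids]
      split <- as.integer(stats::rmultinom(1L, n_go,
                                           .routing_probs(f, mixing, gamma)))
      for (k in seq_along(kids)) {
        if (split[k] > 0) stack[[length(stack) + 1L]] <- c(kids[k], split[k])
      }
    }
    cnt
  }

  frac_mass_arrays <- vector("list", n_frac)

  with_seed(substream_seed(seed, "deposition"), {
    for (fr in seq_len(n_frac)) {
      mass_fr <- schedule$fractions[fr] * (1 - schedule$residual_fraction)
      packet_mass <- mass_fr / n_packets
      p_root <- .routing_probs(F_lobe, mixing, gamma)
      n_lobe <- as.integer(stats::rmultinom(1L, n_packets, p_root))
      for (l in 1:5) {
        cnt <- numeric(nrow(trees[[l]]$segments))
        cnt <- route_lobe(trees[[l]], n_lobe[l], cnt)
        counts[[l]][, fr] <- cnt
      }

      if (is.finite(capacity_coeff)) {
        for (l in 1:5) {
          seg <- trees[[l]]$segments
          cap <- capacity_coeff * seg$radius^3 / packet_mass
          # push overflow upstream, deepest segments first
          ord <- order(seg$gen, decreasing = TRUE)
          for (i in ord) {
            excess <- counts[[l]][i, fr] - cap[i]
            if (excess > 0) {
              counts[[l]][i, fr] <- cap[i]
              if (seg$parent[i] == 0L) {
                stopf("stasis: capacity exhausted at the root of lobe %d", l)
              }
              counts[[l]][seg$parent[i], fr] <-
                counts[[l]][seg$parent[i], fr] + excess
            }
          }
        }
      }

      # rasterise this fraction
      arr <- array(0, dim = d)
      for (l in 1:5) {
        tr <- trees[[l]]
        seg <- tr$segments
        cnt <- counts[[l]][, fr]
        term_ids <- names(tr$territories)
        for (i in which(cnt > 0)) {
          m <- cnt[i] * packet_mass
          if (seg$terminal[i]) {
            k <- match(as.character(seg$id[i]), term_ids)
            vox <- tr$territories[[k]]
            arr[vox] <- arr[vox] + m * territory_w[[l]][[k]]
          } else {
            vox <- centrelines[[l]][[i]]
            arr[vox] <- arr[vox] + m / length(vox)
          }
        }
      }
      total <- sum(arr)
      if (blur_sigma > 0 && total > 0) {
        arr <- gaussian_blur3(arr, blur_sigma)
      }
      # conserve mass inside the liver mask
      arr[!liver] <- 0
      s <- sum(arr)
      if (s > 0) arr <- arr * (total / s)
      frac_mass_arrays[[fr]] <- arr
    }
  })

  # cumulative concentration maps, mg/mL
  cum <- array(0, dim = d)
  true_concentration <- vector("list", n_frac)
  for (fr in seq_len(n_frac)) {
    cum <- cum + frac_mass_arrays[[fr]]
    true_concentration[[fr]] <- volume_grid(cum / vv_ml, labels$spacing,
                                            labels$origin, mask = liver,
                                            role = "concentration")
  }

  packet_masses <- schedule$fractions * (1 - schedule$residual_fraction) /
    n_packets
  deposited <- lapply(1:5, function(l) {
    sweep(counts[[l]], 2, packet_masses, "*")
  })

  seg_all <- do.call(rbind, lapply(1:5, function(l) {
    cbind(lobe = l, trees[[l]]$segments)
  }))

  structure(
    list(label_map = labels, trees = trees, condition = condition,
         schedule = schedule, spheres = spheres,
         lobe_perfusion_fraction = F_lobe,
         deposited_mass = deposited, segments = seg_all,
         true_concentration = true_concentration,
         params = list(n_packets = n_packets, gamma = gamma, lambda = lambda,
                       tau_g = tau_g, capacity_coeff = capacity_coeff,
                       blur_sigma = blur_sigma,
                       territory_tau_mm = territory_tau_mm, seed = seed)),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %s condition (mixing %.2f), %d fractions, %.0f mg delivered\n",
    x$condition$name, x$condition$mixing, length(x$schedule$fractions),
    delivered_mass(x$schedule)))
  cat(sprintf("  lobe deposited mass (mg): %s\n",
              paste(sprintf("%.0f", deposited_mass_by_lobe(x)), collapse = ", ")))
  invisible(x)
}

#' Total deposited mass per lobe (mg)
#' @param truth A `phantom_truth`.
#' @param fractions Which fractions to include (default all).
#' @return Numeric vector of length 5.
#' @export
deposited_mass_by_lobe <- function(truth, fractions = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  fractions <- fractions %||% seq_len(ncol(truth$deposited_mass[[1]]))
  vapply(truth$deposited_mass,
         function(m) sum(m[, fractions, drop = FALSE]), numeric(1))
}

#' Fraction of deposited mass lodged in the stated generations
#' @param truth A `phantom_truth`.
#' @param generations Generation numbers to count (default 1:3, the proximal
#'   large-vessel compartment).
#' @return Mass fraction in `[0, 1]`.
#' @export
mass_fraction_in_generations <- function(truth, generations = 1:3) {
  stopifnot(inherits(truth, "phantom_truth"))
  tot <- 0
  prox <- 0
  for (l in 1:5) {
    m <- rowSums(truth$deposited_mass[[l]])
    gen <- truth$trees[[l]]$segments$gen
    tot <- tot + sum(m)
    prox <- prox + sum(m[gen %in% generations])
  }
  prox / tot
}

#' Mass-weighted mean generation of lodged microspheres
#' @param truth A `phantom_truth`.
#' @return Mean lodged-segment generation.
#' @export
mean_lodged_generation <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  num <- 0
  den <- 0
  for (l in 1:5) {
    m <- rowSums(truth$deposited_mass[[l]])
    num <- num + sum(m * truth$trees[[l]]$segments$gen)
    den <- den + sum(m)
  }
  num / den
}
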