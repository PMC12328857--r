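# DCE-MRI perfusion analysis: per-lobe time-intensity curves, the printed
# percent-enhancement transform, maximum wash-in slope, relative perfusion.

#' Extract per-lobe time-intensity curves from a dynamic series
#'
#' `s0_lobe` is the mean signal over the lobe's voxels and the baseline
#' (pre-contrast) frames; `s_t` is the lobe-mean signal per frame.
#'
#' @param series A `dynamic_series`.
#' @param labels A `lobe_label_map` on the same grid.
#' @param baseline_frames Number of leading pre-contrast frames (default 10,
#'   must be `>= 1` and `< n_frames`).
#' @return A list of 5 `time_intensity_curve` objects (fields `lobe`,
#'   `s0_lobe`, `s_t`, `times`, `frame_interval`).
#' @export
extract_tic <- function(series, labels, baseline_frames = 10L) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(labels, "lobe_label_map"))
  if (!identical(dim(series$data)[1:3], dim(labels$labels))) {
    stopf("geometry mismatch between series and labels")
  }
  if (baseline_frames < 1L) stopf("baseline_frames must be >= 1")
  if (baseline_frames >= series$n_frames) {
    stopf("baseline_frames must be < n_frames")
  }
  nv <- prod(dim(labels$labels))
  S <- matrix(series$data, nrow = nv)
  times <- frame_times(series)
  lapply(1:5, function(l) {
    sel <- which(labels$labels == l)
    if (!length(sel)) {
      stopf("lobe %d (%s) is empty", l, lobe_names()[[as.character(l)]])
    }
    s_t <- colMeans(S[sel, , drop = FALSE])
    structure(
      list(lobe = l, s0_lobe = mean(s_t[seq_len(baseline_frames)]),
           s_t = s_t, times = times,
           frame_interval = series$frame_interval,
           baseline_frames = baseline_frames),
      class = "time_intensity_curve")
  })
}

#' @export
print.time_intensity_curve <- function(x, ...) {
  cat(sprintf("<time_intensity_curve> lobe %d, %d frames, S0 = %.4g a.u.\n",
              x$lobe, length(x$s_t), x$s0_lobe))
  invisible(x)
}

#' Percent-enhancement transform of a time-intensity curve
#'
#' The printed convention normalises by the post-injection signal:
#' `PE = 100 * (S1 - S0) / S1`. The conventional baseline-normalised form
#' `100 * (S1 - S0) / S0` is available via `denominator = "baseline"` for
#' sensitivity analysis; the printed form is the default. Frames with
#' non-positive denominator are flagged undefined (NA).
#'
#' @param tic A `time_intensity_curve`.
#' @param denominator `"post"` (printed form, default) or `"baseline"`.
#' @return A `pe_curve`: list with `pe_t` (percent per frame), `times`,
#'   `frame_interval`, `undefined_frames`.
#' @export
percent_enhancement <- function(tic, denominator = c("post", "baseline")) {
  stopifnot(inherits(tic, "time_intensity_curve"))
  denominator <- match.arg(denominator)
  den <- if (denominator == "post") tic$s_t else rep(tic$s0_lobe,
                                                     length(tic$s_t))
  bad <- !(den > 0)
  pe <- 100 * (tic$s_t - tic$s0_lobe) / den
  pe[bad] <- NA_real_
  structure(
    list(lobe = tic$lobe, pe_t = pe, times = tic$times,
         frame_interval = tic$frame_interval,
         undefined_frames = which(bad), denominator = denominator),
    class = "pe_curve")
}

#' Maximum wash-in slope of a percent-enhancement curve
#'
#' The wash-in window runs from the last frame with PE below
#' `window_lo` of the curve maximum to the first frame attaining
#' `window_hi` of the maximum. The slope is estimated by sliding-window
#' linear regression (default width 5 frames) inside that window; the
#' maximum fitted slope is returned in %/s. A flat curve (max PE at or
#' below `flat_threshold`) returns slope 0 with a `"non-enhancing"` flag.
#'
#' @param pe A `pe_curve` (or plain numeric PE vector).
#' @param frame_interval Frame interval, s (taken from `pe` when absent).
#' @param window Sliding regression width, frames.
#' @param window_lo,window_hi Wash-in window bounds as fractions of the
#'   curve maximum (defaults 0.05 and 0.95).
#' @param flat_threshold Maximum PE (percent) at or below which the curve is
#'   flagged non-enhancing.
#' @return List with `max_slope` (%/s), `window` (frame index range),
#'   `flag` (`NA` or `"non-enhancing"`).
#' @export
max_washin_slope <- function(pe, frame_interval = NULL, window = 5L,
                             window_lo = 0.05, window_hi = 0.95,
                             flat_threshold = 1) {
  if (inherits(pe, "pe_curve")) {
    frame_interval <- frame_interval %||% pe$frame_interval
    pe <- pe$pe_t
  }
  if (is.null(frame_interval)) stopf("frame_interval required")
  ok <- is.finite(pe)
  if (!any(ok)) stopf("curve contains no defined frames")
  pemax <- max(pe[ok])
  if (pemax <= flat_threshold) {
    return(list(max_slope = 0, window = c(NA_integer_, NA_integer_),
                flag = "non-enhancing"))
  }
  below <- which(ok & pe < window_lo * pemax)
  at_hi <- which(ok & pe >= window_hi * pemax)
  i0 <- if (length(below)) max(below) else 1L
  i1 <- if (length(at_hi)) min(at_hi) else length(pe)
  if (i1 <= i0) i1 <- min(length(pe), i0 + 1L)
  w <- max(2L, as.integer(window))
  lo <- max(1L, i0 - (w - 1L))        # windows overlapping the wash-in
  hi <- min(length(pe), i1 + (w - 1L))
  t <- (seq_along(pe) - 1) * frame_interval
  best <- -Inf
  for (s in lo:(hi - w + 1L)) {
    sl <- s:(s + w - 1L)
    if (any(!ok[sl])) next
    fit_t <- t[sl]
    fit_y <- pe[sl]
    b <- stats::cov(fit_t, fit_y) / stats::var(fit_t)
    if (b > best) best <- b
  }
  if (!is.finite(best)) stopf("no usable regression window in wash-in")
  list(max_slope = best, window = c(i0, i1), flag = NA_character_)
}

#' Relative perfusion fractions from per-lobe slopes
#'
#' `fraction_l = slope_l / sum(slopes)`; requires at least one positive
#' slope.
#'
#' @param slopes Per-lobe maximum wash-in slopes, %/s, non-negative.
#' @return Numeric vector of fractions summing to 1.
#' @export
relative_perfusion <- function(slopes) {
  slopes <- as.numeric(slopes)
  if (any(!is.finite(slopes)) || any(slopes < 0)) {
    stopf("slopes must be finite and non-negative")
  }
  if (sum(slopes) <= 0) stopf("all slopes are zero")
  slopes / sum(slopes)
}

#' Per-lobe perfusion analysis of a dynamic series
#'
#' Convenience wrapper: extracts lobe time-intensity curves, applies the
#' percent-enhancement transform, takes each lobe's maximum wash-in slope
#' as its perfusion rate and normalises to relative perfusion fractions.
#'
#' @inheritParams extract_tic
#' @inheritParams percent_enhancement
#' @inheritParams max_washin_slope
#' @return An object of class `perfusion_result`: list with `max_slope`
#'   (per-lobe, %/s), `relative_perfusion`, `flags`, `windows` and the
#'   `pe_curves`.
#' @export
analyze_perfusion <- function(series, labels, baseline_frames = 10L,
                              denominator = c("post", "baseline"),
                              window = 5L, window_lo = 0.05,
                              window_hi = 0.95, flat_threshold = 1) {
  denominator <- match.arg(denominator)
  tics <- extract_tic(series, labels, baseline_frames)
  pes <- lapply(tics, percent_enhancement, denominator = denominator)
  fits <- lapply(pes, max_washin_slope, window = window,
                 window_lo = window_lo, window_hi = window_hi,
                 flat_threshold = flat_threshold)
  slopes <- vapply(fits, `[[`, numeric(1), "max_slope")
  structure(
    list(max_slope = slopes,
         relative_perfusion = relative_perfusion(slopes),
         flags = vapply(fits, `[[`, character(1), "flag"),
         windows = lapply(fits, `[[`, "window"),
         pe_curves = pes, tics = tics),
    class = "perfusion_result")
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat("<perfusion_result>\n")
  for (l in 1:5) {
    cat(sprintf("  lobe %d: max slope %.4g %%/s, relative %.3f%s\n",
                l, x$max_slope[l], x$relative_perfusion[l],
                if (is.na(x$flags[l])) "" else paste0(" [", x$flags[l], "]")))
  }
  invisible(x)
}
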