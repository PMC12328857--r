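# Internal helpers: reproducible substreams, logging, small numerics.

# Named substream offsets so every stage draws from its own deterministic
# stream derived from the single top-level seed.
.substreams <- c(
  phantom = 1L, tree = 2L, deposition = 3L, noise = 4L,
  dce = 5L, microct = 6L, misc = 7L
)

#' Derive a substream seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams, so each stage is individually reproducible.
#'
#' @param seed Integer top-level seed.
#' @param stream Substream name, one of `"phantom"`, `"tree"`, `"deposition"`,
#'   `"noise"`, `"dce"`, `"microct"`, `"misc"`.
#' @return An integer seed below `2^31`.
#' @export
substream_seed <- function(seed, stream = "misc") {
  stream <- match.arg(stream, names(.substreams))
  offset <- .substreams[[stream]]
  as.integer((as.numeric(seed) %% 1e6 + offset * 1000003 + 17) %% 2147483629)
}

# Evaluate expr with a locally set RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

log_stage <- function(verbose, stage, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# Voxel-center coordinates (mm) of the TRUE entries of a 3-D logical array,
# or of all voxels when mask is NULL. 0-based indexing, (x, y, z) order.
voxel_coords <- function(dim, spacing, origin = c(0, 0, 0), mask = NULL) {
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(dim)), .dim = dim)
  } else {
    idx <- which(mask, arr.ind = TRUE)
  }
  cbind(
    origin[1] + (idx[, 1] - 1) * spacing[1],
    origin[2] + (idx[, 2] - 1) * spacing[2],
    origin[3] + (idx[, 3] - 1) * spacing[3]
  )
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
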