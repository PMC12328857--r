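# Shared fixtures: a small (desk-scale, ~240 mL) phantom with trees, cached
# per (seed, shape, generations) so the suite builds each geometry once.

.fixture_cache <- new.env(parent = emptyenv())

test_phantom <- function(seed = 3, shape = c(24L, 24L, 16L),
                         spacing = c(4, 4, 4), generations = 5L) {
  key <- paste(c("ph", seed, shape, generations), collapse = "_")
  if (!exists(key, envir = .fixture_cache)) {
    lab <- build_liver_phantom(shape = shape, spacing = spacing, seed = seed)
    trees <- lapply(1:5, function(l) {
      grow_arterial_tree(lab$labels == l, lab$spacing,
                         generations = generations, seed = seed + l)
    })
    assign(key, list(labels = lab, trees = trees), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Schedule scaled to the phantom's liver volume so the administered
# concentration trajectory (mg per mL liver) matches the study schedule
# (5 x 250 mg, optionally + 4 x 1000 mg, into a ~3.1 L liver).
scaled_schedule <- function(labels, extended = FALSE, ref_volume_ml = 3100) {
  v <- sum(lobe_volumes(labels)$volume_ml)
  fraction_schedule(c(rep(250, 5), if (extended) rep(1000, 4)) *
                      v / ref_volume_ml)
}

# Uniform-valued dose volume on a tiny grid.
uniform_dose <- function(value, dim = c(6, 6, 4)) {
  volume_grid(array(value, dim = dim), role = "dose")
}
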