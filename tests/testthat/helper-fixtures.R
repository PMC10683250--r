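## Shared fixtures, generated once per test run and cached in-session.

.fixture_env <- new.env(parent = emptyenv())

## Small (32^3) phantom spec for fast unit tests.
small_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(32, 32, 32), blob_radius = c(2.5, 5),
               perturb_spacing = 8, seed = seed, ...)
}

cached_phantom <- function(key, spec) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(spec)
  .fixture_env[[key]]
}

## Independent per-voxel PRM rule, written as a plain scalar conditional
## chain (the brute-force oracle against which classify_prm is checked).
oracle_prm_voxel <- function(insp_hu, exp_hu, in_lung,
                             insp_cut = -950, exp_cut = -856) {
  if (!in_lung) return(0L)
  if (exp_hu < exp_cut) {
    if (insp_hu < insp_cut) return(3L)
    return(2L)
  }
  1L
}

oracle_prm_map <- function(insp, exp, lung, insp_cut = -950,
                           exp_cut = -856) {
  out <- array(0L, dim(insp))
  for (i in seq_along(insp))
    out[i] <- oracle_prm_voxel(insp[i], exp[i], lung[i], insp_cut, exp_cut)
  out
}

## Exhaustive HU grid spanning both thresholds (201 x 201 combinations).
hu_grid_pair <- function() {
  insp <- seq(-1050, -850, by = 1)
  exp <- seq(-956, -756, by = 1)
  list(insp = rep(insp, times = length(exp)),
       exp = rep(exp, each = length(insp)))
}
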