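# Shared fixtures, built once per test run and memoised. The small
# 32^3 spec keeps per-operation tests fast; the full 64^3 phantom and
# its reconstructions are built lazily only by the tests that need
# them (end-to-end properties and acceptance checks).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small symmetric spec: 32^3 at 4 mm, scaled-down tumor
small_spec <- function(noise_sigma = 0, seed = 42L) {
  phantom_spec(
    grid_shape = c(32L, 32L, 32L), voxel_size_mm = c(4, 4, 4),
    noise_sigma = noise_sigma, seed = seed,
    tumor = list(center_mm = c(24, 0, 0),
                 radii_mm = list(ed = c(18, 16, 16), et = c(10, 10, 10),
                                 ncr = c(5, 5, 5), tiz = c(6, 8, 8)),
                 tiz_offset_mm = c(13, 0, 0))
  )
}

small_phantom <- function() {
  memo("small_phantom", build_phantom(small_spec(), with_dynamics = FALSE))
}

# full-size noiseless phantom + QSM reconstruction (shared across files)
default_noiseless <- function() {
  memo("default_noiseless", {
    spec <- phantom_spec(noise_sigma = 0)
    ph <- build_phantom(spec, with_dynamics = FALSE)
    tm <- array(ph$truth$labels %in% 6:9, dim(ph$truth$labels))
    q <- qsm_reconstruct(ph$gre, ph$truth$brain_mask, tm,
                         voxel_size_mm = spec$voxel_size_mm)
    list(spec = spec, ph = ph, qsm = q)
  })
}

# full default noisy pipeline run (the reference study conditions):
# all defaults, including the generator's default seed
default_noisy_run <- function() {
  memo("default_noisy_run", run_pipeline(default_config()))
}
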