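# Shared fixtures, memoised so expensive phantoms are built once per run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small full-extent phantom: 48^3 at 4 mm (188 mm extent, full-size organs)
small_phantom <- function(seed = 7) {
  fixture(paste0("ph48_", seed), function()
    generate_phantom(phantom_config(n = 48L, spacing_mm = 4), seed = seed))
}

# default-resolution phantom: 96^3 at 2 mm
default_phantom <- function(seed = 7) {
  fixture(paste0("ph96_", seed), function()
    generate_phantom(phantom_config(), seed = seed))
}

# a smooth random field: per-component smoothed white noise, rescaled to a
# given peak magnitude (fixture for triangle-inequality and recovery tests)
smooth_random_field <- function(geom, peak_mm, seed, smooth_mm = 20) {
  set.seed(seed)
  u <- array(stats::rnorm(prod(geom$dim) * 3), c(geom$dim, 3L))
  for (c in 1:3)
    u[, , , c] <- dirqa:::gaussian_smooth(u[, , , c], smooth_mm, geom$spacing)
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u <- u * (peak_mm / max(mag))
  vector_field(u, geom$origin, geom$spacing)
}

# uniform-translation field
translation_field <- function(geom, t_mm) {
  u <- array(rep(t_mm, each = prod(geom$dim)), c(geom$dim, 3L))
  vector_field(u, geom$origin, geom$spacing)
}
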