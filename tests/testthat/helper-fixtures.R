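# Session-level cache for expensive fixtures (phantom generation and the
# end-to-end pipeline) shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_phantom <- function() {
  cached("phantom_default", generate_phantom(phantom_spec(seed = 101)))
}

default_pcmra <- function() {
  cached("pcmra_default", compute_pcmra(default_phantom()$flow))
}

decoy_phantom <- function() {
  cached("phantom_decoy",
         generate_phantom(phantom_spec(seed = 202, decoy_offset_mm = 12)))
}

unit_grid <- function(n = c(12, 12, 12), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  image_grid(n, spacing = spacing, origin = origin)
}

# random blob-like test mask: union of 1-3 balls plus salt noise, non-empty
random_mask <- function(grid, seed) {
  set.seed(seed)
  centers <- voxel_centers(grid)
  v <- rep(FALSE, nrow(centers))
  for (k in seq_len(sample(1:3, 1))) {
    c0 <- runif(3, 2, grid$shape * grid$spacing - 2)
    r <- runif(1, 1.5, 4)
    v <- v | (rowSums(sweep(centers, 2, c0)^2) <= r^2)
  }
  v <- v | (runif(length(v)) < 0.01)
  if (!any(v)) v[sample(length(v), 3)] <- TRUE
  binary_mask(array(v, grid$shape), grid)
}

random_rigid <- function(seed, max_deg = 30, max_mm = 20) {
  set.seed(seed)
  rigid_transform(angles = runif(3, -max_deg, max_deg) * pi / 180,
                  translation = runif(3, -max_mm, max_mm),
                  center = runif(3, -10, 10))
}

# small flow series with prescribed constant velocity per frame
constant_flow <- function(grid, speeds, direction = c(1, 0, 0), mag = 1) {
  n <- length(speeds)
  d <- direction / sqrt(sum(direction^2))
  magnitude <- array(mag, c(grid$shape, n))
  velocity <- array(0, c(grid$shape, 3, n))
  for (i in seq_len(n)) for (k in 1:3)
    velocity[, , , k, i] <- speeds[i] * d[k]
  flow_series(grid, magnitude, velocity)
}
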