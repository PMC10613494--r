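#' @useDynLib atrialign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd cor median optim
#' @importFrom utils modifyList
NULL

#' Voxel grid with an index-to-world affine
#'
#' An `image_grid` is the coordinate backbone shared by every volume and mask
#' in the package: a voxel lattice (`shape`) together with a 4x4 affine that
#' maps continuous *0-based* voxel indices to world coordinates in
#' millimetres, following the NIfTI s-form convention. Affines are used
#' verbatim as stored in files; no axis flipping is applied.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing Numeric vector of length 3, voxel edge lengths in mm.
#'   Ignored when `affine` is given (it is then derived from the affine's
#'   column norms).
#' @param affine 4x4 index-to-world matrix (mm); last row must be
#'   `(0, 0, 0, 1)`. When omitted, an axis-aligned affine is built from
#'   `spacing` and `origin`.
#' @param origin World coordinates (mm) of voxel index `(0, 0, 0)`; only used
#'   when `affine` is omitted. Default `c(0, 0, 0)`.
#' @return An object of class `image_grid` with fields `shape`, `spacing`,
#'   `affine`.
#' @examples
#' g <- image_grid(c(16, 16, 16), spacing = c(1.2, 1.2, 1.2))
#' world_from_index(g, c(1, 2, 3))
#' @export
image_grid <- function(shape, spacing = NULL, affine = NULL,
                       origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (is.null(affine)) {
    if (is.null(spacing)) stop("either `spacing` or `affine` is required")
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("`spacing` must be 3 positive lengths (mm)")
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing)
    affine[1:3, 4] <- as.numeric(origin)
  }
  affine <- unclass(as.matrix(affine))
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("`affine` must be invertible")
  derived <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (max(abs(spacing - derived) / derived) > 1e-6)
      stop("`spacing` inconsistent with affine column norms")
  }
  structure(list(shape = shape, spacing = derived, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, spacing %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) <= tol
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

#' Map voxel indices to world coordinates
#'
#' Applies the grid affine to (possibly fractional) 0-based voxel indices.
#' Inverse of [index_from_world()].
#'
#' @param grid An [image_grid].
#' @param index Length-3 vector or n x 3 matrix of continuous 0-based voxel
#'   indices.
#' @return n x 3 matrix of world points (mm).
#' @export
world_from_index <- function(grid, index) {
  p <- as_points(index)
  sweep(p %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], "+")
}

#' @rdname world_from_index
#' @param world Length-3 vector or n x 3 matrix of world points (mm).
#' @export
index_from_world <- function(grid, world) {
  p <- as_points(world)
  inv <- solve(grid$affine)
  sweep(p, 2, grid$affine[1:3, 4], "-") %*% t(inv[1:3, 1:3])
}

#' World coordinates of all voxel centers of a grid
#'
#' @param grid An [image_grid].
#' @return (prod(shape)) x 3 matrix, rows in R array (column-major) order.
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1, each = s[1] * s[2])
  )
  world_from_index(grid, idx)
}

#' World center of a grid
#'
#' World coordinates of the voxel-index center `(shape - 1) / 2`; the default
#' rotation center for registration.
#' @param grid An [image_grid].
#' @return Length-3 numeric vector (mm).
#' @export
grid_center <- function(grid) {
  drop(world_from_index(grid, (grid$shape - 1) / 2))
}

#' Scalar image volume on a grid
#'
#' @param values Numeric 3D array matching `grid$shape`; all values finite.
#' @param grid An [image_grid].
#' @return Object of class `scalar_volume` with fields `grid`, `values`.
#' @export
scalar_volume <- function(values, grid) {
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop("value array shape does not match grid shape")
  if (!all(is.finite(values)))
    stop("scalar volume contains non-finite values")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' Binary segmentation mask on a grid
#'
#' @param values Logical 3D array matching `grid$shape`.
#' @param grid An [image_grid].
#' @param label Structure name, one of `"LA"`, `"LAA"`, `"PV"`, `"AORTA"`,
#'   `"LV"`, `"OTHER"`.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid, label = "OTHER") {
  label <- match.arg(label, c("LA", "LAA", "PV", "AORTA", "LV", "OTHER"))
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop("mask shape does not match grid shape")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim = dim(values))
  }
  if (anyNA(values)) stop("mask contains NA")
  structure(list(grid = grid, values = values, label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask [%s]: %d foreground voxels on %s grid\n",
              x$label, sum(x$values), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Time-resolved 4D-flow series
#'
#' Holds the per-frame magnitude images and three-directional velocity fields
#' of a velocity-encoded acquisition. Velocities are stored in m/s.
#'
#' @param grid An [image_grid] (shared by all frames).
#' @param magnitude 4D array `(nx, ny, nz, N)` of magnitude intensities.
#' @param velocity 5D array `(nx, ny, nz, 3, N)` of velocity components in
#'   m/s, component order x, y, z.
#' @param venc Optional velocity-encoding limit (m/s); components must then
#'   satisfy `|v| <= 1.05 * venc`.
#' @param frame_duration Optional temporal resolution (ms).
#' @return Object of class `flow_series` with field `n_frames`.
#' @export
flow_series <- function(grid, magnitude, velocity, venc = NULL,
                        frame_duration = NULL) {
  magnitude <- as.array(magnitude)
  velocity <- as.array(velocity)
  dm <- dim(magnitude)
  dv <- dim(velocity)
  if (length(dm) == 3L) dm <- c(dm, 1L)
  dim(magnitude) <- dm
  if (length(dm) != 4L || !all(dm[1:3] == grid$shape))
    stop("magnitude must be (nx, ny, nz, N) on the series grid")
  n <- dm[4]
  if (n < 1L) stop("at least one frame is required")
  if (length(dv) != 5L || !all(dv[1:3] == grid$shape) || dv[4] != 3L || dv[5] != n)
    stop("velocity must be (nx, ny, nz, 3, N) matching magnitude frames")
  if (!all(is.finite(magnitude)) || !all(is.finite(velocity)))
    stop("flow series contains non-finite values")
  if (!is.null(venc) && max(abs(velocity)) > venc * 1.05)
    stop("velocity components exceed 1.05 * venc; check units (expected m/s)")
  storage.mode(magnitude) <- "double"
  storage.mode(velocity) <- "double"
  structure(list(grid = grid, n_frames = as.integer(n), magnitude = magnitude,
                 velocity = velocity, venc = venc,
                 frame_duration = frame_duration),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("flow_series: %s voxels, %d frames%s\n",
              paste(x$grid$shape, collapse = "x"), x$n_frames,
              if (is.null(x$venc)) "" else sprintf(", venc %.2f m/s", x$venc)))
  invisible(x)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
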