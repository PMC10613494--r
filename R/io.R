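grid_from_nifti <- function(img, path) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  if (is.null(aff) || all(aff[1:3, 1:3] == 0))
    stop(sprintf("'%s' carries no usable affine", path))
  affine <- matrix(as.numeric(aff), 4, 4)
  image_grid(dim(img)[1:3], affine = affine)
}

#' Read and write scalar volumes as NIfTI
#'
#' NIfTI-1 is the canonical interchange format of the package: it carries
#' the index-to-world affine (s-form, used verbatim) that registration and
#' resampling depend on. Volumes are written as float32, masks as uint8.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param vol A [scalar_volume].
#' @return `read_volume` returns a [scalar_volume]; writers return `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L && dim(img)[4] == 1L)
    img <- array(img, dim(img)[1:3])
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path))
  grid <- grid_from_nifti(img, path)
  scalar_volume(array(as.numeric(img), dim(img)), grid)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "scalar_volume")) stop("`vol` must be a scalar_volume")
  img <- RNifti::asNifti(vol$values)
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read and write binary masks as NIfTI
#'
#' @param path NIfTI file path.
#' @param label Structure label to attach on read.
#' @param mask A [binary_mask].
#' @return `read_mask` returns a [binary_mask]; `write_mask` returns `path`
#'   invisibly.
#' @export
read_mask <- function(path, label = "OTHER") {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L && dim(img)[4] == 1L)
    img <- array(img, dim(img)[1:3])
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path))
  grid <- grid_from_nifti(img, path)
  v <- array(as.numeric(img), dim(img))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("'%s' is not binary (values outside {0, 1})", path))
  binary_mask(v, grid, label = label)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  img <- RNifti::asNifti(array(as.integer(mask$values), mask$grid$shape))
  aff <- structure(mask$grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read and write a 4D-flow series
#'
#' The on-disk layout is one 4D NIfTI magnitude volume plus three 4D NIfTI
#' velocity-component volumes and a JSON sidecar:
#' `<prefix>_mag.nii.gz`, `<prefix>_velx.nii.gz`, `<prefix>_vely.nii.gz`,
#' `<prefix>_velz.nii.gz`, `<prefix>_flow.json`. The sidecar must declare
#' `velocity_units` (`"m/s"` or `"cm/s"`; converted to m/s on load) and may
#' carry `venc_m_s` and `frame_duration_ms`.
#'
#' @param prefix Path prefix (directory + basename) of the five files.
#' @param series A [flow_series].
#' @return `read_flow` returns a [flow_series]; `write_flow` returns
#'   `prefix` invisibly.
#' @export
read_flow <- function(prefix) {
  paths <- paste0(prefix, c("_mag.nii.gz", "_velx.nii.gz", "_vely.nii.gz",
                            "_velz.nii.gz", "_flow.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing flow files: %s", paste(missing, collapse = ", ")))
  side <- jsonlite::read_json(paths[5], simplifyVector = TRUE)
  units <- side$velocity_units
  if (is.null(units) || !units %in% c("m/s", "cm/s"))
    stop("sidecar must declare velocity_units as \"m/s\" or \"cm/s\"")
  scale <- if (units == "cm/s") 0.01 else 1
  vols <- lapply(paths[1:4], RNifti::readNifti)
  dims <- lapply(vols, function(v) {
    d <- dim(v)
    if (length(d) == 3L) d <- c(d, 1L)
    d
  })
  if (length(unique(dims)) != 1L)
    stop("flow component volumes have mismatched shapes")
  d <- dims[[1]]
  grid <- grid_from_nifti(vols[[1]], paths[1])
  n <- d[4]
  velocity <- array(0, c(d[1:3], 3, n))
  for (k in 1:3)
    velocity[, , , k, ] <- array(as.numeric(vols[[k + 1]]), c(d[1:3], n)) * scale
  flow_series(grid, array(as.numeric(vols[[1]]), c(d[1:3], n)), velocity,
              venc = side$venc_m_s, frame_duration = side$frame_duration_ms)
}

#' @rdname read_flow
#' @export
write_flow <- function(series, prefix) {
  if (!inherits(series, "flow_series")) stop("`series` must be a flow_series")
  aff <- structure(series$grid$affine, code = 2L)
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::sform(img) <- aff
    RNifti::qform(img) <- aff
    RNifti::writeNifti(img, path, datatype = "float")
  }
  wr(series$magnitude, paste0(prefix, "_mag.nii.gz"))
  wr(series$velocity[, , , 1, , drop = TRUE], paste0(prefix, "_velx.nii.gz"))
  wr(series$velocity[, , , 2, , drop = TRUE], paste0(prefix, "_vely.nii.gz"))
  wr(series$velocity[, , , 3, , drop = TRUE], paste0(prefix, "_velz.nii.gz"))
  side <- list(velocity_units = "m/s", n_frames = series$n_frames)
  if (!is.null(series$venc)) side$venc_m_s <- series$venc
  if (!is.null(series$frame_duration))
    side$frame_duration_ms <- series$frame_duration
  jsonlite::write_json(side, paste0(prefix, "_flow.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a seed configuration (YAML or JSON)
#'
#' The file holds a list of segments, each with `label`, `window`
#' (`[lower, upper]`), and `seeds` (list of world-mm coordinate triples).
#'
#' @param path Configuration file path (`.yaml`, `.yml`, or `.json`).
#' @return Named list of [seed_spec] objects keyed by label.
#' @export
read_seed_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  segs <- cfg$segments
  if (is.null(segs) || length(segs) == 0L)
    stop("seed configuration has no `segments` entry")
  out <- list()
  for (s in segs) {
    if (is.null(s$label) || is.null(s$window) || is.null(s$seeds))
      stop("each segment needs `label`, `window`, and `seeds`")
    pts <- do.call(rbind, lapply(s$seeds, as.numeric))
    out[[s$label]] <- seed_spec(pts, lower = s$window[[1]],
                                upper = s$window[[2]], label = s$label)
  }
  out
}
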