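#' Rigid (rotation + translation) world-space transform
#'
#' Six-parameter rigid transform acting on world coordinates in mm:
#' `p -> R (p - center) + center + translation`. The rotation matrix is built
#' from Euler angles applied in *intrinsic Z-Y-X* order, i.e.
#' `R = Rz(angles[3]) %*% Ry(angles[2]) %*% Rx(angles[1])` with `angles`
#' stored as `(rx, ry, rz)` in radians. Only compositions and
#' parameter-recovery comparisons depend on this convention; comparisons
#' between transforms should be made on the rotation matrix (see
#' [transform_difference()]), not on the angles, to avoid gimbal ambiguity.
#'
#' In registration and resampling the transform always maps *fixed/target*
#' world coordinates to *moving/source* world coordinates (a pull-back); this
#' single convention is shared across the package.
#'
#' @param angles Euler angles `(rx, ry, rz)` in radians.
#' @param translation Translation `(tx, ty, tz)` in mm.
#' @param center Rotation center in world mm.
#' @return Object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(angles = c(0, 0, pi / 2))
#' apply_rigid(t, c(1, 0, 0)) # ~ (0, 1, 0)
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(angles) == 3, length(translation) == 3, length(center) == 3)
  if (!all(is.finite(c(angles, translation, center))))
    stop("rigid transform parameters must be finite")
  structure(list(angles = angles, translation = translation, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "rigid_transform: angles (%s) deg, translation (%s) mm, center (%s) mm\n",
    paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
    paste(signif(x$translation, 4), collapse = ", "),
    paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix from Euler angles (intrinsic Z-Y-X)
#'
#' @param angles `(rx, ry, rz)` in radians.
#' @return 3x3 rotation matrix `Rz %*% Ry %*% Rx`.
#' @export
rotation_matrix <- function(angles) {
  ca <- cos(angles); sa <- sin(angles)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Euler angles (rx, ry, rz) of a rotation matrix under the Z-Y-X convention.
euler_from_matrix <- function(r) {
  ry <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(abs(r[3, 1]) - 1) < 1e-12) {
    # gimbal lock: fold everything into rx
    rz <- 0
    rx <- atan2(-r[1, 2] * sign(-r[3, 1]), r[2, 2])
  } else {
    rz <- atan2(r[2, 1], r[1, 1])
    rx <- atan2(r[3, 2], r[3, 3])
  }
  c(rx, ry, rz)
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param t A [rigid_transform].
#' @return 4x4 matrix `M` with `M %*% c(p, 1) == c(apply_rigid(t, p), 1)`.
#' @export
rigid_matrix <- function(t) {
  r <- rotation_matrix(t$angles)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- t$center + t$translation - r %*% t$center
  m
}

# Rebuild a rigid_transform from a homogeneous matrix, about a chosen center.
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  r <- m[1:3, 1:3]
  translation <- drop(m[1:3, 4]) - center + drop(r %*% center)
  rigid_transform(angles = euler_from_matrix(r), translation = translation,
                  center = center)
}

#' Apply a rigid transform to world points
#'
#' @param t A [rigid_transform].
#' @param p Length-3 vector or n x 3 matrix of world points (mm).
#' @return World points after `R (p - center) + center + translation`; a
#'   vector when `p` was a vector.
#' @export
apply_rigid <- function(t, p) {
  vec <- is.null(dim(p))
  p <- as_points(p)
  r <- rotation_matrix(t$angles)
  q <- sweep(p, 2, t$center, "-") %*% t(r)
  q <- sweep(q, 2, t$center + t$translation, "+")
  if (vec && nrow(q) == 1L) drop(q) else q
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform mapping `p` to `a(b(p))`.
#' The result is re-expressed about center `(0, 0, 0)`.
#'
#' @param a,b,t [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_rigid <- function(a, b) {
  rigid_from_matrix(rigid_matrix(a) %*% rigid_matrix(b))
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(t) {
  rigid_from_matrix(solve(rigid_matrix(t)))
}

#' Pose difference between two rigid transforms
#'
#' Compares transforms on their matrices (rotation-angle of the relative
#' rotation and displacement at a reference point), avoiding Euler-angle
#' ambiguities.
#'
#' @param a,b [rigid_transform] objects.
#' @param point Reference world point (mm) at which the translation
#'   discrepancy is measured; typically the fixed-image grid center.
#' @return List with `rotation_deg` (angle of `Ra %*% t(Rb)`) and
#'   `translation_mm` (`|a(point) - b(point)|`).
#' @export
transform_difference <- function(a, b, point = c(0, 0, 0)) {
  ra <- rotation_matrix(a$angles)
  rb <- rotation_matrix(b$angles)
  rel <- ra %*% t(rb)
  cosang <- (sum(diag(rel)) - 1) / 2
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  dt <- sqrt(sum((apply_rigid(a, point) - apply_rigid(b, point))^2))
  list(rotation_deg = ang, translation_mm = dt)
}

#' Serialize a rigid transform to / from JSON
#'
#' Angles are stored in degrees in the file for readability, together with
#' the Euler convention string.
#'
#' @param t A [rigid_transform].
#' @param path File path for the JSON document.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [rigid_transform].
#' @export
write_transform <- function(t, path) {
  obj <- list(convention = "intrinsic-ZYX, pull-back fixed->moving",
              angles_deg = t$angles * 180 / pi,
              translation_mm = t$translation,
              center_mm = t$center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(angles = obj$angles_deg * pi / 180,
                  translation = obj$translation_mm,
                  center = obj$center_mm)
}
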