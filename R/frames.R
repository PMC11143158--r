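#' Wrap an angle into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
#' wrap_angle(-pi)          # pi
#' @export
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  ifelse(y > pi, y - 2 * pi, y)
}

#' Construct a 2D rigid frame transform
#'
#' A rigid transform between two planar reference frames, stored as a
#' rotation angle and a translation. Applying the transform to a point
#' computes `Rot(phi) %*% p + translation`. Throughout the package a
#' compartment's place-frame transform maps world coordinates into that
#' compartment's local (place-cell) frame.
#'
#' @param phi Rotation angle in radians (wrapped into (-pi, pi]).
#' @param translation Numeric length-2 translation, meters.
#' @return An object of class `frame_transform`.
#' @examples
#' frame_transform(pi / 2, c(1, 0))
#' @export
frame_transform <- function(phi = 0, translation = c(0, 0)) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi)) {
    stop("`phi` must be a single finite number", call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 2L || !all(is.finite(translation))) {
    stop("`translation` must be a finite numeric 2-vector", call. = FALSE)
  }
  structure(
    list(phi = wrap_angle(phi), translation = translation),
    class = "frame_transform"
  )
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf(
    "<frame_transform> phi = %.6g rad, translation = (%.6g, %.6g) m\n",
    x$phi, x$translation[1], x$translation[2]
  ))
  invisible(x)
}

is_frame_transform <- function(x) inherits(x, "frame_transform")

#' Rotation matrix of a frame transform
#'
#' @param transform A [frame_transform()].
#' @return The orthonormal 2x2 rotation matrix with determinant +1.
#' @export
rotation_matrix <- function(transform) {
  stopifnot(is_frame_transform(transform))
  c_ <- cos(transform$phi)
  s_ <- sin(transform$phi)
  matrix(c(c_, s_, -s_, c_), 2L, 2L)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("points must have two columns", call. = FALSE)
    storage.mode(p) <- "double"
    p
  } else {
    p <- as.numeric(p)
    if (length(p) != 2L) stop("a point must be a numeric 2-vector", call. = FALSE)
    matrix(p, 1L, 2L)
  }
}

#' Apply a frame transform to points
#'
#' @param transform A [frame_transform()].
#' @param p A numeric 2-vector or an n x 2 matrix of points (meters).
#' @return Transformed points, in the same shape as the input.
#' @examples
#' apply_transform(frame_transform(pi / 2, c(1, 0)), c(1, 0))  # (1, 1)
#' @export
apply_transform <- function(transform, p) {
  stopifnot(is_frame_transform(transform))
  vec <- !is.matrix(p)
  pm <- as_point_matrix(p)
  if (!all(is.finite(pm))) stop("points must be finite", call. = FALSE)
  out <- pm %*% t(rotation_matrix(transform))
  out[, 1L] <- out[, 1L] + transform$translation[1L]
  out[, 2L] <- out[, 2L] + transform$translation[2L]
  if (vec) drop(out) else out
}

#' Compose two frame transforms
#'
#' `compose_transforms(outer, inner)` is the transform whose application
#' equals applying `inner` first and `outer` second.
#'
#' @param outer,inner [frame_transform()] objects.
#' @return A [frame_transform()] with
#'   `apply_transform(compose_transforms(outer, inner), p) ==
#'    apply_transform(outer, apply_transform(inner, p))`.
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(is_frame_transform(outer), is_frame_transform(inner))
  frame_transform(
    phi = outer$phi + inner$phi,
    translation = drop(rotation_matrix(outer) %*% inner$translation) +
      outer$translation
  )
}

#' Invert a frame transform
#'
#' @param transform A [frame_transform()].
#' @return The inverse transform, so that applying the inverse after the
#'   original recovers the starting point.
#' @export
invert_transform <- function(transform) {
  stopifnot(is_frame_transform(transform))
  rot_inv <- t(rotation_matrix(transform))  # Rot(-phi)
  frame_transform(
    phi = -transform$phi,
    translation = -drop(rot_inv %*% transform$translation)
  )
}

#' Angular and translational difference between two frames
#'
#' Componentwise difference used by the experience-dependent frame
#' adjustment: the angle is wrapped into (-pi, pi] so that a geometric
#' decay of the angular difference is well defined.
#'
#' @param a,b [frame_transform()] objects.
#' @return A list with elements `angle` (radians, in (-pi, pi]) and
#'   `translation` (numeric 2-vector, meters), the differences `a - b`.
#' @export
frame_difference <- function(a, b) {
  stopifnot(is_frame_transform(a), is_frame_transform(b))
  list(
    angle = wrap_angle(a$phi - b$phi),
    translation = a$translation - b$translation
  )
}
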