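#' Define a grid cell
#'
#' A grid cell is characterised by the spacing, orientation and phase of its
#' hexagonal firing lattice. The two lattice basis vectors have length equal
#' to the spacing and subtend 60 degrees, so orientation is periodic with
#' period pi/3 and is stored wrapped into `[0, pi/3)`. The phase is the
#' lattice-unit offset of the firing lattice relative to the place-frame
#' origin; each component is stored wrapped into `[0, 1)`.
#'
#' @param spacing Distance between adjacent firing-field centers, meters
#'   (> 0).
#' @param orientation Angle of the first lattice basis vector, radians.
#' @param phase Numeric length-2 lattice-unit offset.
#' @return An object of class `grid_cell`.
#' @examples
#' grid_cell(1.0, pi / 4, c(0.5, 0))
#' @export
grid_cell <- function(spacing, orientation = 0, phase = c(0, 0)) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(orientation) || length(orientation) != 1L ||
      !is.finite(orientation)) {
    stop("`orientation` must be a single finite number", call. = FALSE)
  }
  phase <- as.numeric(phase)
  if (length(phase) != 2L || !all(is.finite(phase))) {
    stop("`phase` must be a finite numeric 2-vector", call. = FALSE)
  }
  structure(
    list(
      spacing = spacing,
      orientation = orientation %% (pi / 3),
      phase = phase %% 1
    ),
    class = "grid_cell"
  )
}

#' @export
print.grid_cell <- function(x, ...) {
  cat(sprintf(
    "<grid_cell> spacing = %.4g m, orientation = %.4g rad, phase = (%.4g, %.4g)\n",
    x$spacing, x$orientation, x$phase[1], x$phase[2]
  ))
  invisible(x)
}

is_grid_cell <- function(x) inherits(x, "grid_cell")

#' Firing-rate parameters
#'
#' `zeta` is the firing threshold (the scaled lattice distance at which the
#' rate crosses 0.5) and `kappa` sets the sharpness of the rate fall-off
#' around a firing-field center. Defaults follow the single-cell experiment
#' settings.
#'
#' @param zeta Firing threshold, dimensionless, >= 0.
#' @param kappa Bump-sharpness parameter, dimensionless, > 0.
#' @return An object of class `firing_params`.
#' @export
firing_params <- function(zeta = 0.4, kappa = 3.0) {
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) || zeta < 0) {
    stop("`zeta` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("`kappa` must be a single positive number", call. = FALSE)
  }
  structure(list(zeta = zeta, kappa = kappa), class = "firing_params")
}

#' @export
print.firing_params <- function(x, ...) {
  cat(sprintf("<firing_params> zeta = %.4g, kappa = %.4g\n", x$zeta, x$kappa))
  invisible(x)
}

#' Lattice basis vectors of a grid cell
#'
#' The two basis vectors spanning the cell's lattice ("cognitive") space:
#' `eps1 = s * (cos(theta), sin(theta))` and
#' `eps2 = s * (cos(theta + pi/3), sin(theta + pi/3))`.
#'
#' @param cell A [grid_cell()].
#' @return A list with numeric 2-vectors `eps1` and `eps2` (meters).
#' @export
basis_vectors <- function(cell) {
  stopifnot(is_grid_cell(cell))
  s <- cell$spacing
  th <- cell$orientation
  list(
    eps1 = s * c(cos(th), sin(th)),
    eps2 = s * c(cos(th + pi / 3), sin(th + pi / 3))
  )
}

basis_matrix <- function(cell) {
  b <- basis_vectors(cell)
  cbind(b$eps1, b$eps2, deparse.level = 0)
}

#' Place-to-lattice transformation matrix
#'
#' The inverse of the basis matrix `[eps1 eps2]`; multiplying a place-frame
#' position by this matrix yields oblique lattice coordinates in lattice
#' units.
#'
#' @param cell A [grid_cell()].
#' @return A 2x2 matrix with `det = 1 / (s^2 * sin(pi/3))`.
#' @export
place_to_grid_matrix <- function(cell) {
  stopifnot(is_grid_cell(cell))
  solve(basis_matrix(cell))
}

#' Transform place-frame positions into lattice coordinates
#'
#' `g = R_pg %*% p - phase`, where `R_pg` is [place_to_grid_matrix()]. At
#' integer lattice coordinates the cell fires maximally (preferred
#' positions).
#'
#' @param cell A [grid_cell()].
#' @param p A numeric 2-vector or n x 2 matrix of place-frame positions
#'   (meters).
#' @return Lattice coordinates in lattice units, same shape as the input.
#' @export
place_to_grid <- function(cell, p) {
  stopifnot(is_grid_cell(cell))
  vec <- !is.matrix(p)
  pm <- as_point_matrix(p)
  g <- pm %*% t(place_to_grid_matrix(cell))
  g[, 1L] <- g[, 1L] - cell$phase[1L]
  g[, 2L] <- g[, 2L] - cell$phase[2L]
  if (vec) drop(g) else g
}

# deterministic rounding: ties (.5) go away from zero on every platform
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Distance to the nearest preferred lattice point
#'
#' Each lattice coordinate is rounded componentwise to the nearest integer
#' (ties half away from zero) and the residual's norm is returned. The
#' default is the Euclidean norm; `method = "squared"` keeps the literal
#' squared form.
#'
#' @param g A numeric 2-vector or n x 2 matrix of lattice coordinates.
#' @param method `"euclidean"` (default) or `"squared"`.
#' @return Numeric vector of lattice-unit distances, one per point.
#' @export
lattice_distance <- function(g, method = c("euclidean", "squared")) {
  method <- match.arg(method)
  gm <- as_point_matrix(g)
  r1 <- gm[, 1L] - round_half_away(gm[, 1L])
  r2 <- gm[, 2L] - round_half_away(gm[, 2L])
  d2 <- r1 * r1 + r2 * r2
  if (method == "squared") d2 else sqrt(d2)
}

#' Grid-cell firing rate at place-frame positions
#'
#' The rate is a decreasing sigmoid of the lattice distance `d` to the
#' nearest preferred position:
#' `rate = clip(1/2 - arctan(kappa * (d / s - zeta)) / pi, 0, 1)`.
#' It is maximal at firing-field centers, crosses 0.5 where `d / s = zeta`,
#' and tends to 0 far from any center.
#'
#' @param cell A [grid_cell()].
#' @param params A [firing_params()].
#' @param p A numeric 2-vector or n x 2 matrix of place-frame positions
#'   (meters).
#' @param method Distance method passed to [lattice_distance()].
#' @return Numeric vector of rates in `[0, 1]`, one per point.
#' @examples
#' cell <- grid_cell(1.0, pi / 4, c(0.5, 0))
#' firing_rate(cell, firing_params(), c(0, 0))
#' @export
firing_rate <- function(cell, params, p, method = c("euclidean", "squared")) {
  stopifnot(is_grid_cell(cell), inherits(params, "firing_params"))
  d <- lattice_distance(place_to_grid(cell, p), method = method)
  rate <- 0.5 - atan(params$kappa * (d / cell$spacing - params$zeta)) / pi
  pmin(pmax(rate, 0), 1)
}

#' Enumerate firing-field centers inside a region
#'
#' Centers are the pre-images of integer lattice coordinates,
#' `c = B %*% (k + phase)` for integer 2-vectors `k`, enumerated exactly
#' over a bounded region (no center inside the region is missed).
#'
#' @param cell A [grid_cell()].
#' @param region Either an environment built by [build_environment()] or a
#'   list with numeric `xlim` and `ylim` (meters). Interpreted in the place
#'   frame unless `frame` is given.
#' @param frame Optional [frame_transform()] mapping world coordinates into
#'   the place frame; when given, `region` is interpreted in world
#'   coordinates and world-frame centers are returned.
#' @return An n x 2 matrix of center positions (meters).
#' @export
field_centers <- function(cell, region, frame = NULL) {
  stopifnot(is_grid_cell(cell))
  if (inherits(region, "arena_environment")) {
    lims <- list(xlim = region$bbox$xlim, ylim = region$bbox$ylim)
    contains <- function(p) point_in_environment(region, p)
  } else if (is.list(region) && !is.null(region$xlim) && !is.null(region$ylim)) {
    lims <- region
    contains <- function(p) {
      p[, 1L] >= lims$xlim[1] & p[, 1L] <= lims$xlim[2] &
        p[, 2L] >= lims$ylim[1] & p[, 2L] <= lims$ylim[2]
    }
    if (!all(is.finite(unlist(lims)))) stop("region must be bounded", call. = FALSE)
  } else {
    stop("`region` must be an arena_environment or a list(xlim, ylim)",
         call. = FALSE)
  }

  # lattice index bounds from the region corners expressed in lattice units
  corners_world <- cbind(
    rep(lims$xlim, each = 2L),
    rep(lims$ylim, times = 2L)
  )
  corners_place <- if (is.null(frame)) {
    corners_world
  } else {
    apply_transform(frame, corners_world)
  }
  g_corners <- place_to_grid(cell, corners_place)
  k1 <- floor(min(g_corners[, 1L])):ceiling(max(g_corners[, 1L]))
  k2 <- floor(min(g_corners[, 2L])):ceiling(max(g_corners[, 2L]))
  kk <- as.matrix(expand.grid(k1 = k1, k2 = k2))
  centers_place <- sweep(kk, 2L, -cell$phase) %*% t(basis_matrix(cell))
  centers <- if (is.null(frame)) {
    centers_place
  } else {
    apply_transform(invert_transform(frame), centers_place)
  }
  keep <- contains(centers)
  unname(centers[keep, , drop = FALSE])
}

#' Offset of the nearest firing-field bump along a lattice axis
#'
#' Distance from the place-frame origin to the nearest local maximum of the
#' firing rate along the ray of basis vector 1 or 2. Along axis `k` the rate
#' peaks at offsets `(j + phase_k) * spacing` for integer `j`, so the
#' nearest bump sits at `min(w, 1 - w) * spacing` with `w` the wrapped
#' per-axis phase; this closed form is returned (and is cross-checked by
#' peak detection on [profile_along_axis()] output in the test-suite).
#'
#' @param cell A [grid_cell()].
#' @param axis 1 or 2, selecting the lattice basis direction.
#' @return Distance in meters.
#' @examples
#' cell <- grid_cell(1.0, pi / 4, c(0.5, 0))
#' nearest_center_distance_along_axis(cell, 1)  # 0.5
#' nearest_center_distance_along_axis(cell, 2)  # 0
#' @export
nearest_center_distance_along_axis <- function(cell, axis) {
  stopifnot(is_grid_cell(cell))
  if (!axis %in% c(1, 2)) stop("`axis` must be 1 or 2", call. = FALSE)
  w <- cell$phase[axis]
  min(w, 1 - w) * cell$spacing
}
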