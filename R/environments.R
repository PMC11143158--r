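rect_region <- function(xmin, xmax, ymin, ymax) {
  c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

in_rect <- function(r, p) {
  p[, 1L] >= r["xmin"] & p[, 1L] <= r["xmax"] &
    p[, 2L] >= r["ymin"] & p[, 2L] <= r["ymax"]
}

#' Build a simulation arena
#'
#' Four arena layouts are supported:
#' \describe{
#'   \item{`square`}{one compartment `[0, side]^2` (default side 5 m).}
#'   \item{`circle`}{one circular compartment of radius `radius`
#'     (default 2 m) centered at the origin.}
#'   \item{`two_compartment`}{two `width x height` rooms (default 5 x 4 m)
#'     side by side, separated by a `gap`-wide wall and joined by a
#'     `corridor_width`-wide corridor running along the top of both rooms.
#'     Both place frames have the same orientation; each origin is at its
#'     room's left-bottom corner.}
#'   \item{`four_compartment`}{a 2 x 2 grid of `side x side` rooms (default
#'     3 x 3 m) joined by four short doorway corridors. The place frames
#'     differ in both origin and orientation (0, 90, 180, 270 degrees by
#'     default).}
#' }
#' Compartment `"C1"` is always the reference compartment: its place frame
#' is the global (world) frame, i.e. the identity transform. Corridor
#' positions are assigned to the reference frame.
#'
#' @param kind One of `"square"`, `"circle"`, `"two_compartment"`,
#'   `"four_compartment"`.
#' @param side Side length (m) for `square` / `four_compartment` rooms.
#' @param radius Radius (m) for `circle`.
#' @param width,height Room dimensions (m) for `two_compartment`.
#' @param gap Wall thickness between the two rooms (default 0.5 m), or
#'   doorway-corridor length between the four rooms (default 1 m).
#' @param corridor_width Corridor width (m).
#' @param door_width Doorway width (m) for `four_compartment`.
#' @param orientations Place-frame orientations (radians) for the four
#'   compartments of `four_compartment`.
#' @return An object of class `arena_environment`.
#' @examples
#' build_environment("two_compartment")
#' @export
build_environment <- function(kind = c("square", "circle", "two_compartment",
                                       "four_compartment"),
                              side = NULL, radius = 2,
                              width = 5, height = 4,
                              gap = NULL, corridor_width = 1, door_width = 1,
                              orientations = c(0, pi / 2, pi, 3 * pi / 2)) {
  kind <- match.arg(kind)
  pos_check <- function(...) {
    v <- c(...)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("environment dimensions must be positive and finite", call. = FALSE)
    }
  }
  frame_at <- function(phi, anchor) {
    # place = Rot(phi) %*% (world - anchor)
    frame_transform(phi, -drop(rotation_matrix(frame_transform(phi)) %*% anchor))
  }
  env <- switch(kind,
    square = {
      side <- if (is.null(side)) 5 else side
      pos_check(side)
      list(
        compartments = list(C1 = rect_region(0, side, 0, side)),
        corridors = list(),
        circle = NULL,
        frames = list(C1 = frame_transform()),
        bbox = list(xlim = c(0, side), ylim = c(0, side))
      )
    },
    circle = {
      pos_check(radius)
      list(
        compartments = list(),
        corridors = list(),
        circle = list(center = c(0, 0), radius = radius),
        frames = list(C1 = frame_transform()),
        bbox = list(xlim = c(-radius, radius), ylim = c(-radius, radius))
      )
    },
    two_compartment = {
      gap <- if (is.null(gap)) 0.5 else gap  # wall between the two rooms
      pos_check(width, height, gap, corridor_width)
      x2 <- width + gap
      total_w <- 2 * width + gap
      list(
        compartments = list(
          C1 = rect_region(0, width, 0, height),
          C2 = rect_region(x2, x2 + width, 0, height)
        ),
        corridors = list(
          corridor = rect_region(0, total_w, height, height + corridor_width)
        ),
        circle = NULL,
        frames = list(
          C1 = frame_transform(),
          C2 = frame_at(0, c(x2, 0))
        ),
        bbox = list(xlim = c(0, total_w), ylim = c(0, height + corridor_width))
      )
    },
    four_compartment = {
      side <- if (is.null(side)) 3 else side
      gap <- if (is.null(gap)) 1 else gap   # doorway corridors are 1 m long
      pos_check(side, gap, door_width)
      if (length(orientations) != 4L || !all(is.finite(orientations))) {
        stop("`orientations` must be four finite angles", call. = FALSE)
      }
      x2 <- side + gap
      door_lo <- side / 2 - door_width / 2
      door_hi <- side / 2 + door_width / 2
      anchors <- list(c(0, 0), c(x2, 0), c(0, x2), c(x2, x2))
      rooms <- lapply(anchors, function(a) {
        rect_region(a[1], a[1] + side, a[2], a[2] + side)
      })
      names(rooms) <- paste0("C", 1:4)
      frames <- Map(function(phi, a) frame_at(phi, a), orientations, anchors)
      names(frames) <- names(rooms)
      list(
        compartments = rooms,
        corridors = list(
          # doorways centered on the shared walls of each adjacent pair
          door_12 = rect_region(side, x2, door_lo, door_hi),
          door_13 = rect_region(door_lo, door_hi, side, x2),
          door_24 = rect_region(x2 + door_lo, x2 + door_hi, side, x2),
          door_34 = rect_region(side, x2, x2 + door_lo, x2 + door_hi)
        ),
        circle = NULL,
        frames = frames,
        bbox = list(xlim = c(0, x2 + side), ylim = c(0, x2 + side))
      )
    }
  )
  env$kind <- kind
  env$reference <- "C1"
  structure(env, class = "arena_environment")
}

#' @export
print.arena_environment <- function(x, ...) {
  cat(sprintf(
    "<arena_environment> kind = %s, %d compartment(s), %d corridor(s), reference = %s\n",
    x$kind, length(x$compartments) + !is.null(x$circle), length(x$corridors),
    x$reference
  ))
  invisible(x)
}

#' Test whether points lie inside the arena
#'
#' @param env An [build_environment()] arena.
#' @param p A numeric 2-vector or n x 2 matrix of world positions.
#' @return Logical vector, one entry per point.
#' @export
point_in_environment <- function(env, p) {
  stopifnot(inherits(env, "arena_environment"))
  pm <- as_point_matrix(p)
  if (!is.null(env$circle)) {
    dx <- pm[, 1L] - env$circle$center[1L]
    dy <- pm[, 2L] - env$circle$center[2L]
    return(dx * dx + dy * dy <= env$circle$radius^2)
  }
  inside <- rep(FALSE, nrow(pm))
  for (r in c(env$compartments, env$corridors)) {
    inside <- inside | in_rect(r, pm)
  }
  inside
}

#' Compartment containing each point
#'
#' Compartments are checked before corridors, in index order, so a point on
#' a shared edge is deterministically assigned to the lowest-indexed
#' compartment. Corridor points are labelled with the corridor name.
#'
#' @param env An [build_environment()] arena.
#' @param p A numeric 2-vector or n x 2 matrix of world positions; every
#'   point must lie inside the arena.
#' @return Character vector of region labels.
#' @export
compartment_of <- function(env, p) {
  stopifnot(inherits(env, "arena_environment"))
  pm <- as_point_matrix(p)
  if (!is.null(env$circle)) {
    if (!all(point_in_environment(env, pm))) {
      stop("point outside the environment boundary", call. = FALSE)
    }
    return(rep("C1", nrow(pm)))
  }
  lab <- rep(NA_character_, nrow(pm))
  for (nm in names(env$compartments)) {
    hit <- is.na(lab) & in_rect(env$compartments[[nm]], pm)
    lab[hit] <- nm
  }
  for (nm in names(env$corridors)) {
    hit <- is.na(lab) & in_rect(env$corridors[[nm]], pm)
    lab[hit] <- nm
  }
  if (anyNA(lab)) stop("point outside the environment boundary", call. = FALSE)
  lab
}

#' Is a label a corridor of the arena?
#'
#' @param env An [build_environment()] arena.
#' @param label Character vector of region labels.
#' @return Logical vector.
#' @export
is_corridor <- function(env, label) {
  stopifnot(inherits(env, "arena_environment"))
  label %in% names(env$corridors)
}

#' Place frame used at each trajectory position
#'
#' Corridor samples use the reference compartment's frame.
#'
#' @param env An [build_environment()] arena.
#' @param label Character vector of region labels from [compartment_of()].
#' @return Character vector of frame (compartment) names.
#' @export
frame_label <- function(env, label) {
  stopifnot(inherits(env, "arena_environment"))
  ifelse(is_corridor(env, label), env$reference, label)
}
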