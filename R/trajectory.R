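#' Simulate a random-walk foraging trajectory
#'
#' A seedable surrogate for rodent open-field foraging: speed is a constant
#' nominal value with mean-corrected lognormal jitter, heading evolves as a
#' wrapped Gaussian random walk, and a step that would leave the arena
#' triggers uniform re-draws of the heading (the wall is never penetrated;
#' if no admissible heading is found the animal stays put for that step).
#'
#' @param env An [build_environment()] arena.
#' @param n_steps Number of steps (>= 1).
#' @param dt Time step, seconds (> 0).
#' @param speed Nominal speed, m/s.
#' @param speed_sd Log-scale standard deviation of the speed jitter; the
#'   jitter is mean-corrected so the expected speed equals `speed`.
#' @param turn_sd Standard deviation of the per-step heading increment,
#'   radians.
#' @param seed Integer seed; the trajectory is a pure function of
#'   `(env, parameters, seed)`.
#' @param start Optional starting world position; defaults to the center of
#'   the reference compartment (or of the circle).
#' @return A data.frame of class `trajectory` with columns
#'   `t, x, y, v, alpha, compartment` — time (s), world position (m), speed
#'   (m/s), heading (rad) and containing-region label, one row per step.
#' @examples
#' env <- build_environment("square")
#' head(random_walk(env, 100, seed = 1))
#' @export
random_walk <- function(env, n_steps, dt = 0.1, speed = 0.3,
                        speed_sd = 0.1, turn_sd = 0.15, seed,
                        start = NULL) {
  stopifnot(inherits(env, "arena_environment"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("`n_steps` must be >= 1", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (speed < 0) stop("`speed` must be non-negative", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(as.integer(seed))

  if (is.null(start)) {
    start <- if (!is.null(env$circle)) {
      env$circle$center
    } else {
      r <- env$compartments[[env$reference]]
      c(mean(r[c("xmin", "xmax")]), mean(r[c("ymin", "ymax")]))
    }
  }
  start <- as.numeric(start)
  if (!all(point_in_environment(env, start))) {
    stop("`start` must lie inside the environment", call. = FALSE)
  }

  v <- speed * exp(stats::rnorm(n_steps, 0, speed_sd) - speed_sd^2 / 2)
  dalpha <- stats::rnorm(n_steps, 0, turn_sd)

  xs <- numeric(n_steps)
  ys <- numeric(n_steps)
  alpha <- numeric(n_steps)
  px <- start[1L]
  py <- start[2L]
  a_cur <- stats::runif(1, -pi, pi)
  max_tries <- 50L
  for (i in seq_len(n_steps)) {
    a_cur <- wrap_angle(a_cur + dalpha[i])
    step_len <- v[i] * dt
    cx <- px + step_len * cos(a_cur)
    cy <- py + step_len * sin(a_cur)
    if (!point_in_environment(env, c(cx, cy))) {
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        a_cur <- stats::runif(1, -pi, pi)
        cx <- px + step_len * cos(a_cur)
        cy <- py + step_len * sin(a_cur)
        if (point_in_environment(env, c(cx, cy))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        cx <- px
        cy <- py
      }
    }
    px <- cx
    py <- cy
    xs[i] <- px
    ys[i] <- py
    alpha[i] <- a_cur
  }

  out <- data.frame(
    t = seq_len(n_steps) * dt,
    x = xs,
    y = ys,
    v = v,
    alpha = alpha,
    compartment = compartment_of(env, cbind(xs, ys)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Integrate a path from speed and heading samples
#'
#' Rectangular (per-step) path integration:
#' `P[i+1] = P[i] + (v[i] * cos(alpha[i]) * dt[i], v[i] * sin(alpha[i]) * dt[i])`.
#'
#' @param start Numeric 2-vector, the starting position (m).
#' @param v Numeric vector of speeds (m/s).
#' @param alpha Numeric vector of headings (rad), same length as `v`.
#' @param dt Time step(s), seconds; scalar or a vector matching `v`.
#' @return An `(n + 1) x 2` matrix of positions, starting at `start`.
#' @examples
#' path_integrate(c(0, 0), v = rep(1, 4), alpha = c(0, pi/2, pi, 3*pi/2), dt = 1)
#' @export
path_integrate <- function(start, v, alpha, dt) {
  start <- as.numeric(start)
  if (length(start) != 2L || !all(is.finite(start))) {
    stop("`start` must be a finite numeric 2-vector", call. = FALSE)
  }
  if (length(v) != length(alpha)) {
    stop("`v` and `alpha` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(v)) || !all(is.finite(alpha)) || !all(is.finite(dt))) {
    stop("inputs must be finite", call. = FALSE)
  }
  dx <- v * cos(alpha) * dt
  dy <- v * sin(alpha) * dt
  cbind(
    c(start[1L], start[1L] + cumsum(dx)),
    c(start[2L], start[2L] + cumsum(dy)),
    deparse.level = 0
  )
}

#' Write a trajectory to CSV
#'
#' Column-delimited text with header `t,x,y,v,alpha,compartment`.
#'
#' @param trajectory A [random_walk()] trajectory data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path A file written by [write_trajectory()] (or any CSV with
#'   columns `t,x,y,v,alpha,compartment`).
#' @return A `trajectory` data.frame.
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "x", "y", "v", "alpha", "compartment")
  if (!all(needed %in% names(out))) {
    stop("trajectory file must have columns t,x,y,v,alpha,compartment",
         call. = FALSE)
  }
  out <- out[needed]
  class(out) <- c("trajectory", "data.frame")
  out
}
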