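#' Experience-dependent adjustment schedule
#'
#' The per-step adjustment gain is a sigmoid of the experience counter
#' `N_t` (number of trajectory samples taken inside a non-reference
#' compartment):
#' `gamma(N_t) = alpha / (beta + exp(-xi * (N_t - M)))`.
#' The gain is negligible until the animal has accumulated roughly `M`
#' steps of experience in the compartment and then saturates at
#' `alpha / beta`.
#'
#' @param alpha Gain numerator, dimensionless (> 0).
#' @param beta Gain offset, dimensionless (> 0).
#' @param xi Sigmoid steepness per step (>= 0).
#' @param M Experience threshold, steps (>= 0).
#' @return An object of class `adjustment_schedule`.
#' @examples
#' sched <- adjustment_schedule(0.5, 1.0, 0.1, 1e5)
#' gamma_gain(sched, 1e5)  # alpha / (beta + 1) = 0.25
#' @export
adjustment_schedule <- function(alpha = 0.5, beta = 1.0, xi = 0.1, M = 1e5) {
  if (alpha <= 0 || beta <= 0 || xi < 0 || M < 0 ||
      !all(is.finite(c(alpha, beta, xi, M)))) {
    stop("require alpha > 0, beta > 0, xi >= 0, M >= 0, all finite",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, xi = xi, M = M),
            class = "adjustment_schedule")
}

#' @export
print.adjustment_schedule <- function(x, ...) {
  cat(sprintf(
    "<adjustment_schedule> alpha = %.4g, beta = %.4g, xi = %.4g, M = %g\n",
    x$alpha, x$beta, x$xi, x$M
  ))
  invisible(x)
}

#' Adjustment gain at a given experience count
#'
#' @param schedule An [adjustment_schedule()].
#' @param n Experience counter `N_t` (steps); may be a vector.
#' @return `alpha / (beta + exp(-xi * (n - M)))`, in `(0, alpha / beta)`.
#' @export
gamma_gain <- function(schedule, n) {
  stopifnot(inherits(schedule, "adjustment_schedule"))
  schedule$alpha / (schedule$beta + exp(-schedule$xi * (n - schedule$M)))
}

#' Initial frame-adjustment state for an arena
#'
#' Tracks, for every compartment, the current place-frame transform and an
#' experience counter. Non-reference frames are adjusted toward the
#' reference (global) frame; the reference frame never changes.
#'
#' @param env An [build_environment()] arena.
#' @param schedule An [adjustment_schedule()].
#' @param counter `"shared"` (default): the experience counter `N_t` counts
#'   every sample taken in any non-reference compartment, expressing
#'   familiarity with the environment's connectedness; `"per_compartment"`:
#'   each compartment's gain depends only on its own visit count. Both
#'   modes keep per-compartment visit counts for tracing, and in a
#'   two-compartment arena they coincide.
#' @return An object of class `adjustment_state`.
#' @export
adjustment_state <- function(env, schedule = adjustment_schedule(),
                             counter = c("shared", "per_compartment")) {
  stopifnot(inherits(env, "arena_environment"),
            inherits(schedule, "adjustment_schedule"))
  counters <- integer(length(env$frames))
  names(counters) <- names(env$frames)
  structure(
    list(
      frames = env$frames,
      target = env$frames[[env$reference]],
      reference = env$reference,
      schedule = schedule,
      counters = counters,
      counter = match.arg(counter)
    ),
    class = "adjustment_state"
  )
}

#' Experience count governing a compartment's adjustment gain
#'
#' @param state An [adjustment_state()].
#' @param compartment A non-reference compartment label.
#' @return The effective `N_t`: the compartment's own visit count in
#'   `"per_compartment"` mode, the total over all non-reference
#'   compartments in `"shared"` mode.
#' @export
effective_experience <- function(state, compartment) {
  stopifnot(inherits(state, "adjustment_state"))
  if (identical(state$counter, "per_compartment")) {
    state$counters[[compartment]]
  } else {
    sum(state$counters[names(state$counters) != state$reference])
  }
}

#' @export
print.adjustment_state <- function(x, ...) {
  cat(sprintf("<adjustment_state> reference = %s\n", x$reference))
  for (nm in names(x$frames)) {
    d <- frame_difference(x$frames[[nm]], x$target)
    cat(sprintf(
      "  %s: N_t = %d, angle diff = %.4g rad, translation diff = %.4g m\n",
      nm, x$counters[[nm]], d$angle, sqrt(sum(d$translation^2))
    ))
  }
  invisible(x)
}

#' One experience step of frame adjustment
#'
#' Registers one trajectory sample taken inside `compartment` (incrementing
#' its visit count) and moves its place frame a fraction `gamma(N_t)` of
#' the way toward the reference frame, with `N_t` the effective experience
#' under the state's counter mode (see [adjustment_state()]): with the
#' current componentwise difference `(phi, w)` from the target, the new
#' frame has angular difference `(1 - gamma) * phi` and translational
#' difference `(1 - gamma) * w`. The difference is recomputed from the
#' current frames at every step.
#'
#' @param state An [adjustment_state()].
#' @param compartment A non-reference compartment label.
#' @return The updated `adjustment_state`.
#' @export
step_adjustment <- function(state, compartment) {
  stopifnot(inherits(state, "adjustment_state"))
  if (!compartment %in% names(state$frames)) {
    stop("unknown compartment: ", compartment, call. = FALSE)
  }
  if (compartment == state$reference) {
    stop("the reference frame is never adjusted", call. = FALSE)
  }
  state$counters[[compartment]] <- state$counters[[compartment]] + 1L
  g <- gamma_gain(state$schedule, effective_experience(state, compartment))
  cur <- state$frames[[compartment]]
  d <- frame_difference(cur, state$target)
  state$frames[[compartment]] <- frame_transform(
    phi = cur$phi - g * d$angle,
    translation = cur$translation - g * d$translation
  )
  state
}

#' Have all adjusted frames converged to the reference frame?
#'
#' @param state An [adjustment_state()].
#' @param tol_angle Angular tolerance, radians (> 0).
#' @param tol_trans Translational tolerance (Euclidean norm), meters (> 0).
#' @return `TRUE` iff every non-reference frame differs from the reference
#'   by less than both tolerances.
#' @export
has_converged <- function(state, tol_angle = 1e-3, tol_trans = 1e-3) {
  stopifnot(inherits(state, "adjustment_state"))
  if (tol_angle <= 0 || tol_trans <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  for (nm in setdiff(names(state$frames), state$reference)) {
    d <- frame_difference(state$frames[[nm]], state$target)
    if (abs(d$angle) >= tol_angle || sqrt(sum(d$translation^2)) >= tol_trans) {
      return(FALSE)
    }
  }
  TRUE
}
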