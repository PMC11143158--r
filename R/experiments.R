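#' Default experiment configuration
#'
#' Returns the built-in configuration for one of the four experiment kinds,
#' as a nested list that mirrors the YAML config schema:
#' \preformatted{
#' experiment:  single_cell | multi_cell | two_compartment | four_compartment
#' environment: kind + dimensions (see build_environment())
#' cells:       list of {spacing, orientation, phase}
#' firing:      {zeta, kappa}
#' trajectory:  {n_steps, dt, speed, speed_sd, turn_sd, seed}
#' schedule:    {alpha, beta, xi, M}          (connected kinds only)
#' adjust:      logical                       (connected kinds only)
#' snapshots:   step checkpoints for maps / correlation curve
#' bin_size:    rate-map bin, meters
#' }
#' The single-cell default is the worked example: a 5 x 5 m square arena,
#' cell `(spacing 1.0, orientation pi/4, phase (0.5, 0))`, `zeta = 0.4`,
#' `kappa = 3.0`. Connected defaults use the published parameter table:
#' two compartments with cell `(1.5, pi/4, (0, 0))` and schedule
#' `(0.5, 1.0, 0.1, 1e5)`; four compartments with cell `(1.0, pi/4, (0, 0))`
#' and schedule `(0.8, 1.0, 0.2, 1e5)`.
#'
#' @param kind Experiment kind.
#' @return A nested configuration list.
#' @export
default_config <- function(kind = c("single_cell", "multi_cell",
                                    "two_compartment", "four_compartment")) {
  kind <- match.arg(kind)
  base_traj <- list(n_steps = 2e5, dt = 0.1, speed = 0.3,
                    speed_sd = 0.1, turn_sd = 0.15, seed = 1L)
  switch(kind,
    single_cell = list(
      experiment = "single_cell",
      environment = list(kind = "square", side = 5),
      cells = list(list(spacing = 1.0, orientation = pi / 4,
                        phase = c(0.5, 0))),
      firing = list(zeta = 0.4, kappa = 3.0),
      trajectory = base_traj,
      bin_size = 0.1
    ),
    multi_cell = list(
      experiment = "multi_cell",
      environment = list(kind = "circle", radius = 2),
      cells = c(
        # spacing sweep: starts at 0.5, +0.3 per cell
        lapply(c(0.5, 0.8, 1.1), function(s) {
          list(group = "spacing", spacing = s, orientation = 0,
               phase = c(0, 0))
        }),
        # orientation sweep at spacing 1.2, phase (0, 0)
        lapply(c(0, pi / 12, pi / 6), function(th) {
          list(group = "orientation", spacing = 1.2, orientation = th,
               phase = c(0, 0))
        }),
        # phase demonstration
        lapply(list(c(0, 0), c(0.4, 0.8)), function(ph) {
          list(group = "phase", spacing = 1.0, orientation = 0, phase = ph)
        })
      ),
      firing = list(zeta = 0.4, kappa = 3.0),
      trajectory = base_traj,
      bin_size = 0.1
    ),
    two_compartment = list(
      experiment = "two_compartment",
      environment = list(kind = "two_compartment"),
      cells = list(list(spacing = 1.5, orientation = pi / 4,
                        phase = c(0, 0))),
      firing = list(zeta = 0.4, kappa = 3.0),
      schedule = list(alpha = 0.5, beta = 1.0, xi = 0.1, M = 1e5),
      adjust = TRUE,
      trajectory = utils::modifyList(base_traj, list(n_steps = 770000)),
      snapshots = c(10000, 145000, 395000, 770000),
      bin_size = 0.1
    ),
    four_compartment = list(
      experiment = "four_compartment",
      environment = list(kind = "four_compartment", side = 3),
      cells = list(list(spacing = 1.0, orientation = pi / 4,
                        phase = c(0, 0))),
      firing = list(zeta = 0.4, kappa = 3.0),
      schedule = list(alpha = 0.8, beta = 1.0, xi = 0.2, M = 1e5),
      adjust = TRUE,
      trajectory = utils::modifyList(base_traj, list(n_steps = 833000)),
      snapshots = c(50000, 320000, 575000, 833000),
      bin_size = 0.1
    )
  )
}

#' Scale a connected-environment configuration down
#'
#' Divides the step count, experience threshold `M` and snapshot
#' checkpoints by `scale` and multiplies the sigmoid steepness `xi` by
#' `scale`, so the adjustment gain traverses the same sigmoid over the
#' shorter run. Convergence depends only on the gain's sigmoid shape, not
#' on absolute step counts, so scaled runs reproduce the full-scale course.
#'
#' @param config A [default_config()]-style list.
#' @param scale Positive divisor (default 50).
#' @return The scaled configuration.
#' @export
scaled_config <- function(config, scale = 50) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  config$trajectory$n_steps <- max(1, round(config$trajectory$n_steps / scale))
  if (!is.null(config$schedule)) {
    config$schedule$M <- round(config$schedule$M / scale)
    config$schedule$xi <- config$schedule$xi * scale
  }
  if (!is.null(config$snapshots)) {
    config$snapshots <- pmax(1, round(config$snapshots / scale))
  }
  config
}

#' Read an experiment configuration from a YAML file
#'
#' Unset keys fall back to the defaults of the file's `experiment` kind.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment)) {
    stop("config error: key `experiment` is required", call. = FALSE)
  }
  config <- utils::modifyList(default_config(raw$experiment), raw)
  config
}

validate_config <- function(config, connected = FALSE) {
  tr <- config$trajectory
  if (is.null(tr$seed)) {
    stop("config error: key `trajectory.seed` is required", call. = FALSE)
  }
  if (is.null(tr$n_steps) || tr$n_steps < 1) {
    stop("config error: key `trajectory.n_steps` must be >= 1", call. = FALSE)
  }
  if (is.null(tr$dt) || tr$dt <= 0) {
    stop("config error: key `trajectory.dt` must be > 0", call. = FALSE)
  }
  if (is.null(config$cells) || length(config$cells) < 1L) {
    stop("config error: key `cells` must list at least one grid cell",
         call. = FALSE)
  }
  if (connected) {
    if (is.null(config$schedule)) {
      stop("config error: key `schedule` is required for connected runs",
           call. = FALSE)
    }
    if (!config$environment$kind %in% c("two_compartment",
                                        "four_compartment")) {
      stop("config error: key `environment.kind` must be two_compartment ",
           "or four_compartment", call. = FALSE)
    }
  }
  if (!is.null(config$snapshots) &&
      (is.unsorted(config$snapshots) ||
       any(config$snapshots > tr$n_steps))) {
    stop("config error: key `snapshots` must be ascending and <= n_steps",
         call. = FALSE)
  }
  invisible(config)
}

config_cell <- function(spec) {
  grid_cell(spec$spacing,
            if (is.null(spec$orientation)) 0 else spec$orientation,
            if (is.null(spec$phase)) c(0, 0) else spec$phase)
}

config_env <- function(config) {
  do.call(build_environment, config$environment)
}

config_walk <- function(config, env) {
  tr <- config$trajectory
  random_walk(env, n_steps = tr$n_steps, dt = tr$dt, speed = tr$speed,
              speed_sd = if (is.null(tr$speed_sd)) 0.1 else tr$speed_sd,
              turn_sd = if (is.null(tr$turn_sd)) 0.15 else tr$turn_sd,
              seed = tr$seed)
}

write_png_map <- function(map, path, main) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  plot(map, main = main)
}

#' Run the single-cell firing-field experiment
#'
#' Simulates a random walk, computes firing rates, bins a rate map,
#' enumerates analytic field centers, and recovers the lattice parameters
#' and the axis-profile bump offsets.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory; when given, writes the
#'   activation CSV (`t,x,y,rate`), rate-map CSV and PNG, and a summary
#'   JSON.
#' @return A list with the trajectory, rates, `rate_map`, analytic
#'   `centers`, the `estimate` from [estimate_lattice_params()] and a
#'   `summary` list (estimated spacing/orientation/phase and the first
#'   profile-peak offset along each axis).
#' @export
run_single_cell <- function(config = default_config("single_cell"),
                            out_dir = NULL) {
  validate_config(config)
  env <- config_env(config)
  cell <- config_cell(config$cells[[1L]])
  params <- firing_params(config$firing$zeta, config$firing$kappa)
  traj <- config_walk(config, env)
  pos <- cbind(traj$x, traj$y)
  rates <- firing_rate(cell, params, pos)
  map <- bin_rate_map(pos, rates, bin_size = config$bin_size,
                      xlim = env$bbox$xlim, ylim = env$bbox$ylim)
  centers <- field_centers(cell, env)
  est <- estimate_lattice_params(centers)
  half_len <- min(diff(env$bbox$xlim), diff(env$bbox$ylim)) / 2
  p1 <- profile_peaks(profile_along_axis(cell, params, 1, half_len))
  p2 <- profile_peaks(profile_along_axis(cell, params, 2, half_len))
  summary <- list(
    spacing = est$spacing,
    orientation = est$orientation,
    phase = est$phase,
    first_peak_axis1 = abs(p1[1L]),
    first_peak_axis2 = abs(p2[1L]),
    max_rate = max(rates),
    min_rate = min(rates)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(t = traj$t, x = traj$x, y = traj$y, rate = rates),
      file.path(out_dir, "activations.csv"), row.names = FALSE, quote = FALSE
    )
    write_rate_map(map, file.path(out_dir, "rate_map.csv"))
    write_png_map(map, file.path(out_dir, "rate_map.png"),
                  "single-cell firing field")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(env = env, trajectory = traj, rates = rates, map = map,
       centers = centers, estimate = est, summary = summary)
}

#' Run the multi-cell parameter-sweep experiment
#'
#' For every configured cell (by default a spacing sweep, an orientation
#' sweep and a phase pair), enumerates analytic field centers, recovers the
#' lattice parameters, and reports the nearest-bump offset along both axes.
#' A single shared trajectory provides per-cell rate maps.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory (per-cell map PNGs and a
#'   summary CSV/JSON).
#' @return A list with the shared trajectory, the per-cell `rate_map`s and
#'   a `summary` data.frame (one row per cell: true and estimated spacing /
#'   orientation / phase, axis bump offsets).
#' @export
run_multi_cell <- function(config = default_config("multi_cell"),
                           out_dir = NULL) {
  validate_config(config)
  env <- config_env(config)
  params <- firing_params(config$firing$zeta, config$firing$kappa)
  traj <- config_walk(config, env)
  pos <- cbind(traj$x, traj$y)
  rows <- list()
  maps <- list()
  for (i in seq_along(config$cells)) {
    spec <- config$cells[[i]]
    cell <- config_cell(spec)
    est <- estimate_lattice_params(field_centers(cell, env))
    rates <- firing_rate(cell, params, pos)
    maps[[i]] <- bin_rate_map(pos, rates, bin_size = config$bin_size,
                              xlim = env$bbox$xlim, ylim = env$bbox$ylim)
    rows[[i]] <- data.frame(
      cell = i,
      group = if (is.null(spec$group)) "cell" else spec$group,
      spacing = cell$spacing,
      orientation = cell$orientation,
      phase1 = cell$phase[1L],
      phase2 = cell$phase[2L],
      spacing_hat = est$spacing,
      orientation_hat = est$orientation,
      phase1_hat = est$phase[1L],
      phase2_hat = est$phase[2L],
      bump_axis1 = nearest_center_distance_along_axis(cell, 1),
      bump_axis2 = nearest_center_distance_along_axis(cell, 2)
    )
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_along(maps)) {
      write_png_map(maps[[i]], file.path(out_dir, sprintf("cell_%02d.png", i)),
                    sprintf("cell %d (%s)", i, summary$group[i]))
    }
  }
  list(env = env, trajectory = traj, maps = maps, summary = summary)
}

rates_under_frames <- function(env, cell, params, pos, labels, frames) {
  out <- numeric(nrow(pos))
  flab <- frame_label(env, labels)
  for (nm in unique(flab)) {
    sel <- flab == nm
    place <- apply_transform(frames[[nm]], pos[sel, , drop = FALSE])
    out[sel] <- firing_rate(cell, params, place)
  }
  out
}

#' Run a connected-environment experiment
#'
#' Simulates a random walk through a multi-compartment arena. With
#' `adjust = FALSE` the compartment place frames stay fixed, so the firing
#' pattern replicates across compartments (identical local fields); the
#' result reports the Pearson correlation between each compartment's map
#' and the reference compartment's map after aligning frames. With
#' `adjust = TRUE`, every sample taken inside a non-reference compartment
#' advances that compartment's experience counter and moves its frame a
#' gain-weighted step toward the global frame; the result contains the
#' correlation-of-global-fit curve (current-frame map vs all-in-reference
#' ideal map, corridor bins excluded, recomputed over the full trajectory
#' at each checkpoint) and the final convergence state.
#'
#' @param config Configuration list (see [default_config()]), kind
#'   `two_compartment` or `four_compartment`.
#' @param out_dir Optional output directory (snapshot map PNG/CSVs,
#'   correlation curve CSV, adjustment trace CSV, summary JSON).
#' @param curve_points Number of evenly spaced checkpoints for the
#'   correlation curve (snapshot steps are always included).
#' @return A list with the trajectory, `correlation` (data.frame
#'   `step, r`), `trace` (data.frame `step, compartment, N_t, gamma,
#'   angle_diff, trans_diff_x, trans_diff_y`), `snapshot_maps`,
#'   `final_state`, `converged`, and (adjustment off) `aligned_r` per
#'   non-reference compartment.
#' @export
run_connected <- function(config = default_config("two_compartment"),
                          out_dir = NULL, curve_points = 21L) {
  validate_config(config, connected = TRUE)
  env <- config_env(config)
  cell <- config_cell(config$cells[[1L]])
  params <- firing_params(config$firing$zeta, config$firing$kappa)
  sched <- do.call(adjustment_schedule, config$schedule)
  traj <- config_walk(config, env)
  n <- nrow(traj)
  pos <- cbind(traj$x, traj$y)
  labels <- traj$compartment
  adjust <- isTRUE(config$adjust)

  ideal_frames <- stats::setNames(
    rep(list(frame_transform()), length(env$frames)), names(env$frames)
  )
  ideal_rates <- rates_under_frames(env, cell, params, pos, labels,
                                    ideal_frames)
  keep <- !is_corridor(env, labels)
  ideal_map <- bin_rate_map(pos[keep, , drop = FALSE], ideal_rates[keep],
                            bin_size = config$bin_size,
                            xlim = env$bbox$xlim, ylim = env$bbox$ylim)

  checkpoints <- sort(unique(c(
    round(seq(1, n, length.out = curve_points)),
    config$snapshots[config$snapshots <= n]
  )))

  state <- adjustment_state(
    env, sched,
    counter = if (is.null(config$counter)) "shared" else config$counter
  )
  frames_at <- list()
  trace <- list()
  if (adjust) {
    non_ref <- setdiff(names(env$frames), env$reference)
    ci <- 1L
    for (i in seq_len(n)) {
      lab <- labels[i]
      if (lab %in% non_ref) {
        state <- step_adjustment(state, lab)
      }
      if (ci <= length(checkpoints) && i == checkpoints[ci]) {
        frames_at[[ci]] <- state$frames
        for (nm in non_ref) {
          d <- frame_difference(state$frames[[nm]], state$target)
          trace[[length(trace) + 1L]] <- data.frame(
            step = i, compartment = nm, N_t = state$counters[[nm]],
            gamma = gamma_gain(sched, effective_experience(state, nm)),
            angle_diff = d$angle,
            trans_diff_x = d$translation[1L],
            trans_diff_y = d$translation[2L]
          )
        }
        ci <- ci + 1L
      }
    }
  } else {
    frames_at <- rep(list(env$frames), length(checkpoints))
  }

  r_curve <- vapply(seq_along(checkpoints), function(k) {
    rk <- rates_under_frames(env, cell, params, pos, labels, frames_at[[k]])
    mk <- bin_rate_map(pos[keep, , drop = FALSE], rk[keep],
                       bin_size = config$bin_size,
                       xlim = env$bbox$xlim, ylim = env$bbox$ylim)
    global_fit_correlation(mk, ideal_map)
  }, numeric(1))
  correlation <- data.frame(step = checkpoints, r = r_curve)

  # per-compartment maps in local frame coordinates (replication check)
  aligned_r <- NULL
  if (!adjust) {
    local_window <- function(nm) {
      r <- env$compartments[[nm]]
      corners <- cbind(r[c("xmin", "xmax", "xmin", "xmax")],
                       r[c("ymin", "ymin", "ymax", "ymax")])
      lc <- apply_transform(env$frames[[nm]], corners)
      list(xlim = range(lc[, 1L]), ylim = range(lc[, 2L]))
    }
    # half-size bins + an occupancy floor: the comparison error is
    # dominated by within-bin sampling bias (gradient x mean sample
    # offset), which shrinks with the bin and with samples per bin
    cmp_bin <- config$bin_size / 2
    local_map <- function(nm, lims) {
      sel <- labels == nm
      place <- apply_transform(env$frames[[nm]], pos[sel, , drop = FALSE])
      m <- bin_rate_map(place, firing_rate(cell, params, place),
                        bin_size = cmp_bin,
                        xlim = lims$xlim, ylim = lims$ylim)
      m$rate[m$occupancy < 2L] <- NA
      m
    }
    windows <- lapply(names(env$compartments), local_window)
    names(windows) <- names(env$compartments)
    same_window <- all(vapply(windows, function(w) {
      isTRUE(all.equal(w, windows[[env$reference]], tolerance = 1e-8))
    }, logical(1)))
    others <- setdiff(names(env$compartments), env$reference)
    if (same_window) {
      # equal orientations: local windows coincide, compare maps directly
      ref_map <- local_map(env$reference, windows[[env$reference]])
      aligned_r <- vapply(others, function(nm) {
        global_fit_correlation(local_map(nm, windows[[nm]]), ref_map)
      }, numeric(1))
    } else {
      # rotated frames sample disjoint windows of the same lattice field:
      # compare each local map against the analytic field on its own grid
      aligned_r <- vapply(others, function(nm) {
        m <- local_map(nm, windows[[nm]])
        ref <- analytic_rate_map(cell, params, cmp_bin, m$xlim, m$ylim)
        global_fit_correlation(m, ref)
      }, numeric(1))
    }
  }

  snap_idx <- match(intersect(config$snapshots, checkpoints), checkpoints)
  snapshot_maps <- lapply(snap_idx, function(k) {
    rk <- rates_under_frames(env, cell, params, pos, labels, frames_at[[k]])
    bin_rate_map(pos[keep, , drop = FALSE], rk[keep],
                 bin_size = config$bin_size,
                 xlim = env$bbox$xlim, ylim = env$bbox$ylim)
  })
  names(snapshot_maps) <- paste0("step_", checkpoints[snap_idx])

  trace <- if (length(trace)) do.call(rbind, trace) else NULL
  converged <- adjust && has_converged(state)
  out <- list(env = env, trajectory = traj, correlation = correlation,
              trace = trace, snapshot_maps = snapshot_maps,
              final_state = state, converged = converged,
              aligned_r = aligned_r)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(correlation, file.path(out_dir, "correlation.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(trace)) {
      utils::write.csv(trace, file.path(out_dir, "adjustment_trace.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    for (nm in names(snapshot_maps)) {
      write_rate_map(snapshot_maps[[nm]],
                     file.path(out_dir, paste0("map_", nm, ".csv")))
      write_png_map(snapshot_maps[[nm]],
                    file.path(out_dir, paste0("map_", nm, ".png")), nm)
    }
    jsonlite::write_json(
      list(converged = converged,
           final_r = correlation$r[nrow(correlation)],
           aligned_r = aligned_r),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
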