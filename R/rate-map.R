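#' Bin sampled firing rates into an occupancy-normalized rate map
#'
#' Bins are half-open `[lo, lo + bin_size)` in both axes; each visited bin
#' holds the mean of the rates sampled inside it. Samples exactly on the
#' upper map edge are assigned to the last bin.
#'
#' @param positions An n x 2 matrix (or 2-vector) of positions, meters.
#' @param rates Numeric vector of firing rates, one per position.
#' @param bin_size Bin side length, meters (> 0).
#' @param xlim,ylim Map extent; defaults to the range of the positions.
#' @return An object of class `rate_map`: a list with `bin_size`, `xlim`,
#'   `ylim`, `xcenters`, `ycenters`, `rate` (matrix, `NA` where unvisited)
#'   and `occupancy` (matrix of sample counts). Rows index x-bins, columns
#'   y-bins.
#' @export
bin_rate_map <- function(positions, rates, bin_size = 0.1,
                         xlim = NULL, ylim = NULL) {
  pm <- as_point_matrix(positions)
  if (nrow(pm) == 0L) stop("at least one sample is required", call. = FALSE)
  if (length(rates) != nrow(pm)) {
    stop("`rates` must have one value per position", call. = FALSE)
  }
  if (bin_size <= 0) stop("`bin_size` must be positive", call. = FALSE)
  if (is.null(xlim)) xlim <- range(pm[, 1L])
  if (is.null(ylim)) ylim <- range(pm[, 2L])
  nx <- max(1L, as.integer(ceiling((xlim[2] - xlim[1]) / bin_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ylim[2] - ylim[1]) / bin_size - 1e-9)))
  ix <- pmin(pmax(floor((pm[, 1L] - xlim[1]) / bin_size), 0), nx - 1L) + 1L
  iy <- pmin(pmax(floor((pm[, 2L] - ylim[1]) / bin_size), 0), ny - 1L) + 1L
  idx <- (iy - 1L) * nx + ix

  occ <- tabulate(idx, nbins = nx * ny)
  sums <- numeric(nx * ny)
  agg <- rowsum(rates, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  mean_rate <- ifelse(occ > 0L, sums / pmax(occ, 1L), NA_real_)

  structure(
    list(
      bin_size = bin_size,
      xlim = xlim,
      ylim = ylim,
      xcenters = xlim[1] + (seq_len(nx) - 0.5) * bin_size,
      ycenters = ylim[1] + (seq_len(ny) - 0.5) * bin_size,
      rate = matrix(mean_rate, nx, ny),
      occupancy = matrix(occ, nx, ny)
    ),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate_map> %d x %d bins of %.3g m, %.1f%% visited, mean rate %.3f\n",
    nrow(x$rate), ncol(x$rate), x$bin_size,
    100 * mean(x$occupancy > 0), mean(x$rate, na.rm = TRUE)
  ))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    isTRUE(all.equal(a$xlim, b$xlim)) &&
    isTRUE(all.equal(a$ylim, b$ylim)) &&
    all(dim(a$rate) == dim(b$rate))
}

#' Pearson correlation of global fit between two rate maps
#'
#' Quantifies how close the current firing pattern is to the
#' single-global-frame ideal pattern: the Pearson correlation over jointly
#' visited bins between the map produced under the current (possibly
#' mid-adjustment) frame assignments and the map produced with every
#' compartment expressed in the reference frame. Near 0/low under
#' replicated local fields, 1 under a globally coherent field.
#'
#' @param current,reference `rate_map` objects on the same bin grid.
#' @return Pearson r in `[-1, 1]`.
#' @export
global_fit_correlation <- function(current, reference) {
  stopifnot(inherits(current, "rate_map"), inherits(reference, "rate_map"))
  if (!same_grid(current, reference)) {
    stop("rate maps must share the same bin grid", call. = FALSE)
  }
  joint <- !is.na(current$rate) & !is.na(reference$rate)
  if (sum(joint) < 2L) {
    stop("need at least two jointly visited bins", call. = FALSE)
  }
  a <- current$rate[joint]
  b <- reference$rate[joint]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: a map has zero variance over joint bins",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Estimate lattice parameters from firing-field centers
#'
#' Recovers spacing, orientation and phase of the generating hexagonal
#' lattice from a set of field-center positions: spacing as the modal
#' nearest-neighbor distance, orientation as the circular mean (period
#' pi/3) of neighbor directions, and phase as the lattice coordinate of the
#' center nearest the origin, wrapped into `[0, 1)^2`.
#'
#' @param centers An n x 2 matrix of center positions (n >= 7: at least one
#'   interior point plus its hexagonal ring).
#' @return A list with `spacing` (m), `orientation` (rad, in `[0, pi/3)`)
#'   and `phase` (lattice units in `[0, 1)^2`).
#' @export
estimate_lattice_params <- function(centers) {
  centers <- as_point_matrix(centers)
  if (nrow(centers) < 7L) {
    stop("need at least 7 centers (interior point + hexagonal ring)",
         call. = FALSE)
  }
  sv <- svd(scale(centers, scale = FALSE))$d
  if (sv[2] < 1e-8 * sv[1]) {
    stop("centers are collinear; lattice parameters are not identifiable",
         call. = FALSE)
  }
  dm <- as.matrix(stats::dist(centers))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  med <- stats::median(nn)
  s_hat <- mean(nn[abs(nn - med) < 0.25 * med])

  # neighbor directions, folded by the lattice's 60-degree symmetry
  nbr <- which(dm > 0.8 * s_hat & dm < 1.2 * s_hat, arr.ind = TRUE)
  if (nrow(nbr) == 0L) {
    stop("no neighbor pairs near the modal spacing", call. = FALSE)
  }
  dx <- centers[nbr[, 2L], 1L] - centers[nbr[, 1L], 1L]
  dy <- centers[nbr[, 2L], 2L] - centers[nbr[, 1L], 2L]
  folded <- atan2(dy, dx) %% (pi / 3)
  theta_hat <- (Arg(mean(exp(6i * folded))) / 6) %% (pi / 3)
  if (pi / 3 - theta_hat < 1e-9) theta_hat <- 0  # wrap boundary

  ref_cell <- grid_cell(s_hat, theta_hat, c(0, 0))
  i0 <- which.min(rowSums(centers^2))
  g0 <- drop(place_to_grid_matrix(ref_cell) %*% centers[i0, ])
  phase_hat <- g0 %% 1
  phase_hat[1 - phase_hat < 1e-9] <- 0           # wrap boundary
  list(spacing = s_hat, orientation = theta_hat, phase = phase_hat)
}

#' Firing-rate profile along a lattice basis axis
#'
#' Samples the firing rate along the ray from the place-frame origin in the
#' direction of basis vector 1 or 2; the profile's local maxima are the
#' firing-field "bumps" whose offsets expose the cell's per-axis phase and
#' spacing.
#'
#' @param cell A [grid_cell()].
#' @param params A [firing_params()].
#' @param axis 1 or 2.
#' @param half_length Profile extent on each side of the origin, meters.
#' @param step Sampling step, meters (> 0).
#' @return A data.frame with columns `offset` (m, signed along the ray) and
#'   `rate`.
#' @export
profile_along_axis <- function(cell, params, axis, half_length = 2.5,
                               step = 0.01) {
  stopifnot(is_grid_cell(cell))
  if (!axis %in% c(1, 2)) stop("`axis` must be 1 or 2", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  b <- basis_vectors(cell)
  u <- if (axis == 1) b$eps1 else b$eps2
  u <- u / sqrt(sum(u^2))
  offset <- seq(-half_length, half_length, by = step)
  pts <- cbind(offset * u[1L], offset * u[2L])
  data.frame(offset = offset, rate = firing_rate(cell, params, pts))
}

#' Local maxima of an axis profile
#'
#' @param profile A data.frame from [profile_along_axis()].
#' @return Offsets (m) of strict local maxima of the rate profile, sorted
#'   by absolute offset.
#' @export
profile_peaks <- function(profile) {
  r <- profile$rate
  n <- length(r)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1)
  peak <- i[r[i] > r[i - 1] & r[i] >= r[i + 1]]
  off <- profile$offset[peak]
  off[order(abs(off))]
}

boxcar3 <- function(r) {
  nx <- nrow(r)
  ny <- ncol(r)
  sm <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (di in -1:1) {
    for (dj in -1:1) {
      si <- max(1, 1 + di):min(nx, nx + di)
      sj <- max(1, 1 + dj):min(ny, ny + dj)
      ti <- si - di
      tj <- sj - dj
      v <- r[si, sj, drop = FALSE]
      ok <- !is.na(v)
      v[!ok] <- 0
      sm[ti, tj] <- sm[ti, tj] + v
      cnt[ti, tj] <- cnt[ti, tj] + ok
    }
  }
  out <- ifelse(cnt > 0, sm / cnt, NA_real_)
  out[is.na(r)] <- NA_real_
  out
}

#' Detect firing-field peaks in a binned rate map
#'
#' A bin is a peak when its raw rate exceeds `threshold` and its (optionally
#' 3 x 3 boxcar-smoothed) rate is the maximum over a square window of
#' `window` bins on each side; smoothing suppresses spurious maxima from
#' occupancy noise while the raw-rate threshold keeps narrow bumps (a
#' smoothed value would dilute fields only one or two bins wide below the
#' threshold). Peaks whose full window lies inside the map are refined to
#' sub-bin accuracy by the centroid of the above-threshold rate mass in
#' their window; edge peaks keep their bin center. Unvisited bins are
#' treated as unavailable.
#'
#' @param map A `rate_map`.
#' @param threshold Minimum rate for a peak (default 0.5, the sigmoid
#'   midpoint).
#' @param window Neighborhood radius in bins (default 2); choose roughly a
#'   third of the expected field spacing for well-separated peaks.
#' @param smooth Smooth before locating maxima (default `TRUE`).
#' @param refine Centroid-refine interior peaks (default `TRUE`).
#' @return An n x 2 matrix of peak positions (meters).
#' @export
find_rate_map_peaks <- function(map, threshold = 0.5, window = 2L,
                                smooth = TRUE, refine = TRUE) {
  stopifnot(inherits(map, "rate_map"))
  raw <- map$rate
  nx <- nrow(raw)
  ny <- ncol(raw)
  r <- if (smooth) boxcar3(raw) else raw
  w <- as.integer(window)
  rpad <- matrix(-Inf, nx + 2L * w, ny + 2L * w)
  inner <- r
  inner[is.na(inner)] <- -Inf
  rpad[w + seq_len(nx), w + seq_len(ny)] <- inner
  neigh_max <- matrix(-Inf, nx, ny)
  for (di in -w:w) {
    for (dj in -w:w) {
      if (di == 0L && dj == 0L) next
      neigh_max <- pmax(
        neigh_max,
        rpad[w + di + seq_len(nx), w + dj + seq_len(ny)]
      )
    }
  }
  is_peak <- !is.na(raw) & raw > threshold & inner > neigh_max
  idx <- which(is_peak, arr.ind = TRUE)
  out <- cbind(map$xcenters[idx[, 1L]], map$ycenters[idx[, 2L]],
               deparse.level = 0)
  if (refine && nrow(out)) {
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]
      j <- idx[k, 2L]
      if (i <= w || i > nx - w || j <= w || j > ny - w) next
      ii <- (i - w):(i + w)
      jj <- (j - w):(j + w)
      wt <- pmax(raw[ii, jj, drop = FALSE] - threshold, 0)
      wt[is.na(wt)] <- 0
      if (sum(wt) <= 0) next
      out[k, 1L] <- sum(outer(map$xcenters[ii], rep(1, length(jj))) * wt) /
        sum(wt)
      out[k, 2L] <- sum(outer(rep(1, length(ii)), map$ycenters[jj]) * wt) /
        sum(wt)
    }
  }
  out
}

#' Write a rate map as a CSV grid
#'
#' Two comment lines record the bin size and extent, then the rate matrix
#' is written with x-bins as rows and y-bins as columns (`NA` = unvisited).
#'
#' @param map A `rate_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_map <- function(map, path) {
  stopifnot(inherits(map, "rate_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%.17g", map$bin_size), con)
  writeLines(sprintf("# xlim=%.17g,%.17g ylim=%.17g,%.17g",
                     map$xlim[1], map$xlim[2], map$ylim[1], map$ylim[2]), con)
  utils::write.table(map$rate, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot a rate map
#'
#' @param x A `rate_map`.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot.rate_map <- function(x, main = "firing rate", ...) {
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x$xcenters, x$ycenters, x$rate, col = pal,
                  zlim = c(0, 1), asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, ...)
  invisible(x)
}

#' Analytic rate map on a regular grid
#'
#' Evaluates the firing rate at every bin center (no sampling, no
#' occupancy); useful as the noise-free reference a binned empirical map
#' converges to.
#'
#' @param cell A [grid_cell()].
#' @param params A [firing_params()].
#' @param bin_size Bin side length, meters.
#' @param xlim,ylim Map extent, meters.
#' @return A `rate_map` whose every bin holds the rate at the bin center
#'   (occupancy 1 everywhere).
#' @export
analytic_rate_map <- function(cell, params, bin_size, xlim, ylim) {
  nx <- max(1L, as.integer(ceiling((xlim[2] - xlim[1]) / bin_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ylim[2] - ylim[1]) / bin_size - 1e-9)))
  xc <- xlim[1] + (seq_len(nx) - 0.5) * bin_size
  yc <- ylim[1] + (seq_len(ny) - 0.5) * bin_size
  pts <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  structure(
    list(
      bin_size = bin_size, xlim = xlim, ylim = ylim,
      xcenters = xc, ycenters = yc,
      rate = matrix(firing_rate(cell, params, pts), nx, ny),
      occupancy = matrix(1L, nx, ny)
    ),
    class = "rate_map"
  )
}

#' Fit lattice parameters to a binned rate map
#'
#' Model-based refinement of [estimate_lattice_params()] for empirical
#' (sampled, noisy) maps: maximizes the Pearson correlation between the
#' map's visited bins and the analytic rate field over spacing, orientation
#' and phase. Initial values come from peak detection when possible; the
#' phase is multi-started on a coarse grid because the correlation surface
#' is periodic in it.
#'
#' @param map A `rate_map` of sampled firing rates.
#' @param params The [firing_params()] the rates were generated with.
#' @param init Optional list with `spacing`, `orientation`, `phase` used as
#'   the starting point (defaults to the peak-detection estimate).
#' @param window Peak-detection window for the initializer, bins.
#' @return A list with `spacing`, `orientation` (wrapped to `[0, pi/3)`),
#'   `phase` (wrapped to `[0, 1)^2`) and `correlation`, the achieved fit.
#' @export
fit_lattice_to_map <- function(map, params, init = NULL, window = 2L) {
  stopifnot(inherits(map, "rate_map"))
  visited <- !is.na(map$rate)
  obs <- map$rate[visited]
  if (length(obs) < 10L || stats::sd(obs) == 0) {
    stop("map has too few visited bins (or no variance) to fit", call. = FALSE)
  }
  if (is.null(init)) {
    init <- tryCatch(
      estimate_lattice_params(find_rate_map_peaks(map, window = window)),
      error = function(e) list(spacing = 5 * map$bin_size, orientation = 0,
                               phase = c(0, 0))
    )
  }
  objective <- function(par) {
    s <- exp(par[1])
    cand <- analytic_rate_map(grid_cell(s, par[2], par[3:4]), params,
                              map$bin_size, map$xlim, map$ylim)
    pred <- cand$rate[visited]
    if (stats::sd(pred) == 0) return(1)
    -stats::cor(obs, pred)
  }
  starts <- expand.grid(p1 = c(0, 1 / 3, 2 / 3), p2 = c(0, 1 / 3, 2 / 3))
  starts <- rbind(c(init$phase), as.matrix(starts))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(
      c(log(init$spacing), init$orientation, starts[k, 1], starts[k, 2]),
      objective, method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-10)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(
    spacing = exp(best$par[1]),
    orientation = best$par[2] %% (pi / 3),
    phase = best$par[3:4] %% 1,
    correlation = -best$value
  )
}
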