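# shared fixtures and small independent oracles

# the single-cell worked-example configuration
worked_cell <- function() grid_cell(1.0, pi / 4, c(0.5, 0))

random_transform <- function() {
  frame_transform(stats::runif(1, -pi, pi), stats::runif(2, -5, 5))
}

random_cell <- function() {
  grid_cell(stats::runif(1, 0.5, 2),
            stats::runif(1, 0, pi / 3),
            stats::runif(2, 0, 1))
}

# brute-force nearest neighbors of center i within a center set
brute_force_neighbors <- function(centers, i) {
  d <- sqrt(rowSums(sweep(centers, 2L, centers[i, ])^2))
  ord <- order(d)
  list(dist = d[ord][-1L], idx = ord[-1L])
}

# smallest absolute difference between two angles on a circle of the
# given period
angle_gap <- function(a, b, period = 2 * pi) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
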