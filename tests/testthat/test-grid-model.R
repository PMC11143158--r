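test_that("basis vectors have the preferred spacing and subtend exactly 60 degrees", {
  b <- basis_vectors(grid_cell(1, 0))
  expect_equal(b$eps1, c(1, 0))
  expect_equal(b$eps2, c(0.5, 0.8660254), tolerance = 1e-7)
  b2 <- basis_vectors(grid_cell(2, 0))
  expect_equal(b2$eps1, c(2, 0))
  expect_equal(b2$eps2, c(1, 1.7320508), tolerance = 1e-7)
  b3 <- basis_vectors(grid_cell(1, pi / 4))
  expect_equal(b3$eps1, c(0.70710678, 0.70710678), tolerance = 1e-7)
  expect_equal(b3$eps2, c(-0.25881905, 0.96592583), tolerance = 1e-7)

  set.seed(1)
  for (i in 1:10) {
    b <- basis_vectors(random_cell())
    cosang <- sum(b$eps1 * b$eps2) / sqrt(sum(b$eps1^2) * sum(b$eps2^2))
    expect_equal(acos(cosang), pi / 3, tolerance = 1e-12)
  }
})

test_that("the place-to-lattice matrix inverts the basis", {
  cell <- grid_cell(1, 0)
  R <- place_to_grid_matrix(cell)
  b <- basis_vectors(cell)
  expect_equal(drop(R %*% b$eps1), c(1, 0), tolerance = 1e-12)
  expect_equal(drop(R %*% b$eps2), c(0, 1), tolerance = 1e-12)
  # frozen numeric inversion for the worked orientation
  expect_equal(place_to_grid_matrix(grid_cell(1, pi / 4)),
               matrix(c(1.11536, -0.81650, 0.29886, 0.81650), 2, 2),
               tolerance = 1e-5)
  set.seed(2)
  for (i in 1:10) {
    cell <- random_cell()
    expect_equal(det(place_to_grid_matrix(cell)) * cell$spacing^2 * sin(pi / 3),
                 1, tolerance = 1e-12)
  }
})

test_that("place positions map to lattice coordinates minus the phase", {
  expect_equal(place_to_grid(grid_cell(1.3, 0.2), c(0, 0)), c(0, 0))
  expect_equal(place_to_grid(grid_cell(1, pi / 4, c(0.5, 0)), c(0, 0)),
               c(-0.5, 0))
  cell <- grid_cell(1, pi / 4)
  expect_equal(place_to_grid(cell, basis_vectors(cell)$eps1), c(1, 0),
               tolerance = 1e-12)
})

test_that("lattice distance rounds componentwise with ties away from zero", {
  expect_equal(lattice_distance(c(0, 0)), 0)
  expect_equal(lattice_distance(c(2, -3)), 0)
  expect_equal(lattice_distance(c(0.5, 0)), 0.5)
  expect_equal(lattice_distance(c(-0.5, 0)), 0.5)
  expect_equal(lattice_distance(c(0.3, -0.4)), 0.5)
  expect_equal(lattice_distance(c(0.3, -0.4), method = "squared"), 0.25)
  expect_equal(lattice_distance(rbind(c(0.5, 0), c(1, 1))), c(0.5, 0))
})

test_that("firing rate is a bounded decreasing sigmoid of lattice distance", {
  params <- firing_params(zeta = 0.4, kappa = 3)
  cell <- grid_cell(1, 0)
  # midpoint: d/s = zeta
  expect_equal(firing_rate(cell, params, c(0.4, 0)), 0.5, tolerance = 1e-12)
  # maximum at a preferred position: 0.5 + atan(kappa * zeta) / pi
  expect_equal(firing_rate(cell, params, c(0, 0)), 0.77886, tolerance = 1e-5)
  # monotone non-increasing in distance along a ray toward the midpoint
  d <- seq(0, 0.5, by = 0.01)
  r <- firing_rate(cell, params, cbind(d, 0))
  expect_true(all(diff(r) <= 1e-12))
  set.seed(3)
  p <- matrix(stats::runif(400, -10, 10), ncol = 2)
  r <- firing_rate(random_cell(), params, p)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("firing rate is invariant under lattice translations", {
  params <- firing_params()
  set.seed(4)
  for (i in 1:20) {
    cell <- random_cell()
    b <- basis_vectors(cell)
    p <- stats::runif(2, -5, 5)
    ab <- sample(-3:3, 2, replace = TRUE)
    shifted <- p + ab[1] * b$eps1 + ab[2] * b$eps2
    expect_equal(firing_rate(cell, params, shifted),
                 firing_rate(cell, params, p), tolerance = 1e-9)
  }
})

test_that("sharpness and threshold shape the field as expected", {
  cell <- grid_cell(1, 0)
  inside <- c(0.2, 0)   # d/s < zeta
  outside <- c(0.48, 0) # d/s > zeta (0.48 < 0.5 so rounding keeps d = 0.48)
  r_in <- sapply(c(1, 3, 9), function(k) {
    firing_rate(cell, firing_params(0.4, k), inside)
  })
  r_out <- sapply(c(1, 3, 9), function(k) {
    firing_rate(cell, firing_params(0.4, k), outside)
  })
  expect_true(all(diff(r_in) > 0))    # greater kappa: more intense near center
  expect_true(all(diff(r_out) < 0))   # and sharper decay outside
  # greater zeta widens the half-maximum radius
  half_radius <- function(zeta) {
    prof <- profile_along_axis(grid_cell(1, 0), firing_params(zeta, 3), 1,
                               half_length = 0.5, step = 1e-3)
    prof <- prof[prof$offset >= 0, ]
    prof$offset[which.min(abs(prof$rate - 0.5))]
  }
  expect_true(half_radius(0.2) < half_radius(0.4))
})

test_that("field centers enumerate the lattice exactly", {
  cell <- grid_cell(1, 0)
  ctr <- field_centers(cell, list(xlim = c(0, 1), ylim = c(0, 1)))
  expected <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  for (i in seq_len(nrow(expected))) {
    expect_true(min(sqrt(rowSums(sweep(ctr, 2, expected[i, ])^2))) < 1e-9)
  }

  # density in a 5x5 arena: area / (s^2 sin 60) ~ 28.9 plus boundary effects
  n5 <- nrow(field_centers(worked_cell(), build_environment("square")))
  expect_gte(n5, 25)
  expect_lte(n5, 40)

  # phase shifts translate the center set by phase1 * eps1
  base <- field_centers(grid_cell(1, pi / 5), list(xlim = c(-3, 3), ylim = c(-3, 3)))
  shifted <- field_centers(grid_cell(1, pi / 5, c(0.5, 0)),
                           list(xlim = c(-3, 3), ylim = c(-3, 3)))
  b <- basis_vectors(grid_cell(1, pi / 5))
  moved <- sweep(base, 2, -0.5 * b$eps1)
  inner <- moved[abs(moved[, 1]) < 2 & abs(moved[, 2]) < 2, , drop = FALSE]
  for (i in seq_len(nrow(inner))) {
    expect_true(min(sqrt(rowSums(sweep(shifted, 2, inner[i, ])^2))) < 1e-9)
  }
})

test_that("doubling the spacing doubles the center geometry exactly", {
  th <- pi / 7
  small <- field_centers(grid_cell(1, th), list(xlim = c(-4, 4), ylim = c(-4, 4)))
  big <- field_centers(grid_cell(2, th), list(xlim = c(-8, 8), ylim = c(-8, 8)))
  doubled <- 2 * small
  for (i in seq_len(nrow(doubled))) {
    expect_true(min(sqrt(rowSums(sweep(big, 2, doubled[i, ])^2))) < 1e-9)
  }
})

test_that("interior centers have six neighbors at the spacing, 60 degrees apart", {
  cell <- worked_cell()
  env <- build_environment("square")
  ctr <- field_centers(cell, env)
  s <- cell$spacing
  interior <- which(
    ctr[, 1] > s + 0.01 & ctr[, 1] < 5 - s - 0.01 &
      ctr[, 2] > s + 0.01 & ctr[, 2] < 5 - s - 0.01
  )
  expect_gt(length(interior), 3)
  for (i in interior) {
    nb <- brute_force_neighbors(ctr, i)
    near <- which(abs(nb$dist - s) <= 1e-6)
    expect_length(near, 6L)
    ang <- atan2(ctr[nb$idx[near], 2] - ctr[i, 2],
                 ctr[nb$idx[near], 1] - ctr[i, 1])
    gaps <- angle_gap(ang, cell$orientation, period = pi / 3)
    expect_true(all(gaps < 1e-6))
  }
})

test_that("nearest bump offsets along the axes expose the per-axis phase", {
  cell <- worked_cell()
  expect_equal(nearest_center_distance_along_axis(cell, 1), 0.5)
  expect_equal(nearest_center_distance_along_axis(cell, 2), 0)
  expect_equal(nearest_center_distance_along_axis(grid_cell(1.3, 0.1), 1), 0)
  expect_equal(nearest_center_distance_along_axis(grid_cell(2, 0, c(0.8, 0)), 1),
               0.4, tolerance = 1e-12)
  # cross-check against profile peak detection
  params <- firing_params()
  for (axis in 1:2) {
    peaks <- profile_peaks(profile_along_axis(cell, params, axis))
    expect_equal(abs(peaks[1]),
                 nearest_center_distance_along_axis(cell, axis),
                 tolerance = 1e-9)
  }
})
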