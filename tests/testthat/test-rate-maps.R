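test_that("binning averages rates per half-open bin and conserves occupancy", {
  m <- bin_rate_map(c(0.05, 0.05), 0.7, bin_size = 0.1,
                    xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(m$rate[1, 1], 0.7)
  expect_equal(m$occupancy[1, 1], 1L)
  expect_equal(sum(m$occupancy), 1L)
  expect_equal(sum(!is.na(m$rate)), 1L)

  m2 <- bin_rate_map(rbind(c(0.01, 0.01), c(0.09, 0.09)), c(0.2, 0.8),
                     bin_size = 0.1, xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(m2$rate[1, 1], 0.5)

  set.seed(5)
  pts <- matrix(stats::runif(2000, 0, 5), ncol = 2)
  m3 <- bin_rate_map(pts, stats::runif(1000), bin_size = 0.25,
                     xlim = c(0, 5), ylim = c(0, 5))
  expect_equal(sum(m3$occupancy), 1000L)
  # half-open bins: a sample exactly on an interior bin edge goes up
  m4 <- bin_rate_map(c(0.1, 0.0), 1, bin_size = 0.1, xlim = c(0, 1),
                     ylim = c(0, 1))
  expect_equal(m4$occupancy[2, 1], 1L)
  expect_error(bin_rate_map(matrix(numeric(0), ncol = 2), numeric(0)), "sample")
})

test_that("global-fit correlation matches a hand Pearson computation", {
  set.seed(6)
  pts <- matrix(stats::runif(200, 0, 1), ncol = 2)
  r <- stats::runif(100)
  m <- bin_rate_map(pts, r, bin_size = 0.2, xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(global_fit_correlation(m, m), 1)
  anti <- m
  anti$rate <- 1 - anti$rate
  expect_equal(global_fit_correlation(m, anti), -1)

  mk <- function(vals) {
    bin_rate_map(rbind(c(0.5, 0.5), c(1.5, 0.5), c(2.5, 0.5)), vals,
                 bin_size = 1, xlim = c(0, 3), ylim = c(0, 1))
  }
  expect_equal(global_fit_correlation(mk(c(0.1, 0.5, 0.9)),
                                      mk(c(0.2, 0.4, 0.9))),
               0.9707253, tolerance = 1e-6)

  flat <- mk(c(0.5, 0.5, 0.5))
  expect_error(global_fit_correlation(flat, mk(c(0.1, 0.2, 0.3))), "variance")
  other <- bin_rate_map(c(0.5, 0.5), 1, bin_size = 0.5, xlim = c(0, 3),
                        ylim = c(0, 1))
  expect_error(global_fit_correlation(other, mk(c(0.1, 0.2, 0.3))), "grid")
  # disjoint visited sets
  a <- bin_rate_map(rbind(c(0.5, 0.5), c(1.5, 0.5)), c(0.1, 0.9),
                    bin_size = 1, xlim = c(0, 4), ylim = c(0, 1))
  b <- bin_rate_map(rbind(c(2.5, 0.5), c(3.5, 0.5)), c(0.1, 0.9),
                    bin_size = 1, xlim = c(0, 4), ylim = c(0, 1))
  expect_error(global_fit_correlation(a, b), "jointly visited")
})

test_that("lattice parameters are recovered exactly from analytic centers", {
  est <- estimate_lattice_params(
    field_centers(grid_cell(0.5, 0), list(xlim = c(-2, 2), ylim = c(-2, 2)))
  )
  expect_equal(est$spacing, 0.5, tolerance = 1e-9)
  expect_equal(est$orientation, 0, tolerance = 1e-9)
  expect_equal(est$phase, c(0, 0), tolerance = 1e-9)

  cell <- grid_cell(1.2, pi / 6, c(0.25, 0.75))
  est2 <- estimate_lattice_params(
    field_centers(cell, list(xlim = c(-4, 4), ylim = c(-4, 4)))
  )
  expect_equal(est2$spacing, 1.2, tolerance = 1e-6)
  expect_equal(est2$orientation, pi / 6, tolerance = 1e-6)
  expect_equal(est2$phase, c(0.25, 0.75), tolerance = 1e-6)

  expect_error(estimate_lattice_params(matrix(stats::runif(10), ncol = 2)),
               "at least 7")
  line <- cbind(seq(0, 2, length.out = 8), seq(0, 2, length.out = 8) * 0.5)
  expect_error(estimate_lattice_params(line), "collinear")
})

test_that("recovery works for 20 random cells from analytic centers", {
  set.seed(8)
  for (i in 1:20) {
    cell <- random_cell()
    est <- estimate_lattice_params(
      field_centers(cell, list(xlim = c(-5, 5), ylim = c(-5, 5)))
    )
    expect_equal(est$spacing, cell$spacing, tolerance = 1e-6)
    expect_lt(angle_gap(est$orientation, cell$orientation, pi / 3), 1e-6)
    gap <- (est$phase - cell$phase) %% 1
    gap <- pmin(gap, 1 - gap)
    expect_lt(max(gap), 1e-6)
  }
})

test_that("axis profiles show the worked-example phase and spacing", {
  cell <- worked_cell()
  params <- firing_params()
  p1 <- profile_peaks(profile_along_axis(cell, params, 1))
  expect_equal(abs(p1[1]), 0.5, tolerance = 1e-9)
  pos <- sort(p1[p1 > 0])
  expect_equal(diff(pos), rep(1, length(pos) - 1), tolerance = 1e-9)
  p2 <- profile_peaks(profile_along_axis(cell, params, 2))
  expect_equal(abs(p2[1]), 0, tolerance = 1e-9)
  p0 <- profile_peaks(profile_along_axis(grid_cell(1, 0), params, 1))
  expect_equal(p0[1], 0)
})

test_that("binned means converge to the field's spatial mean per bin", {
  cell <- grid_cell(1, pi / 7, c(0.3, 0.6))
  params <- firing_params()
  set.seed(9)
  pts <- matrix(stats::runif(4e5, 0, 5), ncol = 2)
  rates <- firing_rate(cell, params, pts)
  emp <- bin_rate_map(pts, rates, bin_size = 0.1, xlim = c(0, 5),
                      ylim = c(0, 5))
  ana <- analytic_rate_map(cell, params, 0.1, c(0, 5), c(0, 5))
  ok <- emp$occupancy >= 4
  expect_gt(mean(ok), 0.9)
  err <- abs(emp$rate[ok] - ana$rate[ok])
  expect_lt(mean(err), 0.02)
})

test_that("map peak detection localizes centers to within a bin", {
  cell <- grid_cell(1, pi / 5, c(0.2, 0.7))
  ana <- analytic_rate_map(cell, firing_params(), 0.05, c(0, 5), c(0, 5))
  peaks <- find_rate_map_peaks(ana, window = 3)
  truth <- field_centers(cell, list(xlim = c(0.2, 4.8), ylim = c(0.2, 4.8)))
  expect_gte(nrow(peaks), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- min(sqrt(rowSums(sweep(peaks, 2, truth[i, ])^2)))
    expect_lt(d, 0.05 * sqrt(2))
  }
})
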