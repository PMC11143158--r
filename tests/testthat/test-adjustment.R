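test_that("the adjustment gain follows its sigmoid in the experience counter", {
  sched <- adjustment_schedule(alpha = 0.5, beta = 1.0, xi = 0.1, M = 1e5)
  expect_equal(gamma_gain(sched, 1e5), 0.25)
  expect_equal(gamma_gain(sched, 1e12), 0.5, tolerance = 1e-12)  # -> alpha/beta
  expect_lt(gamma_gain(sched, 0), 1e-12)                          # ~0 before M
  n <- seq(0, 2e5, by = 1e4)
  expect_true(all(diff(gamma_gain(sched, n)) >= 0))               # monotone
  # strictly increasing where the sigmoid is resolvable in double precision
  n_mid <- seq(9.5e4, 1.003e5, by = 100)
  expect_true(all(diff(gamma_gain(sched, n_mid)) > 0))
  g <- gamma_gain(sched, seq(0, 1e6, by = 1e4))
  expect_true(all(g >= 0 & g < 0.5 + 1e-12))
  expect_error(adjustment_schedule(alpha = -1), "alpha")
  expect_error(adjustment_schedule(beta = 0), "beta")
})

test_that("one adjustment step contracts the frame difference by 1 - gamma", {
  env <- build_environment("two_compartment")
  # xi = 0, M = 0 makes gamma constant: alpha / (beta + 1)
  st <- adjustment_state(env, adjustment_schedule(0.5, 1, 0, 0))  # gamma 0.25
  st$frames$C2 <- frame_transform(0.8, st$target$translation)
  st <- step_adjustment(st, "C2")
  expect_equal(frame_difference(st$frames$C2, st$target)$angle, 0.6,
               tolerance = 1e-12)

  st2 <- adjustment_state(env, adjustment_schedule(1, 1, 0, 0))   # gamma 0.5
  st2$frames$C2 <- frame_transform(0, st2$target$translation + c(2, 0))
  st2 <- step_adjustment(st2, "C2")
  expect_equal(frame_difference(st2$frames$C2, st2$target)$translation,
               c(1, 0), tolerance = 1e-12)

  # converged state is a fixed point
  st3 <- adjustment_state(env, adjustment_schedule(0.5, 1, 0, 0))
  st3$frames$C2 <- st3$target
  st3 <- step_adjustment(st3, "C2")
  expect_equal(st3$frames$C2$phi, st3$target$phi)
  expect_equal(st3$frames$C2$translation, st3$target$translation)

  expect_error(step_adjustment(st, "C1"), "reference")
  expect_error(step_adjustment(st, "C9"), "unknown")
})

test_that("repeated steps contract monotonically to convergence", {
  env <- build_environment("four_compartment")
  sched <- adjustment_schedule(alpha = 0.8, beta = 1.0, xi = 0.2, M = 20)
  st <- adjustment_state(env, sched)
  expect_false(has_converged(st))
  prev <- frame_difference(st$frames$C3, st$target)
  for (i in 1:300) {
    st <- step_adjustment(st, "C3")
    cur <- frame_difference(st$frames$C3, st$target)
    expect_lte(abs(cur$angle), abs(prev$angle) + 1e-15)
    expect_lte(sqrt(sum(cur$translation^2)),
               sqrt(sum(prev$translation^2)) + 1e-15)
    if (abs(prev$angle) > 1e-12 && st$counters[["C3"]] > 25) {
      expect_lt(abs(cur$angle), abs(prev$angle))
    }
    prev <- cur
  }
  # only C3 was visited, so the state as a whole is not converged
  expect_false(has_converged(st))
  d3 <- frame_difference(st$frames$C3, st$target)
  expect_lt(abs(d3$angle), 1e-3)
  expect_lt(sqrt(sum(d3$translation^2)), 1e-3)
  # reference frame untouched throughout
  expect_equal(st$frames$C1, env$frames$C1)
  for (nm in c("C2", "C4")) {
    for (i in 1:300) st <- step_adjustment(st, nm)
  }
  expect_true(has_converged(st))
})

test_that("counter modes share or separate the experience driving the gain", {
  env <- build_environment("four_compartment")
  sched <- adjustment_schedule(alpha = 0.8, beta = 1.0, xi = 0.2, M = 50)
  shared <- adjustment_state(env, sched, counter = "shared")
  percmp <- adjustment_state(env, sched, counter = "per_compartment")
  for (i in 1:100) {
    shared <- step_adjustment(shared, "C3")
    percmp <- step_adjustment(percmp, "C3")
  }
  # visits to C3 count toward C2's gain only in shared mode
  expect_equal(effective_experience(shared, "C2"), 100L)
  expect_equal(effective_experience(percmp, "C2"), 0L)
  expect_gt(gamma_gain(sched, effective_experience(shared, "C2")),
            gamma_gain(sched, effective_experience(percmp, "C2")))
  # in both modes only the visited frame moved
  expect_equal(percmp$frames$C2, env$frames$C2)
  expect_equal(shared$frames$C2, env$frames$C2)
  expect_gt(abs(frame_difference(env$frames$C3, shared$frames$C3)$angle), 0)
})

test_that("equal-orientation frames adjust translation only", {
  env <- build_environment("two_compartment")
  st <- adjustment_state(env, adjustment_schedule(0.5, 1, 0.5, 10))
  for (i in 1:100) {
    st <- step_adjustment(st, "C2")
    expect_equal(st$frames$C2$phi, 0)  # rotation path is exactly identity
  }
  expect_true(has_converged(st))
})
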