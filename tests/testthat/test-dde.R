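test_that("plain exponential decay is integrated to tolerance", {
  sol <- dde_solve(function(t, y, l) -0.3 * y, y0 = 2, t_end = 10,
                   out_times = 0:10, rtol = 1e-8, atol = 1e-10)
  expect_equal(sol$y[, 1], 2 * exp(-0.3 * (0:10)), tolerance = 1e-6)
  expect_identical(sol$y[1, 1], 2)      # first snapshot is the IC exactly
})

test_that("scalar delay problem matches the method-of-steps closed form", {
  # u'(t) = -u(t - tau), unit history: u = 1 - t on [0, tau],
  # then 1 - t + (t - tau)^2 / 2 on [tau, 2 tau]
  for (tau in c(1, 0.7)) {
    tt <- seq(0, 2 * tau, length.out = 41)
    sol <- dde_solve(function(t, y, l) -l[[1]], y0 = 1, t_end = 2 * tau,
                     lags = tau, history = constant_history(1),
                     out_times = tt, breaks = tau)
    exact <- ifelse(tt <= tau, 1 - tt, 1 - tt + (tt - tau)^2 / 2)
    expect_equal(sol$y[, 1], exact, tolerance = 1e-9)
  }
})

test_that("two-lag linear system matches an independent dde solver", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, l) {
    c(-0.5 * l[[1]][1] + 0.2 * y[2], -0.1 * l[[2]][2] - 0.3 * y[1])
  }
  sol <- dde_solve(rhs, y0 = c(1, 0.5), t_end = 12, lags = c(1.5, 3),
                   history = constant_history(c(1, 0.5)),
                   out_times = 0:12, rtol = 1e-8, atol = 1e-10)
  ref <- deSolve::dede(
    y = c(1, 0.5), times = 0:12,
    func = function(t, y, parms) {
      l1 <- if (t > 1.5) deSolve::lagvalue(t - 1.5) else c(1, 0.5)
      l2 <- if (t > 3) deSolve::lagvalue(t - 3) else c(1, 0.5)
      list(c(-0.5 * l1[1] + 0.2 * y[2], -0.1 * l2[2] - 0.3 * y[1]))
    },
    parms = NULL, control = list(mxhist = 1e5), rtol = 1e-9, atol = 1e-11
  )
  expect_equal(sol$y, unname(ref[, 2:3]), tolerance = 1e-6)
})

test_that("halving the tolerances barely moves the solution", {
  rhs <- function(t, y, l) -0.4 * l[[1]] + 0.1 * sin(t) * y
  run <- function(rtol) {
    dde_solve(rhs, y0 = 1, t_end = 20, lags = 2,
              history = constant_history(1), out_times = c(0, 20),
              rtol = rtol, atol = rtol * 1e-2)$y[2, 1]
  }
  expect_lt(abs(run(1e-6) - run(5e-7)), 10 * 1e-6)
})

test_that("the integrator is deterministic and guards its history span", {
  rhs <- function(t, y, l) -l[[1]]
  a <- dde_solve(rhs, 1, t_end = 3, lags = 1, history = constant_history(1))
  b <- dde_solve(rhs, 1, t_end = 3, lags = 1, history = constant_history(1))
  expect_identical(a$y, b$y)
  expect_error(dde_solve(rhs, 1, t_end = 3, lags = -1,
                         history = constant_history(1)), "strictly positive")
  expect_error(dde_solve(rhs, 1, t_end = 3, lags = 1), "history")
})
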