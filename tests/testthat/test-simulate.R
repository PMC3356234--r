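test_that("delay causality is exact: no EPOR activity before tau_1, no EPO through tau_2", {
  spec <- small_spec()
  p <- spec$params
  ic <- injury_initial_condition(spec)
  zero_hist <- function(t) ic$initial$fields * 0   # identically-zero history
  traj <- simulate_lesion(ic$initial, p, t_end = p$tau_2 + 12,
                          history = zero_hist, check_boundary = FALSE)
  before1 <- traj$times < p$tau_1
  upto2 <- traj$times <= p$tau_2
  expect_true(all(traj$states[, "S_A", before1] == 0))
  expect_true(all(traj$states[, "P", upto2] == 0))
  expect_gt(max(traj$states[, "S_A", !before1]), 0)
  expect_gt(max(traj$states[, "P", !upto2]), 0)
})

test_that("cells are conserved and necrotic decay follows its closed form", {
  spec <- small_spec(horizon = 240)
  ic <- injury_initial_condition(spec)
  traj <- simulate_lesion(ic$initial, spec$params, t_end = 240,
                          history = ic$history, check_boundary = FALSE)
  areas <- traj$grid$cell_areas
  total <- vapply(seq_along(traj$times), function(i) {
    f <- traj$states[, , i]
    sum((f[, "C"] + f[, "S_T"] + f[, "S_A"] + f[, "D_A"]) * areas)
  }, numeric(1))
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-6)
  # the necrotic pool decays exponentially at mu_DN, independent of the rest
  dn0 <- sum(traj$states[, "D_N", 1] * areas)
  dn <- vapply(seq_along(traj$times), function(i) {
    sum(traj$states[, "D_N", i] * areas)
  }, numeric(1))
  expect_equal(dn, dn0 * exp(-spec$params$mu_DN * traj$times),
               tolerance = 1e-6)
})

test_that("matrix density never increases and is constant without TNF", {
  spec <- small_spec()
  ic <- injury_initial_condition(spec)
  traj <- simulate_lesion(ic$initial, spec$params, t_end = 120,
                          history = ic$history, check_boundary = FALSE)
  U <- traj$states[, "U", ]
  expect_true(all(apply(U, 1, diff) <= 1e-12))
  # with TNF production off, F stays zero and U is exactly constant
  p0 <- chondro_params(sigma_F = 0, base = spec$params)
  traj0 <- simulate_lesion(ic$initial, p0, t_end = 120,
                           history = ic$history, check_boundary = FALSE)
  expect_true(all(traj0$states[, "F", ] == 0))
  expect_equal(traj0$states[, "U", dim(traj0$states)[3]],
               traj0$states[, "U", 1], tolerance = 1e-12)
})

test_that("all fields stay non-negative across a reference-style run", {
  spec <- small_spec()
  ic <- injury_initial_condition(spec)
  traj <- simulate_lesion(ic$initial, spec$params, t_end = 120,
                          history = ic$history, check_boundary = FALSE)
  expect_true(all(traj$states >= 0))
})

test_that("a too-small zero-flux domain triggers the boundary warning", {
  spec <- scenario_spec(n_nodes = 30, r_max = 0.75, horizon = 96,
                        params = reference_params("no_epo"))
  ic <- injury_initial_condition(spec)
  expect_warning(
    simulate_lesion(ic$initial, spec$params, t_end = 96,
                    history = ic$history),
    class = "chondrosim_boundary_warning"
  )
})

test_that("checkpoint restart reproduces the uninterrupted run", {
  spec <- small_spec()
  ic <- injury_initial_condition(spec)
  traj <- simulate_lesion(ic$initial, spec$params, t_end = 120,
                          history = ic$history, keep_mesh = TRUE,
                          check_boundary = FALSE)
  again <- restart_trajectory(traj, 60)
  i_end <- length(traj$times)
  j_end <- length(again$times)
  expect_lt(max(abs(again$states[, , j_end] - traj$states[, , i_end])) /
              max(traj$states[, , i_end]), 100 * traj$solver$rtol)
  # restart at t = 0 replays the identical trajectory
  replay <- restart_trajectory(traj, 0)
  expect_identical(replay$states, traj$states)
  expect_error(restart_trajectory(traj, 500), "outside the trajectory span")
})

test_that("spatially uniform fields reduce to the lumped cell-state system", {
  skip_if_not_installed("deSolve")
  p <- reference_params()
  g <- radial_grid(2, 15)
  y0 <- c(R = 0, M = 1.5, F = 0, P = 0, C = 80, S_T = 5, S_A = 0,
          D_N = 10, U = 2, D_A = 0)
  init <- do.call(system_state, c(list(g), as.list(y0)))
  traj <- simulate_lesion(init, p, t_end = 240, history = init,
                          check_boundary = FALSE)
  ref <- deSolve::dede(
    y = y0, times = seq(0, 240, by = 1),
    func = function(t, y, parms) {
      l1 <- if (t > p$tau_1) deSolve::lagvalue(t - p$tau_1) else y0
      l2 <- if (t > p$tau_2) deSolve::lagvalue(t - p$tau_2) else y0
      sat <- function(x, lam) x / (lam + x)
      H <- as.numeric(y["P"] - p$P_c < 0)
      conv <- (p$beta_1 * sat(y["M"], p$lambda_M) +
                 p$beta_2 * sat(y["F"], p$lambda_F)) * y["C"] * H
      act <- p$gamma * l1[6] * sat(l1[3], p$lambda_F)
      rev <- p$alpha * y["S_A"] * sat(y["P"], p$lambda_P)
      degr <- p$delta_U * y["U"] * sat(y["F"], p$lambda_F)
      list(c(
        -p$delta_R * y["R"] + p$sigma_R * y["S_T"],
        -p$delta_M * y["M"] + p$sigma_M * y["D_N"] + degr,
        -p$delta_F * y["F"] + p$sigma_F * y["S_T"],
        -p$delta_P * y["P"] + p$sigma_P * y["C"] * sat(l2[1], p$lambda_R) *
          p$Lambda / (p$Lambda + y["F"]),
        rev - conv,
        conv - act - p$nu * y["S_T"] * sat(y["F"], p$lambda_F) *
          sat(y["M"], p$lambda_M),
        act - rev - p$mu_SA * y["S_A"] * sat(y["F"], p$lambda_F),
        -p$mu_DN * y["D_N"],
        -degr,
        p$nu * y["S_T"] * sat(y["F"], p$lambda_F) * sat(y["M"], p$lambda_M) +
          p$mu_SA * y["S_A"] * sat(y["F"], p$lambda_F)
      ))
    },
    parms = NULL, control = list(mxhist = 1e5), rtol = 1e-9, atol = 1e-11
  )
  for (j in seq_along(CHONDRO_FIELDS)) {
    ref_j <- ref[, j + 1]
    for (node in c(1, 8, 15)) {
      expect_lt(max(abs(traj$states[node, j, ] - ref_j)) /
                  max(abs(ref_j), 1e-8), 1e-3)
    }
  }
})

test_that("smoothed threshold gates converge to the discrete gate", {
  spec <- small_spec(horizon = 96)
  ic <- injury_initial_condition(spec)
  end_radius <- function(p) {
    traj <- simulate_lesion(ic$initial, p, t_end = 96, history = ic$history,
                            check_boundary = FALSE)
    st <- get_state(traj, 96)
    lesion_radius(st, spec$C0)
  }
  r_disc <- end_radius(spec$params)
  gaps <- vapply(c(5, 50, 500), function(k) {
    abs(end_radius(chondro_params(h_sharpness = k, base = spec$params)) -
          r_disc)
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-9))   # monotone approach
  expect_lt(gaps[3], 0.05)               # sharp gate is close to discrete
})
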