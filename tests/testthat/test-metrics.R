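test_that("lesion radius reads the canonical injury and simple profiles", {
  spec <- scenario_spec()
  ic <- injury_initial_condition(spec)
  expect_equal(lesion_radius(ic$initial, spec$C0), 0.25, tolerance = 1e-12)

  g <- radial_grid(2, 80)
  expect_equal(lesion_radius(system_state(g, C = 100), 100), 0)
  ramp <- system_state(g, C = 100 * pmin(1, g$node_centers / 1))
  expect_equal(lesion_radius(ramp, 100, theta_C = 0.5), 0.5,
               tolerance = 1e-9)
  expect_error(lesion_radius(ramp, 100, theta_C = 1.2), "between 0 and 1")
})

test_that("lesion radius is monotone non-increasing in the threshold", {
  g <- radial_grid(2, 60)
  prof <- system_state(g, C = 100 * pmin(1, (g$node_centers / 1.4)^2))
  radii <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(th) lesion_radius(prof, 100, th), numeric(1))
  expect_true(all(diff(radii) >= 0))     # larger theta -> larger radius
})

test_that("penumbra radii bracket the sick annulus with interpolation", {
  g <- radial_grid(2, 100)
  r <- g$node_centers
  s <- system_state(g, S_T = 40 * exp(-((r - 1) / 0.2)^2))
  pen <- penumbra_radii(s, 100, theta_S = 0.05)
  expect_lt(pen[["inner"]], 1)
  expect_gt(pen[["outer"]], 1)
  expect_true(all(is.na(penumbra_radii(system_state(g), 100))))
})

test_that("summaries are pure functions of the trajectory", {
  spec <- small_spec()
  traj <- suppressWarnings(run_scenario(spec = spec, check_boundary = FALSE))
  s1 <- lesion_summary(traj)
  s2 <- lesion_summary(traj)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), length(traj$times))
})

test_that("regime classification handles the degenerate cases", {
  mk <- function(radius, pen) {
    tibble::tibble(time = seq(0, 240, by = 24), lesion_radius = radius,
                   total_penumbra = pen)
  }
  expect_error(classify_regime(mk(0, 0)[1:2, ]), "3 days")
  # injury-free: no lesion, no penumbra -> resolved (vacuously)
  expect_identical(classify_regime(mk(0, 0)), "resolved")
  # steady growth -> expanding
  expect_identical(classify_regime(mk(seq(0.25, 2.75, by = 0.25), 50)),
                   "expanding")
  # flat radius with persistent penumbra -> abated
  expect_identical(classify_regime(mk(1, 50)), "abated")
})

test_that("abatement day finds when daily lesion growth stops", {
  t <- seq(0, 240, by = 1)
  r <- pmin(0.25 + 0.02 * t, 1.45)       # stalls at t = 60 h
  s <- tibble::tibble(time = t, lesion_radius = r)
  expect_equal(abatement_day(s), 60 / 24, tolerance = 0.3)
  s_grow <- tibble::tibble(time = t, lesion_radius = 0.25 + 0.02 * t)
  expect_identical(abatement_day(s_grow), Inf)
  s_flat <- tibble::tibble(time = t, lesion_radius = rep(0.4, length(t)))
  expect_identical(abatement_day(s_flat), 0)
})
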