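test_that("the canonical injury lays down exactly the covered annuli", {
  spec <- scenario_spec()                 # 0.25 mm disc, dr = 0.025 mm
  ic <- injury_initial_condition(spec)
  dn <- ic$initial$fields[, "D_N"]
  expect_equal(dn[1:10], rep(spec$injury_density, 10))
  expect_true(all(dn[11:200] == 0))
  expect_true(all(ic$initial$fields[1:10, "C"] == 0))
  expect_true(all(ic$initial$fields[11:200, "C"] == spec$C0))
  # disc integral equals density times disc area
  expect_equal(integrate_field(ic$initial, "D_N"),
               spec$injury_density * pi * spec$injury_radius^2,
               tolerance = 1e-12)
})

test_that("an off-grid disc edge is overlap-weighted in one annulus", {
  spec <- scenario_spec(injury_radius = 0.26, n_nodes = 100, r_max = 5)
  ic <- injury_initial_condition(spec)
  dn <- ic$initial$fields[, "D_N"]
  w <- (0.26^2 - 0.25^2) / (0.30^2 - 0.25^2)  # covered share of annulus 6
  expect_equal(dn[6], spec$injury_density * w)
  expect_equal(integrate_field(ic$initial, "D_N"),
               spec$injury_density * pi * 0.26^2, tolerance = 1e-12)
})

test_that("pre-injury history is the uninjured healthy equilibrium", {
  spec <- scenario_spec()
  ic <- injury_initial_condition(spec)
  h <- matrix(ic$history(-spec$params$tau_2), spec$n_nodes, 10)
  expect_true(all(h[, 5] == spec$C0))     # healthy everywhere, disc included
  expect_true(all(h[, 1:4] == 0))         # no chemicals
  expect_true(all(h[, 8] == 0))           # no necrotic cells before injury
})

test_that("scenario invariants are enforced", {
  expect_error(scenario_spec(injury_radius = 6, r_max = 5), "smaller")
  expect_error(scenario_spec(horizon = -1), "horizon")
})

test_that("the three regimes share one code path and differ only by parameters", {
  spec_a <- scenario_spec("no_epo", reference_params("no_epo"),
                          n_nodes = 40, r_max = 1.5, horizon = 48)
  spec_b <- scenario_spec("also_no_epo",
                          chondro_params(sigma_P = 0, alpha = 0.1),
                          n_nodes = 40, r_max = 1.5, horizon = 48)
  ta <- suppressWarnings(run_scenario(spec = spec_a, check_boundary = FALSE))
  tb <- suppressWarnings(run_scenario(spec = spec_b, check_boundary = FALSE))
  # with no EPO ever produced, the EPO-response rate is inert
  expect_equal(ta$states, tb$states, tolerance = 1e-12)
})

test_that("rerunning a scenario reproduces the trajectory bit for bit", {
  spec <- scenario_spec(n_nodes = 40, r_max = 1.5, horizon = 48)
  t1 <- suppressWarnings(run_scenario(spec = spec, check_boundary = FALSE))
  t2 <- suppressWarnings(run_scenario(spec = spec, check_boundary = FALSE))
  expect_identical(t1$states, t2$states)
})
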