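test_that("uniform finite-volume partition has the stated edges and areas", {
  g <- radial_grid(1.0, 4)
  expect_equal(g$edges, c(0, 0.25, 0.5, 0.75, 1.0))
  expect_equal(g$cell_areas[1], pi * 0.25^2)
  expect_equal(g$cell_areas[2], pi * (0.5^2 - 0.25^2))
  expect_equal(radial_grid(5, 200)$dr, 0.025)
  expect_error(radial_grid(-1, 10), "positive")
  expect_error(radial_grid(1, 2), ">= 3")
})

test_that("cell areas telescope to the disc area on any grid", {
  for (n in c(3, 17, 200)) {
    g <- radial_grid(3.7, n)
    expect_equal(sum(g$cell_areas), pi * 3.7^2, tolerance = 1e-12)
  }
})

test_that("diffusion of a constant field vanishes; of r^2 equals 4D", {
  g <- radial_grid(2, 50)
  expect_equal(apply_diffusion(rep(3.2, 50), g, 0.7), rep(0, 50))
  D <- 0.42
  lap <- apply_diffusion(g$node_centers^2, g, D)
  # exact for the quadratic away from the zero-flux outer boundary
  expect_equal(lap[1:48], rep(4 * D, 48), tolerance = 1e-10)
})

test_that("operator matches a dense matrix assembled from edge fluxes", {
  g <- radial_grid(1.6, 8)
  n <- g$n_nodes
  # independent dense assembly: flux through each interior edge
  A <- matrix(0, n, n)
  for (e in 2:n) {                      # edge between cells e-1 and e
    r_e <- g$edges[e]
    coef <- 2 * pi * r_e / g$dr         # edge length / spacing
    # flux in = coef * (u[e] - u[e-1]); divide by cell area
    A[e - 1, e] <- A[e - 1, e] + coef / g$cell_areas[e - 1]
    A[e - 1, e - 1] <- A[e - 1, e - 1] - coef / g$cell_areas[e - 1]
    A[e, e - 1] <- A[e, e - 1] + coef / g$cell_areas[e]
    A[e, e] <- A[e, e] - coef / g$cell_areas[e]
  }
  set.seed(7)
  u <- stats::runif(n)
  expect_equal(apply_diffusion(u, g, 1.3), as.vector(1.3 * A %*% u),
               tolerance = 1e-12)
})

test_that("zero-flux diffusion conserves mass and is self-adjoint", {
  g <- radial_grid(2.4, 31)
  set.seed(21)
  for (k in 1:5) {
    u <- stats::runif(g$n_nodes)
    expect_lt(abs(sum(apply_diffusion(u, g, 0.9) * g$cell_areas)), 1e-11)
  }
  # area-weighted operator is symmetric
  n <- g$n_nodes
  L <- vapply(seq_len(n), function(j) {
    apply_diffusion(as.numeric(seq_len(n) == j), g, 1)
  }, numeric(n))
  W <- diag(g$cell_areas)
  expect_equal(W %*% L, t(W %*% L), tolerance = 1e-9)
})

test_that("diffusion-decay of a Gaussian bump converges at second order", {
  D <- 0.02
  delta <- 0.05
  t0 <- 20
  t_end <- 40
  exact <- function(r, t) {
    exp(-r^2 / (4 * D * (t0 + t))) / (4 * pi * D * (t0 + t)) * exp(-delta * t)
  }
  l2_err <- function(n) {
    g <- radial_grid(8, n)
    rhs <- function(t, y, lagged) apply_diffusion(y, g, D) - delta * y
    sol <- dde_solve(rhs, exact(g$node_centers, 0), t_end = t_end,
                     out_times = c(0, t_end), rtol = 1e-9, atol = 1e-12,
                     max_step = 1)
    sqrt(sum((sol$y[2, ] - exact(g$node_centers, t_end))^2 * g$cell_areas))
  }
  errs <- vapply(c(40, 80, 160), l2_err, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders > 1.7))
  expect_error(apply_diffusion(c(1, NaN, rep(1, 48)), radial_grid(2, 50), 1),
               "non-finite")
})
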