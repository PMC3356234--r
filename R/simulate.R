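# Full model integration: method of lines (radial finite volumes for the
# four diffusing chemicals) + method of steps for the two discrete delays.

.as_history_fun <- function(history, initial) {
  if (is.null(history)) {
    return(constant_history(initial$fields))
  }
  if (inherits(history, "chondro_state")) {
    return(constant_history(history$fields))
  }
  if (is.function(history)) {
    n <- initial$grid$n_nodes
    return(function(t) {
      v <- history(t)
      if (is.matrix(v)) v <- .pack_state(v)
      if (length(v) != n * length(CHONDRO_FIELDS)) {
        stop("history function must return all ", length(CHONDRO_FIELDS),
             " fields on the grid", call. = FALSE)
      }
      as.numeric(v)
    })
  }
  stop("`history` must be NULL, a chondro_state, or a function of time",
       call. = FALSE)
}

#' Simulate the lesion model
#'
#' Integrates the full reaction-diffusion-delay system from an initial
#' state (and pre-initial history) to `t_end`, producing snapshots at a
#' fixed cadence. Chemical species diffuse with their own diffusivities;
#' cell-state densities, matrix and the apoptosis ledger do not. The two
#' delays are handled by the method of steps with derivative-discontinuity
#' breakpoints at lag combinations, so delay causality is exact: with zero
#' pre-initial history the EPOR-active density is identically zero before
#' `tau_1` and EPO identically zero through `tau_2`.
#'
#' Negative output values smaller in magnitude than `atol` (inevitable
#' roundoff of an explicit method near zero) are clipped to zero at output;
#' larger violations raise an error naming the field, node and time.
#'
#' @param initial A [system_state()] at the start time.
#' @param params A [chondro_params()] set.
#' @param t_end Horizon in hours (default 240 h = 10 days).
#' @param history Pre-initial history over `[-max(tau_1, tau_2), 0]`:
#'   `NULL` (constant at `initial`), a `chondro_state` (constant at that
#'   state), or a function of time returning a field matrix.
#' @param out_dt Output cadence in hours (default 1).
#' @param rtol,atol Solver tolerances (defaults 1e-6 / 1e-8).
#' @param keep_mesh Retain the full dense solution mesh (needed for
#'   interior restarts); default keeps only the tail spanning the longest
#'   delay.
#' @param check_boundary Warn (class `chondrosim_boundary_warning`) if any
#'   chemical's outer-boundary value ever exceeds 1% of its spatial
#'   maximum, a sign that the zero-flux domain is too small for the run.
#' @return A `chondro_trajectory`: output `times` (h), `states` array
#'   (node x field x time), the `grid` and `params` used, solver
#'   `diagnostics`, and the dense `mesh` tail for restarts.
#' @export
simulate_lesion <- function(initial, params, t_end = 240, history = NULL,
                            out_dt = 1, rtol = 1e-6, atol = 1e-8,
                            keep_mesh = FALSE, check_boundary = TRUE) {
  stopifnot(inherits(initial, "chondro_state"))
  params <- validate_params(params)
  grid <- initial$grid
  n <- grid$n_nodes
  t0 <- initial$t

  op <- .radial_operator(grid)
  Ds <- c(params$D_R, params$D_M, params$D_F, params$D_P)
  chem_idx <- match(CHONDRO_CHEMICALS, CHONDRO_FIELDS)

  rhs <- function(t, y, lagged) {
    now <- .unpack_state(y, n)
    lag1 <- .unpack_state(lagged[[1]], n)
    lag2 <- .unpack_state(lagged[[2]], n)
    d <- .reaction_rhs_matrix(now, lag1, lag2, params)
    for (j in seq_along(chem_idx)) {
      if (Ds[j] > 0) {
        d[, chem_idx[j]] <- d[, chem_idx[j]] +
          Ds[j] * .apply_tridiag(op, now[, chem_idx[j]])
      }
    }
    .pack_state(d)
  }

  hist_fun <- .as_history_fun(history, initial)
  lags <- c(params$tau_1, params$tau_2)
  out_times <- seq(t0, t0 + t_end - t0, by = out_dt)
  if (out_times[length(out_times)] < t_end) out_times <- c(out_times, t_end)
  sol <- dde_solve(
    rhs, .pack_state(initial$fields), t0 = t0, t_end = t_end,
    lags = lags, history = hist_fun, out_times = out_times,
    rtol = rtol, atol = atol,
    breaks = .delay_breaks(t0, t_end, lags),
    keep_mesh = keep_mesh
  )

  n_t <- length(sol$times)
  states <- array(t(sol$y), dim = c(n, length(CHONDRO_FIELDS), n_t),
                  dimnames = list(NULL, CHONDRO_FIELDS, NULL))
  neg <- states < 0
  if (any(neg)) {
    # tolerance-proportional positivity contract: same mixed absolute /
    # relative scale as the local error control (dense output can wiggle
    # at that magnitude near delay-activation kinks)
    for (j in seq_along(CHONDRO_FIELDS)) {
      worst <- min(states[, j, ])
      if (worst < -10 * (atol + rtol * max(abs(states[, j, ])))) {
        idx <- which(states[, j, ] == worst, arr.ind = TRUE)[1, ]
        stop("positivity violation: field `", CHONDRO_FIELDS[j],
             "` = ", format(worst), " at node ", idx[1], ", t = ",
             sol$times[idx[2]], " h", call. = FALSE)
      }
    }
    states[neg] <- 0
  }

  if (check_boundary) {
    for (j in chem_idx) {
      sp_max <- max(states[, j, ])
      if (sp_max > 0 && max(states[n, j, ]) > 0.01 * sp_max) {
        warning(
          warningCondition(
            paste0("chemical `", CHONDRO_FIELDS[j], "` reaches ",
                   format(100 * max(states[n, j, ]) / sp_max, digits = 3),
                   "% of its maximum at the outer boundary; ",
                   "the zero-flux domain may be influencing the run"),
            class = "chondrosim_boundary_warning"
          )
        )
        break
      }
    }
  }

  structure(
    list(times = sol$times, states = states, grid = grid, params = params,
         diagnostics = sol$diagnostics, mesh = sol$mesh,
         history = hist_fun, t0 = t0,
         solver = list(rtol = rtol, atol = atol, out_dt = out_dt,
                       keep_mesh = keep_mesh)),
    class = "chondro_trajectory"
  )
}

#' @export
print.chondro_trajectory <- function(x, ...) {
  cat("<chondro_trajectory> ", length(x$times), " snapshots over [",
      x$times[1], ", ", x$times[length(x$times)], "] h on ",
      x$grid$n_nodes, " nodes\n", sep = "")
  d <- x$diagnostics
  cat("  steps:", d$n_accepted, "accepted,", d$n_rejected, "rejected,",
      d$n_rhs, "rhs evaluations\n")
  invisible(x)
}

#' Extract one snapshot from a trajectory
#'
#' @param traj A `chondro_trajectory`.
#' @param t An output time present in `traj$times` (within rounding).
#' @return A [system_state()] at that time.
#' @export
get_state <- function(traj, t) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  i <- which(abs(traj$times - t) < 1e-9)
  if (length(i) != 1) {
    stop("t = ", t, " is not an output time of this trajectory", call. = FALSE)
  }
  s <- system_state(traj$grid, t = traj$times[i])
  s$fields[, ] <- traj$states[, , i]
  s
}

# Dense evaluation of the retained mesh at an arbitrary interior time.
.mesh_eval <- function(traj, tq) {
  ts <- traj$mesh$t
  if (tq < ts[1] - 1e-12 || tq > ts[length(ts)] + 1e-12) {
    stop("t = ", tq, " is outside the retained dense mesh [",
         ts[1], ", ", ts[length(ts)], "]", call. = FALSE)
  }
  if (tq >= ts[length(ts)]) return(traj$mesh$y[[length(ts)]])
  j <- findInterval(tq, ts, rightmost.closed = TRUE)
  if (abs(tq - ts[j]) < 1e-12) return(traj$mesh$y[[j]])
  .hermite(tq, ts[j], traj$mesh$y[[j]], traj$mesh$f[[j]],
           ts[j + 1], traj$mesh$y[[j + 1]], traj$mesh$f[[j + 1]])
}

#' Restart a simulation from an interior time of a finished run
#'
#' Rebuilds the state and delayed history at `t_restart` from the
#' trajectory's dense mesh (the run must have been made with
#' `keep_mesh = TRUE` unless restarting from the very start) and integrates
#' to `t_end` with the same parameters and tolerances. Used to verify that
#' checkpoint/restart reproduces an uninterrupted run.
#'
#' @param traj A `chondro_trajectory`.
#' @param t_restart Restart time within the trajectory's span.
#' @param t_end Final time (default: the original horizon).
#' @return A `chondro_trajectory` over `[t_restart, t_end]`.
#' @export
restart_trajectory <- function(traj, t_restart, t_end = NULL) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  t_span <- range(traj$times)
  if (is.null(t_end)) t_end <- t_span[2]
  if (t_restart < t_span[1] - 1e-12 || t_restart > t_span[2] + 1e-12) {
    stop("restart time ", t_restart, " is outside the trajectory span [",
         t_span[1], ", ", t_span[2], "]", call. = FALSE)
  }
  p <- traj$params
  maxlag <- max(p$tau_1, p$tau_2)
  mesh_t <- traj$mesh$t
  if (t_restart > traj$t0 && mesh_t[1] > t_restart - maxlag + 1e-9 &&
      mesh_t[1] > traj$t0 + 1e-12) {
    stop("the retained mesh does not cover the delayed history at the ",
         "restart time; rerun with keep_mesh = TRUE", call. = FALSE)
  }

  y_r <- if (t_restart <= traj$t0) {
    .pack_state(get_state(traj, traj$t0)$fields)
  } else {
    .mesh_eval(traj, t_restart)
  }
  init <- system_state(traj$grid, t = t_restart)
  init$fields[, ] <- pmax(.unpack_state(y_r, traj$grid$n_nodes), 0)

  orig_hist <- traj$history
  t0_orig <- traj$t0
  hist_fun <- function(t) {
    if (t <= t0_orig) orig_hist(t) else .mesh_eval(traj, t)
  }

  out <- simulate_lesion(
    init, p, t_end = t_end, history = hist_fun,
    out_dt = traj$solver$out_dt, rtol = traj$solver$rtol,
    atol = traj$solver$atol, keep_mesh = traj$solver$keep_mesh,
    check_boundary = FALSE
  )
  out
}
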