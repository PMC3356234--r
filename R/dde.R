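# Delay-differential integrator: explicit Bogacki-Shampine 2(3) embedded
# pair with FSAL, continuous cubic-Hermite extension for history queries,
# advanced by the method of steps. The maximum step never exceeds the
# shortest delay, so every delayed argument falls in already-accepted
# history; propagated derivative discontinuities are handled by forcing
# step endpoints at the lag combinations i*tau_1 + j*tau_2 (i + j <= 3).
# The integrator contains no randomness: identical inputs give identical
# trajectories on one platform.

#' Constant pre-initial history
#'
#' @param y0 State vector (or field matrix) returned for every query time.
#' @return A history function `h(t)` usable with [dde_solve()].
#' @export
constant_history <- function(y0) {
  y0 <- as.vector(unname(if (is.matrix(y0)) .pack_state(y0) else y0))
  function(t) y0
}

# Cubic Hermite evaluation on [t1, t2] given node values/derivatives.
.hermite <- function(tq, t1, y1, f1, t2, y2, f2) {
  h <- t2 - t1
  th <- (tq - t1) / h
  th2 <- th * th
  th3 <- th2 * th
  (2 * th3 - 3 * th2 + 1) * y1 + (th3 - 2 * th2 + th) * h * f1 +
    (-2 * th3 + 3 * th2) * y2 + (th3 - th2) * h * f2
}

# Lookup of the evolving solution: pre-initial times go to the supplied
# history function, later times to Hermite interpolation on the step mesh.
.make_lookup <- function(env) {
  force(env)
  function(tq) {
    if (tq <= env$t0) return(env$history(tq))
    n <- env$n_mesh
    ts <- env$ts
    if (tq >= ts[n]) {
      if (tq > ts[n] + 1e-7 * max(1, abs(ts[n]))) {
        stop("history query at t = ", tq, " is beyond the computed mesh (",
             ts[n], ")", call. = FALSE)
      }
      return(env$ys[[n]])
    }
    if (tq < ts[1]) {
      stop("history query at t = ", tq,
           " precedes the retained mesh; increase the retained history window",
           call. = FALSE)
    }
    j <- findInterval(tq, ts[seq_len(n)], rightmost.closed = TRUE)
    .hermite(tq, ts[j], env$ys[[j]], env$fs[[j]],
             ts[j + 1], env$ys[[j + 1]], env$fs[[j + 1]])
  }
}

#' Integrate a delay-differential system by the method of steps
#'
#' Advances `y' = rhs(t, y, lagged)` from `t0` to `t_end` with an explicit
#' embedded Runge-Kutta 2(3) pair and cubic dense output, where `lagged` is
#' the list of state vectors at `t - lags[j]` drawn from the evolving
#' continuous extension (or from `history` for pre-initial times). Steps
#' are capped at the shortest delay so delayed arguments always reference
#' already-computed history, and at the supplied breakpoints so derivative
#' discontinuities propagated by the delays land on step endpoints.
#'
#' @param rhs Function `(t, y, lagged)` returning `dy/dt`; `lagged` is a
#'   list with one state vector per entry of `lags`.
#' @param y0 Initial state vector at `t0`.
#' @param t0,t_end Integration span in hours (`t_end > t0`).
#' @param lags Strictly positive delays in hours (possibly empty for a
#'   plain ODE).
#' @param history Function of time returning the state for `t <= t0`;
#'   required when `lags` is non-empty. See [constant_history()].
#' @param out_times Output times (default hourly); must lie in
#'   `[t0, t_end]`. The first snapshot at `t0` is `y0` exactly.
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param max_step Upper bound on the step size; further capped at
#'   `min(lags)`.
#' @param breaks Additional mandatory step endpoints (the model wrapper
#'   passes lag combinations automatically).
#' @param keep_mesh Keep the full step mesh (`TRUE`) or only the tail
#'   spanning the longest delay (`FALSE`, default); the tail is what a
#'   restart needs.
#' @return List with `times`, `y` (rows = output times), `diagnostics`
#'   (accepted/rejected step and rhs-evaluation counts), and `mesh` (the
#'   retained `(t, y, f)` nodes of the continuous extension).
#' @export
dde_solve <- function(rhs, y0, t0 = 0, t_end, lags = numeric(0), history = NULL,
                      out_times = NULL, rtol = 1e-6, atol = 1e-8,
                      max_step = Inf, breaks = numeric(0), keep_mesh = FALSE) {
  stopifnot(is.function(rhs), t_end > t0)
  y0 <- as.numeric(y0)
  if (length(lags) > 0) {
    if (any(lags <= 0)) stop("all `lags` must be strictly positive", call. = FALSE)
    if (is.null(history)) stop("`history` is required when lags are present", call. = FALSE)
    max_step <- min(max_step, min(lags))
  }
  if (is.null(history)) history <- constant_history(y0)
  if (is.null(out_times)) out_times <- seq(t0, t_end, by = 1)
  out_times <- sort(unique(as.numeric(out_times)))
  if (out_times[1] < t0 || out_times[length(out_times)] > t_end + 1e-9) {
    stop("`out_times` must lie within [t0, t_end]", call. = FALSE)
  }
  if (!is.finite(max_step) || max_step <= 0) max_step <- (t_end - t0) / 10
  maxlag <- if (length(lags) > 0) max(lags) else 0

  breaks <- sort(unique(breaks[breaks > t0 & breaks < t_end]))
  nv <- length(y0)

  # mesh environment shared with the lookup closure
  env <- new.env(parent = emptyenv())
  env$t0 <- t0
  env$history <- history
  cap <- 256L
  env$ts <- rep(NA_real_, cap)
  env$ys <- vector("list", cap)
  env$fs <- vector("list", cap)
  env$n_mesh <- 0L
  lookup <- .make_lookup(env)

  push_node <- function(t, y, f) {
    n <- env$n_mesh + 1L
    if (n > length(env$ts)) {
      extra <- length(env$ts)
      env$ts <- c(env$ts, rep(NA_real_, extra))
      env$ys <- c(env$ys, vector("list", extra))
      env$fs <- c(env$fs, vector("list", extra))
    }
    env$ts[n] <- t
    env$ys[[n]] <- y
    env$fs[[n]] <- f
    env$n_mesh <- n
  }
  prune_mesh <- function(t_now) {
    if (keep_mesh) return(invisible())
    keep_from <- t_now - maxlag - 2 * max_step
    n <- env$n_mesh
    first <- findInterval(keep_from, env$ts[seq_len(n)])
    if (first > 1L) {
      idx <- first:n
      env$ts <- env$ts[idx]
      env$ys <- env$ys[idx]
      env$fs <- env$fs[idx]
      env$n_mesh <- length(idx)
    }
  }

  eval_rhs <- function(t, y) {
    lagged <- lapply(lags, function(L) lookup(t - L))
    n_rhs <<- n_rhs + 1L
    rhs(t, y, lagged)
  }

  n_rhs <- 0L
  n_acc <- 0L
  n_rej <- 0L

  t <- t0
  y <- y0
  f1 <- eval_rhs(t, y)
  push_node(t, y, f1)

  out <- matrix(NA_real_, length(out_times), nv)
  out_ptr <- 1L
  if (abs(out_times[1] - t0) < 1e-12) {
    out[1, ] <- y0
    out_ptr <- 2L
  }

  # initial step heuristic (deterministic)
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2))
  d1 <- sqrt(mean((f1 / sc)^2))
  h <- if (d1 > 1e-14) 0.01 * d0 / d1 else 1e-3
  h <- min(h, max_step, (t_end - t0) / 4)
  h <- max(h, 1e-10)

  brk_ptr <- 1L
  tiny <- function(tt) 16 * .Machine$double.eps * max(abs(tt), 1)

  while (t < t_end - tiny(t)) {
    h <- min(h, max_step, t_end - t)
    # do not step across a mandatory breakpoint
    while (brk_ptr <= length(breaks) && breaks[brk_ptr] <= t + tiny(t)) {
      brk_ptr <- brk_ptr + 1L
    }
    if (brk_ptr <= length(breaks) && t + h > breaks[brk_ptr] - tiny(t)) {
      h <- breaks[brk_ptr] - t
    }
    if (h < tiny(t)) {
      stop("step size underflow at t = ", format(t),
           " h (stiffness or discontinuity stall)", call. = FALSE)
    }

    k2 <- eval_rhs(t + h / 2, y + (h / 2) * f1)
    k3 <- eval_rhs(t + 3 * h / 4, y + (3 * h / 4) * k2)
    y_new <- y + (h / 9) * (2 * f1 + 3 * k2 + 4 * k3)
    t_new <- t + h
    k4 <- eval_rhs(t_new, y_new)
    err <- h * (-5 / 72 * f1 + 1 / 12 * k2 + 1 / 9 * k3 - 1 / 8 * k4)
    sc <- atol + rtol * pmax(abs(y), abs(y_new))
    err_norm <- sqrt(mean((err / sc)^2))

    if (!is.finite(err_norm)) {
      bad <- which(!is.finite(y_new) | !is.finite(err))[1]
      stop("non-finite state during step at t = ", format(t),
           " h (component ", bad, ")", call. = FALSE)
    }

    if (err_norm <= 1) {
      push_node(t_new, y_new, k4)
      # emit dense output for all requested times inside (t, t_new]
      while (out_ptr <= length(out_times) &&
             out_times[out_ptr] <= t_new + tiny(t_new)) {
        tq <- out_times[out_ptr]
        out[out_ptr, ] <- if (abs(tq - t_new) < tiny(t_new)) {
          y_new
        } else {
          .hermite(tq, t, y, f1, t_new, y_new, k4)
        }
        out_ptr <- out_ptr + 1L
      }
      t <- t_new
      y <- y_new
      f1 <- k4                      # FSAL
      n_acc <- n_acc + 1L
      prune_mesh(t)
      fac <- if (err_norm > 1e-12) 0.9 * err_norm^(-1 / 3) else 5
      h <- h * min(5, max(0.2, fac))
    } else {
      n_rej <- n_rej + 1L
      h <- h * max(0.2, 0.9 * err_norm^(-1 / 3))
    }
  }

  n <- env$n_mesh
  list(
    times = out_times,
    y = out,
    diagnostics = list(n_accepted = n_acc, n_rejected = n_rej, n_rhs = n_rhs),
    mesh = list(t = env$ts[seq_len(n)], y = env$ys[seq_len(n)],
                f = env$fs[seq_len(n)]),
    t0 = t0, t_end = t_end, lags = lags
  )
}

# Breakpoints where delay-propagated derivative discontinuities land:
# i*tau_1 + j*tau_2 for i + j <= order.
.delay_breaks <- function(t0, t_end, lags, order = 3) {
  if (length(lags) == 0) return(numeric(0))
  combos <- expand.grid(i = 0:order, j = 0:order)
  combos <- combos[combos$i + combos$j > 0 & combos$i + combos$j <= order, ]
  b <- t0 + combos$i * lags[1] + if (length(lags) > 1) combos$j * lags[2] else 0
  sort(unique(b[b > t0 & b < t_end]))
}
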