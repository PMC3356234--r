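# Scalar observables of a run: lesion radius (healthy-cell deficit),
# penumbra extent and composition, population integrals, and the
# expansion / abatement / resolution classification.

#' Lesion radius of one snapshot
#'
#' The outermost radius at which the healthy density falls below
#' `theta_C * C0`, with linear interpolation between the outermost
#' sub-threshold node and its healthy neighbour. 0 if no node is below
#' threshold; the domain radius if every node is.
#'
#' @param state A [system_state()].
#' @param C0 Background healthy density, cells/mm^2.
#' @param theta_C Threshold fraction in (0, 1), default 0.5.
#' @return Radius in mm.
#' @export
lesion_radius <- function(state, C0, theta_C = 0.5) {
  stopifnot(inherits(state, "chondro_state"))
  if (!is.numeric(theta_C) || theta_C <= 0 || theta_C >= 1) {
    stop("`theta_C` must lie strictly between 0 and 1", call. = FALSE)
  }
  .radius_below(state$fields[, "C"], state$grid, theta_C * C0)
}

# outermost radius where profile < level (linear interpolation)
.radius_below <- function(v, grid, level) {
  n <- grid$n_nodes
  below <- v < level
  if (!any(below)) return(0)
  i <- max(which(below))
  if (i == n) return(grid$r_max)
  r <- grid$node_centers
  r[i] + (level - v[i]) / (v[i + 1] - v[i]) * (r[i + 1] - r[i])
}

#' Penumbra radii of one snapshot
#'
#' The penumbra is the annulus of viable but sick cells (catabolic +
#' EPOR-active) around the necrotic core: here, the support of
#' `S_T + S_A > theta_S * C0`, with linear interpolation at both edges.
#'
#' @param state A [system_state()].
#' @param C0 Background healthy density.
#' @param theta_S Threshold fraction of `C0`, default 0.05.
#' @return `c(inner, outer)` in mm, or `c(NA, NA)` if no penumbra exists.
#' @export
penumbra_radii <- function(state, C0, theta_S = 0.05) {
  stopifnot(inherits(state, "chondro_state"))
  s <- state$fields[, "S_T"] + state$fields[, "S_A"]
  level <- theta_S * C0
  grid <- state$grid
  above <- s > level
  if (!any(above)) return(c(inner = NA_real_, outer = NA_real_))
  r <- grid$node_centers
  i1 <- min(which(above))
  i2 <- max(which(above))
  inner <- if (i1 == 1) 0 else {
    r[i1 - 1] + (level - s[i1 - 1]) / (s[i1] - s[i1 - 1]) * (r[i1] - r[i1 - 1])
  }
  outer <- if (i2 == grid$n_nodes) grid$r_max else {
    r[i2] + (level - s[i2]) / (s[i2 + 1] - s[i2]) * (r[i2 + 1] - r[i2])
  }
  c(inner = inner, outer = outer)
}

#' Per-snapshot summary of a trajectory
#'
#' Reduces a run to the time series the model reasons about: lesion
#' radius, penumbra edges, spatially integrated populations, and chemical
#' maxima. A pure function of the trajectory — recomputation reproduces it
#' exactly.
#'
#' @param traj A `chondro_trajectory`.
#' @param C0 Background healthy density; taken from the attached scenario
#'   spec if omitted.
#' @param theta_C,theta_S Lesion / penumbra thresholds (fractions of `C0`).
#' @return A tibble with one row per output time: `time` (h), `day`,
#'   `lesion_radius`, `penumbra_inner`, `penumbra_outer` (mm), `total_C`,
#'   `total_ST`, `total_SA`, `total_DN`, `total_DA` (cells), `max_F`,
#'   `max_P` (concentration).
#' @export
lesion_summary <- function(traj, C0 = NULL, theta_C = 0.5, theta_S = 0.05) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  if (is.null(C0)) {
    spec <- attr(traj, "spec")
    if (is.null(spec)) {
      stop("supply `C0` (trajectory has no attached scenario spec)",
           call. = FALSE)
    }
    C0 <- spec$C0
  }
  grid <- traj$grid
  areas <- grid$cell_areas
  n_t <- length(traj$times)
  rows <- purrr::map(seq_len(n_t), function(i) {
    fl <- traj$states[, , i]
    s <- fl[, "S_T"] + fl[, "S_A"]
    pen <- {
      st <- system_state(grid, t = traj$times[i])
      st$fields[, ] <- fl
      penumbra_radii(st, C0, theta_S)
    }
    tibble::tibble(
      time = traj$times[i],
      lesion_radius = .radius_below(fl[, "C"], grid, theta_C * C0),
      penumbra_inner = pen[["inner"]],
      penumbra_outer = pen[["outer"]],
      total_C = sum(fl[, "C"] * areas),
      total_ST = sum(fl[, "S_T"] * areas),
      total_SA = sum(fl[, "S_A"] * areas),
      total_DN = sum(fl[, "D_N"] * areas),
      total_DA = sum(fl[, "D_A"] * areas),
      total_penumbra = sum(s * areas),
      max_F = max(fl[, "F"]),
      max_P = max(fl[, "P"])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$day <- out$time / 24
  dplyr::relocate(out, "time", "day")
}

#' Classify a run as expanding, abated or resolved
#'
#' `"expanding"` if the lesion radius still grows faster than `eps_slope`
#' over the final three days; otherwise `"abated"` if a penumbra persists
#' at the end of the run; otherwise `"resolved"` (final sick-cell content
#' below `theta_S * C0` times the initial injury area, which an injury-free
#' run satisfies vacuously).
#'
#' @param summary A [lesion_summary()] tibble spanning at least 3 days.
#' @param injury_radius Initial injury radius, mm (for the resolution
#'   threshold).
#' @param C0 Background healthy density.
#' @param theta_S Penumbra threshold fraction, default 0.05.
#' @param eps_slope Slope tolerance in mm/day, default 0.01.
#' @return `"expanding"`, `"abated"`, or `"resolved"`.
#' @export
classify_regime <- function(summary, injury_radius = 0.25, C0 = 100,
                            theta_S = 0.05, eps_slope = 0.01) {
  span <- max(summary$time) - min(summary$time)
  if (span < 72) {
    stop("regime classification needs at least 3 days of output", call. = FALSE)
  }
  tail3 <- summary[summary$time >= max(summary$time) - 72, ]
  slope <- stats::coef(stats::lm(lesion_radius ~ time, data = tail3))[[2]] * 24
  pen_final <- summary$total_penumbra[nrow(summary)]
  pen_floor <- theta_S * C0 * pi * injury_radius^2
  if (slope > eps_slope) {
    "expanding"
  } else if (pen_final >= pen_floor) {
    "abated"
  } else {
    "resolved"
  }
}

#' Day at which lesion expansion abates
#'
#' The first output time after which the lesion radius never again grows
#' by more than `eps_slope` mm/day over any subsequent daily interval;
#' `Inf` if expansion continues to the end of the run.
#'
#' @param summary A [lesion_summary()] tibble.
#' @param eps_slope Growth tolerance, mm/day.
#' @return Abatement time in days (possibly `Inf`).
#' @export
abatement_day <- function(summary, eps_slope = 0.01) {
  t <- summary$time
  r <- summary$lesion_radius
  if (max(t) - min(t) < 24) return(Inf)
  # growth over a trailing 24 h window, evaluated at every output time
  idx <- findInterval(t - 24, t)
  valid <- t - 24 >= min(t) - 1e-9
  growth <- rep(-Inf, length(t))
  growth[valid] <- r[valid] - r[pmax(idx[valid], 1)]
  # earliest time T such that no later daily window grows beyond eps_slope
  exceed <- which(growth > eps_slope)
  if (length(exceed) == 0) return(min(t) / 24)
  last_bad <- max(exceed)
  if (last_bad == length(t)) return(Inf)
  (t[last_bad] - 24) / 24               # start of the last growing window
}
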