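# broom-style tidiers and quick-look plots.

#' Long-format view of a trajectory
#'
#' @param traj A `chondro_trajectory`.
#' @param fields Fields to include (default all ten).
#' @return A tibble `time, radius, field, value` (hours, mm, field name,
#'   concentration or density).
#' @export
tidy_trajectory <- function(traj, fields = CHONDRO_FIELDS) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  fields <- match.arg(fields, CHONDRO_FIELDS, several.ok = TRUE)
  n <- traj$grid$n_nodes
  n_t <- length(traj$times)
  tibble::tibble(
    time = rep(traj$times, each = n * length(fields)),
    radius = rep(rep(traj$grid$node_centers, times = length(fields)),
                 times = n_t),
    field = rep(rep(fields, each = n), times = n_t),
    value = as.vector(traj$states[, fields, , drop = FALSE])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.chondro_trajectory <- function(x, fields = CHONDRO_FIELDS, ...) {
  tidy_trajectory(x, fields = fields)
}

#' @export
glance.chondro_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  C0 <- if (!is.null(spec)) spec$C0 else NULL
  smry <- if (!is.null(C0)) lesion_summary(x) else NULL
  tibble::tibble(
    t_end = max(x$times),
    n_nodes = x$grid$n_nodes,
    r_max = x$grid$r_max,
    n_steps = x$diagnostics$n_accepted,
    n_rejected = x$diagnostics$n_rejected,
    n_rhs = x$diagnostics$n_rhs,
    final_total_C = if (!is.null(smry)) smry$total_C[nrow(smry)] else NA_real_,
    final_lesion_radius = if (!is.null(smry)) {
      smry$lesion_radius[nrow(smry)]
    } else NA_real_,
    regime = if (!is.null(smry)) {
      classify_regime(smry, injury_radius = spec$injury_radius, C0 = spec$C0)
    } else NA_character_
  )
}

#' @export
tidy.chondro_sensitivity <- function(x, ...) x$labels

#' @export
glance.chondro_sensitivity <- function(x, ...) {
  tibble::tibble(
    n_params = length(unique(x$runs$param)),
    n_runs = nrow(x$runs),
    n_failed = sum(!is.na(x$runs$error)),
    base_regime = x$base$regime,
    base_r10 = x$base$r10,
    no_epo_r10 = x$no_epo$r10
  )
}

#' Radial-profile panels of healthy and penumbra cells
#'
#' Mirrors the model's canonical presentation: healthy density and
#' penumbra (catabolic + EPOR-active) density as functions of radius at a
#' few selected days.
#'
#' @param object A `chondro_trajectory`.
#' @param days Days at which to draw profiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chondro_trajectory <- function(object, days = c(0, 1, 3, 5, 7, 10),
                                        ...) {
  days <- days[days * 24 <= max(object$times)]
  long <- tidy_trajectory(object, fields = c("C", "S_T", "S_A"))
  long <- dplyr::filter(long, .data$time %in% (days * 24))
  wide <- tidyr::pivot_wider(long, names_from = "field",
                             values_from = "value")
  wide <- dplyr::mutate(
    wide,
    day = factor(.data$time / 24),
    penumbra = .data$S_T + .data$S_A
  )
  plot_df <- tidyr::pivot_longer(
    dplyr::select(wide, "day", "radius", healthy = "C", "penumbra"),
    cols = c("healthy", "penumbra"),
    names_to = "population", values_to = "density"
  )
  ggplot2::ggplot(plot_df,
                  ggplot2::aes(x = .data$radius, y = .data$density,
                               colour = .data$day)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~population, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "radius (mm)", y = "cell density (cells/mm²)",
                  colour = "day") +
    ggplot2::theme_minimal()
}

#' Qualitative sensitivity table as a tile plot
#'
#' @param object A `chondro_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chondro_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(x = .data$direction, y = .data$param,
                               fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "response") +
    ggplot2::theme_minimal()
}

#' Summary time-series plot
#'
#' @param summary A [lesion_summary()] tibble.
#' @return A ggplot of lesion radius and penumbra edges over time.
#' @export
plot_lesion_radius <- function(summary) {
  df <- tidyr::pivot_longer(
    dplyr::select(summary, "day", "lesion_radius", "penumbra_inner",
                  "penumbra_outer"),
    cols = -"day", names_to = "measure", values_to = "radius"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$radius,
                                   linetype = .data$measure)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "day", y = "radius (mm)") +
    ggplot2::theme_minimal()
}
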