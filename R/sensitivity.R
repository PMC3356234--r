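# One-at-a-time parameter perturbation study. Each tunable constant z is
# swept over [0, 2z] (strictly-positive constants over [0.05 z, 2 z]); the
# qualitative response in each direction is classified against the with-EPO
# base run with documented deterministic thresholds.

#' Parameters covered by the one-at-a-time sensitivity study
#'
#' The sixteen constants attached to nonlinear terms of the model, swept
#' one at a time over `[0, 2z]` (saturation constants, `Lambda` and
#' `alpha` over `[0.05 z, 2 z]`: they must stay strictly positive).
#' @format Character vector of parameter names.
#' @export
SWEEP_PARAMS <- c("sigma_R", "sigma_M", "sigma_F", "sigma_P", "Lambda",
                  "lambda_R", "lambda_M", "lambda_F", "lambda_P", "alpha",
                  "beta_1", "beta_2", "gamma", "nu", "mu_SA", "mu_DN")
.STRICT_POS <- c("lambda_R", "lambda_M", "lambda_F", "lambda_P", "alpha",
                 "Lambda")

SENSITIVITY_LABELS <- c("robust", "abated-sooner", "less-efficient-abatement",
                        "approaches-no-epo", "penumbra-smaller-slower",
                        "no-inflammation", "penumbra-formation-decreases",
                        "slower-recovery", "mixed")

# Scalar endpoints of one run used by the label rules.
.run_stats <- function(spec, ...) {
  traj <- suppressWarnings(run_scenario(spec = spec, check_boundary = FALSE, ...))
  smry <- lesion_summary(traj, C0 = spec$C0)
  i_end <- nrow(smry)
  min_C <- min(smry$total_C)
  tibble::tibble(
    regime = classify_regime(smry, injury_radius = spec$injury_radius,
                             C0 = spec$C0),
    r10 = smry$lesion_radius[i_end],
    r_peak = max(smry$lesion_radius),
    t_abate = abatement_day(smry),
    pen_out10 = smry$penumbra_outer[i_end],
    pen_out_peak = suppressWarnings(max(c(smry$penumbra_outer, 0),
                                        na.rm = TRUE)),
    pen10 = smry$total_penumbra[i_end],
    pen_max = max(smry$total_penumbra),
    recovery = if (smry$total_C[1] - min_C > 0) {
      (smry$total_C[i_end] - min_C) / (smry$total_C[1] - min_C)
    } else 0,
    st_frac10 = if (smry$total_penumbra[i_end] > 0) {
      smry$total_ST[i_end] / smry$total_penumbra[i_end]
    } else NA_real_
  )
}

.sweep_values <- function(z, param, n_points) {
  lo <- if (param %in% .STRICT_POS) 0.05 * z else 0
  vals <- seq(lo, 2 * z, length.out = n_points)
  sort(unique(c(vals, z)))
}

#' Sweep one parameter and classify the response in each direction
#'
#' Runs the scenario at `n_points` values spanning `[0, 2 z]` (lower
#' endpoint `0.05 z` for the strictly positive constants), collects
#' endpoint statistics, and assigns one qualitative label per direction
#' (increase / decrease from the base value) by the documented rules of
#' [sensitivity_labels()].
#'
#' @param spec The with-EPO reference [scenario_spec()] to perturb.
#' @param param One of `SWEEP_PARAMS`.
#' @param n_points Number of sweep values (>= 3).
#' @param base_stats,noepo_stats Optional precomputed [.run_stats] rows for
#'   the base run and the no-EPO reference (computed if omitted).
#' @param ... Passed to [simulate_lesion()].
#' @return List with `runs` (tibble: value, relative value, stats, errors)
#'   and `labels` (tibble: param, direction, label).
#' @export
sweep_parameter <- function(spec, param, n_points = 9,
                            base_stats = NULL, noepo_stats = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!param %in% SWEEP_PARAMS) {
    stop("`", param, "` is not a swept parameter; choose one of: ",
         paste(SWEEP_PARAMS, collapse = ", "), call. = FALSE)
  }
  if (n_points < 3) stop("`n_points` must be >= 3", call. = FALSE)
  z <- spec$params[[param]]
  if (z <= 0) stop("base value of `", param, "` must be positive to sweep",
                   call. = FALSE)
  if (is.null(base_stats)) base_stats <- .run_stats(spec, ...)
  if (is.null(noepo_stats)) {
    noepo_spec <- spec
    noepo_spec$params <- chondro_params(sigma_P = 0, base = spec$params)
    noepo_stats <- .run_stats(noepo_spec, ...)
  }
  vals <- .sweep_values(z, param, n_points)
  runs <- purrr::map(vals, function(v) {
    if (abs(v - z) < 1e-12) {
      return(dplyr::mutate(base_stats, value = v, error = NA_character_))
    }
    sp <- spec
    args <- stats::setNames(list(v), param)
    sp$params <- do.call(chondro_params, c(args, list(base = spec$params)))
    tryCatch(
      dplyr::mutate(.run_stats(sp, ...), value = v, error = NA_character_),
      error = function(e) {
        tibble::tibble(regime = NA_character_, r10 = NA_real_,
                       t_abate = NA_real_, pen_out10 = NA_real_,
                       pen10 = NA_real_, pen_max = NA_real_,
                       recovery = NA_real_, st_frac10 = NA_real_,
                       value = v, error = conditionMessage(e))
      }
    )
  })
  runs <- dplyr::bind_rows(runs)
  runs <- dplyr::mutate(runs, param = param, rel_value = value / z,
                        .before = 1)
  dr <- spec$r_max / spec$n_nodes
  labels <- dplyr::bind_rows(
    .direction_label(runs, base_stats, noepo_stats, z, param, "increase", dr),
    .direction_label(runs, base_stats, noepo_stats, z, param, "decrease", dr)
  )
  list(runs = runs, labels = labels)
}

# Documented deterministic label rules (see sensitivity_labels()).
.direction_label <- function(runs, base, noepo, z, param, direction, dr) {
  dir_runs <- if (direction == "increase") {
    runs[runs$value > z + 1e-12, , drop = FALSE]
  } else {
    runs[runs$value < z - 1e-12, , drop = FALSE]
  }
  dir_runs <- dir_runs[is.na(dir_runs$error), , drop = FALSE]
  out <- function(label) tibble::tibble(param = param, direction = direction,
                                        label = label)
  if (nrow(dir_runs) == 0) return(out(NA_character_))
  # order from base toward the extreme
  dir_runs <- dir_runs[order(abs(dir_runs$value - z)), , drop = FALSE]
  E <- dir_runs[nrow(dir_runs), ]
  mids <- dir_runs[-nrow(dir_runs), , drop = FALSE]
  t_tol <- 1                                       # days
  floor_r <- max(0.15 * base$r_peak, 2 * dr)       # lesion-extent floor
  mids_robust <- nrow(mids) == 0 ||
    all(mids$regime == base$regime &
        abs(mids$t_abate - base$t_abate) < t_tol &
        mids$pen_max >= 0.5 * base$pen_max &
        abs(mids$r_peak - base$r_peak) <= floor_r)

  if (E$pen_max < 0.05 * base$pen_max) {
    # inflammation never takes hold at the extreme; the mid-sweep behavior
    # says whether the collapse is abrupt (only the endpoint kills it) or
    # a steady decline of penumbra formation
    return(out(if (mids_robust) "no-inflammation"
               else "penumbra-formation-decreases"))
  }
  if (identical(E$regime, "expanding") ||
      (E$r_peak >= 0.8 * noepo$r_peak && E$recovery <= 0.05)) {
    return(out("approaches-no-epo"))
  }
  sooner_time <- is.finite(E$t_abate) && E$t_abate <= base$t_abate - t_tol
  sooner_radius <- E$r_peak <= 0.85 * base$r_peak &&
    E$t_abate <= base$t_abate + 0.5
  if (sooner_time || sooner_radius) return(out("abated-sooner"))
  slower <- is.finite(E$recovery) && E$recovery <= 0.9 * base$recovery
  smaller <- is.finite(E$pen_out_peak) && is.finite(base$pen_out_peak) &&
    E$pen_out_peak <= 0.9 * base$pen_out_peak
  if (smaller && slower) return(out("penumbra-smaller-slower"))
  if (E$recovery <= 0.5 * base$recovery &&
      abs(E$r_peak - base$r_peak) <= floor_r &&
      identical(E$regime, base$regime)) {
    return(out("slower-recovery"))
  }
  later <- (is.finite(E$t_abate) && E$t_abate >= base$t_abate + t_tol) ||
    (!is.finite(E$t_abate) && is.finite(base$t_abate)) ||
    E$r_peak >= 1.15 * base$r_peak
  if (later) return(out("less-efficient-abatement"))
  if (identical(E$regime, base$regime) &&
      abs(E$r_peak - base$r_peak) <= floor_r &&
      abs(E$t_abate - base$t_abate) < t_tol &&
      E$recovery >= 0.5 * base$recovery &&
      E$recovery <= 2 * base$recovery) {
    return(out("robust"))
  }
  out("mixed")
}

#' The qualitative response table (all 16 swept parameters)
#'
#' Sweeps every tunable constant one at a time around the with-EPO
#' reference and emits a two-column qualitative table (response to
#' increase / decrease) for side-by-side comparison. Deterministic: the
#' labels are a pure function of the run statistics and the documented
#' thresholds.
#'
#' @param spec The with-EPO reference [scenario_spec()]; for a full table
#'   in desk time use a reduced grid, e.g.
#'   `scenario_spec(n_nodes = 100)`.
#' @param params Parameters to sweep (default all 16).
#' @param n_points Sweep values per parameter (default 9; the table is
#'   stable down to 5).
#' @param ... Passed to [simulate_lesion()].
#' @return A `chondro_sensitivity` object: list with `table` (tibble:
#'   param, increase, decrease), `runs` (all per-run statistics), and the
#'   base / no-EPO reference statistics.
#' @export
sensitivity_table <- function(spec = scenario_spec(n_nodes = 100),
                              params = SWEEP_PARAMS, n_points = 9, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  params <- match.arg(params, SWEEP_PARAMS, several.ok = TRUE)
  base_stats <- .run_stats(spec, ...)
  noepo_spec <- spec
  noepo_spec$params <- chondro_params(sigma_P = 0, base = spec$params)
  noepo_stats <- .run_stats(noepo_spec, ...)
  frags <- purrr::map(params, function(pn) {
    sweep_parameter(spec, pn, n_points = n_points,
                    base_stats = base_stats, noepo_stats = noepo_stats, ...)
  })
  runs <- dplyr::bind_rows(purrr::map(frags, "runs"))
  labels <- dplyr::bind_rows(purrr::map(frags, "labels"))
  table <- tidyr::pivot_wider(labels, names_from = "direction",
                              values_from = "label")
  structure(
    list(table = table, runs = runs, labels = labels,
         base = base_stats, no_epo = noepo_stats, spec = spec),
    class = "chondro_sensitivity"
  )
}

#' @export
print.chondro_sensitivity <- function(x, ...) {
  cat("<chondro_sensitivity> one-at-a-time sweep,",
      length(unique(x$runs$param)), "parameters\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' Label rules of the sensitivity classification
#'
#' Returns the documented thresholds behind the qualitative labels, for
#' reference and for reproducing the classification by hand. Rules are
#' evaluated in order on the extreme sweep value of each direction:
#' \itemize{
#'   \item `no-inflammation`: peak penumbra content at the extreme below 5%
#'     of the base run's peak while intermediate values stay robust;
#'     `penumbra-formation-decreases` when the intermediates already shrink.
#'   \item `approaches-no-epo`: the extreme run classifies expanding, or
#'     its peak lesion radius reaches 80% of the no-EPO reference's with
#'     healthy-population recovery below 5%.
#'   \item `abated-sooner`: abatement day at least 1 day earlier, or peak
#'     lesion radius at least 15% smaller without a later abatement day
#'     (expansion halted earlier along its course).
#'   \item `penumbra-smaller-slower`: peak penumbra outer radius at least
#'     10% smaller with recovery at least 10% weaker (despite no earlier
#'     abatement).
#'   \item `slower-recovery`: recovery collapses to below half of base at
#'     unchanged lesion extent.
#'   \item `less-efficient-abatement`: abatement day at least 1 day later
#'     (or lost entirely), or peak lesion radius at least 15% larger.
#'   \item `robust`: regime unchanged, abatement day within 1 day, peak
#'     lesion radius within max(15%, two grid cells), recovery within a
#'     factor of 2.
#' }
#' @return A character vector of the label vocabulary.
#' @export
sensitivity_labels <- function() SENSITIVITY_LABELS
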