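# Parameter set for the cytokine / cell-state model.
#
# Units: time in hours, space in mm, cell densities in cells mm^-2,
# chemical concentrations in arbitrary units normalized so that the
# reference half-saturation constants are O(1), matrix density in
# arbitrary matrix units.

.param_info <- function() {
  tibble::tribble(
    ~name,       ~unit,                          ~strictly_positive, ~role,
    "D_R",       "mm^2/h",                       FALSE, "diffusivity of ROS",
    "D_M",       "mm^2/h",                       FALSE, "diffusivity of DAMPs",
    "D_F",       "mm^2/h",                       FALSE, "diffusivity of TNF-alpha",
    "D_P",       "mm^2/h",                       FALSE, "diffusivity of EPO",
    "delta_R",   "1/h",                          FALSE, "decay rate of ROS",
    "delta_M",   "1/h",                          FALSE, "decay rate of DAMPs",
    "delta_F",   "1/h",                          FALSE, "decay rate of TNF-alpha",
    "delta_P",   "1/h",                          FALSE, "decay rate of EPO",
    "sigma_R",   "conc/h per cell/mm^2",         FALSE, "ROS production per catabolic cell density",
    "sigma_M",   "conc/h per cell/mm^2",         FALSE, "DAMP production per necrotic cell density",
    "sigma_F",   "conc/h per cell/mm^2",         FALSE, "TNF-alpha production per catabolic cell density",
    "sigma_P",   "conc/h per cell/mm^2",         FALSE, "EPO production per healthy cell density",
    "delta_U",   "1/h",                          FALSE, "matrix degradation rate scale (also DAMP source from degraded matrix)",
    "lambda_R",  "conc",                         TRUE,  "half-saturation of ROS signaling",
    "lambda_M",  "conc",                         TRUE,  "half-saturation of DAMP signaling",
    "lambda_F",  "conc",                         TRUE,  "half-saturation of TNF-alpha signaling",
    "lambda_P",  "conc",                         TRUE,  "half-saturation of EPO signaling",
    "Lambda",    "conc",                         TRUE,  "TNF-alpha inhibition constant in EPO production",
    "alpha",     "1/h",                          TRUE,  "EPOR-active -> healthy reversion rate (EPO-gated)",
    "beta_1",    "1/h",                          FALSE, "healthy -> catabolic switching rate via DAMPs",
    "beta_2",    "1/h",                          FALSE, "healthy -> catabolic switching rate via TNF-alpha",
    "gamma",     "1/h",                          FALSE, "catabolic -> EPOR-active switching rate (delayed, TNF-gated)",
    "nu",        "1/h",                          FALSE, "catabolic apoptosis rate (joint TNF and DAMP gating)",
    "mu_SA",     "1/h",                          FALSE, "EPOR-active apoptosis rate (TNF-gated)",
    "mu_DN",     "1/h",                          FALSE, "necrotic decay-to-inert rate",
    "tau_1",     "h",                            FALSE, "delay before a signaled catabolic cell expresses the EPO receptor",
    "tau_2",     "h",                            FALSE, "delay before a ROS-signaled healthy cell produces EPO",
    "P_c",       "conc",                         FALSE, "critical EPO level gating the healthy -> catabolic switch"
  )
}

.param_names <- function() .param_info()$name

#' Construct and validate a model parameter set
#'
#' Collects every rate, saturation, diffusion, delay and threshold constant
#' of the lesion model into a validated list. Unspecified values default to
#' the calibrated with-EPO reference set (see [reference_params()]).
#'
#' @param ... Named scalar overrides of individual parameters (see
#'   [param_table()] for names and units).
#' @param h_sharpness Non-negative scalar; 0 (default) uses the exact
#'   discrete threshold gate, positive values smooth it (see
#'   [threshold_gate()]). A numerical device, not part of the model.
#' @param base Optional existing `chondro_params` object to modify instead
#'   of the with-EPO reference.
#' @return An object of class `chondro_params`: a named list of the 28 model
#'   constants plus `h_sharpness`.
#' @examples
#' p <- chondro_params(sigma_P = 0)      # no EPO production
#' p$tau_1
#' @export
chondro_params <- function(..., h_sharpness = NULL, base = NULL) {
  defaults <- if (is.null(base)) .reference_values() else unclass(base)
  dots <- list(...)
  if (length(dots) > 0 && (is.null(names(dots)) || any(names(dots) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(dots), .param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- defaults
  p[names(dots)] <- dots
  if (!is.null(h_sharpness)) p$h_sharpness <- h_sharpness
  if (is.null(p$h_sharpness)) p$h_sharpness <- 0
  p <- p[c(.param_names(), "h_sharpness")]
  validate_params(structure(p, class = "chondro_params"))
}

#' @export
print.chondro_params <- function(x, ...) {
  cat("<chondro_params>\n")
  nm <- .param_names()
  vals <- vapply(nm, function(n) format(x[[n]], digits = 6), character(1))
  cat(paste0("  ", format(nm, width = 10), " = ", vals), sep = "\n")
  if (x$h_sharpness > 0) {
    cat("  threshold gate smoothed, sharpness =", x$h_sharpness, "\n")
  }
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks that every constant is a finite (or, for `P_c`, possibly infinite)
#' non-negative scalar, that the half-saturation constants, `Lambda` and
#' `alpha` are strictly positive, and that in any set with both delays the
#' EPOR-activation delay does not exceed the EPO-synthesis delay.
#'
#' @param p A `chondro_params` object (or bare named list with the same fields).
#' @return `p`, invisibly classed, if valid; otherwise an error naming the
#'   offending parameter and the violated bound.
#' @export
validate_params <- function(p) {
  info <- .param_info()
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || is.na(v)) {
      stop("parameter `", nm, "` must be a single numeric value", call. = FALSE)
    }
    if (nm != "P_c" && !is.finite(v)) {
      stop("parameter `", nm, "` must be finite", call. = FALSE)
    }
    if (info$strictly_positive[i]) {
      if (v <= 0) {
        stop("parameter `", nm, "` must be strictly positive (got ", v, ")",
             call. = FALSE)
      }
    } else if (v < 0) {
      stop("parameter `", nm, "` must be >= 0 (got ", v, ")", call. = FALSE)
    }
  }
  if (p$tau_1 <= 0 || p$tau_2 <= 0) {
    stop("delays `tau_1` and `tau_2` must be strictly positive", call. = FALSE)
  }
  if (is.null(p$h_sharpness) || p$h_sharpness < 0) {
    stop("`h_sharpness` must be >= 0", call. = FALSE)
  }
  structure(unclass(p), class = "chondro_params")
}

# Calibrated with-EPO reference values. Time in h, space in mm; chemical
# concentrations normalized so that all half-saturation constants are 1.
# Every value here is a calibration (provenance "calibrated"), chosen so
# that the two reference scenarios reproduce the unabated-expansion and
# EPO-abatement regimes over 10 days from a 0.25 mm necrotic disc; the
# delays are the only constants taken directly from reported physiology
# (8-12 h for EPOR expression, upper end used; 24 h for EPO synthesis).
.reference_values <- function() {
  list(
    D_R = 0.02, D_M = 0.0011, D_F = 0.0014, D_P = 0.03,
    delta_R = 0.04, delta_M = 0.25, delta_F = 0.35, delta_P = 0.015,
    sigma_R = 0.0005, sigma_M = 0.05, sigma_F = 0.025, sigma_P = 0.03,
    delta_U = 0.03,
    lambda_R = 1, lambda_M = 1, lambda_F = 1, lambda_P = 1,
    Lambda = 400,
    alpha = 0.005, beta_1 = 0.5, beta_2 = 0.005,
    gamma = 0.015, nu = 0.003, mu_SA = 0.003, mu_DN = 0.02,
    tau_1 = 12, tau_2 = 24, P_c = 1,
    h_sharpness = 0
  )
}

#' Shipped reference parameter sets
#'
#' Two documented parameter sets drive the package's canonical scenarios:
#' `"with_epo"`, in which healthy cells sense ROS and (after the synthesis
#' delay) produce EPO that abates lesion expansion, and `"no_epo"`,
#' identical except that EPO production is switched off (`sigma_P = 0`), so
#' inflammation spreads unabated. The two sets differ *only* in `sigma_P`,
#' which is what makes their early-time trajectories identical until the
#' delayed EPO pathway activates.
#'
#' All values are calibrations expressed in the model's normalized units
#' (the source analysis does not fix them quantitatively); see
#' [param_table()] for units and the package vignette for the calibration
#' rationale.
#'
#' @param which `"with_epo"` (default) or `"no_epo"`.
#' @return A `chondro_params` object.
#' @examples
#' reference_params("no_epo")$sigma_P  # 0
#' @export
reference_params <- function(which = c("with_epo", "no_epo")) {
  which <- match.arg(which)
  if (which == "with_epo") chondro_params() else chondro_params(sigma_P = 0)
}

#' Infinite-feedback diagnostic variant (threshold gate held at 1)
#'
#' Returns a copy of `p` in which the EPO threshold gate is identically 1
#' for every finite EPO level (operationally `P_c = Inf`, so `P - P_c` is
#' always negative). Under this variant nothing ever shuts off the
#' healthy-to-catabolic switch, and the pro-inflammatory loop
#' (alarmins -> catabolic cells -> TNF-alpha -> more conversion) is
#' self-amplifying until the healthy population is exhausted — the
#' diagnostic that motivates gating the switch on EPO in the first place.
#'
#' @param p A `chondro_params` object.
#' @return A `chondro_params` object with `P_c = Inf`.
#' @export
h_identically_one <- function(p) {
  p <- validate_params(p)
  p$P_c <- Inf
  validate_params(p)
}

#' Tabulate a parameter set with units and provenance
#'
#' @param p A `chondro_params` object.
#' @return A tibble with one row per model constant: `name`, `value`,
#'   `unit`, `role`, and `provenance` (`"physiology"` for the two delays,
#'   `"calibrated"` for everything else).
#' @export
param_table <- function(p = chondro_params()) {
  p <- validate_params(p)
  info <- .param_info()
  tibble::tibble(
    name = info$name,
    value = vapply(info$name, function(n) p[[n]], numeric(1)),
    unit = info$unit,
    role = info$role,
    provenance = ifelse(info$name %in% c("tau_1", "tau_2"), "physiology", "calibrated")
  )
}
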