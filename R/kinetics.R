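#' Michaelis-Menten saturation fraction
#'
#' The dimensionless factor `x / (lam + x)` used throughout the model to
#' convert a chemical concentration into a bounded signaling strength.
#' It is 0 at zero input, 1/2 at the half-saturation constant `lam`, and
#' approaches (never reaches) 1 for large inputs.
#'
#' @param x Non-negative concentration (vectorized).
#' @param lam Strictly positive half-saturation constant, same units as `x`.
#' @return Numeric vector in `[0, 1)`, monotone increasing in `x`.
#' @examples
#' saturation(0, 1)     # 0
#' saturation(1, 1)     # 0.5
#' saturation(1e6, 1)   # ~1
#' @export
saturation <- function(x, lam) {
  if (!all(is.finite(lam)) || any(lam <= 0)) {
    stop("`lam` must be strictly positive and finite", call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop("`x` must be non-negative", call. = FALSE)
  }
  x / (lam + x)
}

#' Threshold gate for the healthy-to-catabolic switch
#'
#' The gate `H(s)` that permits conversion of healthy cells to the catabolic
#' state only while local EPO is below its critical level `P_c`: called with
#' `s = P - P_c`, it returns 1 when `s < 0` (EPO insufficient, switching
#' allowed) and 0 when `s >= 0` (EPO at or above critical, switching shut
#' off). Note the orientation is reversed relative to a conventional
#' Heaviside step.
#'
#' A smoothed variant is available as a numerical device for stiff
#' integration: with `sharpness > 0` the gate is the logistic
#' `1 / (1 + exp(sharpness * s))`, which tends to the discrete gate as
#' `sharpness` grows. The discrete form is the model's default.
#'
#' @param s Concentration difference `P - P_c` (vectorized, finite).
#' @param sharpness Non-negative scalar; 0 (default) selects the exact
#'   discrete gate, positive values select the logistic smoothing with that
#'   steepness (units: inverse concentration).
#' @return Numeric vector in `[0, 1]`; exactly 0/1 when `sharpness = 0`.
#' @examples
#' threshold_gate(-0.5)  # 1: below critical, switching allowed
#' threshold_gate(0)     # 0
#' threshold_gate(0.3)   # 0
#' @export
threshold_gate <- function(s, sharpness = 0) {
  if (sharpness < 0) stop("`sharpness` must be >= 0", call. = FALSE)
  if (sharpness == 0) {
    as.numeric(s < 0)
  } else {
    1 / (1 + exp(pmin(sharpness * s, 700)))
  }
}
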