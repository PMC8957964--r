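#' Piecewise BMI trait transformation
#'
#' Maps body mass index onto a transformed scale used as the regression
#' response when fitting the methylation predictor. Below the healthy-BMI
#' anchor the map is logarithmic, `log(bmi + 1) - log(healthy_bmi + 1)`;
#' above it the map is linear, `(bmi - healthy_bmi) / (healthy_bmi + 1)`.
#' The two branches meet at zero with a common derivative
#' `1 / (healthy_bmi + 1)`, so F is continuously differentiable and
#' strictly increasing. Logs are natural.
#'
#' The log branch compresses the underweight tail while the linear branch
#' keeps overweight/obese BMI on an interpretable linear scale; the anchor
#' (default 25 kg/m^2, the conventional upper limit of healthy BMI) maps
#' to exactly 0.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; must be positive.
#' @param healthy_bmi Anchor BMI in kg/m^2 (default 25).
#' @return Numeric vector on the transformed (unitless) scale.
#' @seealso [inv_f_bmi()] for the exact inverse.
#' @examples
#' f_bmi(25)            # 0 at the anchor
#' f_bmi(51)            # 1 on the linear branch
#' inv_f_bmi(f_bmi(32)) # round trip
#' @export
f_bmi <- function(bmi, healthy_bmi = 25) {
  stopifnot(is.numeric(bmi), is.numeric(healthy_bmi),
            length(healthy_bmi) == 1L, healthy_bmi > 0)
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("`bmi` must be finite and > 0", call. = FALSE)
  ifelse(bmi <= healthy_bmi,
         log(bmi + 1) - log(healthy_bmi + 1),
         (bmi - healthy_bmi) / (healthy_bmi + 1))
}

#' Inverse of the BMI trait transformation
#'
#' Exact inverse of [f_bmi()]: `exp(y + log(healthy_bmi + 1)) - 1` for
#' `y <= 0`, `healthy_bmi + y * (healthy_bmi + 1)` for `y > 0`. The image
#' of F is bounded below by `-log(healthy_bmi + 1)` (the limit as BMI
#' approaches 0), so values at or below that bound are rejected.
#'
#' @param y Numeric vector on the transformed scale.
#' @param healthy_bmi Anchor BMI in kg/m^2 (default 25).
#' @return Numeric vector of BMI values in kg/m^2.
#' @examples
#' inv_f_bmi(0)   # the anchor, 25
#' inv_f_bmi(1)   # 51
#' @export
inv_f_bmi <- function(y, healthy_bmi = 25) {
  stopifnot(is.numeric(y), is.numeric(healthy_bmi),
            length(healthy_bmi) == 1L, healthy_bmi > 0)
  lower <- -log(healthy_bmi + 1)
  if (any(!is.finite(y)) || any(y <= lower))
    stop(sprintf("`y` must be finite and > %.6f (image lower bound)", lower),
         call. = FALSE)
  # the linear branch is evaluated for y >= 0: both branches agree at 0
  # analytically, and the linear form returns the anchor exactly there
  ifelse(y < 0,
         exp(y + log(healthy_bmi + 1)) - 1,
         healthy_bmi + y * (healthy_bmi + 1))
}
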