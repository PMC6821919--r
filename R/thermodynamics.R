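#' @include quenching.R
NULL

.GAS_CONSTANT <- 8.314  # J/(mol K)

#' Gibbs free energy from a binding constant
#'
#' \eqn{\Delta G = -R T \ln K_a}, returned in kJ/mol with
#' R = 8.314 J/(mol K). Negative for \eqn{K_a > 1} (spontaneous binding in
#' molar standard state).
#'
#' @param Ka binding constant, 1/M (> 0); vectors allowed.
#' @param temperatureK absolute temperature, K (> 0).
#' @return \eqn{\Delta G} in kJ/mol.
#' @examples
#' gibbsFromKa(2.24e4, 298)  # about -24.8 kJ/mol
#' @export
gibbsFromKa <- function(Ka, temperatureK) {
  if (any(Ka <= 0)) stop("Ka must be positive")
  if (any(temperatureK <= 0)) stop("temperature must be positive (Kelvin)")
  -.GAS_CONSTANT * temperatureK * log(Ka) / 1000
}

#' Van't Hoff thermodynamic decomposition
#'
#' Ordinary least squares of \eqn{\ln K_a} on \eqn{1/T}:
#' \deqn{\ln K_a = -\frac{\Delta H}{R T} + \frac{\Delta S}{R}}
#' so \eqn{\Delta H = -R \cdot slope} (kJ/mol) and \eqn{\Delta S = R \cdot
#' intercept} (J/(mol K)), with standard errors from the regression
#' covariance. Assumes a temperature-independent enthalpy over the fitted
#' range. \eqn{\Delta G} is tabulated at each input temperature both as
#' \eqn{\Delta H - T\Delta S} (regression form) and directly as
#' \eqn{-R T \ln K_a}; the two differ by the regression residual.
#'
#' @param temperatureK temperatures, K (at least 3).
#' @param Ka binding constants at those temperatures, 1/M.
#' @param KaSE optional standard errors of `Ka`; when supplied with
#'   `weighted = TRUE` the regression is weighted by
#'   \eqn{1/SE(\ln K_a)^2} and they are propagated into the direct
#'   \eqn{\Delta G} errors.
#' @param weighted use `1/SE^2` weights (default `FALSE`: the plain
#'   unweighted Van't Hoff regression).
#' @return a [ThermoResult-class].
#' @examples
#' vantHoffFit(c(288, 298, 308), c(1.72e4, 2.24e4, 2.54e4))
#' @export
vantHoffFit <- function(temperatureK, Ka, KaSE = NULL, weighted = FALSE) {
  if (length(temperatureK) != length(Ka))
    stop("temperatureK and Ka must have equal length")
  if (length(temperatureK) < 3L)
    stop("Van't Hoff regression requires at least 3 temperatures")
  if (any(Ka <= 0)) stop("Ka must be positive")
  if (any(temperatureK <= 0)) stop("temperatures must be positive (Kelvin)")
  o <- order(temperatureK)
  temperatureK <- temperatureK[o]; Ka <- Ka[o]
  if (!is.null(KaSE)) KaSE <- KaSE[o]
  x <- 1 / temperatureK
  y <- log(Ka)
  w <- if (weighted) {
    if (is.null(KaSE)) stop("weighted fit requires KaSE")
    1 / (KaSE / Ka)^2
  } else NULL
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  deltaH <- -.GAS_CONSTANT * unname(cf[2L]) / 1000        # kJ/mol
  deltaS <- .GAS_CONSTANT * unname(cf[1L])                # J/(mol K)
  dGdirect <- gibbsFromKa(Ka, temperatureK)
  dGdirectSE <- if (!is.null(KaSE))
    .GAS_CONSTANT * temperatureK * (KaSE / Ka) / 1000
  else rep(NA_real_, length(Ka))
  new("ThermoResult",
      temperatures = temperatureK,
      deltaH = deltaH, deltaHSE = .GAS_CONSTANT * unname(se[2L]) / 1000,
      deltaS = deltaS, deltaSSE = .GAS_CONSTANT * unname(se[1L]),
      deltaG = deltaH - temperatureK * deltaS / 1000,
      deltaGdirect = dGdirect, deltaGdirectSE = dGdirectSE,
      TdeltaS = temperatureK * deltaS / 1000,
      r2 = suppressWarnings(summary(fit))$r.squared,
      gasConstant = .GAS_CONSTANT)
}
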