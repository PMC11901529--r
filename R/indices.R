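#' Crop nitrogen uptake from tissue concentration and dry matter
#'
#' N uptake (kg N ha-1) = N% x dry matter (kg ha-1) / 100.
#'
#' @param n_pct Tissue nitrogen concentration in percent of dry matter.
#' @param dry_matter Dry matter mass in kg ha-1.
#' @return Nitrogen mass in kg N ha-1.
#' @export
n_uptake_eq1 <- function(n_pct, dry_matter) {
  stopifnot(all(n_pct >= 0), all(n_pct <= 100), all(dry_matter >= 0))
  n_pct * dry_matter / 100
}

#' Agronomic efficiency of applied nitrogen
#'
#' AE_N = (Y_N - Y_0) / F_N: extra grain dry matter per kg of fertilizer N,
#' relative to the unfertilized control.  May be negative if the fertilized
#' yield falls below the control.
#'
#' @param y_n Grain yield under the applied N rate (kg DM ha-1).
#' @param y_0 Grain yield without N application (kg DM ha-1).
#' @param f_n Applied N (kg N ha-1), must be positive.
#' @return kg DM per kg N.
#' @export
ae_n <- function(y_n, y_0, f_n) {
  if (any(f_n <= 0)) stop("ae_n: applied N rate must be positive")
  (y_n - y_0) / f_n
}

#' Partial factor productivity of applied nitrogen
#'
#' The standard Dobermann quotient PFP_N = Y_N / F_N (kg grain DM per kg
#' applied N).  A difference form `y_n - f_n` is available behind
#' `as_difference = TRUE` for comparison, but the quotient is the definition
#' used throughout this package.
#'
#' @param y_n Grain yield under the applied N rate (kg DM ha-1).
#' @param f_n Applied N (kg N ha-1), must be positive.
#' @param as_difference Use the (non-standard) difference form.
#' @return kg DM per kg N (quotient form).
#' @export
pfp_n <- function(y_n, f_n, as_difference = FALSE) {
  if (any(f_n <= 0)) stop("pfp_n: applied N rate must be positive")
  if (as_difference) y_n - f_n else y_n / f_n
}

#' Recovery efficiency of applied nitrogen
#'
#' RE_N = (U_N - U_0) / F_N: fraction of applied N recovered in grain at
#' maturity, relative to the unfertilized control.  Not clamped to \[0, 1\].
#'
#' @param u_n Grain N uptake at maturity with fertilization (kg N ha-1).
#' @param u_0 Grain N uptake at maturity without fertilization (kg N ha-1).
#' @param f_n Applied N (kg N ha-1), must be positive.
#' @return Dimensionless fraction.
#' @export
re_n <- function(u_n, u_0, f_n) {
  if (any(f_n <= 0)) stop("re_n: applied N rate must be positive")
  (u_n - u_0) / f_n
}

#' Water use efficiency
#'
#' WUE = grain yield / water used, in kg ha-1 mm-1.
#'
#' @param grain_yield Grain yield (kg DM ha-1).
#' @param water_used Water used to produce the yield (mm), must be positive.
#' @return kg ha-1 mm-1.
#' @export
wue <- function(grain_yield, water_used) {
  if (any(water_used <= 0)) stop("wue: water used must be positive")
  grain_yield / water_used
}

#' Willmott index of agreement
#'
#' d = 1 - sum((Y - X)^2) / sum((|Y - M0| + |X - M0|)^2) with Y simulated,
#' X measured and M0 the measured mean.  Bounded in \[0, 1\]; 1 is a perfect
#' match, 0 is no agreement (the measured-mean predictor scores 0).  For the
#' degenerate zero-denominator case (constant measured series matched
#' exactly) d is defined as 1; with nonzero residuals it is 0.
#'
#' @param simulated,measured Paired numeric vectors, length >= 2.
#' @return Index of agreement in \[0, 1\].
#' @export
willmott_d <- function(simulated, measured) {
  check_fit_series(simulated, measured)
  m0 <- mean(measured)
  num <- sum((simulated - measured)^2)
  den <- sum((abs(simulated - m0) + abs(measured - m0))^2)
  if (den == 0) return(if (num == 0) 1 else 0)
  1 - num / den
}

#' Root mean squared error of a simulated-vs-measured series
#' @inheritParams willmott_d
#' @return RMSE in the units of the variable.
#' @export
rmse <- function(simulated, measured) {
  check_fit_series(simulated, measured)
  sqrt(mean((simulated - measured)^2))
}

#' Systematic bias of a simulated-vs-measured series
#'
#' BIAS = mean(measured - simulated): positive values indicate model
#' under-prediction, negative values over-prediction.
#'
#' @inheritParams willmott_d
#' @return Bias in the units of the variable.
#' @export
bias <- function(simulated, measured) {
  check_fit_series(simulated, measured)
  mean(measured - simulated)
}

check_fit_series <- function(simulated, measured) {
  if (length(simulated) != length(measured))
    stop("fit series: simulated and measured must be paired")
  if (length(measured) < 2)
    stop("fit series: need at least 2 pairs")
  if (anyNA(simulated) || anyNA(measured))
    stop("fit series: NA values not allowed")
  invisible(TRUE)
}

#' Fit statistics table for one variable
#'
#' Convenience wrapper returning d, RMSE and BIAS in one row, the format used
#' for per-depth soil water content and per-organ biomass evaluation.
#'
#' @inheritParams willmott_d
#' @param variable Optional label.
#' @return One-row data.frame with columns `variable,n,d,rmse,bias`.
#' @export
fit_stats <- function(simulated, measured, variable = NA_character_) {
  data.frame(
    variable = variable,
    n = length(measured),
    d = willmott_d(simulated, measured),
    rmse = rmse(simulated, measured),
    bias = bias(simulated, measured),
    stringsAsFactors = FALSE
  )
}

#' Yield loss relative to the potential yield
#'
#' @param y_pot Potential (stress-free) yield, must be positive.
#' @param y_limited Yield under the limitation considered, same units.
#' @return List with `absolute` (same units as inputs) and `relative`
#'   (percent of potential).
#' @export
yield_loss <- function(y_pot, y_limited) {
  if (any(y_pot <= 0)) stop("yield_loss: potential yield must be positive")
  absolute <- y_pot - y_limited
  list(absolute = absolute, relative = 100 * absolute / y_pot)
}
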