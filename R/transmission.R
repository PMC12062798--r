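# Actuator-to-lung mechanical transmission: supply pressure -> assistive
# force (linear, per-subject calibrated) and assistive force -> effective
# lung pressure (lumped thoraco-abdominal coefficient delta).

#' Force-pressure transmission model
#'
#' Per-subject linear actuator characteristic \eqn{F_a = \alpha_t P_{sup} + \mu}
#' over the rated supply range 0-20 kPa, plus the lumped force-to-lung-pressure
#' coefficient \eqn{P_{exo} = \delta F_a}. `delta` carries an explicit unit
#' tag: the parameter-table convention is kPa/N, but the airway-side safety
#' arithmetic is in cmH2O, so the tag decides the conversion applied at
#' module boundaries (1 kPa = 10.1972 cmH2O).
#'
#' @param alpha_t force gain, N/kPa (> 0).
#' @param mu force offset, N (>= 0). An offset force, although the
#'   parameter table prints its unit as N/kPa; the linear law demands N.
#' @param delta force-to-lung-pressure coefficient (> 0), in the unit named
#'   by `delta_unit`.
#' @param delta_unit `"cmH2O/N"` (default) or `"kPa/N"`.
#' @return an object of class `transmission_model`.
#' @examples
#' transmission_model(alpha_t = 8.09, mu = 67.41, delta = 0.03)
#' @export
transmission_model <- function(alpha_t, mu, delta,
                               delta_unit = c("cmH2O/N", "kPa/N")) {
  delta_unit <- match.arg(delta_unit)
  check_num(alpha_t, "alpha_t", lo = 0, strict_lo = TRUE)
  check_num(mu, "mu", lo = 0)
  check_num(delta, "delta", lo = 0, strict_lo = TRUE)
  new_transmission_model(alpha_t, mu, delta, delta_unit)
}

# internal constructor without range validation (used by calibration, where
# a degenerate fit may produce a zero slope)
new_transmission_model <- function(alpha_t, mu, delta = NA_real_,
                                   delta_unit = "cmH2O/N") {
  structure(list(alpha_t = alpha_t, mu = mu, delta = delta,
                 delta_unit = delta_unit),
            class = "transmission_model")
}

#' @export
print.transmission_model <- function(x, ...) {
  cat(sprintf("Transmission model: Fa = %.4g * Psup + %.4g  [N, Psup in kPa]\n",
              x$alpha_t, x$mu))
  if (is.finite(x$delta))
    cat(sprintf("  Pexo = %.4g * Fa  [%s]\n", x$delta, x$delta_unit))
  invisible(x)
}

# delta expressed in cmH2O/N regardless of the stored tag
delta_cmh2o <- function(tm) {
  if (tm$delta_unit == "cmH2O/N") tm$delta else kpa_to_cmh2o(tm$delta)
}

#' Assistive force from supply pressure
#'
#' Evaluates the linear actuator characteristic. The supply pressure must be
#' inside the rated 0-20 kPa range; callers clamp before invoking.
#'
#' @param tm a [transmission_model()].
#' @param Psup supply pressure, kPa, in [0, 20]; vectorised.
#' @return assistive force, N.
#' @export
force_from_pressure <- function(tm, Psup) {
  if (any(!is.finite(Psup)) || any(Psup < 0) || any(Psup > 20))
    stop("Psup outside the rated range [0, 20] kPa", call. = FALSE)
  tm$alpha_t * Psup + tm$mu
}

#' Thoraco-abdominal cascade constants
#'
#' The stage-wise transmission chain: contact force to abdominal pressure
#' over an equivalent area A, abdominal pressure to abdominal volume change
#' through diaphragmatic compliance Cab, volume change to thoracic pressure
#' through thoracic elasticity kth over initial volume V0, and finally
#' tissue transmission efficiency eta.
#'
#' @param A_contact equivalent pressure-transmission contact area.
#' @param Cab diaphragmatic compliance coefficient.
#' @param kth thoracic elastic coefficient.
#' @param V0 initial thoracic volume.
#' @param eta tissue transmission efficiency, in (0, 1].
#' @return an object of class `cascade_constants`.
#' @export
cascade_constants <- function(A_contact, Cab, kth, V0, eta) {
  check_num(A_contact, "A_contact", lo = 0, strict_lo = TRUE)
  check_num(Cab, "Cab", lo = 0, strict_lo = TRUE)
  check_num(kth, "kth", lo = 0, strict_lo = TRUE)
  check_num(V0, "V0", lo = 0, strict_lo = TRUE)
  check_num(eta, "eta", lo = 0, hi = 1, strict_lo = TRUE)
  structure(list(A_contact = A_contact, Cab = Cab, kth = kth, V0 = V0,
                 eta = eta),
            class = "cascade_constants")
}

#' Lumped transmission coefficient from the cascade
#'
#' Eliminating the intermediate abdominal/thoracic variables collapses the
#' four-stage chain to \eqn{\delta = k_{th} C_{ab} \eta / (A V_0)}. The
#' cascade's negative sign (thoracic pressure falls as abdominal volume
#' rises) is absorbed into the expiration-positive convention, so delta is
#' stored positive.
#'
#' @param c a [cascade_constants()] object.
#' @return the scalar transmission coefficient delta (unit: pressure per N,
#'   consistent with the units of the inputs).
#' @export
compose_delta <- function(c) {
  stopifnot(inherits(c, "cascade_constants"))
  den <- c$A_contact * c$V0
  if (den == 0) stop("zero denominator in delta composition", call. = FALSE)
  c$kth * c$Cab * c$eta / den
}

#' Lung pressure from assistive force
#'
#' @param tm a [transmission_model()].
#' @param Fa assistive force, N (>= 0); vectorised.
#' @return effective lung pressure delta * Fa, in the unit tagged on `tm`.
#' @export
pexo_from_force <- function(tm, Fa) {
  if (any(!is.finite(Fa)) || any(Fa < 0))
    stop("Fa must be non-negative", call. = FALSE)
  tm$delta * Fa
}

#' Calibrate the force-pressure characteristic
#'
#' Ordinary least-squares fit of the linear actuator law to observed
#' (supply pressure, force) pairs, the per-subject calibration performed
#' with a standardized 60-s wear test. Reports the coefficient of
#' determination and Pearson correlation alongside the fitted model; on
#' noiseless linear input the generating coefficients are recovered to
#' machine precision.
#'
#' @param pairs two-column data frame or matrix: supply pressure (kPa) and
#'   force (N). Column names are ignored; order matters.
#' @param delta optional transmission coefficient to attach to the fitted
#'   model (with `delta_unit`).
#' @param delta_unit unit tag for `delta`.
#' @return object of class `transmission_calibration` with fields `model`,
#'   `r_squared`, `pearson_r`, `n`, `degenerate` and the underlying `lm` fit.
#' @examples
#' psup <- seq(0, 20, length.out = 21)
#' cal <- calibrate_transmission(cbind(psup, 8.09 * psup + 67.41))
#' coef(cal)
#' @export
calibrate_transmission <- function(pairs, delta = NA_real_,
                                   delta_unit = "cmH2O/N") {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("'pairs' needs two columns (Psup, Fa)",
                             call. = FALSE)
  psup <- as.numeric(pairs[[1L]]); fa <- as.numeric(pairs[[2L]])
  n <- length(psup)
  if (n < 3L) stop("need at least 3 calibration pairs", call. = FALSE)
  if (stats::sd(psup) == 0)
    stop("singular fit: all supply pressures identical", call. = FALSE)
  fit <- stats::lm(fa ~ psup)
  co <- stats::coef(fit)
  degenerate <- stats::sd(fa) == 0
  r2 <- if (degenerate) 1 else suppressWarnings(summary(fit)$r.squared)
  pr <- if (degenerate) NA_real_ else stats::cor(psup, fa)
  structure(list(model = new_transmission_model(unname(co[2L]),
                                                unname(co[1L]),
                                                delta, delta_unit),
                 r_squared = r2, pearson_r = pr, n = n,
                 degenerate = degenerate, fit = fit),
            class = "transmission_calibration")
}

#' @export
coef.transmission_calibration <- function(object, ...) {
  c(alpha_t = object$model$alpha_t, mu = object$model$mu)
}

#' @export
print.transmission_calibration <- function(x, ...) {
  cat(sprintf("Force-pressure calibration (n = %d): Fa = %.4g * Psup + %.4g\n",
              x$n, x$model$alpha_t, x$model$mu))
  cat(sprintf("  R^2 = %.4g, Pearson r = %.4g%s\n", x$r_squared, x$pearson_r,
              if (x$degenerate) "  [degenerate: flat response]" else ""))
  invisible(x)
}

#' @export
plot.transmission_calibration <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$psup, d$fa, xlab = "Supply pressure (kPa)",
                 ylab = "Assistive force (N)", ...)
  graphics::abline(x$model$mu, x$model$alpha_t, col = 2)
  invisible(x)
}
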