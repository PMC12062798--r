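#' Single-compartment lung parameters
#'
#' Constructs the parameter set of the first-order resistance-elastance
#' respiratory plant \eqn{R\,dV/dt + E\,V = P_{mus} + P_{exo}}, the tidal
#' (expiration-positive) reduction of the absolute-volume pressure balance.
#' The residual volume and PEEP terms cancel in the reduced form under the
#' substitution \eqn{E\,V_{lung0} + P_{PEEP} = 0}; they are retained in the
#' object for completeness but never enter the simulated dynamics.
#'
#' @param R airway resistance, cmH2O.s/L; must be > 0.
#' @param E lung elastance, cmH2O/L; must be > 0.
#' @param Vlung0 residual lung volume, L (default 0).
#' @param PPEEP positive end-expiratory pressure, cmH2O. Defaults to
#'   `-E * Vlung0` so the reduced-form substitution holds exactly.
#' @return an object of class `lung_params`.
#' @examples
#' lung_params(R = 2.7, E = 4.8)
#' @export
lung_params <- function(R, E, Vlung0 = 0, PPEEP = -E * Vlung0) {
  check_num(R, "R", lo = 0, strict_lo = TRUE)
  check_num(E, "E", lo = 0, strict_lo = TRUE)
  check_num(Vlung0, "Vlung0", lo = 0)
  check_num(PPEEP, "PPEEP")
  if (abs(E * Vlung0 + PPEEP) > 1e-9 * max(1, E * Vlung0))
    stop("E * Vlung0 + PPEEP must equal 0 for the reduced tidal form",
         call. = FALSE)
  structure(list(R = R, E = E, Vlung0 = Vlung0, PPEEP = PPEEP),
            class = "lung_params")
}

#' @export
print.lung_params <- function(x, ...) {
  cat(sprintf("Lung parameters: R = %.3g cmH2O.s/L, E = %.3g cmH2O/L (tau = %.3g s)\n",
              x$R, x$E, x$R / x$E))
  invisible(x)
}

#' Metronome breathing pattern
#'
#' @param Q0 flow amplitude, L/s (> 0).
#' @param rate breathing rate, breaths/min, in [1, 80].
#' @param insp_fraction inspiratory share of the cycle, in (0, 1).
#' @return an object of class `breath_pattern`.
#' @export
breath_pattern <- function(Q0 = 0.5, rate = 20, insp_fraction = 0.5) {
  check_num(Q0, "Q0", lo = 0, strict_lo = TRUE)
  check_num(rate, "rate", lo = 1, hi = 80)
  check_num(insp_fraction, "insp_fraction", lo = 0, hi = 1,
            strict_lo = TRUE, strict_hi = TRUE)
  structure(list(Q0 = Q0, rate = rate, insp_fraction = insp_fraction),
            class = "breath_pattern")
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta > 1))
    stop("'theta' must lie in [0, 1]", call. = FALSE)
  theta
}

#' Expiratory flow waveform
#'
#' Natural expiratory flow follows a near-trigonometric arc over the
#' normalised expiratory phase: \eqn{Q(\theta) = Q_0 \sin(\pi\theta)}.
#'
#' @param theta expiratory phase in [0, 1] (0 = onset, 1 = completion);
#'   vectorised.
#' @param Q0 flow amplitude, L/s (> 0).
#' @return flow in L/s, in [0, Q0].
#' @examples
#' flow_waveform(0.25, Q0 = 1)  # sin(pi/4)
#' @export
flow_waveform <- function(theta, Q0) {
  check_theta(theta)
  check_num(Q0, "Q0", lo = 0, strict_lo = TRUE)
  Q0 * sin(pi * theta)
}

#' Normalised expiratory volume
#'
#' Integral of the flow waveform over the dimensionless phase,
#' \eqn{V(\theta) = -\frac{Q_0}{\pi}\cos(\pi\theta)}, with the integration
#' constant chosen as zero (odd-symmetric about mid-expiration). Note this is
#' an integral over \eqn{\theta}, not time: to obtain litres multiply by the
#' expiratory duration (see [muscle_pressure_profile_physical()] for the
#' physical-time analogue).
#'
#' @inheritParams flow_waveform
#' @return normalised volume (L per unit phase).
#' @export
normalized_volume <- function(theta, Q0) {
  check_theta(theta)
  check_num(Q0, "Q0", lo = 0, strict_lo = TRUE)
  -(Q0 / pi) * cos(pi * theta)
}

#' Resistive and elastic pressure components
#'
#' The muscle pressure needed to drive the flow waveform splits into a
#' resistive drop \eqn{P_R = R\,Q(\theta)} and an elastic (alveolar recoil)
#' component \eqn{P_E = E\,V(\theta)}.
#'
#' @inheritParams flow_waveform
#' @param lung a [lung_params()] object.
#' @return list with components `P_R` and `P_E` (cmH2O).
#' @export
pressure_components <- function(theta, Q0, lung) {
  stopifnot(inherits(lung, "lung_params"))
  list(P_R = lung$R * flow_waveform(theta, Q0),
       P_E = lung$E * normalized_volume(theta, Q0))
}

#' Muscle-pressure waveform amplitude and phase
#'
#' Summing the resistive and elastic components collapses to a single
#' sinusoid \eqn{P_{mus}(\theta) = A \sin(\pi\theta + \varphi)} with
#' amplitude \eqn{A = Q_0\sqrt{R^2 + (E/\pi)^2}} and phase lead
#' \eqn{\varphi = \arctan(-E/(\pi R))}. The negative phase expresses that
#' pressure build-up precedes flow.
#'
#' @param Q0 flow amplitude, L/s.
#' @param lung a [lung_params()] object.
#' @param allow_zero_resistance if `TRUE`, R = 0 is accepted as the limiting
#'   case phi = -pi/2; otherwise R = 0 is an error (default).
#' @return object of class `muscle_pressure_profile` with fields `A_mus`
#'   (cmH2O) and `phi` (radians, in (-pi/2, 0]).
#' @examples
#' muscle_pressure_profile(1, lung_params(2.7, 4.8))
#' @export
muscle_pressure_profile <- function(Q0, lung, allow_zero_resistance = FALSE) {
  stopifnot(inherits(lung, "lung_params") || is.list(lung))
  check_num(Q0, "Q0", lo = 0)
  R <- lung$R; E <- lung$E
  if (R <= 0 && !allow_zero_resistance)
    stop("R must be > 0 (set allow_zero_resistance = TRUE for the limit)",
         call. = FALSE)
  A <- Q0 * sqrt(R^2 + (E / pi)^2)
  phi <- if (R <= 0) -pi / 2 else atan(-E / (pi * R))
  structure(list(A_mus = A, phi = phi, Q0 = Q0, R = R, E = E),
            class = "muscle_pressure_profile")
}

#' @export
print.muscle_pressure_profile <- function(x, ...) {
  cat(sprintf("Muscle pressure profile: A = %.4g cmH2O, phi = %.4g rad\n",
              x$A_mus, x$phi))
  invisible(x)
}

#' Evaluate a muscle-pressure profile at given phases
#'
#' @param profile a `muscle_pressure_profile`.
#' @param theta expiratory phase in [0, 1]; vectorised.
#' @return pressure in cmH2O.
#' @export
muscle_pressure <- function(profile, theta) {
  check_theta(theta)
  profile$A_mus * sin(pi * theta + profile$phi)
}

#' Physical-time muscle-pressure waveform
#'
#' The phase-domain amplitude above integrates flow over the dimensionless
#' phase, so its elastic term carries \eqn{E/\pi}. Driving the plant in
#' physical time at angular breathing frequency \eqn{\omega = 2\pi f} (f in
#' Hz) requires the elastic term \eqn{E/\omega}:
#' \eqn{A = Q_0\sqrt{R^2 + (E/\omega)^2}},
#' \eqn{\varphi = \arctan(-E/(\omega R))}. A subject driven by this waveform
#' produces a true Q0-amplitude sinusoidal flow at the given rate in steady
#' state. This is the waveform the virtual subject uses.
#'
#' @inheritParams muscle_pressure_profile
#' @param rate breathing rate, breaths/min.
#' @return a `muscle_pressure_profile` whose amplitude and phase are
#'   rate-dependent.
#' @export
muscle_pressure_profile_physical <- function(Q0, lung, rate) {
  stopifnot(inherits(lung, "lung_params"))
  check_num(Q0, "Q0", lo = 0)
  check_num(rate, "rate", lo = 1, hi = 80)
  omega <- 2 * pi * rate / 60
  A <- Q0 * sqrt(lung$R^2 + (lung$E / omega)^2)
  phi <- atan(-lung$E / (omega * lung$R))
  structure(list(A_mus = A, phi = phi, Q0 = Q0, R = lung$R, E = lung$E,
                 omega = omega),
            class = "muscle_pressure_profile")
}

#' Simulate the first-order lung plant
#'
#' Integrates \eqn{R\,dv/dt + E\,v = P_{mus}(t) + P_{exo}(t)} for the tidal
#' excursion v (expiration-positive) from v(0) = 0 with a fixed-step
#' classical 4th-order Runge-Kutta scheme; the forcing is linearly
#' interpolated at half-steps. For constant forcing P0 the solution matches
#' the closed form \eqn{v(t) = (P_0/E)(1 - e^{-Et/R})}.
#'
#' @param lung a [lung_params()] object.
#' @param Pmus muscle pressure series, cmH2O.
#' @param Pexo robot-applied lung pressure series, cmH2O; same length.
#' @param dt uniform sampling step, s.
#' @param t optional time stamps; if supplied they must be uniformly spaced
#'   at `dt` (non-uniform sampling is an error).
#' @return list with `volume` (L) and `flow` (L/s) series, flow being
#'   \eqn{dv/dt} evaluated from the plant equation at the sample times.
#' @examples
#' l <- lung_params(2.7, 4.8)
#' out <- simulate_plant(l, Pmus = rep(4.8, 2000), Pexo = rep(0, 2000),
#'                       dt = 0.005)
#' tail(out$volume, 1)  # -> P0/E = 1 L
#' @export
simulate_plant <- function(lung, Pmus, Pexo, dt, t = NULL) {
  stopifnot(inherits(lung, "lung_params"))
  check_num(dt, "dt", lo = 0, strict_lo = TRUE)
  n <- length(Pmus)
  if (length(Pexo) != n)
    stop("Pmus and Pexo must be aligned series of equal length", call. = FALSE)
  if (!is.null(t)) {
    if (length(t) != n || any(abs(diff(t) - dt) > 1e-9 * dt))
      stop("non-uniform sampling: time stamps must be spaced at dt",
           call. = FALSE)
  }
  tau <- lung$R / lung$E
  if (dt > tau / 10)
    warning(sprintf("dt = %g s exceeds one tenth of the plant time constant (%g s)",
                    dt, tau), call. = FALSE)
  P <- Pmus + Pexo
  R <- lung$R; E <- lung$E
  v <- numeric(n)
  f <- function(P_t, v_t) (P_t - E * v_t) / R
  for (i in seq_len(n - 1L)) {
    P0 <- P[i]; P1 <- P[i + 1L]; Pm <- 0.5 * (P0 + P1)
    k1 <- f(P0, v[i])
    k2 <- f(Pm, v[i] + 0.5 * dt * k1)
    k3 <- f(Pm, v[i] + 0.5 * dt * k2)
    k4 <- f(P1, v[i] + dt * k3)
    v[i + 1L] <- v[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(volume = v, flow = (P - E * v) / R)
}
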