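# Proportional-valve pneumatics: orifice statics, current-to-flow law, the
# lumped static pressure map and a first-order chamber with dead time that
# realises the measured actuation lag.

#' Pneumatic plant parameters
#'
#' @param Pin source pressure, kPa (constant).
#' @param k1 current-to-flow conversion coefficient of the proportional
#'   valve.
#' @param Cf valve flow coefficient.
#' @param Cv flow coefficient of the feedforward term; the same physical
#'   valve, aliased to `Cf` by default.
#' @param A_orifice orifice area (consistent units with `rho` and the
#'   pressure fed to [orifice_flow()]).
#' @param rho gas density.
#' @param tau_fill chamber filling time constant, s (default 0.030, chosen
#'   so closed-loop settling is commensurate with sub-50 ms tracking).
#' @param delay actuation dead time, s (default 0.200, the measured lag of
#'   the elasticity adjustment mechanism).
#' @return an object of class `pneumatic_params`.
#' @export
pneumatic_params <- function(Pin = 20, k1 = 1, Cf = 1, Cv = Cf,
                             A_orifice = 1e-4, rho = 1.2,
                             tau_fill = 0.030, delay = 0.200) {
  check_num(Pin, "Pin", lo = 0, strict_lo = TRUE)
  check_num(k1, "k1", lo = 0, strict_lo = TRUE)
  check_num(Cf, "Cf", lo = 0, strict_lo = TRUE)
  check_num(Cv, "Cv", lo = 0, strict_lo = TRUE)
  check_num(A_orifice, "A_orifice", lo = 0, strict_lo = TRUE)
  check_num(rho, "rho", lo = 0, strict_lo = TRUE)
  check_num(tau_fill, "tau_fill", lo = 0, strict_lo = TRUE)
  check_num(delay, "delay", lo = 0)
  structure(list(Pin = Pin, k1 = k1, Cf = Cf, Cv = Cv,
                 A_orifice = A_orifice, rho = rho,
                 tau_fill = tau_fill, delay = delay),
            class = "pneumatic_params")
}

#' Orifice flow (Bernoulli law)
#'
#' \eqn{Q_{sup} = C_f A \sqrt{2\Delta P/\rho}} in consistent units (e.g.
#' dP in Pa, rho in kg/m3, A in m2 gives m3/s). Reverse flow is not
#' modelled: a negative pressure difference is an error.
#'
#' @param p a [pneumatic_params()].
#' @param dP pressure difference across the orifice (>= 0); vectorised.
#' @return supply flow.
#' @export
orifice_flow <- function(p, dP) {
  if (any(!is.finite(dP)) || any(dP < 0))
    stop("dP must be non-negative (no reverse flow modelled)", call. = FALSE)
  p$Cf * p$A_orifice * sqrt(2 * dP / p$rho)
}

#' Valve flow from control current
#'
#' @param p a [pneumatic_params()].
#' @param I control current (>= 0); vectorised.
#' @return supply flow `k1 * I`.
#' @export
valve_flow <- function(p, I) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("control current must be non-negative", call. = FALSE)
  p$k1 * I
}

#' Static supply pressure for a given current
#'
#' The lumped valve statics \eqn{P_{sup} = P_{in} - (I/(k_1 C_f))^2},
#' floored at 0. The expression is dimensionally lumped; unit
#' reconciliation is confined to [pneumatic_params()] construction.
#'
#' @param p a [pneumatic_params()].
#' @param I control current (>= 0); vectorised.
#' @return supply pressure, kPa, in [0, Pin].
#' @export
static_pressure <- function(p, I) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("control current must be non-negative", call. = FALSE)
  pmax(0, p$Pin - (I / (p$k1 * p$Cf))^2)
}

#' Initialise pneumatic dynamic state
#'
#' @param p a [pneumatic_params()].
#' @param dt simulation step, s.
#' @param Psup0 initial chamber pressure, kPa.
#' @param I0 current assumed to have been applied throughout the dead-time
#'   window before t = 0; defaults to the equilibrium current holding
#'   `Psup0`, so a state starts at rest and a current step has no effect
#'   until the dead time elapses.
#' @return an object of class `pneumatic_state` holding the chamber pressure
#'   and the dead-time buffer of pending current commands.
#' @export
pneumatic_state <- function(p, dt, Psup0 = 0,
                            I0 = p$k1 * p$Cf * sqrt(max(0, p$Pin - Psup0))) {
  nd <- max(0L, as.integer(round(p$delay / dt)))
  structure(list(Psup = Psup0, Ibuf = rep(I0, nd), dt = dt),
            class = "pneumatic_state")
}

#' One step of chamber pressure dynamics
#'
#' The valve model itself is static; the chamber is realised as a
#' first-order lag toward the static pressure of the current delayed by the
#' dead time: exact exponential update with time constant `tau_fill`,
#' bounded in [0, Pin].
#'
#' @param p a [pneumatic_params()].
#' @param state a [pneumatic_state()].
#' @param I control current applied this step (>= 0).
#' @param dt simulation step, s (must equal the state's step).
#' @return the updated `pneumatic_state`; the new pressure is in `$Psup`.
#' @export
step_dynamics <- function(p, state, I, dt) {
  stopifnot(inherits(state, "pneumatic_state"), dt > 0)
  if (abs(dt - state$dt) > 1e-12)
    stop("dt must match the state's step", call. = FALSE)
  if (length(state$Ibuf) > 0L) {
    I_eff <- state$Ibuf[1L]
    state$Ibuf <- c(state$Ibuf[-1L], I)
  } else {
    I_eff <- I
  }
  target <- static_pressure(p, I_eff)
  a <- exp(-dt / p$tau_fill)
  state$Psup <- clamp(target + (state$Psup - target) * a, 0, p$Pin)
  state
}
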