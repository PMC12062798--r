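# Dual-layer assistive controller: high-level expiration-synchronised
# pressure profile with airway-pressure safety clipping; low-level
# interaction-force feedback planning, force-to-supply-pressure mapping and
# a PD + nonlinear feedforward current law for the proportional valve.

#' Controller configuration
#'
#' Gains and safety ceilings of the dual-layer controller. Bounds follow the
#' published adjustment ranges of the human-robot interaction control
#' system; violating them is a hard configuration error. The proportional
#' gain must exceed 1 strictly and the derivative gain must be positive -
#' the Lyapunov stability condition of the tracking loop.
#'
#' @param assist_gain dimensionless assistance gain in [0, 1] scaling the
#'   reference pressure profile.
#' @param B damping planning gain, in [0.1, 10].
#' @param K stiffness planning gain, in [0.1, 5].
#' @param kP proportional tracking gain, in (1, 10].
#' @param kD derivative tracking gain, in (0, 1].
#' @param Fmax assistive force ceiling, N (<= 400).
#' @param Psup_max supply pressure ceiling, kPa (<= 20).
#' @param Pairway_max total airway pressure ceiling, cmH2O (default 30, the
#'   ATS-guided safety threshold).
#' @param hysteresis_frac phase-flip hysteresis as a fraction of the flow
#'   amplitude (default 0.02; prevents chatter at zero crossings).
#' @param vex_weight exponential weight for the predicted expired volume
#'   update (1 = pure previous breath, the default).
#' @param exact_inverse if `TRUE` the force-to-pressure map inverts the full
#'   affine actuator law; default `FALSE` uses the gain-only literal form.
#' @return an object of class `controller_config`.
#' @examples
#' controller_config(assist_gain = 0.8, kP = 2.6, kD = 0.5)
#' @export
controller_config <- function(assist_gain = 0.5, B = 0.25, K = 0.5,
                              kP = 2.6, kD = 0.5,
                              Fmax = 400, Psup_max = 20, Pairway_max = 30,
                              hysteresis_frac = 0.02, vex_weight = 1,
                              exact_inverse = FALSE) {
  check_num(assist_gain, "assist_gain", lo = 0, hi = 1)
  check_num(B, "B", lo = 0.1, hi = 10)
  check_num(K, "K", lo = 0.1, hi = 5)
  check_num(kP, "kP", lo = 1, hi = 10, strict_lo = TRUE)
  check_num(kD, "kD", lo = 0, hi = 1, strict_lo = TRUE)
  check_num(Fmax, "Fmax", lo = 0, hi = 400, strict_lo = TRUE)
  check_num(Psup_max, "Psup_max", lo = 0, hi = 20, strict_lo = TRUE)
  check_num(Pairway_max, "Pairway_max", lo = 0, strict_lo = TRUE)
  check_num(hysteresis_frac, "hysteresis_frac", lo = 0, hi = 0.5)
  check_num(vex_weight, "vex_weight", lo = 0, hi = 1, strict_lo = TRUE)
  structure(list(assist_gain = assist_gain, B = B, K = K, kP = kP, kD = kD,
                 Fmax = Fmax, Psup_max = Psup_max, Pairway_max = Pairway_max,
                 hysteresis_frac = hysteresis_frac, vex_weight = vex_weight,
                 exact_inverse = isTRUE(exact_inverse)),
            class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(
    "Controller: assist_gain = %.2g, B = %.2g, K = %.2g, kP = %.2g, kD = %.2g\n",
    x$assist_gain, x$B, x$K, x$kP, x$kD))
  cat(sprintf("  ceilings: %g N, %g kPa, %g cmH2O\n",
              x$Fmax, x$Psup_max, x$Pairway_max))
  invisible(x)
}

#' Initial expiratory-phase estimator state
#'
#' @return an object of class `phase_state`: current phase label, continuous
#'   expiratory phase theta, cumulative expired volume of the running breath,
#'   predicted total expired volume (NA until one breath completes), warm-up
#'   flag and completed-breath counter.
#' @export
phase_state <- function() {
  structure(list(phase_label = "inspiration", theta = 0, vex_cum = 0,
                 vex_pred = NA_real_, warmup = TRUE, breaths = 0L),
            class = "phase_state")
}

#' One step of expiratory-phase estimation from flow
#'
#' Binary phase segmentation by hysteresis on the flow sign (expiratory flow
#' positive), then a continuous expiratory phase as the ratio of expired
#' volume so far to the total predicted from the previous breath:
#' theta = Vex(k) / Vex(k-1), clamped to [0, 1]. During the very first
#' expiration no prediction exists yet: theta is pinned at 0 and the state
#' carries a warm-up flag. On breath completion the prediction is updated by
#' an exponentially weighted rule (weight 1 = pure previous breath).
#'
#' @param flow_sample measured flow, L/s (expiration positive).
#' @param state a `phase_state`.
#' @param dt time since the previous sample, s.
#' @param hysteresis flow threshold for phase flips, L/s.
#' @param vex_weight weight of the just-completed breath in the prediction
#'   update.
#' @param min_vex_frac completed expirations smaller than this fraction of
#'   the current prediction are flow flutter at a phase boundary, not
#'   breaths, and do not update the prediction (default 0.1).
#' @return the updated `phase_state`.
#' @export
estimate_phase <- function(flow_sample, state, dt, hysteresis,
                           vex_weight = 1, min_vex_frac = 0.1) {
  stopifnot(inherits(state, "phase_state"), dt > 0, hysteresis >= 0)
  if (state$phase_label == "expiration") {
    if (flow_sample < -hysteresis) {
      # expiration complete: update prediction, flip to inspiration
      if (state$vex_cum > 0 &&
          (is.na(state$vex_pred) ||
           state$vex_cum >= min_vex_frac * state$vex_pred)) {
        state$vex_pred <- if (is.na(state$vex_pred)) state$vex_cum else
          (1 - vex_weight) * state$vex_pred + vex_weight * state$vex_cum
        state$warmup <- FALSE
        state$breaths <- state$breaths + 1L
      }
      state$phase_label <- "inspiration"
      state$theta <- 0
      state$vex_cum <- 0
    } else {
      state$vex_cum <- state$vex_cum + max(flow_sample, 0) * dt
      state$theta <- if (is.na(state$vex_pred)) 0 else
        min(1, state$vex_cum / state$vex_pred)
    }
  } else {
    if (flow_sample > hysteresis) {
      state$phase_label <- "expiration"
      state$theta <- 0
      state$vex_cum <- max(flow_sample, 0) * dt
    }
  }
  state
}

#' High-level reference assistive pressure profile
#'
#' The reference robot-applied lung pressure is the muscle-pressure waveform
#' scaled by the assistance gain,
#' \eqn{P_{exo}^{ref}(\theta) = \alpha A \sin(\pi\theta + \varphi)}, floored
#' at zero (no suction) and clipped so that the predicted total airway
#' pressure \eqn{P_{mus}(\theta) + P_{exo}^{ref}(\theta)} never exceeds the
#' configured ceiling (30 cmH2O by default).
#'
#' @param theta expiratory phase in [0, 1]; vectorised.
#' @param profile a [muscle_pressure_profile()] (the controller's internal
#'   model of the subject).
#' @param cfg a [controller_config()].
#' @return reference pressure, cmH2O.
#' @export
desired_pressure_profile <- function(theta, profile, cfg) {
  check_theta(theta)
  pmus <- profile$A_mus * sin(pi * theta + profile$phi)
  p <- pmax(0, cfg$assist_gain * pmus)
  pmin(p, pmax(0, cfg$Pairway_max - pmus))
}

#' Reference assistive force from reference pressure
#'
#' Inverts the lumped transmission law, \eqn{F_a^{ref} = P_{exo}^{ref}/\delta},
#' then clamps to [0, Fmax]. The transmission coefficient is reconciled to
#' cmH2O/N from its tagged unit before dividing.
#'
#' @param P_exo_ref reference lung pressure, cmH2O; vectorised.
#' @param tm a [transmission_model()].
#' @param cfg a [controller_config()].
#' @return reference force, N.
#' @export
desired_force <- function(P_exo_ref, tm, cfg) {
  d <- delta_cmh2o(tm)
  if (!is.finite(d) || d <= 0) stop("delta must be > 0", call. = FALSE)
  clamp(P_exo_ref / d, 0, cfg$Fmax)
}

#' Low-level dynamic force planning from interaction-force feedback
#'
#' \eqn{F_{plan} = F_a^{ref} - B\,dF_{int}/d\theta - K\,F_{int}}, clamped to
#' [0, Fmax]. The damping term suppresses rapid interaction-force changes;
#' the stiffness term maintains compliance.
#'
#' @param F_a_ref reference force, N.
#' @param F_int measured interaction force, N.
#' @param dFint_dtheta smoothed derivative of the interaction force with
#'   respect to the expiratory phase (computed by the caller).
#' @param cfg a [controller_config()].
#' @return planned force, N.
#' @export
plan_force <- function(F_a_ref, F_int, dFint_dtheta, cfg) {
  stopifnot(all(is.finite(c(F_a_ref, F_int, dFint_dtheta))))
  clamp(F_a_ref - cfg$B * dFint_dtheta - cfg$K * F_int, 0, cfg$Fmax)
}

#' Supply-pressure reference from planned force
#'
#' Default (literal) form divides by the actuator gain only,
#' \eqn{P_{sup}^{ref} = F_{plan}/\alpha_t}; the exact inverse of the affine
#' actuator law, \eqn{(F_{plan} - \mu)/\alpha_t} floored at 0, is available
#' for physical consistency. Both are clamped to [0, Psup_max].
#'
#' @param F_plan planned force, N.
#' @param tm a [transmission_model()].
#' @param cfg a [controller_config()].
#' @param exact_inverse override of `cfg$exact_inverse`.
#' @return supply-pressure reference, kPa.
#' @export
supply_pressure_ref <- function(F_plan, tm, cfg,
                                exact_inverse = cfg$exact_inverse) {
  if (tm$alpha_t <= 0) stop("alpha_t must be > 0", call. = FALSE)
  p <- if (isTRUE(exact_inverse)) pmax(0, (F_plan - tm$mu) / tm$alpha_t)
       else F_plan / tm$alpha_t
  clamp(p, 0, cfg$Psup_max)
}

#' PD + nonlinear feedforward valve current
#'
#' Tracking law for the proportional valve:
#' \eqn{I = k_1 C_v \sqrt{P_{in} - k_P e - k_D \dot e}} with
#' \eqn{e = P_{sup}^{ref} - P_{sup}}. The square root compensates the
#' orifice flow-pressure nonlinearity. A negative radicand is floored at 0
#' (fully-open valve) and flagged as saturation, not raised as an error.
#'
#' @param P_sup_ref,P_sup reference and measured supply pressure, kPa.
#' @param dref_dtheta,dmeas_dtheta their phase derivatives.
#' @param cfg a [controller_config()].
#' @param k1 valve current-to-flow coefficient.
#' @param Cv valve flow coefficient.
#' @param Pin source pressure, kPa.
#' @return list with `I` (control current) and logical `saturated`.
#' @export
control_current <- function(P_sup_ref, P_sup, dref_dtheta, dmeas_dtheta,
                            cfg, k1, Cv, Pin) {
  e <- P_sup_ref - P_sup
  edot <- dref_dtheta - dmeas_dtheta
  rad <- Pin - cfg$kP * e - cfg$kD * edot
  sat <- rad < 0
  list(I = k1 * Cv * sqrt(max(rad, 0)), saturated = sat)
}

#' Stability check of the pressure-tracking loop
#'
#' The quadratic Lyapunov function \eqn{V = \tfrac12 x_1^2 + \tfrac12 x_2^2}
#' of the tracking-error states (pressure error and its rate) has
#' \eqn{\dot V = (1-k_P)x_1^2 - k_D x_2^2}, non-positive iff kP > 1 and
#' kD > 0. Besides the algebraic condition, the check integrates the error
#' dynamics \eqn{\dot x_1 = (1-k_P)x_1}, \eqn{\dot x_2 = -k_D x_2} from a
#' given initial state and verifies V is non-increasing step by step.
#'
#' @param cfg a [controller_config()], or a list with `kP`, `kD` (which may
#'   lie outside the config bounds, e.g. to probe rejected gain pairs).
#' @param x0 initial error state for the numerical check (length 2).
#' @param t_end,dt horizon and step of the numerical integration, s.
#' @return list with `stable` (logical), `margin` = min(kP - 1, kD), and
#'   `lyapunov_nonincreasing` from the simulated trajectory.
#' @examples
#' check_stability(list(kP = 2.6, kD = 0.5))$stable
#' @export
check_stability <- function(cfg, x0 = c(1, 1), t_end = 5, dt = 1e-3) {
  kP <- cfg$kP; kD <- cfg$kD
  stable <- kP > 1 && kD > 0
  margin <- min(kP - 1, kD)
  n <- ceiling(t_end / dt)
  x1 <- x0[1]; x2 <- x0[2]
  # exact exponential propagation of the decoupled linear error dynamics
  a1 <- exp((1 - kP) * dt); a2 <- exp(-kD * dt)
  V <- numeric(n + 1L)
  V[1L] <- 0.5 * (x1^2 + x2^2)
  for (i in seq_len(n)) {
    x1 <- x1 * a1; x2 <- x2 * a2
    V[i + 1L] <- 0.5 * (x1^2 + x2^2)
  }
  list(stable = stable, margin = margin,
       lyapunov_nonincreasing = all(diff(V) <= 1e-9))
}
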