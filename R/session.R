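# Closed-loop session runner: couples virtual subject, dual-layer
# controller, pneumatic plant, transmission and lung plant on a sampled
# grid, reproducing the crossover protocol (natural vs assisted sessions at
# metronome rates).

#' Session specification
#'
#' @param mode `"natural"` (no robot: Pexo and Fa identically zero) or
#'   `"assisted"`.
#' @param rate metronome breathing rate, breaths/min (protocol rates are
#'   12, 20, 30, 40; any value in [1, 80] is accepted).
#' @param duration session length, s (protocol sessions last 180 s).
#' @param fs sampling frequency, Hz (default 200).
#' @param seed integer seed for every random stream of the session.
#' @param ctrl_div controller decimation: the controller updates every
#'   `ctrl_div`-th sample (default 2, i.e. 100 Hz on the 200 Hz grid) and
#'   its outputs are zero-order-held in between.
#' @param loop_delay sensor-read communication latency, s (default 0.005).
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(mode = c("natural", "assisted"), rate = 20,
                         duration = 180, fs = 200, seed = 1L,
                         ctrl_div = 2L, loop_delay = 0.005) {
  mode <- match.arg(mode)
  check_num(rate, "rate", lo = 1, hi = 80)
  check_num(duration, "duration", lo = 0, strict_lo = TRUE)
  check_num(fs, "fs", lo = 0, strict_lo = TRUE)
  check_num(loop_delay, "loop_delay", lo = 0)
  structure(list(mode = mode, rate = rate, duration = duration, fs = fs,
                 seed = as.integer(seed), ctrl_div = as.integer(ctrl_div),
                 loop_delay = loop_delay),
            class = "session_spec")
}

#' Run one closed-loop breathing session
#'
#' Simulates a virtual subject breathing at the metronome rate, with or
#' without robotic assistance. The loop order per sample follows the
#' control architecture: flow sensing (with communication latency) ->
#' expiratory-phase estimation -> reference pressure profile (expiration
#' only, safety-clipped) -> interaction-force feedback planning -> supply
#' pressure reference -> valve current -> pneumatic chamber (fast
#' first-order fill) -> actuator force (lagged by the mechanical actuation
#' dead time) -> transmitted lung pressure -> lung plant update. The
#' pressure-tracking loop itself is fast (sub-50 ms settling); the 200 ms
#' actuation lag sits in the pressure-to-force transmission, which is where
#' the compliance-adjustment lag is observed. The controller runs at
#' `fs/ctrl_div` Hz with
#' zero-order hold; the plant updates every sample with a trapezoidal
#' (Crank-Nicolson) scheme, which makes the recorded flow and volume
#' satisfy both the plant equation and the trapezoidal volume-flow
#' consistency exactly at the sample times.
#'
#' The subject's muscle drive is the physical-time sinusoidal waveform
#' scaled per breath by amplitude jitter (coefficient of variation
#' `subject$pmus_jitter_cv`); effort is the same in natural and assisted
#' modes (constant-effort assumption). The actuator contact force follows
#' the calibrated affine law while the chamber is pressurised; its offset
#' component ramps in over the first 1 kPa of inflation (belt engagement),
#' so a fully deflated chamber exerts no force. The delivered force is
#' hard-limited at the force ceiling.
#'
#' @param subject a [virtual_subject()].
#' @param cfg a [controller_config()].
#' @param spec a [session_spec()].
#' @param pneu a [pneumatic_params()].
#' @param noise if `FALSE`, sensor noise, breath jitter and
#'   interaction-force modulation are switched off (deterministic run).
#' @return a `session_trace`: a data frame sampled at `fs` with columns
#'   `t, phase_label, theta, Q, V, Pmus, Pexo, Pexo_ref, Fa, Fint, Fplan,
#'   Psup, Psup_ref, I`, plus attributes recording the spec and subject id.
#'   Identical spec + seed give bitwise-identical traces.
#' @examples
#' s <- subject_from_table("S1")
#' tr <- run_session(s, controller_config(), session_spec("assisted",
#'   rate = 20, duration = 10), noise = FALSE)
#' max(tr$Pmus + tr$Pexo)
#' @export
run_session <- function(subject, cfg = controller_config(),
                        spec = session_spec(), pneu = pneumatic_params(),
                        noise = TRUE) {
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(cfg, "controller_config"),
            inherits(spec, "session_spec"),
            inherits(pneu, "pneumatic_params"))
  if (!noise) subject <- quiet_subject(subject)
  assisted <- spec$mode == "assisted"
  fs <- spec$fs; dt <- 1 / fs
  n <- round(spec$duration * fs)
  tt <- (seq_len(n) - 1L) * dt
  Tb <- 60 / spec$rate
  lung <- subject$lung; tm <- subject$tm
  R <- lung$R; E <- lung$E
  dC <- delta_cmh2o(tm)

  # deterministic random streams: draw all noise up front in fixed order so
  # natural/assisted runs with the same seed share the same physiology
  set.seed(spec$seed)
  nb <- ceiling(spec$duration / Tb) + 2L
  jit <- pmax(0.5, 1 + subject$pmus_jitter_cv * stats::rnorm(nb))
  flow_noise <- if (subject$flow_noise_sd > 0)
    stats::rnorm(n, 0, subject$flow_noise_sd) else numeric(n)
  fint_noise <- if (subject$fint_noise_sd > 0)
    stats::rnorm(n, 0, subject$fint_noise_sd) else numeric(n)

  # physical-time muscle drive producing Q0-amplitude sinusoidal flow
  prof_phys <- muscle_pressure_profile_physical(subject$breath$Q0, lung,
                                                spec$rate)
  breath_ix <- pmin(nb, floor(tt / Tb) + 1L)
  Pmus <- jit[breath_ix] * prof_phys$A_mus *
    sin(prof_phys$omega * tt + prof_phys$phi)

  # controller's internal (phase-domain) model of the subject
  prof <- muscle_pressure_profile(subject$breath$Q0, lung)
  hyst <- cfg$hysteresis_frac * subject$breath$Q0
  dt_ctrl <- spec$ctrl_div * dt
  ds <- max(0L, as.integer(round(spec$loop_delay * fs)))

  # state; the 200 ms actuation lag is mechanical (belt/tissue), so the
  # chamber itself runs without dead time (pressure tracking is fast) and
  # the delay applies on the supply-pressure-to-force transmission below
  st <- phase_state()
  pneu_fast <- pneu; pneu_fast$delay <- 0
  pstate <- pneumatic_state(pneu_fast, dt)
  nd_act <- max(0L, as.integer(round(pneu$delay * fs)))
  v <- 0
  # derivative conditioning: the interaction force is low-pass filtered
  # (tau 0.2 s) before phase-differencing, and all phase derivatives are
  # windowed first-order differences over the last 5 controller ticks;
  # raw per-tick differencing of the ratio-based theta is unusably noisy
  tau_f <- 0.2
  a_f <- exp(-dt_ctrl / tau_f)
  nw <- 6L  # window: current + 5 past ticks
  ring_th <- numeric(nw); ring_fint <- numeric(nw); ring_ref <- numeric(nw)
  ring_meas <- numeric(nw); ri <- 0L; nfill <- 0L
  fint_f <- 0
  I_cmd <- 0; pexo_ref_c <- 0; faref_c <- 0; fplan_c <- 0; psref_c <- 0

  Q <- numeric(n); V <- numeric(n); Pexo <- numeric(n); Fa <- numeric(n)
  Fint <- numeric(n); Fplan <- numeric(n); Psup <- numeric(n)
  Psup_ref <- numeric(n); Pexo_ref <- numeric(n); Icur <- numeric(n)
  theta_v <- numeric(n); phase_v <- character(n)

  half <- dt / (2 * R); den <- 1 + dt * E / (2 * R)

  for (i in seq_len(n)) {
    # 1. sensor read with communication latency
    qmeas <- if (i > ds) Q[i - ds] + flow_noise[i] else 0

    # 2. controller tick (zero-order hold otherwise)
    if ((i - 1L) %% spec$ctrl_div == 0L) {
      st <- estimate_phase(qmeas, st, dt_ctrl, hyst, cfg$vex_weight)
      th <- st$theta
      in_exp <- st$phase_label == "expiration" && !st$warmup
      pexo_ref_c <- if (assisted && in_exp)
        desired_pressure_profile(th, prof, cfg) else 0
      if (assisted) {
        faref_c <- desired_force(pexo_ref_c, tm, cfg)
        fa_prev <- if (i > 1L) Fa[i - 1L] else 0
        fint_m <- max(0, fa_prev *
                        (1 + subject$fint_modulation * sin(pi * th)) +
                        fint_noise[i])
        fint_f <- a_f * fint_f + (1 - a_f) * fint_m
        psup_m <- psup_prev_meas(i, ds, Psup)
        # windowed phase derivatives over the last nw-1 ticks
        ri <- ri %% nw + 1L
        ring_th[ri] <- th; ring_fint[ri] <- fint_f
        ring_meas[ri] <- psup_m
        nfill <- min(nfill + 1L, nw)
        old <- if (nfill < nw) 1L else ri %% nw + 1L
        dth_w <- th - ring_th[old]
        dfint <- if (dth_w > 1e-3) (fint_f - ring_fint[old]) / dth_w else 0
        fplan_c <- plan_force(faref_c, fint_m, dfint, cfg)
        psref_c <- supply_pressure_ref(fplan_c, tm, cfg)
        ring_ref[ri] <- psref_c
        dref <- if (dth_w > 1e-3) (psref_c - ring_ref[old]) / dth_w else 0
        dmeas <- if (dth_w > 1e-3) (psup_m - ring_meas[old]) / dth_w else 0
        cc <- control_current(psref_c, psup_m, dref, dmeas, cfg,
                              pneu$k1, pneu$Cv, pneu$Pin)
        I_cmd <- cc$I
        Fint[i] <- fint_m
      }
    } else if (assisted) {
      Fint[i] <- Fint[i - 1L]
    }

    # 3. pneumatic plant and transmission
    if (assisted) {
      pstate <- step_dynamics(pneu_fast, pstate, I_cmd, dt)
      ps <- pstate$Psup
      # actuation lag: force follows the chamber pressure nd_act samples ago
      ps_act <- if (i > nd_act) Psup[i - nd_act] else 0
      if (nd_act == 0L) ps_act <- ps
      # belt engagement: the calibrated offset force builds up over the
      # first kPa of inflation; a fully deflated chamber exerts no force
      eng <- min(1, ps_act)
      fa <- min(tm$alpha_t * ps_act + tm$mu * eng, cfg$Fmax)
      px <- dC * fa
    } else {
      ps <- 0; fa <- 0; px <- 0
    }

    # 4. lung plant: trapezoidal update of R dv/dt + E v = Pmus + Pexo
    P_i <- Pmus[i] + px
    if (i == 1L) {
      v <- 0
    } else {
      v <- (v + dt / 2 * Q[i - 1L] + half * P_i) / den
    }
    Q[i] <- (P_i - E * v) / R
    V[i] <- v
    Pexo[i] <- px; Fa[i] <- fa; Psup[i] <- ps
    Psup_ref[i] <- psref_c; Pexo_ref[i] <- pexo_ref_c; Fplan[i] <- fplan_c
    Icur[i] <- I_cmd
    theta_v[i] <- st$theta; phase_v[i] <- st$phase_label
  }

  trace <- data.frame(t = tt, phase_label = phase_v, theta = theta_v,
                      Q = Q, V = V, Pmus = Pmus, Pexo = Pexo,
                      Pexo_ref = Pexo_ref, Fa = Fa, Fint = Fint,
                      Fplan = Fplan, Psup = Psup, Psup_ref = Psup_ref,
                      I = Icur, stringsAsFactors = FALSE)
  attr(trace, "fs") <- fs
  attr(trace, "spec") <- spec
  attr(trace, "subject_id") <- subject$id
  class(trace) <- c("session_trace", "data.frame")
  trace
}

# delayed supply-pressure sensor read
psup_prev_meas <- function(i, ds, Psup) {
  j <- i - max(1L, ds)
  if (j >= 1L) Psup[j] else 0
}

#' @export
print.session_trace <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("Session trace: %s, %g breaths/min, %.4g s at %g Hz (%d samples)\n",
              sp$mode, sp$rate, sp$duration, attr(x, "fs"), nrow(x)))
  cat(sprintf("  subject %s; PEF %.3g L/s; max(Pmus+Pexo) %.3g cmH2O; max Fa %.3g N\n",
              attr(x, "subject_id"), max(x$Q), max(x$Pmus + x$Pexo),
              max(x$Fa)))
  invisible(x)
}

#' @export
plot.session_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$Q, type = "l", xlab = "", ylab = "Flow (L/s)", ...)
  graphics::plot(x$t, x$Pmus, type = "l", xlab = "", col = 4,
                 ylim = range(c(x$Pmus, x$Pexo)), ylab = "Pressure (cmH2O)")
  graphics::lines(x$t, x$Pexo, col = 2)
  graphics::legend("topright", c("Pmus", "Pexo"), col = c(4, 2), lty = 1,
                   bty = "n")
  graphics::plot(x$t, x$Fa, type = "l", col = 2, xlab = "Time (s)",
                 ylab = "Force (N)")
  invisible(x)
}

#' Safety-envelope check of a session trace
#'
#' Verifies the three hard limits over the whole trace: total airway
#' pressure (muscle + robot) at most `Pairway_max`, supply pressure at most
#' `Psup_max`, assistive force at most `Fmax`.
#'
#' @param trace a `session_trace`.
#' @param cfg a [controller_config()] providing the ceilings.
#' @return a data frame of violations (zero rows when the trace is safe)
#'   with columns `quantity`, `limit`, `observed_max`.
#' @export
check_safety <- function(trace, cfg = controller_config()) {
  obs <- c(airway_pressure = max(trace$Pmus + trace$Pexo),
           supply_pressure = max(trace$Psup),
           assistive_force = max(trace$Fa))
  lim <- c(cfg$Pairway_max, cfg$Psup_max, cfg$Fmax)
  bad <- obs > lim
  data.frame(quantity = names(obs)[bad], limit = lim[bad],
             observed_max = unname(obs[bad]))
}

#' Run a crossover protocol for one subject
#'
#' For each rate and repetition, runs a matched pair of sessions (baseline
#' natural, then assisted) with the same derived seed, so the simulated
#' physiology (muscle drive, sensor noise streams) is identical within a
#' pair; different repetitions use rep-indexed seeds.
#'
#' @param subject a [virtual_subject()].
#' @param cfg a [controller_config()].
#' @param rates vector of breathing rates, breaths/min.
#' @param reps repetitions per rate (>= 1).
#' @param seed root seed; per-session seeds derive deterministically from it.
#' @param duration session length, s.
#' @param pneu a [pneumatic_params()].
#' @param noise passed to [run_session()].
#' @return an object of class `crossover_set`: a list of records with
#'   fields `rate`, `rep`, `baseline`, `assisted`.
#' @export
run_crossover <- function(subject, cfg = controller_config(),
                          rates = c(12, 20, 30, 40), reps = 3, seed = 1L,
                          duration = 60, pneu = pneumatic_params(),
                          noise = TRUE) {
  stopifnot(reps >= 1)
  out <- list()
  for (ri in seq_along(rates)) {
    for (rep in seq_len(reps)) {
      s <- derive_seed(seed, ri, rep)
      base <- run_session(subject, cfg,
                          session_spec("natural", rates[ri], duration,
                                       seed = s),
                          pneu, noise = noise)
      asst <- run_session(subject, cfg,
                          session_spec("assisted", rates[ri], duration,
                                       seed = s),
                          pneu, noise = noise)
      out[[length(out) + 1L]] <- list(rate = rates[ri], rep = rep,
                                      baseline = base, assisted = asst)
    }
  }
  structure(out, class = "crossover_set", subject_id = subject$id)
}

#' @export
print.crossover_set <- function(x, ...) {
  cat(sprintf("Crossover set for subject %s: %d matched session pairs\n",
              attr(x, "subject_id"), length(x)))
  invisible(x)
}
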