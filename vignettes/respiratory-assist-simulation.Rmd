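---
title: "Modelling robot-assisted expiration: plant, transmission, control and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling robot-assisted expiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(respsim)
```

## The problem

Patients with weakened respiratory muscles (for example intensive-care-unit
acquired weakness, ICU-AW) cannot generate sufficient expiratory pressure.
A wearable pneumatic belt that compresses the abdomen in phase with
expiration can supplement the muscles' work. Designing and testing the
control logic of such a device on people is slow and risky; `respsim`
reproduces the whole loop — physiology, mechanics, pneumatics and control —
as a deterministic desk-scale simulation, so the control architecture,
parameter identification and evaluation metrics can be exercised end to
end with virtual subjects.

## The models

### Lung plant

The respiratory system is reduced to a single-compartment first-order
model: airway resistance $R$ (cmH$_2$O·s/L) in series with lung elastance
$E$ (cmH$_2$O/L),

$$R\,\dot v + E\,v = P_{mus}(t) + P_{exo}(t),$$

where $v$ is the tidal excursion (expiration-positive, litres), $P_{mus}$
the pressure generated by the respiratory muscles and $P_{exo}$ the
effective lung pressure contributed by the robot. Residual volume and PEEP
cancel out of this reduced form and never enter the dynamics. The model
deliberately ignores airway branching, tissue viscoelasticity and gas
exchange; it is the standard clinical single-compartment description and
is what makes the identification below linear.

Natural expiratory flow is close to a half-sine over the expiratory phase
$\theta \in [0,1]$: $Q(\theta) = Q_0 \sin(\pi\theta)$. Substituting into
the plant gives the muscle-pressure waveform
$P_{mus}(\theta) = A\sin(\pi\theta + \varphi)$ with
$A = Q_0\sqrt{R^2 + (E/\pi)^2}$ and $\varphi = \arctan(-E/(\pi R))$: a
pressure lead, because pressure build-up precedes flow. Note the $E/\pi$
term comes from integrating over the *dimensionless* phase; the virtual
subject is instead driven in physical time with
$A_\omega = Q_0\sqrt{R^2+(E/\omega)^2}$, $\omega = 2\pi f$
(`muscle_pressure_profile_physical()`), so that its steady-state flow is a
true $Q_0$-amplitude sinusoid at the metronome rate $f$. The controller's
internal model keeps the phase-domain amplitude; the distinction only
scales the assistance and both are exposed.

### Force transmission

The actuator characteristic is affine in supply pressure,
$F_a = \alpha_t P_{sup} + \mu$ over the rated 0–20 kPa, calibrated per
subject (`calibrate_transmission()`, ordinary least squares). The
force-to-lung-pressure path through abdomen, diaphragm and thorax lumps
into a single coefficient, $P_{exo} = \delta F_a$, with
$\delta = k_{th} C_{ab} \eta / (A V_0)$ available stage-wise
(`compose_delta()`).

Two deliberate unit decisions:

* $\delta$ carries an explicit unit tag. The published adjustment range
  (0.1–0.5 kPa/N) applied at the 400 N force ceiling yields 400–2000
  cmH$_2$O — far past the 30 cmH$_2$O airway ceiling, so a loop using it
  saturates instantly. The virtual cohort therefore draws
  $\delta \sim U(0.005, 0.02)$ cmH$_2$O/N: peak $P_{exo}$ at rated force is
  2–8 cmH$_2$O, the scale of clinical pressure support and commensurate
  with the modest per-subject improvements expiratory assistance yields.
  The literal kPa/N range remains selectable for unit-fidelity tests.
* $\mu$ is an offset *force* in newtons (the affine law demands it), even
  though the parameter table prints its unit as N/kPa.

The calibrated offset also shapes the contact model in the closed loop:
the belt's offset force ramps in over the first 1 kPa of inflation and a
fully deflated chamber exerts no force. Without this, zero commanded
assistance would still push ~$\mu\delta$ cmH$_2$O into the lung, and an
assisted session with assistance gain 0 could never equal the natural
baseline.

### Pneumatics

The proportional valve obeys an orifice law; its supply flow is
proportional to control current, giving the lumped statics
$P_{sup} = P_{in} - (I/(k_1 C_f))^2$. The chamber fills as a first-order
lag (`tau_fill`, default 30 ms — chosen so closed-loop pressure settling
is commensurate with sub-50 ms tracking). The measured 200 ms actuation
lag is placed in the *mechanical* pressure-to-force transmission, not
inside the pressure-tracking feedback: a proportional gain $k_P > 1$
through a pure 200 ms loop delay is structurally unstable (it limit-cycles
between the pressure clamps), which would contradict the fast tracking the
architecture is designed for. The lag is observed where compliance
adjustments are observed to lag — between chamber pressure and delivered
force.

### Dual-layer controller

High level: the expiratory phase $\theta$ is estimated online from flow —
binary segmentation by a hysteresis on the flow sign (default 2% of
$Q_0$), then $\theta = V_{ex}(k)/V_{ex}(k-1)$, the expired volume so far
over the previous breath's total, clamped to $[0,1]$. The first breath is
a warm-up with $\theta$ pinned at 0 and no assistance. Completed
expirations smaller than 10% of the prediction do not update it: they are
flow flutter at phase boundaries (the lagged force decay produces ~mL
scale blips), not breaths. The reference assistance is the scaled muscle
waveform $P_{exo}^{ref} = \alpha A \sin(\pi\theta + \varphi)$, floored at
zero and clipped so the *predicted* $P_{mus} + P_{exo}^{ref}$ never
exceeds 30 cmH$_2$O (the ATS-guided ceiling). Assistance acts only during
expiration.

Low level: $F_a^{ref} = P_{exo}^{ref}/\delta$, then dynamic planning from
interaction-force feedback,
$F_{plan} = F_a^{ref} - B\,dF_{int}/d\theta - K F_{int}$, clamped to
$[0, F_{max}]$; mapping to the supply reference $P_{sup}^{ref} =
F_{plan}/\alpha_t$ (the affine law's exact inverse is available under
`exact_inverse`, the gain-only literal form is the default); and a PD law
with square-root feedforward for the valve current,
$I = k_1 C_v\sqrt{P_{in} - k_P e - k_D \dot e}$, radicand floored at zero
with a saturation flag.

Numerical conditioning of the $\theta$-derivatives matters: $\theta$
advances by $\sim 10^{-2}$ per controller tick, so raw per-tick
differencing amplifies any force-change into huge derivative estimates
and, through $B$, drives the planned force bang-bang between its clamps.
The session runner therefore low-pass filters the interaction force
(time constant 0.2 s) and computes all phase derivatives as causal
first-order differences over a 5-tick window. Defaults
(`assist_gain = 0.5`, `B = 0.25`, `K = 0.5`, `kP = 2.6`, `kD = 0.5`, all
within the published adjustment ranges) were chosen for loop stability
margin against the 200 ms mechanical lag.

Stability of the tracking loop: with error states $x_1 = e$ and
$x_2 = \dot e$, the quadratic Lyapunov function
$V = \tfrac12 x_1^2 + \tfrac12 x_2^2$ has
$\dot V = (1-k_P)x_1^2 - k_D x_2^2 \le 0$ iff $k_P > 1,\ k_D > 0$. The
printed derivation is ambiguous about the cross terms, so
`check_stability()` tests the stated conclusion numerically: it
propagates the decoupled error dynamics $\dot x_1 = (1-k_P)x_1$,
$\dot x_2 = -k_D x_2$ and asserts $V$ non-increasing step by step.

### Identification

$P_{mus}$ is not measurable. With metronome pacing, a natural session
(group B) and an assisted session (group A) share the same muscle drive at
matched phase, so subtracting the two plant balances cancels it:

$$R\,(Q_A - Q_B) + E\,(V_A - V_B) = \delta F_a.$$

Stacking samples gives $y = H\,(R, E)^\top$, solved by the normal
equations (`identify_RE()`; `identify_lung()` builds the design from a
trace pair). Breath boundaries are detected once, on the natural trace,
and both traces are resampled onto the same per-breath grid of 200 points
by linear interpolation — using one set of time points for both traces is
what preserves the muscle-pressure cancellation exactly. $V$ here is the
*continuous* tidal excursion recorded in the trace (flow integrated from
session start), not a per-breath reset integral: a per-breath reset would
introduce a different integration constant into each breath of each group
and break the identity above. Rows where both differences fall below 1%
of their maxima are dropped (they only inflate the conditioning); the
condition number is always reported and an ill-conditioned design is an
error, never a silent pseudo-inverse.

On noiseless paired simulations the identifier recovers the generating
$(R, E)$ to numerical precision — by construction: the session runner
integrates the plant with a trapezoidal (Crank–Nicolson) step whose
recorded flow satisfies the plant identity exactly at the sample times,
and whose volume increments equal the trapezoidal integral of flow
exactly. (The standalone `simulate_plant()` uses a classical fixed-step
RK4 with interpolated forcing; for this linear stiff-free plant either
scheme is far inside tolerance, and the RK4 version is validated against
the closed-form step response.)

### Metrics

`compute_metrics()` reports peak expiratory flow (PEF, the session
maximum of expiratory flow; a per-breath-mean variant is a flag), mean
tidal volume (MTV, per-breath end-expiratory minus end-inspiratory
volume), and minute ventilation (MV, expired volume normalised to one
minute). MV conventions vary; this package uses the expiration-side
definition and always reports the phase split MV$_e$/MV$_i$ alongside.
Breath segmentation is the offline analogue of the controller's
hysteresis state machine, with the same minimum-volume artifact rejection
(10% of the largest expired volume). Incomplete first/last breaths are
discarded. Improvement rates are plain percent changes
(assisted − baseline)/baseline, aggregated across subjects as the
arithmetic mean; the paired significance test is a two-sided paired
t-test (Wilcoxon as an option) with the conventional star coding.

## The virtual cohort

A virtual subject bundles the actuator line $(\alpha_t, \mu)$ — sampled
uniformly within the published adjustment ranges (gain 5–15 N/kPa, offset
50–110 N) or taken from the published eight-subject calibration table —
lung parameters $R \in [1.5, 5]$, $E \in [2, 10]$, a breathing pattern
($Q_0 \sim U(0.4, 0.7)$ L/s, a realistic adult range giving tidal volumes
of 0.2–1.1 L across 12–40 breaths/min), and a noise model: Gaussian flow
sensor noise (sd 0.01 L/s), Gaussian interaction-force noise (sd 2 N)
with a 5% breathing-phase modulation, and per-breath muscle-amplitude
jitter (CV 5%) for natural variability. The published per-subject offsets
reach 118.23 N, slightly outside the 50–110 N adjustment range, so the
subject invariant admits offsets up to 120 N while the sampler stays
within 50–110.

The calibration noise default (8 N force sd over a 0–20 kPa sweep)
reproduces the spread of the published per-subject Pearson correlations
(0.96–0.996) across the admissible gain range.

What the generator deliberately does not emulate: effort adaptation under
assistance (the virtual subject keeps a constant muscle drive in both
arms — real subjects may relax when assisted, which would shift the
improvement magnitudes), irregular breathing rhythms, airway
nonlinearity, and motion artifacts (an optional burst model is off by
default). Passing tests therefore demonstrate correctness of the loop,
the estimators and the metrics under the stated physiology — not the
magnitude of clinical effect sizes.

## A complete run

```{r crossover, eval = FALSE}
subject <- subject_from_table("S2")
pair <- list(
  baseline = run_session(subject, spec = session_spec("natural", 20, 60,
                                                      seed = 7)),
  assisted = run_session(subject, spec = session_spec("assisted", 20, 60,
                                                      seed = 7)))
improvement_rates(compute_metrics(pair$baseline),
                  compute_metrics(pair$assisted))
fit <- identify_lung(pair$assisted, pair$baseline, subject$tm)
summary(fit)
```

## Problem sizes and numerical choices

* Sampling 200 Hz; controller at 100 Hz with zero-order hold; sensor
  latency 5 ms (one sample).
* Sessions of 30–60 s (6–40 breaths) are used throughout the test suite
  and the acceptance script; the full 3-min protocol is the default of
  `session_spec()`.
* The directional-efficacy check runs the full eight-subject table cohort
  at all four protocol rates; the safety stress cohort samples 50
  subjects at maximum assistance gain and minimum planning attenuation
  (B = K = 0.1) across all four rates.
* Trapezoidal plant update in the loop (exact flow/volume consistency);
  RK4 in `simulate_plant()`; exact exponential updates for the pneumatic
  chamber and all first-order filters; tie-breaks: phase flips require
  crossing the hysteresis strictly, the airway clip takes the smaller of
  profile and remaining headroom, all clamps are closed intervals.
* Degenerate inputs are explicit errors (singular calibration, singular
  or ill-conditioned identification, traces without a complete breath) or
  flagged results (flat calibration, saturated valve current,
  zero-variance significance differences).

## Known limitations

The constant-effort assumption inflates assisted ventilation relative to
a crossover on real subjects; improvements here are directional, not
effect-size predictions. The single-compartment plant cannot represent
flow limitation or dynamic hyperinflation, so the safety ceiling on
$P_{mus}+P_{exo}$ is a conservative proxy for airway pressure. The
force-planning law is sensitive to its damping gain at the top of its
admissible range; the shipped defaults are stable against the 200 ms lag,
but the range itself is not a stability guarantee.
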