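# shared fixtures, all generated in code

# deterministic subject carrying the identified lung values
quiet_s1 <- function() quiet_subject(subject_from_table("S1"))

# matched natural/assisted session pair with shared physiology
run_pair <- function(subject, rate = 20, duration = 30, seed = 7,
                     cfg = controller_config(), noise = FALSE) {
  list(natural = run_session(subject, cfg,
                             session_spec("natural", rate, duration,
                                          seed = seed), noise = noise),
       assisted = run_session(subject, cfg,
                              session_spec("assisted", rate, duration,
                                           seed = seed), noise = noise))
}

# synthetic sinusoidal trace with analytic volume (no plant, no robot)
sine_trace <- function(Q0 = 0.5, rate = 12, duration = 60, fs = 200) {
  t <- seq(0, duration, by = 1 / fs)
  om <- 2 * pi * rate / 60
  data.frame(t = t, Q = Q0 * sin(om * t), V = Q0 / om * (1 - cos(om * t)))
}
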