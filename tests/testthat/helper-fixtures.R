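# shared fixtures for the test suite

# PRC with the measured-spheroid morphology (prolonging early segment,
# discontinuity at 0.7, hook, near-unit linear tail)
fixture_truth_prc <- function() example_empirical_prc()

# the linear-tail PRC and parameters used for synthetic patients
fixture_patient_prc <- function() prc_linear_tail(0.65, 0.5)

fixture_patient_params <- function(t_s = 0.78, t_e = 1.8, t_lag = 0.15) {
  parasystole_params(t_s = t_s, t_e = t_e,
                     theta = list(m = 2.5, c = -0.25, epsilon = 0.05),
                     t_lag = t_lag, prc = fixture_patient_prc())
}

# a small synthetic Holter for inference tests (kept short for speed)
fixture_holter <- function(seed = 11, duration = 1800, ...) {
  gen_holter_record(holter_spec(seed = seed, duration = duration, ...))
}

# strict-bigeminy beat record built by construction
fixture_bigeminy <- function(n = 20, t_s = 1, ci = 0.45) {
  tN <- (0:(n - 1)) * t_s
  tV <- tN + ci
  beat_record(c(tN, tV), rep(c("N", "V"), each = n))
}
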