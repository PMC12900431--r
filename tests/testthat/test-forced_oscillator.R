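test_that("the phase map advances by tau - g(phi) modulo 1", {
  g <- prc_pwlinear(0.7)
  expect_equal(step_phase(0.2, 0.4, g), 0.6)
  expect_equal(step_phase(0.8, 0.4, g), 0.4)
  expect_equal(step_phase(0.9, 1.74, g), 0.74)
  expect_error(step_phase(1.2, 0.4, g), "\\[0, 1\\)")
  # phases stay in [0,1) under iteration for random configurations
  set.seed(42)
  for (i in 1:50) {
    phi <- runif(1)
    tau <- runif(1, 0.05, 1.8)
    prc <- prc_pwlinear(runif(1, 0.2, 0.95))
    for (k in 1:20) {
      phi <- step_phase(phi, tau, prc)
      expect_true(phi >= 0 && phi < 1)
    }
  }
})

test_that("orbits classify the expected N:M rhythms", {
  g <- prc_pwlinear(0.7)
  o <- iterate_orbit(stimulus_config(0.4), g)
  expect_false(o$aperiodic)
  expect_equal(c(o$N, o$M), c(2L, 1L))
  expect_setequal(round(o$phases, 9), c(0.4, 0.8))

  o11 <- iterate_orbit(stimulus_config(0.75), g)
  expect_equal(c(o11$N, o11$M), c(1L, 1L))
  expect_equal(o11$phases, 0.75)
  # every tau in [phi_r, 1) locks 1:1 (closed form)
  for (tau in seq(0.7, 0.99, by = 0.04)) {
    o1 <- iterate_orbit(stimulus_config(tau), g)
    expect_equal(c(o1$N, o1$M), c(1L, 1L))
  }

  o43 <- iterate_orbit(stimulus_config(0.75), prc_pwlinear(0.8))
  expect_equal(c(o43$N, o43$M), c(4L, 3L))
  expect_setequal(round(o43$phases, 9), c(0, 0.25, 0.5, 0.75))

  # irrational rotation with no resetting never recurs
  oa <- iterate_orbit(stimulus_config(1 / sqrt(5)), prc_pwlinear(1))
  expect_true(oa$aperiodic)
})

test_that("bifurcation diagram records post-transient phases per tau", {
  g <- prc_pwlinear(0.7)
  bd <- bifurcation_diagram(c(0.75), g, n_keep = 20)
  expect_true(all(abs(bd$phase - 0.75) < 1e-9))
  bd2 <- bifurcation_diagram(c(0.4), g, n_keep = 20)
  expect_true(all(abs(bd2$phase - 0.4) < 1e-9 | abs(bd2$phase - 0.8) < 1e-9))
  expect_equal(nrow(bifurcation_diagram(numeric(0), g)), 0)
})

test_that("event rendering realizes the map in continuous time", {
  g <- prc_pwlinear(0.7)
  ev <- render_events(stimulus_config(0.4, T = 1, phi0 = 0.4), g, 4)
  # period-2 orbit: each stimulus landing at phase 0.8 triggers a beat
  expect_equal(ev$beat_times, seq(0.8, 4, by = 0.8))
  expect_true(all(ev$beat_kind == "triggered"))

  # no-reset identity: beats strictly every T regardless of stimuli
  ev1 <- render_events(stimulus_config(0.33, T = 1.2, phi0 = 0.1),
                       prc_pwlinear(1), 25)
  expect_equal(ev1$beat_times, seq(1.2, 25, by = 1.2), tolerance = 1e-9)
  expect_lt(abs(length(ev1$beat_times) - 25 / 1.2), 1)

  # tau = 1 fixed point: one spontaneous beat per stimulus interval
  ev2 <- render_events(stimulus_config(1, T = 1, phi0 = 0.2), g, 20)
  expect_true(all(ev2$beat_kind == "spontaneous"))
  expect_equal(diff(ev2$beat_times), rep(1, length(ev2$beat_times) - 1),
               tolerance = 1e-9)
})

test_that("stimulus-time phases in rendered events equal the map iterates", {
  set.seed(7)
  for (i in 1:40) {
    tau <- runif(1, 0.05, 1.8)
    prc <- prc_pwlinear(runif(1, 0.2, 0.95))
    cfg <- stimulus_config(tau, T = runif(1, 0.5, 2), phi0 = runif(1))
    ev <- render_events(cfg, prc, 30 * cfg$T)
    phi <- cfg$phi0
    it <- numeric(length(ev$stimulus_phases))
    for (k in seq_along(it)) {
      it[k] <- phi
      phi <- step_phase(phi, tau, prc)
    }
    expect_lt(max(abs(it - ev$stimulus_phases)), 1e-9)
  }
})

test_that("event intervals are tagged SS / S-AP / AP-S / AP-AP", {
  ci <- classify_event_intervals(list(stimulus_times = c(0, 1, 2),
                                      beat_times = c(0.1, 1.1)))
  expect_equal(ci$interval[ci$type == "SS"], c(1, 1))
  expect_equal(ci$interval[ci$type == "S-AP"], c(0.1, 0.1))
  expect_equal(ci$interval[ci$type == "AP-S"], c(0.9, 0.9))
  expect_equal(ci$interval[ci$type == "AP-AP"], 1.0)

  only_b <- classify_event_intervals(list(stimulus_times = numeric(0),
                                          beat_times = c(0, 1, 2.5)))
  expect_true(all(only_b$type == "AP-AP"))
  expect_equal(only_b$interval, c(1, 1.5))

  # a triggered beat coincident with its stimulus: stimulus ordered first,
  # so the second stimulus pairs with the simultaneous beat at interval 0
  tie <- classify_event_intervals(list(stimulus_times = c(0, 1),
                                       beat_times = 1))
  expect_equal(tie$interval[tie$type == "S-AP"], c(1, 0))
  expect_equal(nrow(classify_event_intervals(list(stimulus_times = 1,
                                                  beat_times = numeric(0)))),
               0)
})
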