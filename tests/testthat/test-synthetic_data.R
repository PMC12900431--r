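test_that("PRC sample generation is exact at zero noise and seeded", {
  truth <- fixture_truth_prc()
  s0 <- gen_prc_samples(truth, 60, noise_sd = 0, seed = 1)
  expect_equal(s0$ncl, eval_prc(truth, s0$phase))
  s1 <- gen_prc_samples(truth, 60, noise_sd = 0.056, seed = 2)
  s2 <- gen_prc_samples(truth, 60, noise_sd = 0.056, seed = 2)
  expect_identical(s1, s2)
  expect_false(identical(s1, gen_prc_samples(truth, 60, 0.056, seed = 3)))
})

test_that("sample scatter about the curve matches the requested noise", {
  truth <- fixture_truth_prc()
  rmse <- vapply(1:20, function(s) {
    sm <- gen_prc_samples(truth, 200, 0.056, seed = s)
    sqrt(mean((sm$ncl - eval_prc(truth, sm$phase))^2))
  }, numeric(1))
  # chi-square band for the sd estimate at n = 200
  expect_gte(mean(rmse >= 0.045 & rmse <= 0.068), 0.9)
})

test_that("paced records follow the protocol segments", {
  prc <- prc_pwlinear(0.7)
  proto <- pacing_protocol_spec(R = 0.75)
  rec <- gen_paced_record(prc, proto, T = 1.2, jitter_sd = 0, seed = 5)
  sg <- rec$segments
  expect_equal(sg$segment, c("spontaneous", "paced", "recovery"))
  # spontaneous segments contain no stimuli
  expect_true(all(rec$stimulus_times >= sg$start[2] - 1e-9 &
                    rec$stimulus_times <= sg$end[2] + 1e-9))
  # tau = 0.75 >= phi_r: 1:1 entrainment in the paced segment
  pb <- rec$beat_times[rec$beat_times > sg$start[2] + 2 &
                         rec$beat_times <= sg$end[2]]
  expect_equal(diff(pb), rep(0.75 * 1.2, length(pb) - 1), tolerance = 1e-9)
  # spontaneous-rate beats in the leading segment
  sb <- rec$beat_times[rec$beat_times <= sg$end[1]]
  expect_equal(diff(sb), rep(1.2, length(sb) - 1), tolerance = 1e-9)
  r2 <- gen_paced_record(prc, proto, T = 1.2, jitter_sd = 0.005, seed = 7)
  r3 <- gen_paced_record(prc, proto, T = 1.2, jitter_sd = 0.005, seed = 7)
  expect_identical(r2$beat_times, r3$beat_times)
})

test_that("Holter generation satisfies the record invariants", {
  rec <- fixture_holter(seed = 21, duration = 1200)
  expect_s3_class(rec, "beat_record")
  expect_true(all(diff(rec$time) > 0))
  expect_true(all(rec$expressed))           # blocked beats are dropped
  expect_true(all(rec$label %in% c("N", "V")))
  vb <- rec[rec$label == "V", ]
  expect_true(all(!is.na(vb$morph)))
  frac <- max(table(vb$morph)) / nrow(vb)
  expect_gt(frac, 0.8)                      # mix A:0.9/B:0.1, binomial
  expect_lt(frac, 0.97)
  # determinism and seed sensitivity
  r1 <- fixture_holter(seed = 22, duration = 600)
  r2 <- fixture_holter(seed = 22, duration = 600)
  expect_identical(r1$time, r2$time)
  expect_false(identical(r1$time, fixture_holter(seed = 23,
                                                 duration = 600)$time))
})

test_that("drift-free records return the base sinus period exactly", {
  rec <- gen_holter_record(holter_spec(seed = 8, duration = 900,
                                       drift_amplitude = 0, ar_sd = 0,
                                       jitter_sd = 0))
  est <- estimate_sinus_period(rec)
  expect_true(all(abs(est$t_s - 0.72) < 1e-9))
  # with drift, measured t_s stays inside the specified drift envelope
  rec2 <- fixture_holter(seed = 9, duration = 1800)
  est2 <- estimate_sinus_period(rec2)
  expect_true(all(est2$t_s > 0.72 - 0.12 - 0.1 &
                    est2$t_s < 0.72 + 0.12 + 0.1))
})
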