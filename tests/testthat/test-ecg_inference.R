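test_that("morphology and cycling screens classify records", {
  tN <- seq(0, 400, by = 0.8)
  tV <- seq(0.45, 400, by = 3.7)
  morph <- rep(NA_character_, length(tN) + length(tV))
  lab <- c(rep("N", length(tN)), rep("V", length(tV)))
  tt <- c(tN, tV)
  o <- order(tt)
  mk <- function(fracA) {
    m <- morph
    nv <- length(tV)
    m[lab == "V"] <- rep(c("A", "B"),
                         c(round(fracA * nv), nv - round(fracA * nv)))
    beat_record(tt[o], lab[o], TRUE, m[o])
  }
  s90 <- screen_record(mk(0.9))
  expect_equal(s90$dominant_morphology_fraction, 0.9, tolerance = 0.01)
  expect_true(s90$passes_morphology)
  s50 <- screen_record(mk(0.5))
  expect_equal(s50$dominant_morphology_fraction, 0.5, tolerance = 0.01)
  expect_false(s50$passes_morphology)
  # missing morphology: screen skipped with a warning, cycling still runs
  nom <- beat_record(tt[o], lab[o])
  expect_warning(sn <- screen_record(nom), "morphology")
  expect_true(is.na(sn$passes_morphology))

  # a drifting-t_s parasystole record has cycling coupling intervals
  rec <- fixture_holter()
  sr <- screen_record(rec)
  expect_gte(nrow(sr$cycling_segments), 1)
  expect_true(sr$passes_cycling)
})

test_that("per-window sinus period is the median NN interval", {
  r <- beat_record(cumsum(c(0, rep(0.8, 20))), rep("N", 21))
  est <- estimate_sinus_period(r)
  expect_equal(est$t_s, 0.8)
  r2 <- beat_record(cumsum(c(0, 0.8, 0.8, 1.2)), rep("N", 4))
  expect_equal(estimate_sinus_period(r2, min_nn = 3)$t_s, 0.8)
  # strict bigeminy has no NN pairs: window skipped
  expect_equal(nrow(estimate_sinus_period(fixture_bigeminy(30))), 0)
})

test_that("the tail slope is recovered from NIB=1 episodes", {
  # noiseless bigeminy regime with linear-tail PRC, S = 0.5
  p <- fixture_patient_params(t_s = 0.78)
  rec <- simulate_beats(p, 600)
  est <- estimate_slope_S(beat_record(rec$time[rec$expressed],
                                      rec$label[rec$expressed]))
  expect_lt(abs(est$S - 0.5), 1e-6)
  expect_gte(est$n, 3)

  # constant VV independent of VN: slope 0
  tN <- seq(0, 40, by = 2)
  tV <- tN[-length(tN)] + seq(0.4, 0.9, length.out = length(tN) - 1)
  r0 <- beat_record(c(tN, tV), rep(c("N", "V"), c(length(tN), length(tV))))
  # VV intervals are constant 2 s by construction while VN varies
  expect_lt(abs(estimate_slope_S(r0)$S), 1e-9)
  expect_error(estimate_slope_S(fixture_bigeminy(3)), "NIB=1")
})

test_that("the refractory function is recovered from the coupling envelope", {
  # couplings with a 5th-percentile envelope CI5(t_s) ~= 0.1 + 0.4 t_s
  set.seed(31)
  beats_t <- c(); beats_l <- c()
  t0 <- 0
  for (ts in c(0.65, 0.75, 0.85, 0.95)) {
    n_sin <- 320
    tN <- t0 + cumsum(rep(ts, n_sin))
    env <- 0.1 + 0.4 * ts
    keepN <- rep(TRUE, n_sin)
    tV <- c()
    for (k in seq(2, n_sin - 2, by = 3)) {
      ci <- env + 0.25 * runif(1)^2   # dense near the envelope
      tV <- c(tV, tN[k] + ci)
      keepN[k + 1] <- FALSE           # compensatory pause
    }
    beats_t <- c(beats_t, tN[keepN], tV)
    beats_l <- c(beats_l, rep("N", sum(keepN)), rep("V", length(tV)))
    t0 <- max(tN) + 5
  }
  o <- order(beats_t)
  rec <- beat_record(beats_t[o], beats_l[o])
  est <- estimate_refractory(rec)
  expect_equal(est$m, 2.5, tolerance = 0.15)
  expect_equal(est$theta(1.0), 0.45, tolerance = 0.03)
  # epsilon = 0 returns the envelope itself
  est0 <- estimate_refractory(rec, epsilon = 0)
  expect_equal(est0$theta(1.0), 0.5, tolerance = 0.03)
  # an envelope that does not vary with t_s is degenerate
  beats2 <- c(); labs2 <- c(); t0 <- 0
  for (ts in c(0.65, 0.75, 0.85, 0.95)) {
    tN <- t0 + cumsum(rep(ts, 320))
    keepN <- rep(TRUE, 320); tV <- c()
    for (k in seq(2, 318, by = 3)) {
      tV <- c(tV, tN[k] + 0.4 + 0.2 * runif(1)^2)
      keepN[k + 1] <- FALSE
    }
    beats2 <- c(beats2, tN[keepN], tV)
    labs2 <- c(labs2, rep("N", sum(keepN)), rep("V", length(tV)))
    t0 <- max(tN) + 5
  }
  o2 <- order(beats2)
  expect_error(estimate_refractory(beat_record(beats2[o2], labs2[o2])),
               "degenerate")
})

test_that("PRC points reconstructed from bigeminy and trigeminy lie on the curve", {
  prc <- fixture_patient_prc()
  rec1 <- simulate_beats(fixture_patient_params(t_s = 0.78), 400)
  pts1 <- reconstruct_prc_points(rec1, 1.8, 0.15)
  expect_gt(nrow(pts1), 20)
  expect_lt(max(abs(reconstruction_overlay(pts1, prc)$residual)), 1e-9)

  rec2 <- simulate_beats(fixture_patient_params(t_s = 0.60), 400)
  pts2 <- reconstruct_prc_points(rec2, 1.8, 0.15, prc = prc)
  expect_gt(sum(pts2$episode == "trigeminy"), 5)
  expect_lt(max(abs(reconstruction_overlay(pts2, prc)$residual)), 1e-9)

  # a no-reset episode reconstructs the point (phase, 1)
  r0 <- beat_record(c(0, 1.2, 2), c("V", "N", "V"))
  p0 <- reconstruct_prc_points(r0, t_e = 2, t_lag = 0)
  expect_equal(p0$ncl, 1.0)
  expect_equal(p0$phase, 0.6)
  # conduction shift past the cycle end drops the episode
  expect_message(pd <- reconstruct_prc_points(r0, t_e = 2, t_lag = 1.7),
                 "dropped")
  expect_equal(nrow(pd), 0)
})

test_that("noiseless records return the generating (t_e, t_lag, phi_r)", {
  # constant sinus period in a long-period (21:11) locking regime: the
  # coupling interval cycles by itself and the record is exactly trackable
  rec <- gen_holter_record(holter_spec(seed = 5, duration = 2400,
                                       t_s_base = 0.92, drift_amplitude = 0,
                                       jitter_sd = 0, ar_sd = 0))
  truth <- c(1.8, 0.15, 0.65)
  fit <- fit_patient(rec, S = 0.5,
                     theta = list(m = 2.5, c = -0.25, epsilon = 0.05),
                     search_box = list(t_e = c(1.5, 2.2),
                                       t_lag = c(0, 0.35),
                                       phi_r = c(0.45, 0.85)),
                     n_grid = c(12, 7, 7), max_segments = 3,
                     polish_segments = 8)
  est <- c(fit$t_e, fit$t_lag, fit$phi_r)
  # parameters within one grid step of truth; the sequence is then
  # reproduced exactly (phi_r is identifiable only up to the gap between
  # the phases the locked orbit visits)
  steps <- c((2.2 - 1.5) / 11, 0.35 / 6, (0.85 - 0.45) / 6)
  expect_true(all(abs(est - truth) <= steps + 1e-9))
  expect_lt(fit$mae, 1e-6)

  nr <- beat_record(cumsum(rep(0.8, 50)), rep("N", 50))
  expect_error(fit_patient(nr, S = 0.5, theta = 0.3), "no V beats")
})

test_that("KS scoring separates self-consistent and incompatible models", {
  # identical interval samples: KS statistic 0, p = 1
  x <- rnorm(40)
  expect_equal(suppressWarnings(stats::ks.test(x, x, exact = FALSE))$p.value,
               1)
  # pure-sinus record scored against a model that expresses frequent PVCs
  # (short refractory period: every combination of the +/-5% grid still
  # produces ectopy)
  rec <- beat_record(cumsum(rep(0.78, 160)), rep("N", 160))
  fit <- structure(list(t_e = 1.8, t_lag = 0.15, phi_r = 0.65, S = 0.5,
                        theta = 0.1),
                   class = "patient_fit")
  sc <- score_segments(rec, fit, min_beats = 10)
  expect_lt(sc$proportion_well_fit, 0.05)
})
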