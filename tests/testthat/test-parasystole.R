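test_that("the sinus-phase map follows the two-branch structure", {
  p <- parasystole_params(t_s = 1, t_e = 2, theta = 0.3, t_lag = 0,
                          prc = prc_pwlinear(0.7))
  s1 <- step_sinus_phase(0.2, p)   # below (t_s - theta)/t_e = 0.35
  expect_equal(s1$phase, 0.7)
  expect_equal(s1$branch, 1L)
  expect_equal(s1$context, "V(N)")
  s2 <- step_sinus_phase(0.5, p)
  expect_equal(s2$phase, 0)
  expect_equal(s2$branch, 2L)
  s3 <- step_sinus_phase(0.8, p)
  expect_equal(s3$phase, 0.5)
  expect_equal(s3$branch, 2L)
  expect_equal(s3$context, "N")
  # equality at the branch threshold goes to branch 2
  expect_equal(step_sinus_phase(0.35, p)$branch, 2L)
  # conduction shift past the firing is flagged
  p2 <- parasystole_params(t_s = 1, t_e = 2, theta = 0.3, t_lag = 1.8,
                           prc = prc_pwlinear(0.7))
  expect_true(step_sinus_phase(0.95, p2)$stim_after_firing)
})

test_that("the event simulator applies the blocking rules beat by beat", {
  # g == 1, t_s = 1, t_e = 2.5, theta = 0.4, t_lag = 0 over 10 s:
  # firings at 2.5/5/7.5/10; those at 5 and 10 coincide with sinus beats
  # and are blocked (sinus wins); the sinus beats at 3 and 8 follow an
  # expressed V and are blocked (compensatory pause)
  p <- parasystole_params(t_s = 1, t_e = 2.5, theta = 0.4, t_lag = 0,
                          prc = prc_pwlinear(1))
  r <- simulate_beats(p, 10)
  v <- r[r$label == "V", ]
  expect_equal(v$time, c(2.5, 5, 7.5, 10))
  expect_equal(v$expressed, c(TRUE, FALSE, TRUE, FALSE))
  n <- r[r$label == "N", ]
  expect_equal(n$time, 0:10)
  expect_equal(n$time[!n$expressed], c(3, 8))
  expect_equal(pvc_burden(r), 100 * 2 / 11)
  expect_equal(interval_series(r)$nib, 4L)
})

test_that("theta >= t_s suppresses every ectopic beat", {
  for (te in c(1.7, 2.3, 3.1)) {
    p <- parasystole_params(t_s = 1, t_e = te, theta = 1.2, t_lag = 0.3,
                            prc = prc_pwlinear(0.6))
    r <- simulate_beats(p, 150)
    expect_equal(sum(r$label == "V" & r$expressed), 0)
    expect_equal(pvc_burden(r), 0)
  }
})

test_that("event-simulator sinus phases reproduce the map iterates", {
  set.seed(2)
  for (i in 1:40) {
    ts <- runif(1, 0.7, 1.1); th <- runif(1, 0.25, 0.45)
    te <- runif(1, ts + th + 0.15, 3.2)
    phir <- runif(1, 0.45, 0.85)
    tlag <- runif(1, 0, 0.9 * (1 - phir) * te)
    pp <- parasystole_params(ts, te, th, tlag,
                             prc_linear_tail(phir, runif(1, 0.3, 1)))
    rec <- simulate_beats(pp, 120, record_phases = TRUE)
    sp <- attr(rec, "sinus_phases")
    i0 <- which(sp$time > 20)[1]
    phi <- sp$phi_map[i0]
    err <- 0
    for (k in (i0 + 1):nrow(sp)) {
      phi <- step_sinus_phase(phi, pp)$phase
      err <- max(err, abs(phi - sp$phi_map[k]))
    }
    expect_lt(err, 1e-9)
  }
})

test_that("interval series, NIB and coupling are derived from expressed beats", {
  r <- beat_record(c(0, 0.5, 1), c("N", "V", "N"))
  s <- interval_series(r)
  expect_equal(s$intervals$type, c("NV", "VN"))
  expect_equal(s$intervals$interval, c(0.5, 0.5))
  expect_length(s$nib, 0)
  expect_equal(s$coupling$ci, 0.5)

  big <- fixture_bigeminy(10)
  expect_true(all(interval_series(big)$nib == 1L))
  expect_equal(pvc_burden(big), 50)

  # blocked beats do not contribute: removing them is idempotent
  p <- fixture_patient_params()
  rec <- simulate_beats(p, 300)
  kept <- beat_record(rec$time[rec$expressed], rec$label[rec$expressed])
  expect_identical(interval_series(rec), interval_series(kept))
  expect_equal(pvc_burden(rec), pvc_burden(kept))
  expect_error(pvc_burden(beat_record(numeric(0), character(0))), "no expressed")
})

test_that("classical parasystole shows at most three distinct NIB values", {
  set.seed(9)
  for (i in 1:10) {
    ts <- runif(1, 0.7, 1.0)
    te <- ts * (2 + sqrt(2) + runif(1, 0, 0.6))  # generic irrational ratio
    th <- runif(1, 0.25, 0.4)
    p <- parasystole_params(ts, te, th, 0, prc_pwlinear(1))
    r <- simulate_beats(p, ceiling(10000 * ts))
    nib <- interval_series(r)$nib
    expect_gt(length(nib), 50)
    expect_lte(length(unique(nib)), 3)
  }
})

test_that("PVC burden is bounded and non-increasing in the refractory period", {
  prev <- rep(Inf, 3)
  k <- 0
  for (th in c(0.25, 0.35, 0.45, 0.6, 0.9)) {
    k <- k + 1
    b <- vapply(c(0.72, 0.78, 0.92), function(ts) {
      p <- parasystole_params(ts, 1.8, th, 0.15, fixture_patient_prc())
      pvc_burden(simulate_beats(p, 400))
    }, numeric(1))
    expect_true(all(b >= 0 & b <= 100))
    if (k > 1) expect_true(all(b <= prev + 1e-9))
    prev <- b
  }
})

test_that("locking ratios count sinus cycles against pacemaker firings", {
  # unmodulated 2:1 with every firing blocked
  p21 <- parasystole_params(t_s = 1, t_e = 2, theta = 1.5, t_lag = 0,
                            prc = prc_pwlinear(1))
  o <- locking_ratio(p21)
  expect_equal(c(o$N, o$M), c(2L, 1L))
  expect_equal(pvc_burden(simulate_beats(p21, 100)), 0)

  # irrational rotation never locks
  pir <- parasystole_params(t_s = 1, t_e = sqrt(2) * 1.3, theta = 1.5,
                            t_lag = 0, prc = prc_pwlinear(1))
  expect_true(locking_ratio(pir)$aperiodic)

  # a stable (superstable) fixed point of the map is 1:1
  p11 <- parasystole_params(t_s = 0.75, t_e = 1, theta = 0.3, t_lag = 0,
                            prc = prc_pwlinear(0.7))
  o11 <- locking_ratio(p11)
  expect_equal(c(o11$N, o11$M), c(1L, 1L))
})

test_that("beat records survive CSV round trips and parse WFDB listings", {
  p <- fixture_patient_params()
  rec <- simulate_beats(p, 120)
  csv <- tempfile(fileext = ".csv")
  write_beat_record(rec, csv)
  back <- read_beat_record(csv)
  expect_equal(back$time, rec$time, tolerance = 1e-12)
  expect_equal(back$label, rec$label)
  expect_equal(back$expressed, rec$expressed)
  # two-column variant: everything expressed
  df <- data.frame(time_s = c(0, 0.8, 1.3), label = c("N", "N", "V"))
  csv2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, csv2, row.names = FALSE)
  expect_true(all(read_beat_record(csv2)$expressed))
  # rdann-style listing with a non-beat symbol dropped
  ann <- tempfile(fileext = ".txt")
  writeLines(c("  0:00.500   128   N    0    0    0",
               "  0:01.250   320   V    0    0    0",
               "  0:01.900   486   +    0    0    0",
               "  1:02.000 15872   N    0    0    0"), ann)
  expect_message(w <- read_wfdb_annotations(ann), "dropped")
  expect_equal(w$time, c(0.5, 1.25, 62))
  expect_equal(w$label, c("N", "V", "N"))
  unlink(c(csv, csv2, ann))
})
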