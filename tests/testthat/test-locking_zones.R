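test_that("oscillator locking grid matches the closed-form tongues", {
  taus <- seq(0.1, 1.7, by = 0.1)
  phirs <- seq(0.15, 0.9, by = 0.15)
  lg <- locking_grid_oscillator(taus, phirs, "pwlinear")
  for (i in seq_along(phirs)) for (j in seq_along(taus)) {
    if (phirs[i] <= taus[j] && taus[j] < 1) {
      expect_equal(lg$N[i, j], 1L)
      expect_equal(lg$M[i, j], 1L)
    }
  }
  # rational rotations below phi_r lock q:p when the orbit avoids the tail
  c1 <- locking_grid_oscillator(0.4, 0.7, "pwlinear")
  expect_equal(c(c1$N[1, 1], c1$M[1, 1]), c(2L, 1L))
  c2 <- locking_grid_oscillator(0.75, 0.8, "pwlinear")
  expect_equal(c(c2$N[1, 1], c2$M[1, 1]), c(4L, 3L))
  # long-period and aperiodic cells are masked as period 0
  expect_true(all(is.na(lg$N[lg$period0])))
  expect_equal(dim(lg$N), c(length(phirs), length(taus)))
})

test_that("the parasystole grid agrees with per-cell locking ratios", {
  base <- fixture_patient_params()
  taus <- seq(0.35, 0.5, by = 0.05)
  phirs <- c(0.55, 0.65)
  lg <- locking_grid_parasystole(taus, phirs, base)
  for (i in seq_along(phirs)) for (j in seq_along(taus)) {
    pp <- parasystole_params(taus[j] * base$t_e, base$t_e, base$theta,
                             base$t_lag, prc_linear_tail(phirs[i], 0.5))
    o <- locking_ratio(pp)
    if (!o$aperiodic && o$N <= 5) {
      expect_equal(lg$N[i, j], o$N)
      expect_equal(lg$M[i, j], o$M)
    } else {
      expect_true(lg$period0[i, j])
    }
  }
  # fully blocked row at tau = 1/2 is 2:1 everywhere: a zero-slope tail
  # keeps g == 1 whatever phi_r the grid substitutes
  b2 <- parasystole_params(t_s = 1, t_e = 2, theta = 1.5, t_lag = 0,
                           prc = prc_linear_tail(0.5, 0))
  lg2 <- locking_grid_parasystole(0.5, c(0.3, 0.6, 0.9), b2)
  expect_true(all(lg2$N == 2L & lg2$M == 1L))
})

test_that("burden maps respect the blocking bound and converge", {
  # theta >= t_s: zero burden over the whole (phi_r, t_lag) plane
  blocked <- parasystole_params(t_s = 1, t_e = 2, theta = 5, t_lag = 0.1,
                                prc = prc_pwlinear(0.7))
  bm <- pvc_burden_maps(blocked, tau_grid = c(0.45, 0.5),
                        phir_grid = seq(0.2, 0.8, length.out = 4),
                        tlag_grid = c(0, 0.2, 0.4),
                        n_cycles = 150, n_transient = 50)
  expect_true(all(bm$tau_phir$burden == 0))
  expect_true(all(bm$phir_tlag$burden == 0))

  # expressed-bigeminy cell sits at 50% and burden is always within [0,100]
  base <- fixture_patient_params()
  bm2 <- pvc_burden_maps(base, tau_grid = 0.78 / 1.8, phir_grid = 0.65,
                         tlag_grid = 0.15, n_cycles = 400,
                         n_transient = 200)
  expect_equal(bm2$tau_phir$burden, 50, tolerance = 0.01)
  expect_true(all(bm2$phir_tlag$burden >= 0 & bm2$phir_tlag$burden <= 100))

  # periodic cells are insensitive to doubling the simulation length
  b_short <- pvc_burden_maps(base, 0.78 / 1.8, 0.65, 0.15,
                             n_cycles = 300, n_transient = 200)
  b_long <- pvc_burden_maps(base, 0.78 / 1.8, 0.65, 0.15,
                            n_cycles = 600, n_transient = 200)
  expect_lt(abs(b_short$tau_phir$burden - b_long$tau_phir$burden), 1)
})
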