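test_that("piecewise-linear PRC is 1 below phi_r and phi at/above it", {
  g <- prc_pwlinear(0.7)
  expect_identical(eval_prc(g, 0.3), 1)
  expect_identical(eval_prc(g, 0.8), 0.8)
  expect_identical(eval_prc(g, 0.7), 0.7)  # boundary uses the tail branch
  # exactness over a dense grid
  ph <- seq(0, 0.999, by = 0.001)
  expect_identical(eval_prc(g, ph), ifelse(ph < 0.7, 1, ph))
  # degenerate phi_r = 1: no resetting
  expect_true(all(eval_prc(prc_pwlinear(1), ph) == 1))
})

test_that("empirical family reduces to piecewise-linear and stays positive", {
  ph <- seq(0, 0.999, by = 0.001)
  red <- prc_empirical(phi_r = 0.7, S = 1, b0 = 0, h = 0, w = 0.05,
                       a1 = 0, a2 = 0)
  expect_equal(eval_prc(red, ph), eval_prc(prc_pwlinear(0.7), ph))
  for (prc in list(fixture_truth_prc(), prc_linear_tail(0.4, 0.3),
                   prc_pwlinear(0.25))) {
    expect_true(all(eval_prc(prc, ph) > 0))
    f <- prc_fun(prc)
    expect_equal(vapply(c(0, 0.31, 0.7, 0.95), f, numeric(1)),
                 eval_prc(prc, c(0, 0.31, 0.7, 0.95)))
  }
})

test_that("phase domain and parameter validation are enforced", {
  g <- prc_pwlinear(0.7)
  expect_error(eval_prc(g, 1), "\\[0, 1\\)")
  expect_error(eval_prc(g, -0.1), "\\[0, 1\\)")
  expect_error(prc_pwlinear(0), "phi_r")
  expect_error(prc_empirical(phi_r = 0.7, S = 1, h = -1), "h")
  # curve forced non-positive on the tail is rejected at construction
  expect_error(prc_empirical(phi_r = 0.5, S = 0, b0 = -1), "positive")
})

test_that("noiseless fits recover the generating parameters", {
  truth <- fixture_truth_prc()
  ph <- sort(unique(c(seq(0, 0.995, by = 0.005), truth$phi_r)))
  fit <- fit_prc(prc_samples(ph, eval_prc(truth, ph)), "empirical")
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-9)
  for (k in c("phi_r", "S", "b0", "h", "w", "a1", "a2"))
    expect_lt(abs(fit$prc[[k]] - truth[[k]]) / max(abs(truth[[k]]), 1e-12),
              1e-6)
  gp <- prc_pwlinear(0.7)
  php <- seq(0, 0.99, by = 0.01)
  fp <- fit_prc(prc_samples(php, eval_prc(gp, php)), "pwlinear")
  expect_equal(fp$prc$phi_r, 0.7)
  expect_lt(fp$rmse, 1e-12)
})

test_that("fit preconditions reject degenerate sample sets", {
  expect_error(fit_prc(prc_samples((1:5) / 10, rep(1, 5))), "at least 8")
  # all samples outside the admissible candidate range
  ph <- c(0.005, 0.01, 0.02, 0.03, 0.04, 0.96, 0.97, 0.99)
  expect_error(fit_prc(prc_samples(ph, rep(1, 8))), "side")
  expect_error(fit_prc(prc_samples(c(1:8) / 10, c(rep(1, 7), NA))),
               "finite|missing")
})

test_that("noisy fits land in the measured-scatter band", {
  truth <- fixture_truth_prc()
  res <- t(vapply(1:12, function(s) {
    sm <- gen_prc_samples(truth, 200, 0.056, seed = s)
    ft <- fit_prc(sm, "empirical")
    c(ft$rmse, ft$prc$phi_r)
  }, numeric(2)))
  expect_true(all(res[, 1] >= 0.04 & res[, 1] <= 0.075))
  expect_true(all(abs(res[, 2] - truth$phi_r) <= 0.02))
})

test_that("discontinuity detection finds the jump or reports absence", {
  ph <- seq(0, 0.99, by = 0.01)
  for (phi_r in c(0.2, 0.45, 0.7, 0.9)) {
    s <- prc_samples(ph, eval_prc(prc_pwlinear(phi_r), ph))
    # threshold below the smallest jump in the set (1 - 0.9 = 0.1)
    expect_lt(abs(detect_discontinuity(s, jump_threshold = 0.05) - phi_r),
              0.011)
  }
  expect_true(is.na(detect_discontinuity(prc_samples(ph, rep(1, length(ph))))))
  expect_error(detect_discontinuity(prc_samples(0.5, 1)), "at least 2")
  expect_error(detect_discontinuity(prc_samples(c(0.2, 0.2, 0.3), rep(1, 3))),
               "increasing")
})

test_that("reconstruction overlay computes per-point residuals", {
  truth <- fixture_truth_prc()
  ph <- seq(0.05, 0.95, by = 0.05)
  ov <- reconstruction_overlay(prc_samples(ph, eval_prc(truth, ph)), truth)
  expect_true(all(abs(ov$residual) < 1e-12))
  # g(0.9) = 0.9 on the triggering branch, so the residual is 0.1
  ov1 <- reconstruction_overlay(prc_samples(0.9, 1.0), prc_pwlinear(0.7))
  expect_equal(ov1$residual, 0.1)
})

test_that("PRC samples round-trip through CSV and fits through JSON", {
  truth <- fixture_truth_prc()
  sm <- gen_prc_samples(truth, 50, 0.02, seed = 3)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(sm, csv, row.names = FALSE)
  expect_equal(read_prc_samples(csv)$ncl, sm$ncl)
  fit <- fit_prc(gen_prc_samples(truth, 100, 0.02, seed = 4), "empirical")
  js <- tempfile(fileext = ".json")
  write_prc_fit(fit, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$family, "empirical")
  expect_equal(parsed$rmse, fit$rmse, tolerance = 1e-12)
  expect_equal(parsed$phi_r, fit$prc$phi_r, tolerance = 1e-12)
  unlink(c(csv, js))
})
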