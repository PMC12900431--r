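#' Locking-zone grid for the forced oscillator
#'
#' Classifies the N:M locking ratio of the forced-oscillator map on a
#' (tau, phi_r) grid. Cells that are aperiodic or have period N greater
#' than `n_show` are masked as "period 0", the display convention for
#' locking-zone maps.
#'
#' @param tau_grid,phir_grid numeric axis vectors (non-empty).
#' @param family `"pwlinear"` or `"empirical"`; the empirical family uses
#'   `prc_template` with its `phi_r` overridden per row.
#' @param prc_template an `empirical_prc` used when
#'   `family = "empirical"` (default [example_empirical_prc()]).
#' @param n_show maximum displayed period (default 5).
#' @param n_transient,n_max passed to [iterate_orbit()].
#' @return a `locking_grid`: list with `axis1` (`tau`), `axis2` (`phi_r`),
#'   integer matrices `N` and `M` (`NA` where masked), logical `period0`
#'   mask, and `table` in long format (`tau, phi_r, N, M`).
#' @export
locking_grid_oscillator <- function(tau_grid, phir_grid,
                                    family = c("pwlinear", "empirical"),
                                    prc_template = example_empirical_prc(),
                                    n_show = 5, n_transient = 1000,
                                    n_max = 50) {
  family <- match.arg(family)
  if (!length(tau_grid) || !length(phir_grid))
    stop("grids must be non-empty", call. = FALSE)
  N <- M <- matrix(NA_integer_, length(phir_grid), length(tau_grid))
  for (i in seq_along(phir_grid)) {
    prc <- if (family == "pwlinear") prc_pwlinear(phir_grid[i])
           else prc_empirical(phi_r = phir_grid[i], S = prc_template$S,
                              b0 = prc_template$b0, h = prc_template$h,
                              w = prc_template$w, a1 = prc_template$a1,
                              a2 = prc_template$a2)
    for (j in seq_along(tau_grid)) {
      o <- iterate_orbit(stimulus_config(tau_grid[j]), prc,
                         n_transient = n_transient, n_max = n_max)
      if (!o$aperiodic) { N[i, j] <- o$N; M[i, j] <- o$M }
    }
  }
  finish_locking_grid(tau_grid, phir_grid, N, M, n_show, "tau", "phi_r")
}

#' Locking-zone grid for the parasystole model
#'
#' As [locking_grid_oscillator] but for the modulated parasystole map:
#' tau = t_s/t_e is realized by varying the sinus period with `t_e` fixed,
#' and `phi_r` overrides the discontinuity of the base PRC (linear-tail
#' family with the base tail slope). Cells whose parameters violate the
#' model invariants are masked.
#'
#' @param tau_grid,phir_grid numeric axis vectors.
#' @param base a [parasystole_params] providing `t_e`, `theta`, `t_lag` and
#'   the tail slope.
#' @param n_show,n_transient,n_max as in [locking_grid_oscillator].
#' @return a `locking_grid` (see [locking_grid_oscillator]).
#' @export
locking_grid_parasystole <- function(tau_grid, phir_grid, base,
                                     n_show = 5, n_transient = 1000,
                                     n_max = 50) {
  stopifnot(inherits(base, "parasystole_params"))
  if (!length(tau_grid) || !length(phir_grid))
    stop("grids must be non-empty", call. = FALSE)
  S <- if (inherits(base$prc, "linear_tail_prc")) base$prc$S else 1
  N <- M <- matrix(NA_integer_, length(phir_grid), length(tau_grid))
  n_masked <- 0L
  for (i in seq_along(phir_grid)) {
    prc <- if (S == 1) prc_pwlinear(phir_grid[i])
           else prc_linear_tail(phir_grid[i], S)
    for (j in seq_along(tau_grid)) {
      pp <- tryCatch(
        parasystole_params(t_s = tau_grid[j] * base$t_e, t_e = base$t_e,
                           theta = base$theta, t_lag = base$t_lag,
                           prc = prc),
        error = function(e) NULL)
      if (is.null(pp)) { n_masked <- n_masked + 1L; next }
      o <- locking_ratio(pp, n_transient = n_transient, n_max = n_max)
      if (!o$aperiodic) { N[i, j] <- o$N; M[i, j] <- o$M }
    }
  }
  if (n_masked > 0) message(n_masked, " cell(s) masked (invalid parameters)")
  finish_locking_grid(tau_grid, phir_grid, N, M, n_show, "tau", "phi_r")
}

finish_locking_grid <- function(ax1, ax2, N, M, n_show, nm1, nm2) {
  period0 <- is.na(N) | N > n_show
  Nm <- N; Mm <- M
  Nm[period0] <- NA_integer_; Mm[period0] <- NA_integer_
  tab <- data.frame(rep(ax1, each = length(ax2)), rep(ax2, length(ax1)),
                    N = as.vector(Nm), M = as.vector(Mm))
  names(tab)[1:2] <- c(nm1, nm2)
  structure(list(axis1 = stats::setNames(list(ax1), nm1)[[1]],
                 axis2 = stats::setNames(list(ax2), nm2)[[1]],
                 axis1_name = nm1, axis2_name = nm2,
                 N = Nm, M = Mm, period0 = period0, table = tab),
            class = "locking_grid")
}

#' @export
print.locking_grid <- function(x, ...) {
  cat(sprintf("<locking grid: %d x %d cells (%s x %s), %.1f%% period 0>\n",
              length(x$axis2), length(x$axis1), x$axis2_name, x$axis1_name,
              100 * mean(x$period0)))
  invisible(x)
}

#' PVC-burden maps over parameter space
#'
#' Computes the PVC burden of the parasystole model on a (tau, phi_r) grid
#' (tau varied through the sinus period) and a tau-averaged burden on a
#' (phi_r, t_lag) grid. Each cell simulates `n_cycles` sinus cycles after a
#' transient of `n_transient` sinus beats.
#'
#' @param base a [parasystole_params] (supplies `t_e`, `theta` and the tail
#'   slope).
#' @param tau_grid,phir_grid,tlag_grid axis vectors; `tlag_grid` in seconds.
#' @param n_cycles sinus cycles per cell after the transient (default 500).
#' @param n_transient sinus beats discarded (default 500).
#' @return list with `tau_phir` (`data.frame tau, phi_r, burden`; burden for
#'   the base `t_lag`) and `phir_tlag` (`data.frame phi_r, t_lag, burden`,
#'   burden averaged uniformly over `tau_grid`).
#' @export
pvc_burden_maps <- function(base, tau_grid, phir_grid, tlag_grid,
                            n_cycles = 500, n_transient = 500) {
  stopifnot(inherits(base, "parasystole_params"))
  S <- if (inherits(base$prc, "linear_tail_prc")) base$prc$S else 1
  cell <- function(tau, phi_r, t_lag) {
    t_s <- tau * base$t_e
    prc <- if (S == 1) prc_pwlinear(phi_r) else prc_linear_tail(phi_r, S)
    pp <- tryCatch(
      parasystole_params(t_s, base$t_e, base$theta, t_lag, prc),
      error = function(e) NULL)
    if (is.null(pp)) return(NA_real_)
    dur <- (n_transient + n_cycles) * t_s
    rec <- simulate_beats(pp, dur)
    eb <- rec[rec$expressed & rec$time >= n_transient * t_s, , drop = FALSE]
    if (!nrow(eb)) return(NA_real_)
    100 * sum(eb$label == "V") / nrow(eb)
  }
  m1 <- expand.grid(tau = tau_grid, phi_r = phir_grid)
  m1$burden <- mapply(cell, m1$tau, m1$phi_r,
                      MoreArgs = list(t_lag = base$t_lag))
  m2 <- expand.grid(phi_r = phir_grid, t_lag = tlag_grid)
  m2$burden <- mapply(function(pr, tl)
    mean(vapply(tau_grid, cell, numeric(1), phi_r = pr, t_lag = tl),
         na.rm = TRUE),
    m2$phi_r, m2$t_lag)
  list(tau_phir = m1, phir_tlag = m2)
}
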