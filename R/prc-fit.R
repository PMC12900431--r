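#' Construct a table of PRC samples
#'
#' A PRC sample is a (stimulus phase, normalized perturbed cycle length)
#' measurement. Phases must lie in \[0,1) and cycle lengths must be positive.
#'
#' @param phase numeric vector of stimulus phases in \[0,1).
#' @param ncl numeric vector of normalized cycle lengths, > 0.
#' @return a `data.frame` with columns `phase`, `ncl`.
#' @export
prc_samples <- function(phase, ncl) {
  if (length(phase) != length(ncl))
    stop("`phase` and `ncl` must have equal length", call. = FALSE)
  if (any(!is.finite(phase)) || any(!is.finite(ncl)))
    stop("non-finite sample values", call. = FALSE)
  if (any(phase < 0 | phase >= 1)) stop("phases must lie in [0,1)", call. = FALSE)
  if (any(ncl <= 0)) stop("ncl must be > 0", call. = FALSE)
  data.frame(phase = phase, ncl = ncl)
}

#' Read PRC samples from CSV
#'
#' Expects a header line `phase,ncl`.
#'
#' @param path file path.
#' @return a validated PRC sample table.
#' @export
read_prc_samples <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("phase", "ncl") %in% names(df)))
    stop("PRC sample file must have columns `phase` and `ncl`", call. = FALSE)
  prc_samples(df$phase, df$ncl)
}

#' Fit a PRC family to measured samples
#'
#' Least-squares fit of a parametric PRC to (phase, ncl) samples. Because the
#' objective is discontinuous in the discontinuity location `phi_r`, `phi_r`
#' is handled by grid search: for each candidate the remaining parameters are
#' solved in closed form (the empirical family is linear in all shape
#' parameters once the hook width `w` is profiled out by a one-dimensional
#' optimization). The fitted `phi_r` is then placed at the smallest sample
#' phase assigned to the triggering branch: within one branch assignment the
#' residuals do not constrain `phi_r` further (for the empirical family a
#' shift of `phi_r` is absorbed exactly by rescaling the hook amplitude), so
#' the first shortened sample is the natural estimate of the discontinuity.
#'
#' @param samples PRC sample table (see [prc_samples]); at least 8 rows, with
#'   at least 3 on each side of every admissible `phi_r` candidate.
#' @param family `"empirical"` or `"pwlinear"`.
#' @param init optional list; `init$phi_r` centres the candidate grid on
#'   `init$phi_r + c(-0.2, 0.2)`.
#' @param grid_step spacing of the `phi_r` candidate grid (default 0.005).
#' @return an object of class `prc_fit`: list with elements `prc` (the fitted
#'   PRC object), `rmse` (root mean squared residual of ncl), `n_samples`,
#'   and `converged`.
#' @export
fit_prc <- function(samples, family = c("empirical", "pwlinear"),
                    init = NULL, grid_step = 0.005) {
  family <- match.arg(family)
  if (!all(c("phase", "ncl") %in% names(samples)))
    stop("`samples` must have columns `phase` and `ncl`", call. = FALSE)
  phase <- samples$phase; ncl <- samples$ncl
  if (any(!is.finite(phase)) || any(!is.finite(ncl)))
    stop("non-finite sample values", call. = FALSE)
  n <- length(phase)
  if (n < 8) stop("need at least 8 samples to fit a PRC", call. = FALSE)

  lo <- 0.05; hi <- 0.95
  if (!is.null(init$phi_r)) {
    lo <- max(lo, init$phi_r - 0.2); hi <- min(hi, init$phi_r + 0.2)
  }
  # candidates are sample phases (each candidate = the first sample of the
  # triggering branch), thinned to roughly grid_step spacing; an abstract
  # numeric grid would mis-assign boundary samples by floating-point dust
  cand <- sort(unique(phase))
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) > 250) {
    keep <- logical(length(cand)); keep[1] <- TRUE; last <- cand[1]
    for (k in seq_along(cand)[-1]) {
      if (cand[k] - last >= grid_step) { keep[k] <- TRUE; last <- cand[k] }
    }
    cand <- cand[keep]
  }
  n_early <- vapply(cand, function(p) sum(phase < p), integer(1))
  ok <- n_early >= 3 & (n - n_early) >= 3
  if (!any(ok))
    stop("too few samples on one side of every candidate phi_r", call. = FALSE)
  cand <- cand[ok]

  fit_one <- switch(family,
                    pwlinear = fit_branches_pwlinear,
                    empirical = fit_branches_empirical)
  fits <- lapply(cand, function(p) fit_one(p, phase, ncl))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  best <- which.min(sse)
  phi_r_hat <- cand[best]
  final <- fits[[best]]
  structure(list(prc = final$prc,
                 rmse = sqrt(final$sse / n),
                 n_samples = n,
                 converged = final$converged),
            class = "prc_fit")
}

fit_branches_pwlinear <- function(phi_r, phase, ncl) {
  early <- phase < phi_r
  sse <- sum((ncl[early] - 1)^2) + sum((ncl[!early] - phase[!early])^2)
  list(prc = prc_pwlinear(phi_r), sse = sse, converged = TRUE)
}

fit_branches_empirical <- function(phi_r, phase, ncl) {
  early <- phase < phi_r
  pe <- phase[early]; ye <- ncl[early]
  pt <- phase[!early]; yt <- ncl[!early]
  # early branch: g = 1 + a1 phi + a2 phi^2, linear in (a1, a2)
  Xe <- cbind(pe, pe^2)
  ce <- tryCatch(stats::lm.fit(Xe, ye - 1)$coefficients,
                 error = function(e) c(0, 0))
  ce[!is.finite(ce)] <- 0
  sse_early <- sum((ye - (1 + Xe %*% ce))^2)

  # tail branch: b0 + S phi - h exp(-(phi - phi_r)/w); linear given w
  tail_fit <- function(w) {
    X <- cbind(1, pt, -exp(-(pt - phi_r) / w))
    cf <- tryCatch(stats::lm.fit(X, yt)$coefficients,
                   error = function(e) rep(NA_real_, 3))
    if (any(!is.finite(cf)) || cf[3] < 0) {
      X0 <- cbind(1, pt)
      cf0 <- stats::lm.fit(X0, yt)$coefficients
      cf <- c(cf0, 0)
    }
    list(coef = cf, sse = sum((yt - cbind(1, pt, -exp(-(pt - phi_r) / w)) %*% cf)^2))
  }
  op <- stats::optimize(function(w) tail_fit(w)$sse,
                        interval = c(0.005, 0.6), tol = 1e-9)
  tf <- tail_fit(op$minimum)
  prc <- tryCatch(
    prc_empirical(phi_r = phi_r, S = tf$coef[2], b0 = tf$coef[1],
                  h = tf$coef[3], w = op$minimum,
                  a1 = ce[1], a2 = ce[2]),
    error = function(e) NULL)
  if (is.null(prc)) {
    # invalid (non-positive) curve at this candidate: reject with huge SSE
    return(list(prc = NULL, sse = Inf, converged = FALSE))
  }
  list(prc = prc, sse = sse_early + tf$sse, converged = TRUE)
}

#' @export
print.prc_fit <- function(x, ...) {
  cat(sprintf("<PRC fit: %s family, n = %d, RMSE = %.4g%s>\n",
              sub("_prc$", "", class(x$prc)[1]), x$n_samples, x$rmse,
              if (x$converged) "" else ", NOT converged"))
  print(x$prc)
  invisible(x)
}

#' Write a fitted PRC as JSON
#'
#' Emits the fitted parameters (keys matching the family's field names) plus
#' `family`, `rmse` and `n_samples`.
#'
#' @param fit a `prc_fit` object.
#' @param path output path.
#' @export
write_prc_fit <- function(fit, path) {
  out <- c(list(family = sub("_prc$", "", class(fit$prc)[1])),
           unclass(fit$prc),
           list(rmse = fit$rmse, n_samples = fit$n_samples,
                converged = fit$converged))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Detect a PRC discontinuity from sorted samples
#'
#' Scans adjacent sample pairs (sorted by phase) for the largest drop in
#' normalized cycle length. If that drop exceeds `jump_threshold`, the
#' midpoint of the flanking phases is returned as the discontinuity estimate;
#' otherwise the curve is declared continuous (weak or short stimuli produce
#' no discontinuity).
#'
#' @param samples PRC sample table sorted by strictly increasing phase.
#' @param jump_threshold minimum ncl drop counting as a discontinuity
#'   (default 0.15, normalized units).
#' @return the estimated `phi_r`, or `NA_real_` when no jump exceeds the
#'   threshold.
#' @export
detect_discontinuity <- function(samples, jump_threshold = 0.15) {
  phase <- samples$phase; ncl <- samples$ncl
  if (length(phase) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(phase) <= 0))
    stop("sample phases must be strictly increasing", call. = FALSE)
  drops <- ncl[-length(ncl)] - ncl[-1]
  i <- which.max(drops)
  if (drops[i] > jump_threshold) (phase[i] + phase[i + 1]) / 2 else NA_real_
}

#' Residuals of reconstructed PRC points against a fitted curve
#'
#' Compares externally reconstructed (phase, ncl) points — e.g. from
#' bigeminy/trigeminy episodes of a beat record — against a parametric PRC.
#'
#' @param points PRC sample table.
#' @param prc a PRC object.
#' @return `data.frame` with columns `phase`, `ncl`, `predicted`, `residual`
#'   (`ncl - g(phase)`).
#' @export
reconstruction_overlay <- function(points, prc) {
  pred <- eval_prc(prc, points$phase)
  data.frame(phase = points$phase, ncl = points$ncl,
             predicted = pred, residual = points$ncl - pred)
}
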