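#' Phase response curve (PRC) families
#'
#' A PRC gives the normalized perturbed cycle length g(phi) of a spontaneously
#' beating oscillator as a function of the phase phi in \[0,1) at which a
#' single stimulus lands. g(phi) = 1 means the cycle is unchanged; g < 1 means
#' the cycle is shortened (the stimulus advances or triggers the next beat);
#' g > 1 means prolongation. All families here share the defining feature of
#' cardiac PRCs measured in spontaneously beating preparations: a
#' discontinuity at phase `phi_r` separating a no-effect/prolonging early
#' segment from an all-or-none triggering tail.
#'
#' Three families are provided:
#' \describe{
#'   \item{piecewise-linear}{g(phi) = 1 for phi < phi_r, g(phi) = phi for
#'     phi_r <= phi < 1. `phi_r = 1` degenerates to g == 1 (no resetting).}
#'   \item{linear tail}{g(phi) = 1 for phi < phi_r, g(phi) = 1 + S(phi - 1)
#'     for phi >= phi_r: a tail of slope `S` anchored at g(1) = 1. `S = 1`
#'     recovers the piecewise-linear family.}
#'   \item{empirical}{early branch 1 + a1 phi + a2 phi^2 on \[0, phi_r);
#'     tail b0 + S phi - h exp(-(phi - phi_r)/w) on \[phi_r, 1). The
#'     exponential term is the transient "hook" (a dip just past the
#'     discontinuity) seen in measured human cardiomyocyte-spheroid PRCs.}
#' }
#'
#' The phase domain is half-open: g evaluated exactly at `phi_r` uses the
#' tail branch.
#'
#' @param phi_r discontinuity phase in (0, 1].
#' @param S tail slope (dimensionless).
#' @param b0 tail intercept.
#' @param h hook amplitude, >= 0.
#' @param w hook width, > 0 (phase units).
#' @param a1,a2 early-branch polynomial coefficients; the early branch is
#'   constrained to g(0) = 1.
#' @return an object of class `c("<family>_prc", "prc")`.
#' @examples
#' g <- prc_pwlinear(0.7)
#' eval_prc(g, c(0.3, 0.8))  # 1.0, 0.8
#' @name prc_families
NULL

#' @rdname prc_families
#' @export
prc_pwlinear <- function(phi_r) {
  stopifnot_scalar(phi_r)
  if (phi_r <= 0 || phi_r > 1)
    stop("`phi_r` must lie in (0, 1]", call. = FALSE)
  structure(list(phi_r = phi_r), class = c("pwlinear_prc", "prc"))
}

#' @rdname prc_families
#' @export
prc_linear_tail <- function(phi_r, S) {
  stopifnot_scalar(phi_r); stopifnot_scalar(S)
  if (phi_r <= 0 || phi_r > 1)
    stop("`phi_r` must lie in (0, 1]", call. = FALSE)
  obj <- structure(list(phi_r = phi_r, S = S),
                   class = c("linear_tail_prc", "prc"))
  check_prc_positive(obj)
  obj
}

#' @rdname prc_families
#' @export
prc_empirical <- function(phi_r, S, b0 = 1 - S, h = 0, w = 0.05,
                          a1 = 0, a2 = 0) {
  for (v in list(phi_r, S, b0, h, w, a1, a2)) stopifnot_scalar(v)
  if (phi_r <= 0 || phi_r > 1)
    stop("`phi_r` must lie in (0, 1]", call. = FALSE)
  if (h < 0) stop("hook amplitude `h` must be >= 0", call. = FALSE)
  if (w <= 0) stop("hook width `w` must be > 0", call. = FALSE)
  obj <- structure(
    list(phi_r = phi_r, S = S, b0 = b0, h = h, w = w, a1 = a1, a2 = a2),
    class = c("empirical_prc", "prc"))
  check_prc_positive(obj)
  obj
}

# positivity of g on [0,1) is required for the maps (a beat-time going
# non-positive is unphysical); validated on a dense grid at construction
check_prc_positive <- function(prc) {
  grid <- seq(0, 1 - 1e-9, length.out = 2001)
  g <- eval_prc(prc, grid)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("invalid PRC parameters: g(phi) must be positive on [0,1)",
         call. = FALSE)
  invisible(prc)
}

#' Evaluate a PRC
#'
#' @param prc a PRC object (see [prc_families]).
#' @param phase numeric vector of phases, each in \[0, 1).
#' @return normalized cycle lengths g(phase).
#' @export
eval_prc <- function(prc, phase) {
  if (any(!is.finite(phase)) || any(phase < 0) || any(phase >= 1))
    stop("`phase` must lie in [0, 1)", call. = FALSE)
  UseMethod("eval_prc")
}

#' @export
eval_prc.pwlinear_prc <- function(prc, phase) {
  ifelse(phase < prc$phi_r, 1, phase)
}

#' @export
eval_prc.linear_tail_prc <- function(prc, phase) {
  ifelse(phase < prc$phi_r, 1, 1 + prc$S * (phase - 1))
}

#' @export
eval_prc.empirical_prc <- function(prc, phase) {
  early <- phase < prc$phi_r
  out <- numeric(length(phase))
  out[early] <- 1 + prc$a1 * phase[early] + prc$a2 * phase[early]^2
  pt <- phase[!early]
  out[!early] <- prc$b0 + prc$S * pt - prc$h * exp(-(pt - prc$phi_r) / prc$w)
  out
}

#' Fast scalar evaluator for a PRC
#'
#' Returns a closure `function(phi)` evaluating g without S3 dispatch or
#' domain checks, for use in inner simulation loops. The caller guarantees
#' `phi` in \[0, 1).
#'
#' @param prc a PRC object.
#' @return a function of one numeric scalar.
#' @export
prc_fun <- function(prc) {
  if (inherits(prc, "pwlinear_prc")) {
    phi_r <- prc$phi_r
    function(phi) if (phi < phi_r) 1 else phi
  } else if (inherits(prc, "linear_tail_prc")) {
    phi_r <- prc$phi_r; S <- prc$S
    function(phi) if (phi < phi_r) 1 else 1 + S * (phi - 1)
  } else if (inherits(prc, "empirical_prc")) {
    phi_r <- prc$phi_r; S <- prc$S; b0 <- prc$b0; h <- prc$h; w <- prc$w
    a1 <- prc$a1; a2 <- prc$a2
    function(phi) {
      if (phi < phi_r) 1 + a1 * phi + a2 * phi * phi
      else b0 + S * phi - h * exp(-(phi - phi_r) / w)
    }
  } else stop("unknown PRC class", call. = FALSE)
}

#' @export
print.prc <- function(x, ...) {
  fam <- sub("_prc$", "", class(x)[1])
  cat(sprintf("<%s PRC>\n", fam))
  cat(" ", paste(sprintf("%s = %.6g", names(unclass(x)), unlist(x)),
                 collapse = ", "), "\n")
  invisible(x)
}

#' An illustrative empirical PRC
#'
#' A parameter set with the morphology typical of measured human
#' cardiomyocyte-spheroid PRCs: a mildly prolonging early segment, a
#' discontinuity near phase 0.7, a hook just past it, and a near-unit-slope
#' linear tail. Used as the default ground truth in examples and synthetic
#' data.
#'
#' @return an `empirical_prc` object.
#' @export
example_empirical_prc <- function() {
  prc_empirical(phi_r = 0.7, S = 0.9, b0 = 0.1, h = 0.15, w = 0.05,
                a1 = 0.05, a2 = 0.15)
}
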