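#' Oscillator models for in-silico PRC construction
#'
#' [toy_oscillator()] builds the package's built-in spontaneously beating
#' cell: a FitzHugh-Nagumo relaxation oscillator
#' `dv/dt = v - v^3/3 - w + I0 + I_stim`, `dw/dt = eps (v + a - b w)`,
#' whose default parameters give a sustained limit cycle. A beat is the
#' upward crossing of `v = 0`.
#'
#' [oscillator_adapter()] wraps any user-supplied limit-cycle model (for
#' example a CellML-derived ionic cardiomyocyte model) in the same
#' interface, so the PRC protocol and sweeps run unchanged: the contract is
#' a derivative function with an additive stimulus current, an initial
#' state, named scalable parameters, and a beat definition (state variable
#' and threshold).
#'
#' @param a,b,eps,I0 FitzHugh-Nagumo parameters (dimensionless defaults
#'   0.7, 0.8, 0.08, 0.5).
#' @return an `oscillator_model` object.
#' @export
toy_oscillator <- function(a = 0.7, b = 0.8, eps = 0.08, I0 = 0.5) {
  oscillator_adapter(
    derivs = function(t, state, params, I_stim) {
      v <- state[1]; w <- state[2]
      c(v - v^3 / 3 - w + params[["I0"]] + I_stim,
        params[["eps"]] * (v + params[["a"]] - params[["b"]] * w))
    },
    state0 = c(v = -1.2, w = -0.6),
    params = c(a = a, b = b, eps = eps, I0 = I0),
    beat_var = "v", beat_level = 0, beat_lockout = 1,
    class = "toy_oscillator")
}

#' @rdname toy_oscillator
#' @param derivs function `(t, state, params, I_stim)` returning the state
#'   derivative vector; `I_stim` is the additive stimulus current.
#' @param state0 named initial state vector.
#' @param params named numeric parameter vector (entries scalable by name).
#' @param beat_var name of the state variable defining beats.
#' @param beat_level threshold whose upward crossing marks a beat.
#' @param beat_lockout refractory lockout between detected beats, in model
#'   time units.
#' @param class optional extra S3 class.
#' @export
oscillator_adapter <- function(derivs, state0, params, beat_var,
                               beat_level = 0, beat_lockout = 1,
                               class = NULL) {
  stopifnot(is.function(derivs), beat_var %in% names(state0))
  structure(list(derivs = derivs, state0 = state0, params = params,
                 beat_var = beat_var, beat_level = beat_level,
                 beat_lockout = beat_lockout),
            class = c(class, "oscillator_model"))
}

#' Stimulus specification for the PRC protocol
#'
#' @param amplitude stimulus current amplitude (model units, >= 0).
#' @param duration pulse duration (model time units, > 0).
#' @param phases phase grid in (0, 1) (default 100 uniform phases).
#' @return a `stimulus_spec` object.
#' @export
stimulus_spec <- function(amplitude, duration,
                          phases = seq_len(100) / 101) {
  stopifnot_scalar(amplitude); stopifnot_scalar(duration)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (any(phases <= 0 | phases >= 1))
    stop("phases must lie in (0, 1)", call. = FALSE)
  structure(list(amplitude = amplitude, duration = duration,
                 phases = phases), class = "stimulus_spec")
}

# integrate the model with a constant stimulus current over [t0, t1],
# returning times, states and the beat-variable derivative at each point
integrate_piece <- function(model, state, t0, t1, I_stim, dt, rtol, atol) {
  times <- seq(t0, t1, by = dt)
  if (times[length(times)] < t1) times <- c(times, t1)
  f <- function(t, y, p) list(model$derivs(t, y, model$params, I_stim))
  out <- deSolve::lsoda(state, times, f, parms = NULL,
                        rtol = rtol, atol = atol)
  out
}

# refine an upward crossing inside [t_i, t_{i+1}] with cubic Hermite
# interpolation of the beat variable (values + derivatives at both ends)
refine_crossing <- function(t0, t1, v0, v1, d0, d1, level) {
  h <- t1 - t0
  hermite <- function(t) {
    s <- (t - t0) / h
    h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s); h11 <- s^2 * (s - 1)
    h00 * v0 + h10 * h * d0 + h01 * v1 + h11 * h * d1 - level
  }
  stats::uniroot(hermite, c(t0, t1), tol = 1e-12)$root
}

# beat (upward-crossing) times within an integration piece; returns times
# and the interpolated full state at each crossing
find_beats <- function(model, piece, I_stim, after = -Inf) {
  iv <- which(colnames(piece) == model$beat_var)
  v <- piece[, iv]; tt <- piece[, 1]
  lvl <- model$beat_level
  idx <- which(v[-length(v)] < lvl & v[-1] >= lvl)
  if (!length(idx)) return(list(times = numeric(0), states = list()))
  states <- list(); times <- numeric(0)
  for (i in idx) {
    st0 <- piece[i, -1]; st1 <- piece[i + 1, -1]
    d0 <- model$derivs(tt[i], st0, model$params, I_stim)
    d1 <- model$derivs(tt[i + 1], st1, model$params, I_stim)
    tc <- refine_crossing(tt[i], tt[i + 1], v[i], v[i + 1],
                          d0[iv - 1], d1[iv - 1], lvl)
    if (tc <= after + model$beat_lockout) next
    if (length(times) && tc <= times[length(times)] + model$beat_lockout)
      next
    s <- (tc - tt[i]) / (tt[i + 1] - tt[i])
    # Hermite-interpolated state at the crossing, per component
    h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s); h11 <- s^2 * (s - 1)
    hh <- tt[i + 1] - tt[i]
    sc <- h00 * st0 + h10 * hh * d0 + h01 * st1 + h11 * hh * d1
    times <- c(times, tc); states[[length(states) + 1]] <- sc
    after <- tc
  }
  list(times = times, states = states)
}

#' Measure a PRC from a simulated limit-cycle oscillator
#'
#' Implements the stimulus-at-phase protocol: run the model to its limit
#' cycle, measure the intrinsic period T0 from unperturbed cycles, then for
#' each phase in the grid restart from the beat-aligned state, deliver a
#' square current pulse at `phi * T0`, and record the perturbed cycle
#' length (beat-to-beat interval of the cycle containing the stimulus)
#' normalized by T0. Second-cycle aftereffects are not folded in: the maps
#' built on the PRC assume the cycle is re-established after one
#' perturbed cycle.
#'
#' @param model an `oscillator_model`.
#' @param stim a [stimulus_spec].
#' @param n_runin limit-cycle run-in, in beats (default 10).
#' @param n_period unperturbed cycles averaged for T0 (default 5).
#' @param dt output/search step for beat detection (model time units,
#'   default 0.05; crossings are refined by Hermite interpolation).
#' @param rtol,atol integration tolerances (defaults 1e-8, 1e-10).
#' @return a PRC sample table with attributes `"T0"` (intrinsic period) and
#'   `"beat_state"` (the beat-aligned state used).
#' @export
prc_from_oscillator <- function(model, stim, n_runin = 10, n_period = 5,
                                dt = 0.05, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "oscillator_model"),
            inherits(stim, "stimulus_spec"))
  need <- n_runin + n_period + 1
  state <- model$state0
  t_cur <- 0; beats <- numeric(0); states <- list()
  for (chunk in 1:40) {
    piece <- integrate_piece(model, state, t_cur, t_cur + 200, 0,
                             dt, rtol, atol)
    fb <- find_beats(model, piece, 0,
                     after = if (length(beats)) beats[length(beats)]
                             else -Inf)
    beats <- c(beats, fb$times); states <- c(states, fb$states)
    state <- piece[nrow(piece), -1]
    t_cur <- piece[nrow(piece), 1]
    if (length(beats) >= need) break
    if (chunk >= 5 && length(beats) < 2)
      stop("model not oscillating (no beat found)", call. = FALSE)
  }
  if (length(beats) < need)
    stop("model not oscillating (too few beats)", call. = FALSE)
  iv <- diff(beats)
  T0 <- mean(utils::tail(iv, n_period))
  s_beat <- states[[length(states)]]   # beat-aligned limit-cycle state

  ncl <- vapply(stim$phases, function(phi) {
    perturbed_cycle(model, s_beat, phi * T0, stim$amplitude,
                    stim$duration, T0, dt, rtol, atol) / T0
  }, numeric(1))
  out <- prc_samples(stim$phases, ncl)
  attr(out, "T0") <- T0
  attr(out, "beat_state") <- s_beat
  out
}

# one perturbed cycle: from the beat-aligned state, integrate to the pulse,
# through it, and on until the next beat; returns the beat-to-beat interval
perturbed_cycle <- function(model, s_beat, t_on, amp, dur, T0,
                            dt, rtol, atol) {
  t_max <- 5 * T0
  segs <- list(c(0, t_on, 0), c(t_on, t_on + dur, amp),
               c(t_on + dur, t_max, 0))
  state <- s_beat
  for (sg in segs) {
    if (sg[2] <= sg[1]) next
    piece <- integrate_piece(model, state, sg[1], sg[2], sg[3],
                             dt, rtol, atol)
    fb <- find_beats(model, piece, sg[3], after = 0)
    if (length(fb$times)) return(fb$times[1])
    state <- piece[nrow(piece), -1]
  }
  stop("model not oscillating (no beat within 5*T0 after the stimulus)",
       call. = FALSE)
}

#' Sensitivity of the PRC discontinuity to a model parameter
#'
#' Rebuilds the PRC for each scaling of the named parameter (a model
#' parameter, or `"amplitude"`/`"duration"` of the stimulus) and locates
#' the discontinuity. Scales at which the model fails to oscillate, or at
#' which no discontinuity exceeds the jump threshold, yield `NA`.
#'
#' @param model an `oscillator_model`.
#' @param stim a [stimulus_spec].
#' @param parameter parameter name to scale.
#' @param scale_grid multiplicative scales (default 0.4 to 1.4 by 0.1).
#' @param jump_threshold passed to [detect_discontinuity()].
#' @param ... passed to [prc_from_oscillator()].
#' @return `data.frame` with columns `scale`, `phi_r`; attribute `"pm30"`
#'   summarizes the change in phi_r at scales 0.7 and 1.3 relative to 1.0
#'   (when those scales are in the grid).
#' @export
phir_sensitivity <- function(model, stim, parameter,
                             scale_grid = seq(0.4, 1.4, by = 0.1),
                             jump_threshold = 0.15, ...) {
  known <- c(names(model$params), "amplitude", "duration")
  if (!parameter %in% known)
    stop("unknown parameter: ", parameter, call. = FALSE)
  phir <- vapply(scale_grid, function(sc) {
    m <- model; st <- stim
    if (parameter == "amplitude") st$amplitude <- st$amplitude * sc
    else if (parameter == "duration") st$duration <- st$duration * sc
    else m$params[[parameter]] <- m$params[[parameter]] * sc
    samples <- tryCatch(prc_from_oscillator(m, st, ...),
                        error = function(e) NULL)
    if (is.null(samples)) return(NA_real_)
    detect_discontinuity(samples, jump_threshold)
  }, numeric(1))
  out <- data.frame(scale = scale_grid, phi_r = phir)
  ref <- out$phi_r[abs(out$scale - 1) < 1e-9]
  lo <- out$phi_r[abs(out$scale - 0.7) < 1e-9]
  hi <- out$phi_r[abs(out$scale - 1.3) < 1e-9]
  if (length(ref) == 1)
    attr(out, "pm30") <- c(minus30 = if (length(lo)) lo - ref else NA_real_,
                           plus30 = if (length(hi)) hi - ref else NA_real_)
  out
}

#' Family of PRCs over a stimulus amplitude/duration sweep
#'
#' @param model an `oscillator_model`.
#' @param amplitudes,durations numeric vectors.
#' @param phases phase grid (default 100 uniform phases).
#' @param ... passed to [prc_from_oscillator()].
#' @return list of entries `list(amplitude, duration, samples, T0, phi_r)`,
#'   one per (amplitude, duration) pair.
#' @export
stimulus_sweep <- function(model, amplitudes, durations,
                           phases = seq_len(100) / 101, ...) {
  out <- list()
  for (amp in amplitudes) for (dur in durations) {
    samples <- tryCatch(
      prc_from_oscillator(model, stimulus_spec(amp, dur, phases), ...),
      error = function(e) NULL)
    out[[length(out) + 1]] <- list(
      amplitude = amp, duration = dur, samples = samples,
      T0 = if (is.null(samples)) NA_real_ else attr(samples, "T0"),
      phi_r = if (is.null(samples)) NA_real_
              else detect_discontinuity(samples))
  }
  out
}
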