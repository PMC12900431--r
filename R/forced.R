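#' Stimulus configuration for a periodically forced oscillator
#'
#' @param tau normalized pacing cycle length T_stim / T, > 0.
#' @param T intrinsic cycle length in seconds, > 0.
#' @param phi0 phase of the first stimulus in the oscillator's cycle, in
#'   \[0, 1).
#' @return a `stimulus_config` object.
#' @export
stimulus_config <- function(tau, T = 1, phi0 = 0) {
  stopifnot_scalar(tau); stopifnot_scalar(T); stopifnot_scalar(phi0)
  if (tau <= 0 || T <= 0) stop("`tau` and `T` must be > 0", call. = FALSE)
  if (phi0 < 0 || phi0 >= 1) stop("`phi0` must lie in [0, 1)", call. = FALSE)
  structure(list(tau = tau, T = T, phi0 = phi0), class = "stimulus_config")
}

#' One step of the forced-oscillator phase map
#'
#' The phase of stimulus i+1 in the oscillator's cycle is
#' `phi + tau - g(phi) (mod 1)`: the oscillator's cycle is rescaled to
#' g(phi) by the stimulus, and the next stimulus arrives tau later.
#'
#' @param phi phase(s) in \[0, 1).
#' @param tau normalized pacing cycle length.
#' @param prc a PRC object.
#' @return next phase(s), in \[0, 1).
#' @export
step_phase <- function(phi, tau, prc) {
  wrap01(phi + tau - eval_prc(prc, phi))
}

# single map step with beat bookkeeping. Returns next phase, triggered-beat
# count at the stimulus (phase jump reaching 1) and spontaneous-beat count
# before the next stimulus, plus the post-jump phase for event timing.
.step_beats <- function(phi, tau, g, tol = 1e-12) {
  u <- phi + 1 - g(phi)            # post-jump unwrapped phase, in (phi, 2)
  trig <- u >= 1 - tol
  q <- u - as.numeric(trig)
  if (q < 0) q <- 0
  v <- q + tau
  nsp <- floor(v + tol)
  nxt <- v - nsp
  if (nxt < 0) nxt <- 0
  if (nxt >= 1) nxt <- 0
  list(phi_next = nxt, triggered = as.integer(trig),
       n_spont = as.integer(nsp), q = q)
}

#' Long-term orbit of the forced-oscillator map
#'
#' Iterates the phase map, discards transients, and looks for a phase
#' recurrence within `tol` to classify the attractor as an N:M rhythm:
#' N stimuli per M oscillator beats over one period. M counts both triggered
#' beats (phase jumps reaching 1 at a stimulus) and spontaneous beats
#' (phase crossing 1 between stimuli). When no recurrence is found within
#' `n_max` iterates the orbit is flagged aperiodic (covering both chaos and
#' periods longer than `n_max`).
#'
#' @param config a [stimulus_config], or a bare `tau` (then `phi0 = 0`).
#' @param prc a PRC object.
#' @param n_transient iterates discarded before period detection.
#' @param n_max maximum period searched.
#' @param tol recurrence tolerance on the phase (default 1e-9).
#' @return an `orbit_result`: list with `phases` (the recurring phases, length
#'   N), `N`, `M`, `aperiodic`.
#' @export
iterate_orbit <- function(config, prc, n_transient = 1000, n_max = 50,
                          tol = 1e-9) {
  if (!inherits(config, "stimulus_config"))
    config <- stimulus_config(tau = config)
  tau <- config$tau
  g <- prc_fun(prc)
  phi <- config$phi0
  for (i in seq_len(n_transient)) phi <- .step_beats(phi, tau, g)$phi_next
  traj <- numeric(n_max + 1)
  traj[1] <- phi
  for (i in seq_len(n_max)) {
    phi <- .step_beats(phi, tau, g)$phi_next
    traj[i + 1] <- phi
  }
  d <- abs(traj[-1] - traj[1])
  d <- pmin(d, 1 - d)               # circular distance
  hit <- which(d < tol)
  if (!length(hit)) {
    return(structure(list(phases = traj[-1], N = NA_integer_,
                          M = NA_integer_, aperiodic = TRUE),
                     class = "orbit_result"))
  }
  N <- hit[1]
  phases <- traj[seq_len(N)]
  M <- 0L
  phi <- traj[1]
  for (i in seq_len(N)) {
    st <- .step_beats(phi, tau, g)
    M <- M + st$triggered + st$n_spont
    phi <- st$phi_next
  }
  structure(list(phases = phases, N = N, M = M, aperiodic = FALSE),
            class = "orbit_result")
}

#' @export
print.orbit_result <- function(x, ...) {
  if (x$aperiodic) cat("<orbit: aperiodic>\n")
  else cat(sprintf("<orbit: %d:%d locking, phases %s>\n", x$N, x$M,
                   paste(signif(x$phases, 6), collapse = ", ")))
  invisible(x)
}

#' Bifurcation diagram of the forced-oscillator map
#'
#' For each value of tau, iterates the map past a transient and records
#' `n_keep` successive phases.
#'
#' @param tau_grid numeric vector of tau values, all > 0.
#' @param prc a PRC object.
#' @param n_transient transient iterates discarded per tau.
#' @param n_keep phases kept per tau.
#' @param phi0 initial phase.
#' @return `data.frame` with columns `tau`, `phase`.
#' @export
bifurcation_diagram <- function(tau_grid, prc, n_transient = 1000,
                                n_keep = 100, phi0 = 0) {
  if (!length(tau_grid))
    return(data.frame(tau = numeric(0), phase = numeric(0)))
  if (any(tau_grid <= 0)) stop("tau values must be > 0", call. = FALSE)
  g <- prc_fun(prc)
  res <- lapply(tau_grid, function(tau) {
    phi <- phi0
    for (i in seq_len(n_transient)) phi <- .step_beats(phi, tau, g)$phi_next
    kept <- numeric(n_keep)
    for (i in seq_len(n_keep)) {
      kept[i] <- phi
      phi <- .step_beats(phi, tau, g)$phi_next
    }
    data.frame(tau = tau, phase = kept)
  })
  do.call(rbind, res)
}

#' Continuous-time event rendering of periodic stimulation
#'
#' Realizes the forced oscillator as a stream of timestamped events. The
#' oscillator phase advances at rate 1/T and emits a (spontaneous) beat each
#' time it reaches 1, resetting to 0. A stimulus landing at phase phi jumps
#' the phase to `phi + 1 - g(phi)`; a jump reaching 1 emits a triggered beat
#' at the stimulus time. The oscillator starts at phase 0 at time 0 and the
#' first stimulus is delivered at `phi0 * T`, so it lands at phase `phi0`.
#' Phases sampled at the stimulus times equal the iterates of the phase map.
#'
#' @param config a [stimulus_config].
#' @param prc a PRC object.
#' @param duration record length in seconds, > 0.
#' @param stim_end last time at which stimuli are delivered (default
#'   `duration`); the oscillator free-runs from `stim_end` to `duration`.
#' @return an `event_record`: list with `stimulus_times`, `beat_times`,
#'   `beat_kind` (`"triggered"` or `"spontaneous"`), `stimulus_phases` (map
#'   iterates at the stimuli), `T`, `tau`.
#' @export
render_events <- function(config, prc, duration, stim_end = duration) {
  stopifnot(inherits(config, "stimulus_config"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  T <- config$T; tau <- config$tau
  g <- prc_fun(prc)
  stim <- seq(config$phi0 * T, min(duration, stim_end), by = tau * T)
  beat_t <- numeric(0); beat_k <- character(0)
  phases <- numeric(length(stim))
  if (!length(stim)) {
    # no stimuli within the record: free-running beats every T
    bt <- seq(T, duration, by = T)
    return(structure(list(stimulus_times = numeric(0), beat_times = bt,
                          beat_kind = rep("spontaneous", length(bt)),
                          stimulus_phases = numeric(0), T = T, tau = tau),
                     class = "event_record"))
  }
  phi <- config$phi0
  for (k in seq_along(stim)) {
    phases[k] <- phi
    st <- .step_beats(phi, tau, g)
    if (st$triggered) {
      beat_t <- c(beat_t, stim[k]); beat_k <- c(beat_k, "triggered")
    }
    if (k < length(stim)) {
      if (st$n_spont > 0) {
        cross <- stim[k] + (seq_len(st$n_spont) - st$q) * T
        beat_t <- c(beat_t, cross)
        beat_k <- c(beat_k, rep("spontaneous", length(cross)))
      }
    } else {
      # past the last stimulus: free run from phase q to the end of record
      first <- stim[k] + (1 - st$q) * T
      if (first <= duration + 1e-12) {
        cross <- seq(first, duration + 1e-12, by = T)
        beat_t <- c(beat_t, cross)
        beat_k <- c(beat_k, rep("spontaneous", length(cross)))
      }
    }
    phi <- st$phi_next
  }
  o <- order(beat_t)
  structure(list(stimulus_times = stim, beat_times = beat_t[o],
                 beat_kind = beat_k[o], stimulus_phases = phases,
                 T = T, tau = tau),
            class = "event_record")
}

#' Tagged inter-event intervals of a paced recording
#'
#' Computes the four interval families used to visualize entrainment in
#' paced-oscillator recordings: stimulus-stimulus (SS), stimulus to next
#' action potential (S-AP), action potential to next stimulus (AP-S), and
#' consecutive action potentials (AP-AP). A stimulus that triggers a beat at
#' the same timestamp is ordered before the beat, so the corresponding S-AP
#' interval is 0.
#'
#' @param events an `event_record` (or any list with `stimulus_times` and
#'   `beat_times`).
#' @return `data.frame` with columns `time` (interval start), `interval`,
#'   `type` (one of `"SS"`, `"S-AP"`, `"AP-S"`, `"AP-AP"`); empty when there
#'   are fewer than two events in total.
#' @export
classify_event_intervals <- function(events) {
  s <- sort(events$stimulus_times)
  b <- sort(events$beat_times)
  empty <- data.frame(time = numeric(0), interval = numeric(0),
                      type = character(0))
  if (length(s) + length(b) < 2) return(empty)
  out <- list(empty)
  if (length(s) >= 2)
    out <- c(out, list(data.frame(time = s[-length(s)], interval = diff(s),
                                  type = "SS")))
  if (length(b) >= 2)
    out <- c(out, list(data.frame(time = b[-length(b)], interval = diff(b),
                                  type = "AP-AP")))
  if (length(s) && length(b)) {
    # stimulus ordered first at ties: next beat at time >= stimulus time
    nb <- vapply(s, function(t) {
      i <- which(b >= t)
      if (length(i)) b[i[1]] - t else NA_real_
    }, numeric(1))
    ok <- !is.na(nb)
    if (any(ok))
      out <- c(out, list(data.frame(time = s[ok], interval = nb[ok],
                                    type = "S-AP")))
    ns <- vapply(b, function(t) {
      i <- which(s > t)
      if (length(i)) s[i[1]] - t else NA_real_
    }, numeric(1))
    ok <- !is.na(ns)
    if (any(ok))
      out <- c(out, list(data.frame(time = b[ok], interval = ns[ok],
                                    type = "AP-S")))
  }
  res <- do.call(rbind, out)
  res[order(res$time, res$type), , drop = FALSE]
}
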