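#' Parameters of the modulated parasystole model
#'
#' The model has a sinus pacemaker of period `t_s` (never reset), an ectopic
#' pacemaker of period `t_e` modulated by conducted sinus beats through a PRC,
#' a refractory period `theta` gating the expression of ectopic beats, and a
#' conduction delay `t_lag = t_in + t_out` into and out of the ectopic focus:
#' a conducted sinus beat reaches the focus `t_in` seconds after it appears on
#' the surface record, and an ectopic firing is expressed as a V beat `t_out`
#' seconds after the focus fires.
#'
#' Blocking rules: an ectopic arrival is expressed only if it falls at least
#' `theta` after the most recent expressed beat of either type (an arrival
#' coincident with a sinus beat is blocked; the sinus wins). The first sinus
#' beat after an expressed ectopic beat is blocked (compensatory pause),
#' and blocked sinus beats do not conduct to the focus.
#'
#' @param t_s sinus period in seconds: a positive scalar, or a
#'   `data.frame(time, value)` piecewise-constant schedule (`value` applies
#'   from `time` onward).
#' @param t_e ectopic period in seconds, > 0.
#' @param theta refractory period: a positive scalar (< every `t_s`), or a
#'   list `list(m =, c =, epsilon =)` defining the linear refractory function
#'   `theta(t_s) = (t_s - c)/m - epsilon`.
#' @param t_lag total conduction delay in seconds, >= 0 and < `t_e`.
#' @param prc a PRC object.
#' @param t_in,t_out split of `t_lag` (defaults: half each; only the sum
#'   enters the phase map).
#' @return a `parasystole_params` object.
#' @export
parasystole_params <- function(t_s, t_e, theta, t_lag, prc,
                               t_in = t_lag / 2, t_out = t_lag - t_in) {
  stopifnot_scalar(t_e); stopifnot_scalar(t_lag)
  if (t_e <= 0) stop("`t_e` must be > 0", call. = FALSE)
  if (t_lag < 0) stop("`t_lag` must be >= 0", call. = FALSE)
  if (t_lag >= t_e) stop("`t_lag` must be < `t_e`", call. = FALSE)
  if (abs(t_in + t_out - t_lag) > 1e-12 || t_in < 0 || t_out < 0)
    stop("`t_in` + `t_out` must equal `t_lag`, both >= 0", call. = FALSE)
  if (is.data.frame(t_s)) {
    if (!all(c("time", "value") %in% names(t_s)) || !nrow(t_s))
      stop("`t_s` schedule needs columns `time`, `value`", call. = FALSE)
    if (any(t_s$value <= 0)) stop("sinus periods must be > 0", call. = FALSE)
    if (is.unsorted(t_s$time)) stop("schedule times must be sorted", call. = FALSE)
    ts_vals <- t_s$value
  } else {
    stopifnot_scalar(t_s)
    if (t_s <= 0) stop("`t_s` must be > 0", call. = FALSE)
    ts_vals <- t_s
  }
  th_vals <- vapply(ts_vals, function(ts) eval_theta(theta, ts), numeric(1))
  if (any(th_vals <= 0))
    stop("refractory period must be > 0 over the t_s schedule", call. = FALSE)
  # theta >= t_s is permitted: it is the fully blocked limit in which no
  # ectopic beat can ever be expressed (useful for burden bounds)
  if (!inherits(prc, "prc")) stop("`prc` must be a PRC object", call. = FALSE)
  structure(list(t_s = t_s, t_e = t_e, theta = theta, t_lag = t_lag,
                 t_in = t_in, t_out = t_out, prc = prc),
            class = "parasystole_params")
}

# refractory period at a given sinus period
eval_theta <- function(theta, ts) {
  if (is.numeric(theta)) theta
  else (ts - theta$c) / theta$m - theta$epsilon
}

# sinus period at time t for scalar-or-schedule t_s
eval_ts <- function(t_s, t) {
  if (!is.data.frame(t_s)) return(t_s)
  i <- findInterval(t, t_s$time)
  t_s$value[pmax(i, 1L)]
}

#' One step of the modulated-parasystole phase map
#'
#' `phi` is the phase of a sinus beat in the ectopic cycle, referenced to the
#' expressed ectopic beat time (surface record). When
#' `phi < (t_s - theta)/t_e` the preceding ectopic firing fell more than
#' `theta` after the prior sinus beat, so it was expressed and the current
#' sinus beat is blocked: the phase advances by `t_s/t_e` with no resetting.
#' Otherwise the ectopic firing was blocked, the sinus beat conducts, and the
#' focus is reset through the PRC evaluated at the conduction-shifted phase
#' `phi + t_lag/t_e`.
#'
#' @param phi phase in \[0, 1).
#' @param params a [parasystole_params] with scalar `t_s`.
#' @return list with `phase` (next phase), `branch` (1 or 2), `context`
#'   (`"V(N)"` blocked sinus after an expressed ectopic beat, `"(V)N"` sinus
#'   preceded by a blocked ectopic firing, `"N"` plain sinus beat), and
#'   `stim_after_firing` (TRUE when the shifted phase reaches past 1, i.e.
#'   the stimulus arrives after the focus has fired; the map then applies the
#'   PRC in the new cycle, mirroring the event simulator).
#' @export
step_sinus_phase <- function(phi, params, ...) {
  stopifnot(inherits(params, "parasystole_params"))
  if (!is.numeric(phi) || phi < 0 || phi >= 1)
    stop("`phi` must lie in [0, 1)", call. = FALSE)
  ts <- eval_ts(params$t_s, 0)
  if (length(ts) != 1) stop("map form requires scalar `t_s`", call. = FALSE)
  th <- eval_theta(params$theta, ts)
  te <- params$t_e
  rho <- ts / te
  thr <- (ts - th) / te
  if (phi < thr) {
    return(list(phase = wrap01(phi + rho), branch = 1L, context = "V(N)",
                stim_after_firing = FALSE))
  }
  arg <- phi + params$t_lag / te
  flag <- arg >= 1
  gval <- eval_prc(params$prc, wrap01(arg))
  ctx <- if (phi < rho) "(V)N" else "N"
  list(phase = wrap01(phi + rho + 1 - gval), branch = 2L, context = ctx,
       stim_after_firing = flag)
}

#' Event-level simulation of modulated parasystole
#'
#' Simulates the competing pacemakers as timestamped events. The sinus node
#' fires every `t_s` (never reset). The ectopic focus advances at rate
#' `1/t_e` and fires when its phase reaches 1; each firing conducts out and
#' arrives `t_out` later, where it is expressed as a V beat iff it falls at
#' least `theta` after the most recent expressed beat. A sinus beat is
#' blocked iff an expressed V occurred since the previous sinus beat
#' (compensatory pause); every expressed sinus beat conducts into the focus,
#' arriving `t_in` later and resetting the focus phase by `+1 - g(phase)`
#' (a jump reaching 1 fires the focus immediately). Blocked beats are
#' retained in the output with `expressed = FALSE`.
#'
#' @param params a [parasystole_params].
#' @param duration record length in seconds.
#' @param t_start start time of the record (default 0).
#' @param sinus_anchor time of the first sinus beat (default `t_start`).
#' @param ectopic_phase0 focus phase at `t_start`, in \[0, 1) (default 0).
#' @param record_phases if TRUE, attach per-sinus-beat focus phases and
#'   map-referenced phases (attribute `"sinus_phases"`) for map/event
#'   comparison.
#' @param init_last_expressed time of the most recent expressed beat before
#'   `t_start` (refractory reference; default `-Inf`).
#' @param init_v_since_sinus TRUE when an expressed V occurred after the
#'   last sinus beat before `t_start`, so the first simulated sinus beat is
#'   blocked (default FALSE). Together with `ectopic_phase0` this lets a
#'   simulation be anchored at an observed PVC.
#' @param sinus_times optional vector of explicit sinus beat times (driven
#'   mode, used when fitting to a measured record: the sinus stream is taken
#'   from the data instead of the `t_s` clock; `t_s` then only enters the
#'   refractory function).
#' @return a `beat_record` (see [beat_record]) with attribute
#'   `"n_firings"` (ectopic pacemaker firings, expressed or not) and,
#'   optionally, `"sinus_phases"`.
#' @export
simulate_beats <- function(params, duration, t_start = 0,
                           sinus_anchor = t_start, ectopic_phase0 = 0,
                           record_phases = FALSE,
                           init_last_expressed = -Inf,
                           init_v_since_sinus = FALSE,
                           sinus_times = NULL) {
  stopifnot(inherits(params, "parasystole_params"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  te <- params$t_e; t_in <- params$t_in; t_out <- params$t_out
  g <- prc_fun(params$prc)
  t_end <- t_start + duration

  n_guess <- max(64L, ceiling(duration / min(eval_ts(params$t_s, t_start), te) * 3))
  bt <- numeric(n_guess); bl <- character(n_guess); bx <- logical(n_guess)
  nb <- 0L
  push_beat <- function(t, lab, expr) {
    nb <<- nb + 1L
    if (nb > length(bt)) {
      bt <<- c(bt, numeric(length(bt))); bl <<- c(bl, character(length(bl)))
      bx <<- c(bx, logical(length(bx)))
    }
    bt[nb] <<- t; bl[nb] <<- lab; bx[nb] <<- expr
  }
  ph_t <- numeric(0); ph_focus <- numeric(0); ph_map <- numeric(0)

  driven <- !is.null(sinus_times)
  if (driven) {
    sinus_times <- sort(sinus_times)
    sin_i <- 1L
    t_sin <- if (length(sinus_times)) sinus_times[1] else Inf
  } else {
    t_sin <- sinus_anchor
  }
  p_ref <- ectopic_phase0; t_ref <- t_start
  t_fire <- t_ref + (1 - p_ref) * te
  stim_q <- numeric(0)   # pending conducted-sinus arrivals at the focus
  varr_q <- numeric(0)   # pending ectopic arrivals at the heart
  last_expr <- init_last_expressed
  v_since_sinus <- init_v_since_sinus
  n_fir <- 0L

  repeat {
    cand_t <- c(t_fire, t_sin,
                if (length(stim_q)) stim_q[1] else Inf,
                if (length(varr_q)) varr_q[1] else Inf)
    # which.min takes the first minimum: ties resolve as FIRE < SIN < STIM
    # < VARR, so a coincident ectopic arrival sees the sinus beat already
    # expressed (sinus wins) and a stimulus lands in the post-firing cycle
    ev <- which.min(cand_t)
    tt <- cand_t[ev]
    if (tt > t_end) break
    if (ev == 1L) {                     # focus fires
      n_fir <- n_fir + 1L
      p_ref <- 0; t_ref <- tt
      t_fire <- tt + te
      varr_q <- c(varr_q, tt + t_out)
    } else if (ev == 2L) {              # sinus beat
      expr <- !v_since_sinus
      push_beat(tt, "N", expr)
      if (record_phases) {
        p <- p_ref + (tt - t_ref) / te
        ph_t <- c(ph_t, tt); ph_focus <- c(ph_focus, p)
        ph_map <- c(ph_map, wrap01(p - t_out / te))
      }
      if (expr) {
        last_expr <- tt
        stim_q <- c(stim_q, tt + t_in)
      }
      v_since_sinus <- FALSE
      if (driven) {
        sin_i <- sin_i + 1L
        t_sin <- if (sin_i <= length(sinus_times)) sinus_times[sin_i] else Inf
      } else {
        t_sin <- tt + eval_ts(params$t_s, tt)
      }
    } else if (ev == 3L) {              # conducted sinus reaches the focus
      stim_q <- stim_q[-1]
      p <- p_ref + (tt - t_ref) / te
      if (p >= 1) p <- 1 - 1e-15       # guard: firing has priority at ties
      pn <- p + 1 - g(p)
      if (pn >= 1 - 1e-12) {            # reset fires the focus immediately
        n_fir <- n_fir + 1L
        varr_q <- c(varr_q, tt + t_out)
        pn <- pn - 1
        if (pn < 0) pn <- 0
      }
      p_ref <- pn; t_ref <- tt
      t_fire <- tt + (1 - pn) * te
    } else {                            # ectopic arrival at the heart
      varr_q <- varr_q[-1]
      th <- eval_theta(params$theta, eval_ts(params$t_s, tt))
      expr <- (tt - last_expr) >= th - 1e-12
      push_beat(tt, "V", expr)
      if (expr) {
        last_expr <- tt
        v_since_sinus <- TRUE
      }
    }
  }
  rec <- beat_record(bt[seq_len(nb)], bl[seq_len(nb)], bx[seq_len(nb)])
  attr(rec, "n_firings") <- n_fir
  if (record_phases)
    attr(rec, "sinus_phases") <-
      data.frame(time = ph_t, phi_focus = ph_focus, phi_map = ph_map)
  rec
}

#' Sinus-to-ectopic locking ratio of the parasystole model
#'
#' Iterates the parasystole phase map past a transient and detects the
#' attractor period by phase recurrence. The ratio is N sinus cycles per M
#' ectopic cycles, where M counts ectopic pacemaker firings per orbit period
#' whether expressed or blocked (2:1 locking can coexist with a zero PVC
#' burden when every firing falls in the refractory period). M is the number
#' of phase wraps accumulated over one orbit period, which equals the firing
#' count in the event rendering.
#'
#' @param params a [parasystole_params] with scalar `t_s`.
#' @param n_transient transient iterates discarded.
#' @param n_max maximum period searched.
#' @param phi0 initial phase.
#' @param tol recurrence tolerance (default 1e-9).
#' @return an `orbit_result` with `N` sinus cycles and `M` ectopic cycles.
#' @export
locking_ratio <- function(params, n_transient = 1000, n_max = 50,
                          phi0 = 0, tol = 1e-9) {
  step_adv <- function(phi) {
    st <- step_sinus_phase(phi, params)
    ts <- eval_ts(params$t_s, 0); te <- params$t_e
    adv <- if (st$branch == 1L) ts / te
           else ts / te + 1 - eval_prc(params$prc,
                                       wrap01(phi + params$t_lag / te))
    list(phase = st$phase, adv = adv)
  }
  phi <- phi0
  for (i in seq_len(n_transient)) phi <- step_adv(phi)$phase
  traj <- numeric(n_max + 1); traj[1] <- phi
  for (i in seq_len(n_max)) {
    phi <- step_adv(phi)$phase
    traj[i + 1] <- phi
  }
  d <- abs(traj[-1] - traj[1]); d <- pmin(d, 1 - d)
  hit <- which(d < tol)
  if (!length(hit))
    return(structure(list(phases = traj[-1], N = NA_integer_,
                          M = NA_integer_, aperiodic = TRUE),
                     class = "orbit_result"))
  N <- hit[1]
  phi <- traj[1]; total <- 0
  for (i in seq_len(N)) {
    st <- step_adv(phi)
    total <- total + st$adv
    phi <- st$phase
  }
  structure(list(phases = traj[seq_len(N)], N = N, M = as.integer(round(total)),
                 aperiodic = FALSE),
            class = "orbit_result")
}
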