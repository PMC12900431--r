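#' Generate noisy PRC samples from a known curve
#'
#' Draws stimulus phases uniformly on (0, 1) and adds Gaussian measurement
#' noise to the true normalized cycle lengths, emulating the scatter of
#' optically measured spheroid PRCs. Non-positive noisy values (possible
#' only in pathological noise regimes) are redrawn.
#'
#' @param truth a PRC object.
#' @param n number of samples.
#' @param noise_sd Gaussian noise s.d. on ncl (dimensionless).
#' @param seed integer seed (optional).
#' @return a PRC sample table, sorted by phase.
#' @export
gen_prc_samples <- function(truth, n, noise_sd = 0.056, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  with_seed(seed, {
    phase <- sort(stats::runif(n, 0, 1 - 1e-9))
    ncl <- eval_prc(truth, phase) + stats::rnorm(n, 0, noise_sd)
    bad <- which(ncl <= 0)
    while (length(bad)) {
      ncl[bad] <- eval_prc(truth, phase[bad]) +
        stats::rnorm(length(bad), 0, noise_sd)
      bad <- which(ncl <= 0)
    }
    prc_samples(phase, ncl)
  })
}

#' Pacing protocol specification
#'
#' Describes one paced-recording run: an initial spontaneous segment, a
#' paced segment at a stimulus frequency defined by the ratio
#' `R = spontaneous frequency / stimulus frequency` (so the stimulus period
#' is `R * T` and `R` equals the normalized pacing cycle length tau), and a
#' final spontaneous recovery segment.
#'
#' @param R ratio of spontaneous to stimulus frequency, > 0.
#' @param spontaneous,paced,recovery segment durations in seconds
#'   (defaults 30, 60, 30).
#' @return a `pacing_protocol` object.
#' @export
pacing_protocol_spec <- function(R, spontaneous = 30, paced = 60,
                                 recovery = 30) {
  stopifnot_scalar(R)
  if (R <= 0) stop("`R` must be > 0", call. = FALSE)
  if (spontaneous < 0 || paced <= 0 || recovery < 0)
    stop("invalid segment plan", call. = FALSE)
  structure(list(R = R, spontaneous = spontaneous, paced = paced,
                 recovery = recovery), class = "pacing_protocol")
}

#' Generate a paced-spheroid event record
#'
#' Renders a spontaneous / paced / recovery recording of an oscillator with
#' the given PRC: beats every `T` in the spontaneous segments, the forced
#' dynamics during pacing, with optional Gaussian timing jitter added to the
#' beat times afterwards (stimulus times are device-controlled and exact).
#'
#' @param prc a PRC object.
#' @param protocol a [pacing_protocol_spec].
#' @param T intrinsic cycle length in seconds.
#' @param jitter_sd beat-time jitter s.d. in seconds (default 0).
#' @param seed integer seed (optional).
#' @return an `event_record` with attribute `"segments"` giving the segment
#'   boundaries.
#' @export
gen_paced_record <- function(prc, protocol, T, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  d1 <- protocol$spontaneous; d2 <- protocol$paced; d3 <- protocol$recovery
  tau <- protocol$R
  # spontaneous beats on (0, d1]
  b1 <- if (d1 >= T) seq(T, d1 + 1e-12, by = T) else numeric(0)
  p1 <- wrap01(d1 / T)   # oscillator phase when pacing starts
  # paced + recovery rendered in oscillator-native time then shifted so the
  # first stimulus falls exactly at d1 (where the phase is p1)
  shift <- d1 - p1 * T
  ev <- render_events(stimulus_config(tau, T, p1), prc,
                      duration = p1 * T + d2 + d3,
                      stim_end = p1 * T + d2)
  keep_b <- ev$beat_times > p1 * T + 1e-12
  beats <- c(b1, ev$beat_times[keep_b] + shift)
  kinds <- c(rep("spontaneous", length(b1)), ev$beat_kind[keep_b])
  stims <- ev$stimulus_times + shift
  with_seed(seed, {
    if (jitter_sd > 0) {
      beats <- beats + stats::rnorm(length(beats), 0, jitter_sd)
      o <- order(beats); beats <- beats[o]; kinds <- kinds[o]
    }
    structure(list(stimulus_times = stims, beat_times = beats,
                   beat_kind = kinds, stimulus_phases = ev$stimulus_phases,
                   T = T, tau = tau,
                   segments = data.frame(
                     segment = c("spontaneous", "paced", "recovery"),
                     start = c(0, d1, d1 + d2),
                     end = c(d1, d1 + d2, d1 + d2 + d3))),
              class = "event_record")
  })
}

#' Specification of a synthetic Holter-like record
#'
#' Bundles the parasystole parameters with the features of real multi-hour
#' ambulatory records that the inference pipeline must cope with: a slowly
#' drifting sinus period (sinusoid plus first-order autoregressive noise,
#' emulating autonomic variation), annotation timing jitter, and a PVC
#' morphology mix.
#'
#' @param t_e ectopic period, seconds.
#' @param t_lag total conduction delay, seconds.
#' @param phi_r PRC discontinuity phase.
#' @param S PRC tail slope (the PRC is the linear-tail family unless `prc`
#'   is supplied).
#' @param theta refractory specification, scalar or `list(m=, c=, epsilon=)`.
#' @param t_s_base base sinus period, seconds.
#' @param duration record length, seconds (default 7200).
#' @param drift_amplitude sinusoidal t_s drift amplitude, seconds
#'   (default 0.12).
#' @param drift_period drift period, seconds (default 3600).
#' @param ar_sd stationary s.d. of the AR(1) component of t_s, seconds
#'   (default 0.015).
#' @param ar_phi AR(1) coefficient (default 0.8).
#' @param ts_update t_s schedule resolution, seconds (default 30).
#' @param jitter_sd annotation timing jitter s.d., seconds (default 0.01).
#' @param morph_mix named proportions of V-beat morphologies (must sum
#'   to 1; default `c(A = 0.9, B = 0.1)`).
#' @param prc optional PRC object overriding the linear-tail default.
#' @param seed integer seed.
#' @return a `holter_spec` object.
#' @export
holter_spec <- function(t_e = 1.8, t_lag = 0.15, phi_r = 0.65, S = 0.5,
                        theta = list(m = 2.5, c = -0.25, epsilon = 0.05),
                        t_s_base = 0.72, duration = 7200,
                        drift_amplitude = 0.12, drift_period = 3600,
                        ar_sd = 0.015, ar_phi = 0.8, ts_update = 30,
                        jitter_sd = 0.01, morph_mix = c(A = 0.9, B = 0.1),
                        prc = NULL, seed = NULL) {
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  if (abs(sum(morph_mix) - 1) > 1e-8)
    stop("`morph_mix` proportions must sum to 1", call. = FALSE)
  if (is.null(prc)) prc <- prc_linear_tail(phi_r, S)
  structure(list(t_e = t_e, t_lag = t_lag, phi_r = phi_r, S = S,
                 theta = theta, t_s_base = t_s_base, duration = duration,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, ar_sd = ar_sd,
                 ar_phi = ar_phi, ts_update = ts_update,
                 jitter_sd = jitter_sd, morph_mix = morph_mix,
                 prc = prc, seed = seed),
            class = "holter_spec")
}

#' Generate a synthetic Holter-like beat record
#'
#' Simulates modulated parasystole under a drifting sinus period, drops
#' blocked beats (real annotation streams contain only expressed beats),
#' jitters the annotation times, and assigns morphology labels to the
#' expressed V beats according to the specified mix.
#'
#' @param spec a [holter_spec].
#' @return a [beat_record] with a `morph` column and attribute `"truth"`
#'   (the generating spec, including the realized t_s schedule).
#' @export
gen_holter_record <- function(spec) {
  stopifnot(inherits(spec, "holter_spec"))
  with_seed(spec$seed, {
    tt <- seq(0, spec$duration, by = spec$ts_update)
    ar <- numeric(length(tt))
    if (spec$ar_sd > 0) {
      innov_sd <- spec$ar_sd * sqrt(1 - spec$ar_phi^2)
      ar[1] <- stats::rnorm(1, 0, spec$ar_sd)
      for (k in seq_along(tt)[-1])
        ar[k] <- spec$ar_phi * ar[k - 1] + stats::rnorm(1, 0, innov_sd)
    }
    ts_vals <- spec$t_s_base +
      spec$drift_amplitude * sin(2 * pi * tt / spec$drift_period) + ar
    sched <- data.frame(time = tt, value = ts_vals)
    pp <- parasystole_params(sched, spec$t_e, spec$theta, spec$t_lag,
                             spec$prc)
    rec <- simulate_beats(pp, spec$duration)
    eb <- rec[rec$expressed, , drop = FALSE]
    times <- eb$time + stats::rnorm(nrow(eb), 0, spec$jitter_sd)
    o <- order(times)
    times <- times[o]; labels <- eb$label[o]
    # jitter must not reorder beats; nudge any collision apart
    while (any(diff(times) <= 0)) {
      i <- which(diff(times) <= 0)
      times[i + 1] <- times[i] + 1e-6
    }
    morph <- rep(NA_character_, length(times))
    vi <- which(labels == "V")
    if (length(vi))
      morph[vi] <- sample(names(spec$morph_mix), length(vi), replace = TRUE,
                          prob = spec$morph_mix)
    out <- beat_record(times, labels, TRUE, morph)
    attr(out, "truth") <- c(unclass(spec)[setdiff(names(unclass(spec)),
                                                  "prc")],
                            list(ts_schedule = sched))
    out
  })
}
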