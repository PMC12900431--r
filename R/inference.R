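#' Screen a beat record for parasystole analysis
#'
#' Two screens are applied, mirroring the selection of clinical records
#' suitable for parasystole modelling: (i) a dominant PVC morphology —
#' the most frequent morphology id must account for more than 80% of V
#' beats; (ii) presence of cycling (sawtooth) coupling intervals, the
#' hallmark of modulated parasystole as opposed to fixed-coupling ectopy.
#'
#' @param record a [beat_record]; morphology screening needs a `morph`
#'   column and at least 20 V beats.
#' @param min_fraction dominant-morphology threshold (default 0.80,
#'   exceeded strictly).
#' @param ... passed to [detect_cycling_windows()].
#' @return a `screen_report`: list with `dominant_morphology_fraction`,
#'   `cycling_segments` (data.frame `start`, `end`), `passes_morphology`,
#'   `passes_cycling`.
#' @export
screen_record <- function(record, min_fraction = 0.80, ...) {
  eb <- expressed_beats(record)
  vb <- eb[eb$label == "V", , drop = FALSE]
  if (!"morph" %in% names(eb) || all(is.na(vb$morph))) {
    warning("no morphology ids: morphology screen skipped")
    frac <- NA_real_; pass_m <- NA
  } else {
    if (nrow(vb) < 20)
      stop("morphology screening needs at least 20 V beats", call. = FALSE)
    tab <- table(vb$morph)
    frac <- max(tab) / sum(tab)
    pass_m <- frac > min_fraction
  }
  cyc <- detect_cycling_windows(record, ...)
  structure(list(dominant_morphology_fraction = frac,
                 cycling_segments = cyc,
                 passes_morphology = pass_m,
                 passes_cycling = nrow(cyc) > 0),
            class = "screen_report")
}

#' Detect windows with cycling coupling intervals
#'
#' Slides a window across the record and flags it when the PVC coupling
#' intervals show the sawtooth progression characteristic of modulated
#' parasystole: enough PVCs, sufficient coupling-interval range, and at
#' least `min_runs` maximal monotone runs (of at least `min_run` coupling
#' values) sharing the same direction.
#'
#' @param record a [beat_record].
#' @param window window length in seconds (default 30).
#' @param stride window stride in seconds (default 15).
#' @param min_v minimum V beats per window (default 6).
#' @param min_range minimum coupling-interval range in seconds (default 0.12).
#' @param min_run minimum length (in coupling values) of a monotone run
#'   (default 3).
#' @param min_runs minimum number of same-direction monotone runs (default 2).
#' @return `data.frame` with columns `start`, `end`; zero rows when no
#'   window qualifies. Overlapping flagged windows are returned as flagged.
#' @export
detect_cycling_windows <- function(record, window = 30, stride = 15,
                                   min_v = 6, min_range = 0.12,
                                   min_run = 3, min_runs = 2) {
  cp <- interval_series(record)$coupling
  out <- data.frame(start = numeric(0), end = numeric(0))
  if (nrow(cp) < min_v) return(out)
  t0 <- min(record$time); t1 <- max(record$time)
  starts <- seq(t0, max(t0, t1 - window), by = stride)
  for (s in starts) {
    ci <- cp$ci[cp$time >= s & cp$time < s + window]
    if (length(ci) < min_v) next
    if (diff(range(ci)) <= min_range) next
    dr <- sign(diff(ci))
    dr <- dr[dr != 0]
    if (!length(dr)) next
    r <- rle(dr)
    # run of k same-sign increments spans k+1 coupling values
    long <- r$lengths >= (min_run - 1)
    up <- sum(long & r$values > 0); dn <- sum(long & r$values < 0)
    if (max(up, dn) >= min_runs)
      out <- rbind(out, data.frame(start = s, end = s + window))
  }
  out
}

#' Per-window sinus period
#'
#' Median NN interval (consecutive expressed sinus beats) in fixed windows.
#' Windows with fewer than `min_nn` NN intervals are skipped.
#'
#' @param record a [beat_record].
#' @param window window length in seconds (default 30).
#' @param min_nn minimum NN intervals per window (default 3).
#' @return `data.frame` with columns `window_start`, `t_s`, `n_nn`.
#' @export
estimate_sinus_period <- function(record, window = 30, min_nn = 3) {
  iv <- interval_series(record)$intervals
  nn <- iv[iv$type == "NN", , drop = FALSE]
  t0 <- min(record$time)
  starts <- seq(t0, max(record$time), by = window)
  res <- lapply(starts, function(s) {
    x <- nn$interval[nn$time >= s & nn$time < s + window]
    if (length(x) < min_nn) return(NULL)
    data.frame(window_start = s, t_s = stats::median(x), n_nn = length(x))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(window_start = numeric(0), t_s = numeric(0),
                               n_nn = integer(0))
  else out
}

# NIB=1 episodes: indices i of expressed beats with pattern V N V
nib1_episodes <- function(eb) {
  n <- nrow(eb)
  if (n < 3) return(integer(0))
  l <- eb$label
  which(l[seq_len(n - 2)] == "V" & l[seq_len(n - 2) + 1] == "N" &
          l[seq_len(n - 2) + 2] == "V")
}

# NIB=2 episodes: indices i with pattern V N N V
nib2_episodes <- function(eb) {
  n <- nrow(eb)
  if (n < 4) return(integer(0))
  l <- eb$label
  which(l[seq_len(n - 3)] == "V" & l[seq_len(n - 3) + 1] == "N" &
          l[seq_len(n - 3) + 2] == "N" & l[seq_len(n - 3) + 3] == "V")
}

#' Estimate the post-discontinuity PRC slope from bigeminy
#'
#' During runs of NIB = 1 (a single sinus beat between two ectopic beats)
#' the modified ectopic cycle VV is linear in the VN interval with slope
#' equal to the resetting-curve tail slope S:
#' `VV = g((VN + t_lag)/t_e) * t_e` is affine in VN on the linear tail.
#' Ordinary least squares of VV on VN therefore estimates S.
#'
#' @param record a [beat_record].
#' @param min_pairs minimum number of (VN, VV) pairs (default 3).
#' @return list with `S` (slope), `intercept`, `n` (pairs used), and `pairs`
#'   (the data.frame of VN and VV).
#' @export
estimate_slope_S <- function(record, min_pairs = 3) {
  eb <- expressed_beats(record)
  idx <- nib1_episodes(eb)
  if (length(idx) < min_pairs)
    stop("need at least ", min_pairs, " NIB=1 episodes to estimate S",
         call. = FALSE)
  vn <- eb$time[idx + 1] - eb$time[idx]
  vv <- eb$time[idx + 2] - eb$time[idx]
  cf <- stats::lm.fit(cbind(1, vn), vv)$coefficients
  if (any(!is.finite(cf))) cf <- c(mean(vv), 0)
  list(S = unname(cf[2]), intercept = unname(cf[1]), n = length(idx),
       pairs = data.frame(vn = vn, vv = vv))
}

#' Estimate the refractory period as a function of sinus period
#'
#' The shortest coupling intervals observed at a given sinus period trace
#' out the refractory bound. Coupling intervals are binned by the local
#' sinus period (bin width 0.1 s); in each sufficiently populated bin the
#' 5th percentile of the coupling-interval distribution is taken; a linear
#' regression of t_s on these percentile values, `t_s = m * CI + c`, yields
#' the refractory evaluator `theta(t_s) = (t_s - c)/m - epsilon` with a
#' fixed safety margin `epsilon` (default 0.05 s).
#'
#' @param record a [beat_record].
#' @param bin_width t_s bin width in seconds (default 0.1).
#' @param epsilon safety margin in seconds (default 0.05).
#' @param min_per_bin minimum coupling intervals per bin (default 20).
#' @param min_bins minimum populated bins (default 3).
#' @param window window for the local sinus period (default 30 s).
#' @return list with `m`, `c`, `epsilon`, `theta` (the evaluator, a
#'   function of t_s), `sim` (the coefficient list with the margin set to
#'   zero — the envelope form recommended for model simulation, see
#'   Details), and `bins` (per-bin t_s location, 5th percentile, count).
#' @export
estimate_refractory <- function(record, bin_width = 0.1, epsilon = 0.05,
                                min_per_bin = 20, min_bins = 3,
                                window = 30) {
  cp <- interval_series(record)$coupling
  tsw <- estimate_sinus_period(record, window = window)
  if (!nrow(cp) || !nrow(tsw))
    stop("not enough data to estimate the refractory period", call. = FALSE)
  # local sinus period of the window containing each PVC
  wi <- findInterval(cp$time, tsw$window_start)
  keep <- wi >= 1
  keep[keep] <- cp$time[keep] - tsw$window_start[wi[keep]] < window
  ts_local <- rep(NA_real_, nrow(cp))
  ts_local[keep] <- tsw$t_s[wi[keep]]
  cp <- cp[keep, , drop = FALSE]; ts_local <- ts_local[keep]
  bins <- floor(ts_local / bin_width)
  agg <- lapply(split(seq_along(bins), bins), function(ii) {
    if (length(ii) < min_per_bin) return(NULL)
    # regress against the realized mean t_s of the bin, not the bin
    # midpoint: sparse edge bins are otherwise mis-located
    data.frame(t_s_mid = mean(ts_local[ii]),
               ci5 = stats::quantile(cp$ci[ii], 0.05, names = FALSE),
               n = length(ii))
  })
  agg <- do.call(rbind, agg)
  if (is.null(agg) || nrow(agg) < min_bins)
    stop("fewer than ", min_bins, " populated t_s bins", call. = FALSE)
  # degeneracy guard: the envelope must actually vary with t_s (otherwise
  # the t_s-on-CI regression slope blows up and theta is undetermined)
  env_slope <- stats::cov(agg$t_s_mid, agg$ci5) / stats::var(agg$t_s_mid)
  if (!is.finite(env_slope) || abs(env_slope) < 0.02)
    stop("degenerate refractory regression (coupling envelope does not ",
         "vary with t_s)", call. = FALSE)
  cf <- stats::lm.fit(cbind(1, agg$ci5), agg$t_s_mid)$coefficients
  m <- unname(cf[2]); c0 <- unname(cf[1])
  if (!is.finite(m))
    stop("degenerate refractory regression", call. = FALSE)
  list(m = m, c = c0, epsilon = epsilon,
       theta = function(ts) (ts - c0) / m - epsilon,
       # envelope form recommended when *simulating* the model (the
       # epsilon margin is a conservative convention for the reported
       # refractory period; as a point estimate the envelope itself is
       # less biased, and simulating with the margin systematically
       # shifts expression decisions)
       sim = list(m = m, c = c0, epsilon = 0),
       bins = agg)
}

#' Reconstruct PRC points from bigeminy and trigeminy episodes
#'
#' Each NIB = 1 (bigeminy) episode yields one PRC point: the conducted
#' sinus beat reaches the ectopic focus at phase `(VN1 + t_lag)/t_e` and the
#' modified ectopic cycle normalized by the intrinsic cycle (`VV0 = t_e`)
#' gives the resetting value `VV1/t_e`. An NIB = 2 (trigeminy) episode adds
#' a second point: the effective phase after the first reset jumps by
#' `1 - g1` (with `g1` the first reset's normalized cycle length, evaluated
#' from `prc`), so the second stimulus lands at
#' `(VN2 + t_lag)/t_e + 1 - g1` and its resetting value is
#' `VV2/t_e + 1 - g1`. Trigeminy points therefore require a reference curve
#' for `g1`; typical usage is two-pass — fit a curve to the bigeminy points,
#' then pass it here to add the trigeminy points.
#'
#' Episodes with non-positive modified cycles or shifted phases at or past 1
#' (stimulus after the focus has fired) are dropped; a message reports the
#' dropped count.
#'
#' @param record a [beat_record].
#' @param t_e intrinsic ectopic period in seconds.
#' @param t_lag total conduction delay in seconds.
#' @param prc optional PRC object supplying `g1` for trigeminy points;
#'   when `NULL`, only bigeminy points are returned.
#' @return a PRC sample table with an extra column `episode`
#'   (`"bigeminy"`/`"trigeminy"`).
#' @export
reconstruct_prc_points <- function(record, t_e, t_lag, prc = NULL) {
  if (t_e <= 0 || t_lag < 0) stop("invalid t_e / t_lag", call. = FALSE)
  eb <- expressed_beats(record)
  dropped <- 0L
  phase <- ncl <- numeric(0); kind <- character(0)
  i1 <- nib1_episodes(eb)
  for (i in i1) {
    vn1 <- eb$time[i + 1] - eb$time[i]
    vv1 <- eb$time[i + 2] - eb$time[i]
    ph <- (vn1 + t_lag) / t_e
    if (vv1 <= 0 || ph >= 1 || ph < 0) { dropped <- dropped + 1L; next }
    phase <- c(phase, ph); ncl <- c(ncl, vv1 / t_e)
    kind <- c(kind, "bigeminy")
  }
  if (!is.null(prc)) {
    i2 <- nib2_episodes(eb)
    for (i in i2) {
      vn1 <- eb$time[i + 1] - eb$time[i]
      vn2 <- eb$time[i + 2] - eb$time[i]
      vv2 <- eb$time[i + 3] - eb$time[i]
      ph1 <- (vn1 + t_lag) / t_e
      if (ph1 >= 1 || ph1 < 0) { dropped <- dropped + 1L; next }
      g1 <- eval_prc(prc, ph1)
      ph2 <- (vn2 + t_lag) / t_e + 1 - g1
      g2 <- vv2 / t_e + 1 - g1
      if (vv2 <= 0 || ph2 >= 1 || ph2 < 0 || g2 <= 0) {
        dropped <- dropped + 1L; next
      }
      phase <- c(phase, ph2); ncl <- c(ncl, g2)
      kind <- c(kind, "trigeminy")
    }
  }
  if (dropped > 0) message(dropped, " episode(s) dropped")
  out <- prc_samples(phase, ncl)
  out$episode <- kind
  out
}
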