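---
title: "Phase resetting, modulated parasystole, and inference from beat annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase resetting, modulated parasystole, and inference from beat annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasereset)
```

## The model

A spontaneously beating cardiac oscillator — a cardiomyocyte spheroid, or
an ectopic focus in a ventricle — responds to a single stimulus delivered
at phase $\phi \in [0,1)$ of its cycle by rescaling that cycle to
$g(\phi)$ times its intrinsic length. The function $g$ is the phase
response curve (PRC). Measured cardiac PRCs share a characteristic shape:
stimuli early in the cycle have little effect or prolong it slightly;
past a discontinuity phase $\phi_r$ the stimulus triggers an immediate
action potential, so the cycle is cut short, with a transient "hook" just
past $\phi_r$ followed by a nearly linear segment whose slope we call $S$.

The package provides three nested parametric families
(`prc_pwlinear()`, `prc_linear_tail()`, `prc_empirical()`):

* piecewise-linear: $g(\phi) = 1$ for $\phi < \phi_r$, $g(\phi) = \phi$
  for $\phi_r \le \phi < 1$;
* linear tail: the tail is $1 + S(\phi - 1)$, anchored at $g(1) = 1$,
  reducing to the piecewise-linear family at $S = 1$;
* empirical: early branch $1 + a_1\phi + a_2\phi^2$ (so $g(0) = 1$),
  tail $b_0 + S\phi - h\,e^{-(\phi-\phi_r)/w}$ with a hook of amplitude
  $h \ge 0$ and width $w$.

The phase domain is half-open and $g$ at exactly $\phi_r$ uses the tail
branch. All constructors validate $g > 0$ on a dense grid, since a
non-positive cycle length is unphysical and breaks the maps below.

If such an oscillator is paced with period $T_{stim}$, writing
$\tau = T_{stim}/T$ with $T$ the intrinsic period, the phase of successive
stimuli obeys the one-dimensional circle map

$$\phi_{i+1} = \phi_i + \tau - g(\phi_i) \pmod 1 .$$

`iterate_orbit()` classifies its attractors as N:M rhythms (N stimuli per
M beats) by phase recurrence; `render_events()` realizes the same dynamics
as a continuous-time stream of stimulus and beat events and is guaranteed
(and tested) to reproduce the map iterates at the stimulus times to within
$10^{-9}$.

## Modulated parasystole

In parasystole an ectopic pacemaker of period $t_e$ competes with the
sinus node of period $t_s$. Conducted sinus beats reset the ectopic focus
through its PRC; ectopic beats never reset the sinus node (they are
blocked at the AV node), but they blank the ventricle: an ectopic impulse
arriving within the refractory period $\theta$ of the last expressed beat
is concealed, and the first sinus beat after an expressed ectopic beat is
blocked (the compensatory pause). Conduction into and out of the focus
takes $t_{in}$ and $t_{out}$, with only the sum $t_{lag} = t_{in}+t_{out}$
dynamically relevant; the phase at which a sinus beat, observed on the
surface record at phase $\phi$ of the ectopic cycle, actually reaches the
focus is $\phi + t_{lag}/t_e$.

The sinus-beat-to-sinus-beat phase map (`step_sinus_phase()`) has two
branches split at $(t_s - \theta)/t_e$: below it the preceding ectopic
firing was expressed, the current sinus beat is blocked and the phase
advances freely by $t_s/t_e$; at or above it the firing was concealed,
the sinus beat conducts, and the phase is reset through
$g(\phi + t_{lag}/t_e)$. The event-level simulator (`simulate_beats()`)
implements the same physiology beat by beat, keeps blocked beats with an
`expressed` flag, and agrees with the map to $10^{-9}$ in the regime
$t_e > t_s + \theta$ where refractoriness referenced to the most recent
expressed beat coincides with sinus-referenced refractoriness (outside
that regime the event layer is taken as authoritative). Ties are
deterministic: an ectopic arrival coincident with a sinus beat is blocked
(the sinus wins), and a conducted stimulus arriving exactly at a firing
acts on the new cycle.

Two conventions deserve note. First, a stimulus whose shifted phase
reaches past 1 ("stimulus after firing") is applied in the new cycle at
the wrapped phase; the map flags such steps. Second, `locking_ratio()`
reports N sinus cycles against M ectopic *firings*, expressed or not —
2:1 entrainment can coexist with a zero PVC burden when every firing is
concealed, which is precisely the clinically interesting suppressed
regime.

## What can be estimated from an annotation stream, and how

Only expressed beats appear in a clinical annotation record. The pipeline
estimates, in order:

* **$t_s$** — median NN interval per 30-s window (`estimate_sinus_period()`).
  The median is robust to isolated mis-annotations; windows of strict
  bigeminy contain no NN pairs and are skipped.
* **$S$** — during runs of bigeminy (NIB = 1), the modified ectopic cycle
  satisfies $VV = g((VN + t_{lag})/t_e)\,t_e$, which on the linear tail is
  affine in VN with slope exactly $S$; `estimate_slope_S()` is the OLS
  slope of VV on VN.
* **$\theta(t_s)$** — expressed couplings satisfy $NV \ge \theta$, so the
  lower envelope of the coupling-interval distribution traces the
  refractory bound. Couplings are binned by local $t_s$ (0.1-s bins, each
  with at least 20 couplings); the 5th percentile per bin is regressed as
  $t_s = m\,CI + c$ and $\theta(t_s) = (t_s - c)/m - \epsilon$ with a
  safety margin $\epsilon = 0.05$ s. The regression uses each bin's mean
  realized $t_s$ rather than the bin midpoint (sparse edge bins are
  otherwise mis-located). Note the estimator targets the envelope minus
  $\epsilon$: it is deliberately conservative and sits slightly below the
  generative $\theta$.
* **$(t_e, t_{lag}, \phi_r)$** — `fit_patient()`, described next.
* **PRC points** — `reconstruct_prc_points()` inverts bigeminy episodes to
  $(\,(VN_1+t_{lag})/t_e,\; VV_1/t_e\,)$ and extends to trigeminy with the
  bookkeeping $\phi_2 = (VN_2+t_{lag})/t_e + 1 - g_1$,
  $g_2 = VV_2/t_e + 1 - g_1$. The trigeminy inversion needs the
  first-reset value $g_1$, which the data do not determine pointwise; the
  intended use is two-pass (fit a curve on bigeminy points, then pass it
  in for $g_1$). On simulated records the round trip is exact to
  $10^{-9}$.

### The fitting objective

The three parameters not directly measurable are fit by minimizing the
mean absolute error between observed and simulated inter-beat interval
sequences over 30-s windows with cycling coupling intervals, via a coarse
grid (50 x 20 x 20 by default) and Nelder-Mead refinement. Three design
choices were genuinely open and are worth recording:

* **Anchoring.** Each simulated window is anchored at the window's first
  PVC: the observed V fixes the ectopic firing time ($V - t_{out}$) and
  the refractory and compensatory state. An initial sinus beat pins
  nothing about the focus, so aligning at "the first expressed beat"
  is only identifiable when that beat is a V.
* **The sinus stream is measured, not modelled.** Within a window the
  simulation is driven by the observed sinus beats (plus slots for the
  sinus beats hidden in compensatory pauses, reconstructed by dividing
  long N-N gaps evenly). A constant-$t_s$ free-running simulation
  decoheres from the record whenever the sinus period drifts within the
  window, burying the parameter signal; driving with the measured stream
  removes that error source entirely and mirrors the estimation
  philosophy: the sinus node is observed, the model explains the ectopy.
* **Gap-tolerant sequence alignment.** The interval sequences are
  compared by a minimum-cost monotone alignment in which a skipped beat
  on either side costs the window-mean interval. An element-wise
  comparison would charge a single expression flip (a beat appearing or
  disappearing near the refractory boundary) against every subsequent
  interval; the alignment charges it once, which is what "penalized by
  the segment-mean interval per extra or missing beat" should mean.

The sequence MAE resolves $t_e$ and $\phi_r$ well but is nearly flat
along a ridge trading $t_e$ against $t_{lag}$ (on the linear tail only
$(1-S)t_e + S\,t_{lag}$ enters the VV intervals). A final polish stage
therefore minimizes a capped mean of per-ectopic-cycle prediction
errors: anchor at each PVC, predict the next PVC time through the
simulator, and take $\min(|{\rm predicted} - {\rm observed}|,\, c)$ with
a fixed cap $c = 0.1$ s.
Single-cycle predictions accumulate no trajectory divergence, and the
mixture of NIB = 1 and NIB = 2 episodes breaks the ridge (their
intercepts weight $t_e$ and $t_{lag}$ differently). Three details
matter. First, the polish episodes come from windows spread across the
*whole* record (up to 24), not only the cycling windows: parameter sets
can tie on a handful of dynamically similar cycling windows, and it is
the windows in other entrainment regimes that break the tie. Second, the
episode span cap is absolute (3.2 mean ectopic periods of the search
box), so every candidate is scored on the identical episode set. Third,
the loss is capped rather than trimmed: episodes whose expression
outcome is unpredictable at 10-ms annotation jitter (arrivals within a
jitter width of the refractory boundary) each cost at most $c$, but no
candidate gets to choose which episodes to ignore — a trimmed mean would
let a wrong parameter set discard exactly its own discriminating
episodes. Minimization is two-phase per start — first on the *uncapped*
mean (the capped loss is flat at long range, since distant candidates
sit on a plateau of capped episodes, while the uncapped mean slopes
toward the optimum from far away), then on the capped loss for local
robustness. The polish is started from the sequence-MAE optimum and
from the best point of a coarse episode-objective grid, and adds a
candidate from a Brent alternation *along the data ridge* — the
bigeminy regression pins $(1-S)t_e + S\,t_{lag}$ to a few milliseconds,
so searching $t_e$ with $t_{lag}$ slaved to that line walks exactly the
direction free simplex steps resolve poorly. The final parameters are
the candidate with the smallest capped episode error, with ties broken
by the sequence MAE (the episode objective is exactly flat over an
interval of $\phi_r$ when the discriminating episodes exceed the span
cap).

### Segment scoring

`score_segments()` splits the record into 30-s segments, simulates each
with the segment's measured $t_s$, and calls a segment well fit if any
combination on the $\{-5\%, 0, +5\%\}$ grid over
$(t_e, t_{lag}, \phi_r, S)$ gives a two-sample Kolmogorov–Smirnov
p-value above 0.05 between observed and simulated inter-beat interval
distributions (asymptotic p-values; combinations are tried unperturbed
first with early exit). Segments without a PVC are simulated driven by
their observed sinus stream, so a pure-sinus segment is reproduced
exactly if and only if the model also expresses nothing there. Segments
with fewer than 10 expressed beats or no measurable NN interval are
skipped and reported; the well-fit proportion is over scored segments.

## The synthetic records

The generators produce every input the pipeline needs, with the
statistical structure the estimators rely on:

* `gen_prc_samples()` — uniform stimulus phases, Gaussian scatter on the
  normalized cycle length (default s.d. 0.056, the scatter scale of
  optically measured spheroid PRCs).
* `gen_paced_record()` — spontaneous / paced / recovery segments; the
  stimulus period is $R\,T$ where $R$ is the spontaneous-to-stimulus
  frequency ratio, so $R$ is numerically the pacing ratio $\tau$.
* `gen_holter_record()` — modulated parasystole under a drifting sinus
  period: a sinusoid (default amplitude 0.12 s, period 3600 s) plus an
  AR(1) component (stationary s.d. 0.015 s, coefficient 0.8) on a 30-s
  schedule, annotation jitter of 10 ms, and a 90/10 PVC morphology mix.
  Blocked beats are dropped from the output, as in real annotation
  streams. Defaults for the ectopic side are patient-scale:
  $t_e = 1.8$ s, $t_{lag} = 0.15$ s, $\phi_r = 0.65$, $S = 0.5$,
  $\theta(t_s) = (t_s + 0.25)/2.5 - 0.05$ s, base $t_s = 0.72$ s, 2-h
  duration.

The base sinus period and drift amplitude were chosen so that $\tau$
sweeps roughly 0.32–0.48: the record then traverses expressed bigeminy,
concealed 2:1 locking, and higher-order rhythms — the variety the
screens and the fit need — and the realized $t_s$ values populate at
least three 0.1-s bins for the refractory regression. Sinus drift is
also what makes coupling intervals cycle at the 30-s window scale in
locked regimes; with a constant sinus period, cycling coupling appears
only in long-period or quasiperiodic regimes.

What the generator does *not* emulate: morphology feature noise (labels
are exact), atrial or junctional ectopy, artefactual annotations, sinus
arrhythmia at the beat-to-beat scale (drift is piecewise-constant on a
30-s grid), multifocal parasystole, and any waveform-level physics. Tests
passing on these records therefore certify the estimation machinery under
the model's own assumptions plus timing noise — not robustness to every
failure mode of real ambulatory data.

## The toy oscillator

`toy_oscillator()` is a FitzHugh–Nagumo cell
($\dot v = v - v^3/3 - w + I_0 + I_{stim}$,
$\dot w = \varepsilon(v + a - bw)$; $a = 0.7$, $b = 0.8$,
$\varepsilon = 0.08$, $I_0 = 0.5$), a relaxation oscillator with intrinsic
period about 39.5 time units. A beat is an upward crossing of $v = 0$
with a one-time-unit lockout. `prc_from_oscillator()` measures the PRC by
the stimulus-at-phase protocol: run to the limit cycle (10-beat run-in),
take $T_0$ as the mean of five unperturbed cycles, then for each phase
restart from the beat-aligned state, deliver a square pulse at
$\phi T_0$, and record the first beat-to-beat interval, normalized by
$T_0$. Aftereffects beyond the perturbed cycle are not folded into $g$ —
the maps assume single-cycle re-establishment of the rhythm.

Numerics: `deSolve::lsoda` at relative tolerance $10^{-8}$, sampled at
0.05 time units, with beat times refined by cubic-Hermite interpolation
(values and derivatives at the bracketing samples), so measured cycle
lengths are solver-limited rather than grid-limited; halving the
tolerance moves any ncl by less than $10^{-5}$. A stimulus amplitude of
3 with a 1-unit pulse is the canonical "strong" stimulus: the measured
PRC then shows a clean discontinuity near 0.37 and a tail within 0.05 of
the identity line. At intermediate amplitudes (near 2) the toy cell shows
an isolated early triggering window — excitability along the FitzHugh–
Nagumo cycle is non-monotone — which is a property of the toy model, not
of the protocol. External limit-cycle models (e.g. CellML-derived ionic
cells) plug into the same protocol through `oscillator_adapter()`:
a derivative function with an additive stimulus current, an initial
state, named scalable parameters, and a beat definition.

## Locking zones and burden maps

`locking_grid_oscillator()` and `locking_grid_parasystole()` classify
N:M locking on parameter grids, masking aperiodic cells and periods
above 5 as "period 0" (no Lyapunov estimate is attempted: the
discontinuity at $\phi_r$ makes derivative-based exponents ill-defined,
and the display convention does not need one). `pvc_burden_maps()`
simulates 500 sinus cycles per cell after a 500-beat transient; for
periodic cells, doubling the length moves any cell by less than one
percentage point. The $\tau$-averaged burden over $(\phi_r, t_{lag})$
averages uniformly over the $\tau$ grid.

## Numerical conventions and degenerate inputs

* Phase recurrence tolerance $10^{-9}$; periods searched up to 50
  (orbits), 5 displayed (grids). Transients: 1000 map iterates, 500
  sinus beats for burden maps.
* Map steps snap post-jump phases within $10^{-12}$ of 1 to a triggered
  beat, so exact-arithmetic orbits (rational rotations) are classified
  exactly.
* `fit_prc()` profiles the hook width by one-dimensional optimization
  (the model is linear in all other shape parameters given $w$) and
  searches $\phi_r$ over candidate values placed at the sample phases —
  an abstract grid mis-assigns boundary samples by floating-point dust.
  Within one branch assignment, $\phi_r$ is not further identified (a
  shift is absorbed exactly by rescaling $h$), so the fitted $\phi_r$ is
  by convention the first sample on the triggering branch. The
  refractory constraint $\theta \ge t_s$ is allowed (the fully blocked
  limit, useful for burden bounds) even though real parasystole has
  $\theta < t_s$.
* `detect_discontinuity()` needs the true jump to exceed its threshold
  (default 0.15); for families whose jump at $\phi_r$ is small (e.g.
  piecewise-linear with $\phi_r$ near 1, jump $1-\phi_r$) the threshold
  must be set below the jump or the curve is declared continuous —
  which is also the correct report for weak stimuli.

## Problem sizes

The shipped analyses and tests use: 200-sample PRC fits; 100 random
configurations for each map/event equivalence check; locking grids of a
few thousand cells; a 2-h synthetic Holter (about 10,000 beats) for the
end-to-end recovery, with the fit's sequence-MAE grid at 50 x 20 x 20
over 4 windows and the episode polish over up to 24 windows. These sizes
resolve every structure the analyses discuss; all grids and durations
are arguments and scale up trivially.

## Known limitations

* The empirical PRC family is one parameterization of the described
  morphology; the fitting interface is family-pluggable, but no claim is
  made that these are the same polynomial coefficients a different
  parameterization would report. $\phi_r$ comparisons across families
  are meaningful; $(a_1, a_2, b_0, h, w)$ comparisons are not.
* Map/event equivalence for parasystole is only claimed for
  $t_e > t_s + \theta$; outside it the simulator (expressed-beat-
  referenced refractoriness) is the model.
* `fit_patient()` assumes a single ectopic focus with one morphology;
  multifocal records should be screened out (that is what the dominant-
  morphology screen is for).
* $t_{lag}$ is the weakest-identified parameter. The combination
  $(1-S)t_e + S\,t_{lag}$ is pinned to a few milliseconds by the
  bigeminy regression, but separating the two leans on trigeminy
  structure and expression-pattern changes, whose intercept contrast
  degenerates exactly at $S = 0.5$ (the concealed-firing trigeminy type
  weights $t_e$ and $t_{lag}$ equally there). At 10-ms annotation jitter
  on a 2-h record the episode objective can be left with near-tied
  minima along the ridge: across drift realizations $t_e$, $\phi_r$, $S$
  and $\theta$ recover within a few percent consistently, while
  $t_{lag}$ recovers within 5% on favourable records and within a factor
  of about two on hard ones. Longer records, smaller jitter, or a tail
  slope away from 0.5 all sharpen it.
* Recovery tolerances quoted in the tests are calibrated to 10-ms
  annotation jitter; heavier-tailed annotation errors would mostly
  inflate the refractory envelope estimate.
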