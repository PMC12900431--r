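# phasereset

Phase-resetting analysis of competing cardiac pacemakers: parametric phase
response curves (PRCs), circle-map entrainment of a periodically paced
oscillator, a modulated-parasystole model with conduction delay, and the
inference pipeline that fits that model to timestamped beat annotations.

## The problem

A spontaneously beating cardiac oscillator — a cardiomyocyte spheroid in a
dish, or an ectopic focus firing premature ventricular complexes (PVCs) in
a patient — responds to a stimulus at phase φ of its cycle by rescaling
the cycle to g(φ) times its intrinsic length. Measured cardiac PRCs share
one morphology: little effect or mild prolongation early in the cycle, a
discontinuity at a phase φ_r beyond which the stimulus triggers an
immediate beat, a transient "hook", and a nearly linear tail of slope S.

Two maps turn the PRC into rhythm predictions:

* **Forced oscillator.** Pacing with normalized cycle length
  τ = T_stim/T gives φ_{i+1} = φ_i + τ − g(φ_i) (mod 1); its attractors
  are the N:M entrainment rhythms (N stimuli per M beats) and its
  bifurcations organize which rhythm appears at which pacing rate.
* **Modulated parasystole.** An ectopic focus of period t_e competes with
  the sinus node of period t_s; conducted sinus beats reset the focus
  through g after a conduction delay t_lag, ectopic beats within the
  refractory period θ of the last expressed beat are concealed, and the
  sinus beat right after an expressed PVC is blocked (compensatory
  pause). The sinus-phase map is

      φ_{i+1} = φ_i + t_s/t_e                            (mod 1),  0 ≤ φ_i < (t_s−θ)/t_e
      φ_{i+1} = φ_i + t_s/t_e + 1 − g(φ_i + t_lag/t_e)   (mod 1),  otherwise

Of the model's parameters, t_s, S and θ(t_s) are measured directly from an
annotation stream; (t_e, t_lag, φ_r) are fit by matching simulated beat
sequences to the record. Because none of the underlying recordings are
public, the package ships generators that produce PRC measurement tables,
paced event trains and multi-hour Holter-like N/V annotation records with
the statistical structure the pipeline assumes, so every stage is testable
end to end.

## A worked example

Fit the empirical PRC family to noisy phase-resetting measurements, then
predict entrainment:

```r
library(phasereset)

truth <- example_empirical_prc()          # phi_r = 0.7, S = 0.9, hook
samples <- gen_prc_samples(truth, n = 200, noise_sd = 0.056, seed = 1)
fit <- fit_prc(samples, family = "empirical")
fit
#> <PRC fit: empirical family, n = 200, RMSE = 0.0553>
#> <empirical PRC>
#>   phi_r = 0.711121, S = 1.04434, b0 = -0.0267896, h = 0.0806188,
#>   w = 0.0436162, a1 = 0.0637821, a2 = 0.108637

iterate_orbit(stimulus_config(tau = 0.4), fit$prc)
#> <orbit: 2:1 locking, phases 0.769027, 0.414063>
```

The fitted RMSE (0.055) matches the injected measurement scatter, the
discontinuity is recovered to within 0.02, and pacing at τ = 0.4 is
predicted to entrain 2:1 — one triggered beat every second stimulus.

The same PRC drives the parasystole model. With patient-scale parameters
(t_e = 1.8 s, t_lag = 0.15 s, φ_r = 0.65, S = 0.5,
θ(t_s) = (t_s + 0.25)/2.5 − 0.05):

```r
prc <- prc_linear_tail(0.65, 0.5)
theta <- list(m = 2.5, c = -0.25, epsilon = 0.05)
for (t_s in c(0.76, 0.86)) {
  p <- parasystole_params(t_s, 1.8, theta, 0.15, prc)
  r <- simulate_beats(p, 600)
  o <- locking_ratio(p)
  cat(sprintf("t_s = %.2f: %d:%d locking, burden %.1f%%\n",
              t_s, o$N, o$M, pvc_burden(r)))
}
#> t_s = 0.76: 2:1 locking, burden 49.6%
#> t_s = 0.86: 2:1 locking, burden 0.0%
```

Both sinus periods lock 2:1, but at t_s = 0.76 every other beat is a PVC
(bigeminy) while at t_s = 0.86 every ectopic firing falls in the
refractory period and the record is pure sinus — the same arrhythmia,
expressed or concealed, depending on a 0.1-s change in sinus period.

`gen_holter_record()` embeds these dynamics in a 2-hour record with a
drifting sinus period and 10-ms annotation jitter; `screen_record()`,
`estimate_slope_S()`, `estimate_refractory()`, `fit_patient()` and
`score_segments()` recover the generating parameters from the annotations
alone (see `analysis/04_holter_inference.R`).

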