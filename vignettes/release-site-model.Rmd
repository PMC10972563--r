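---
title: "A dual-sensor release-site model of synchronous and asynchronous transmitter release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-sensor release-site model of synchronous and asynchronous transmitter release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(vesikin)
```

## The model

`vesikin` simulates neurotransmitter release at a population of independent
release sites. Each site is in one of three occupancy states — empty (`E`),
holding a tethered vesicle (`T`), or holding a docked, fusion-competent
vesicle (`D`) — and cycles between them with first-order rates: tethering
`k_tet` (and untethering at the same rate), docking `k_docking` (and
undocking, ditto). Only docked vesicles fuse.

Three calcium sensors act on this cycle:

* **syt1** rides on the vesicle and binds up to five Ca²⁺ ions, but only
  while the vesicle is docked. Each bound ion multiplies the fusion rate by
  `f1` (27.98).
* **Doc2α** sits on the release site itself and binds up to two ions in any
  site state, so its activation survives fusion of the resident vesicle.
  Each ion multiplies the fusion rate by `f2` (16). Because its binding is
  slow and its affinity high, it is the sensor of *asynchronous* release.
* **syt7** also sits on the release site (two ions) and acts on a different
  step: each bound ion multiplies *both* the docking and the undocking rate
  by `f7` (10). It is a catalyst — it accelerates equilibration of the
  docked pool without moving its equilibrium — and is the engine of
  *transient docking* after an action potential.

The fusion rate of a docked vesicle with `s1` ions on syt1 and `d2` on
Doc2α is

$$f(d_2, s_1) = l_+ \, f_1^{s_1} f_2^{d_2},$$

with basal rate `l_plus` = 3.5e-4 s⁻¹. syt1 and Doc2α compete for a shared
budget of five ions per site (standing in for a limited pool of SNARE
machinery), so binding stops whenever `d2 + s1 = 5`. The enumeration keeps
all 3 (E) + 3 (T) + 18 (D) = 24 states for a fixed, reproducible indexing;
the three docked states violating the budget (`D[1,5]`, `D[2,4]`,
`D[2,5]`) receive no inbound flux and provably stay empty.

Calcium unbinding is cooperative: from `m` bound ions the off-rate is
`m k_minus b^(m-1)` with `b = 0.5` for every sensor. Where a dissociation
constant is configured, `k_minus` is derived as `k_plus * K_D` (28 × 1.5 =
42 s⁻¹ for Doc2α and syt7).

syt7's two-state-per-ion occupancy is factorised out of the site chain and
integrated as its own three-state ODE; it couples back through the common
docking/undocking multiplier `g(t) = Σ S[s7] f7^s7`. At any instant the
site chain is therefore a time-inhomogeneous Markov chain with generator

$$Q(t) = A + \mathrm{ca}(t)\,B + g(t)\,C,$$

with constant matrices `A` (tethering, unbinding, fusion), `B` (all
calcium-binding steps) and `C` (docking/undocking). The package integrates
the 24 occupancies, the 3 syt7 fractions and the cumulative fusion count
jointly with a stiff solver (deSolve's `lsoda`; relative and absolute
tolerance 1e-5, maximum step 1e-5 s — tight enough to resolve the 0.2 ms
calcium spike) and returns
output on a uniform 50 kHz grid, the same grid the quantification uses.

## The calcium transient

The driver is phenomenological: per action potential (AP), a synchronous
Gaussian bump (mean +1.5 ms after AP onset, SD 0.2 ms) scaled so its *peak*
equals `amplitude_ap` (30 µM), plus a residual component

$$A\, e^{-(t - t_0)/\tau}\, \frac{t - t_0}{(t - t_0) + k_m}$$

starting `t0` = +1.6 ms after onset (A = 0.75 µM, τ = 0.2 s, `km` =
0.1 ms; the Michaelis-type factor smooths the onset), on top of a 0.05 µM
resting concentration. Residuals from successive APs add linearly — the
standard assumption for residual calcium, and the one consistent with
EGTA's suppression of asynchronous release. The transient is evaluated
analytically on demand, so the ODE solver is free to choose steps; there
is no spatial diffusion, buffering or channel gating.

```{r transient}
p <- default_parameters()
tr <- build_transient(p, n_aps = 10, freq = 20)
plot(tr, log = "y")
```

## Steady states, knockouts, quantification

The initial condition is the resting steady state. The syt7 occupancy has
a detailed-balance closed form; the 24-state stationary distribution is
computed as the null space of `t(Q)` (SVD), and cross-checked against
propagating the all-empty vector through `expm(Q * 1000 s)`, the long-time
limit of the master equation. The two agree to better than 1e-6 of the site
count,
and serve as mutual oracles in the test suite.

Genotypes are parameter presets: Doc2α knockout sets `k2+ = 0` (the sensor
never binds calcium), syt7 knockout sets `f7 = 1` (bound calcium has no
effect on docking), the double knockout applies both.

From a trajectory, `per_stimulus_metrics()` computes, per AP: the peak
release rate (maximum of the 50 kHz forward-differenced cumulative fusion
count between stimulus onset and the next onset), the asynchronous count
(release between +5 ms and the next onset; the first 5 ms are synchronous),
docked counts at +5/+11/+15 ms, and two readings of "vesicles docking
between +5 and +15 ms": the **events** measure (integral of the docking
flux `k_docking · g(t) · tethered(t)`, the default, which counts docking
events and nearly vanishes without syt7) and the **net** measure (change in
the docked count, which confounds docking with concurrent undocking and
fusion and stays visibly positive even without syt7 because the docked
pool also relaxes passively). We report both; the events reading is the
one under which "transient docking requires syt7" is quantitatively sharp.

```{r report, cache = FALSE}
rep <- report_fig7(p)
print(rep)
plot(rep, what = "docked")
```

The qualitative phenotypes this reproduces with the default parameters:
first-AP peak release rate equal across genotypes (within a few percent);
asynchronous release after a single AP strongly reduced without Doc2α but
not without syt7; docking between +5 and +15 ms nearly abolished without
syt7; depression across the train strongest without syt7 and weakest
without Doc2α; cumulative train asynchronous release roughly halved in
each single knockout, and lower still in the double knockout (a model
property; experimentally the double knockout does not drop below the
single knockouts, a divergence the model makes explicit).

`parameter_sweep()` re-simulates with one parameter scaled across a
log-spaced grid spanning 0.1× to 10× (13 points by default) and records
the four headline
metrics above.

## The stochastic oracle

`simulate_site_stochastic()` simulates single sites exactly, by thinning:
time is cut into 0.5 ms cells, the calcium and `g` maxima per cell bound
the current state's exit rate, and candidate events are accepted with
probability actual/bound. Because sites are independent and the drivers
deterministic, the replicate mean of the fusion count times `n_sites` must
match the ODE — a genuinely independent check of the whole generator
assembly, used in the test suite at 10⁴ replicates on a two-AP protocol
(agreement within three standard errors).

## Trace analysis

The measurement-side module mirrors standard optical and
electrophysiological quantification:

* `fluorescence_trace()` normalises raw per-bouton traces to ΔF/F₀ with F₀
  the mean over the 500 ms baseline.
* `detect_events()` thresholds frame-to-frame *rises* of ΔF/F₀ at 5× the
  SD of the baseline rises. Thresholding changes rather than absolute
  levels keeps detection exact while earlier events are still decaying;
  the event time is the frame the rise lands on (the sensor rises within
  one frame). Events are binned in 10 ms bins from their stimulus;
  first-bin events are synchronous, later ones asynchronous. Two caveats
  are inherited from the peak-counting definition itself: multiquantal
  peaks count once, and two events landing on *adjacent* frames of the
  same bouton merge. The exact-recovery guarantees in the tests therefore
  assume at least one intervening frame between events of one bouton.
* `train_ar_fraction()`, `percent_asynchronous()`,
  `paired_pulse_ratio()` summarise the event tables.
* `cumulative_charge_decomposition()` integrates a baseline-subtracted
  evoked current over 400 ms (inward current → positive charge, pA·s =
  pC) and fits Q_f(1−e^{−t/τ_f}) + Q_s(1−e^{−t/τ_s}) by multi-start
  Levenberg–Marquardt on log-transformed parameters (positivity by
  construction; τ starts at {5, 100} ms; components ordered so τ_fast <
  τ_slow; a `degenerate` flag is raised when the fitted τs differ by less
  than 3×, where the split is not identifiable).
* `tonic_charge()` quantifies asynchronous build-up during a train as the
  area between the pre-train baseline and the piecewise-linear envelope
  through tail currents sampled 1 ms before each stimulus (anchored at the
  baseline at the first onset — the envelope is a physical build-up from
  zero, and linear interpolation is the minimal choice; whether the
  original analysis interpolated linearly or stepwise is not stated).

## Synthetic data

Every analysis stage is testable without any recording. `synth_iglu()`
draws, per bouton and stimulus, at most one synchronous event (on the
first frame after the stimulus) and one asynchronous event, with a
truncated-exponential latency law (mean 20 ms, support (10, 100] ms to
match the asynchronous analysis window; the exponential mean is a
configurable modelling choice), lognormal amplitudes, an
instant-rise/exponential-decay kernel (decay 100 ms for the
medium-affinity sensor variant, ~30 ms for the faster low-affinity
variant used in trains) and white Gaussian noise in ΔF/F₀ units (no
photobleaching; acquisition settings are chosen to make it negligible).
The ground-truth table is emitted with every trace and re-rendering it
noiselessly reproduces the clean traces exactly. `synth_epsc()` builds
20 Hz current trains from biexponential unitary currents with
geometrically depressing amplitudes on a configurable tonic envelope, and
returns the envelope's analytic tail-node trapezoid as the tonic-charge
ground truth. `model_driven_synth()` closes the loop: simulated
per-stimulus fusion counts set event probabilities
(`1 − exp(−gain·count)`) and the model's own release-time distribution
sets asynchronous latencies, so model predictions can be pushed through
the full measurement chain.

All generators take an explicit seed and are bit-reproducible (R's
default Mersenne-Twister).

## Numerical choices and limitations

* Output and quantification share the 50 kHz grid; release rates are
  forward differences on it. Halving solver tolerances moves the total
  fusion count by well under 0.1%.
* The null-space steady state refuses matrices whose numerical null space
  is not one-dimensional; occupancies are clipped at zero before
  renormalising (clipping magnitude ~1e-12 of a site).
* Closed-form limit checks (syt1 detailed balance, syt7 catalyst
  neutrality) are exercised in the limits where they are exact: fusion off
  (`l_plus → 0`), and for the within-docked-block distribution also slow
  docking exchange, since docking injects vesicles at `s1 = 0` only and
  fusion breaks detailed balance by construction.
* Problem sizes in the tests — 10 APs at 20 Hz for trajectories, 10⁴
  stochastic replicates on 2 APs, a few hundred synthetic boutons — were
  chosen as the smallest sizes at which the checked contrasts are far from
  their noise floors.
* The model is phenomenological where the underlying biology is spatial:
  no calcium microdomains, no explicit SNARE counting (the five-ion budget
  stands in for it), no vesicle positions. The synthetic traces are
  per-bouton time series, not movies, and make no claim about amplitude
  distributions of multiquantal events.
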