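---
title: "Modelling seizure-like recruitment with exact QIF neural masses on structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure-like recruitment with exact QIF neural masses on structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massnet)
```

## The model

Each brain region is described by the exact mean-field reduction of an
infinite, all-to-all coupled population of quadratic integrate-and-fire
(QIF) neurons whose excitabilities follow a Lorentzian distribution of
half-width $\Delta$ centred at $\bar\eta$. The macroscopic state of
region $k$ is its population firing rate $r_k(t)$ and mean membrane
potential $v_k(t)$:

$$\tau_m \dot r_k = \frac{\Delta}{\tau_m \pi} + 2 r_k v_k, \qquad
  \tau_m \dot v_k = v_k^2 + \bar\eta(k) + I_B + I_S^{(k)}(t)
  - (\pi \tau_m r_k)^2 + \tau_m \sum_l J_{kl}\, r_l .$$

Unlike heuristic firing-rate models, this reduction is exact in the
thermodynamic limit, and the mean voltage gives a direct analogue of a
field potential, including the damped macroscopic oscillations that
accompany transient synchronisation. The system has only fixed points as
attractors: a low-activity (LA) node-like equilibrium, a high-activity
(HA) focus approached through damped (ringing) oscillations, and a
bistable window bounded by saddle-node bifurcations in which both
coexist, separated by a saddle. A seizure-like event is the
stimulus-triggered transition of one or more regions from LA to HA; it
is *not* a limit cycle, and the package makes no attempt to model
self-sustained oscillatory seizures.

The coupling matrix is built from a structural connectome
$\tilde J_{kl}$, normalized to $[0,1]$ with zero diagonal:
$J_{kl} = 5\,\sigma\,\tilde J_{kl}$ for $k \ne l$ and
$J_{kk} = 20\,\sigma$. The strong recurrent diagonal places each region
in (or near) its bistable window, which is what makes recruitment
cascades possible; the global factor $\sigma$ (1 for the healthy-cohort
preset, 1.25 for the patient preset) rescales every synapse at once.

Units: time is in ms throughout, rates in 1/ms (1000 times the value in
Hz); voltages, currents, $\bar\eta$ and $\Delta$ are dimensionless. The
defaults $\tau_m = 20$ ms, $\Delta = 1$, $I_B = 0$ are used everywhere
unless stated.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `tau_m` | membrane time constant (ms) | 20 | sets all time scales |
| `delta` | excitability spread (HWHM) | 1 | exactness requires Lorentzian |
| `eta_bar` | mean excitability | protocol-dependent | the bifurcation parameter |
| `sigma` | global coupling factor | 1 (healthy), 1.25 (patient) | linear in every synapse |
| `intra`, `inter_scale` | coupling construction | 20, 5 | diagonal vs off-diagonal |
| `I_S`, `t_I` | stimulus amplitude, duration | 10, 400 ms | rectangular pulse |
| `dt` | RK4 step (ms) | 0.01 | see *Numerical choices* |

## Protocols

`adiabaticSweep()` reproduces the bifurcation-diagram experiment: the
network starts at $\bar\eta = -50$ from $(r, v) = (0, 0)$, the common
excitability rises in steps of 1.5 with a 2 s relaxation per step
(carrying the state forward), then descends again. The LA$\to$HA jump on
the way up and the HA$\to$LA collapse on the way down occur at different
excitabilities (`hysteresisBounds()`), delimiting the multistable band;
`mapOfRegimes()` repeats this over a $\sigma$ grid.

`runStimulation()` + `detectRecruitments()` implement the recruitment
experiment: prepare the network LA state, apply the pulse to the
epileptogenic-zone (EZ) region(s), and count which regions end in HA. A
region is recruited when its rate crosses and stays above the criterion
rate $r_c$ until the end of the observation window (2 s after pulse
offset by default). `thresholdMap()` scans $\bar\eta$ (default
$[-15, -4]$ in steps of 0.1) and records, per stimulated region, the
smallest excitability producing any recruitment
($\bar\eta_{asy}$, the asymptomatic threshold) and the smallest
producing full recruitment ($\bar\eta_{gen}$, the generalized
threshold); thresholds are reported as grid values, never interpolated.
`heterogeneousScan()` repeats this with per-region excitabilities drawn
from a Gaussian (sd 0.1, 10 repetitions by default);
`amplitudeSweep()`/`durationSweep()` vary the pulse.

### The recruitment criterion

The source experiments count regions that "pass from LA to HA" without
defining the boundary numerically. We use the separatrix of the
single-region system: $r_c$ is the rate of the middle (saddle)
equilibrium at the run's $\bar\eta$ with self-coupling $\sigma \cdot 20$.
Where no saddle exists, the geometric mean of the LA and HA rates at
the nearest bistable excitability is used, and a fixed user-supplied
threshold is always accepted. Two refinements proved necessary in
practice:

* *Sustained crossing.* Unstimulated regions count as recruited only if
  they stay above $r_c$ through the end of the window, so the transient
  bump that coupling injects into non-recruited neighbours during the
  pulse is not miscounted.
* *Stimulated regions use their first crossing.* Recruitment proper is
  a property of unstimulated regions; the forced ringing of the
  stimulated region under a strong pulse can dip briefly below $r_c$,
  and dating it by its last upward crossing would misplace the event
  origin in the recruitment order.

## The microscopic oracle

`qifSimulate()` integrates the finite network of $N$ QIF neurons the
mean field reduces, and is used to verify exactness: with deterministic
Lorentzian quantile sampling of the excitabilities, the time-averaged
$(r, v)$ of $10^4$ neurons initialized near a stable mean-field
equilibrium agrees with that equilibrium to a few percent.

Numerics of the microscopic simulator, chosen after the obvious Euler
scheme failed quantitatively (stiff spike flights bias a sampled
voltage average by tens of percent at any affordable step):

* Between synaptic events the drift of each neuron is constant, so the
  flow $\tau_m \dot V = V^2 + a$ is advanced by its closed-form
  solution (a phase rotation for $a > 0$, the matching `tanh` map for
  $a < 0$); spikes are exact crossings of the finite threshold
  $V_p = -V_r$ (default 100).
* Delta-pulse synapses contribute an instantaneous increment $J/N$ per
  presynaptic spike (no autapses), accumulated within a step and
  delivered at its end.
* The ideal QIF neuron spends $2\tau_m/V_p$ per spike beyond the finite
  threshold. That time is restored as a refractory hold represented at
  $+V_p$ then $-V_p$, which removes the period-shortening bias of the
  truncation; the neuron then resumes from the residual-phase re-entry
  point, keeping the sampling grid uniform.
* The mean voltage is *not* averaged over sampled voltages — discrete
  samples of a `tan` trajectory have Cauchy-like tails and never
  converge cleanly. Instead each step contributes its exact time
  integral $\tfrac{1}{2}\ln\lvert V_1^2 + a\rvert -
  \tfrac{1}{2}\ln\lvert V_0^2 + a\rvert$, which telescopes through the
  threshold wrap.

One systematic finite-size effect remains and is worth knowing about:
the deterministic quantile sample truncates the Lorentzian tails at
$|\eta| \approx 2(N{+}1)/\pi$, which removes roughly $2/(\pi\sqrt{\eta_{max}})
\approx 0.008$ of (negative) rest-voltage mass at $N = 10^4$. States
with a large HA rate have $|v^*| = \Delta/(2\pi\tau_m r^*)$ small, so
their *relative* voltage error is dominated by this sampling deficit,
not by the simulator. The exactness checks therefore use regimes with
$|v^*| \gtrsim 0.25$ for voltage comparisons and verify the
strong-coupling regime on the rate.

## Synthetic connectomes

`synthConnectome()` replaces the study's diffusion-MRI data with seeded
surrogates: a connected topology (edges first laid along a random
spanning tree), log-normal weights normalized by the maximal
off-diagonal entry, optional asymmetry and hub bias. Defaults are chosen
to emulate probabilistic-tractography parcellation connectomes: 90
regions, connection density 0.5, log-normal shape parameter 1 (a few
strong connections per region, many weak ones). With these defaults the
per-region strengths fall in the 0.5–4 range, which is what makes the
surrogate networks behave like the study's: recruitment cascades and
generalized events occur inside the scanned excitability range. What
the surrogates do **not** emulate: spatial embedding and distance-
dependent connection probability, hemispheric symmetry, the community
structure of real cortex, and subject-level individual variability.
Passing tests on surrogates therefore validates the machinery and the
qualitative phenomenology (hysteresis, threshold ordering,
strength–threshold anticorrelation, weight/path-ordered recruitment),
not any patient-specific quantitative claim.

`synthEzPz()` builds EZ/PZ fixtures: the EZ drawn at random, the PZ as
the strongest-connected (or shortest-path) non-EZ regions, which is the
configuration the clinical evaluation layer expects.

## Graph metrics and clinical evaluation

`metricTable()` collects node strength (weighted degree), the Barrat
weighted clustering coefficient, average shortest path length under
reciprocal edge lengths $1/w$, and weighted betweenness centrality.
The printed formula for the weighted path average in the source
material divides path length by weight, which is dimensionally
inconsistent with the stated reciprocal relation ("doubling a weight
halves the distance"); we implement reciprocal edge lengths with
Dijkstra, which reproduces that halving property exactly. Betweenness
excludes endpoints and is unnormalized; pairs are unordered on
symmetric matrices, ordered on asymmetric ones. Disconnected pairs are
excluded from per-node averages and reported.

`pzFromEnergy()` is the simulated analogue of the SEEG energy rule: a
4th-order zero-phase Butterworth band-pass (1–50 Hz), energy as the sum
of squared samples, inclusion at 30% of the maximum over regions, EZ
always excluded. It operates directly on simulated region voltages
rather than electrode contacts — a stated substitution, not an
equivalence. `mannWhitneyPz()` tests one-sided for earlier PZ
recruitment (exact null for group sizes up to 8 without ties, normal
approximation with tie correction otherwise; an all-tied comparison
carries no information and reports p = 0.5). Unrecruited regions are
excluded by default rather than imputed — the source experiments
recruit essentially all regions, so inventing censoring semantics would
add assumptions without data to support them; a `max_rank` mode is
provided.

`stSpectrogram()` estimates spectrograms of simulated voltages with
0.2 s Hann windows at 95% overlap, power normalized to its global
maximum, log10 scale clipped at $-2$, and the time axis shifted right
by half a window for causality. The clipping threshold is read as
applying to the normalized linear power (so the floor is exactly $-2$
on the log grid); the framing satisfies "slice count =
$\lfloor (L - w)/h \rfloor + 1$" exactly, which is why the frames are
built in package code on top of the base FFT.

## Numerical choices and degenerate inputs

* Network integration: explicit RK4, default `dt = 0.01` ms (several
  dozen steps per period of the fastest damped focus oscillations);
  protocol wrappers accept `dt`, and the test-suite examples run at
  0.05 ms, which changes LA terminal states by less than $10^{-8}$.
  Divergence raises an error naming the blow-up time.
* Fixed points: the equilibrium quartic is solved through the
  companion-matrix eigenvalues; roots with $|\mathrm{Im}| < 10^{-9}$
  and $r > 10^{-12}$ are kept, near-coincident roots are collapsed and
  flagged `degenerate`, and zero-real-part Jacobian eigenvalues yield
  the label `"degenerate"` rather than a guess.
* Region labels outside the bistable wedge: a single equilibrium is
  called high-activity only when its focus is underdamped
  ($|\mathrm{Im}\,\lambda| > |\mathrm{Re}\,\lambda|$). At zero
  self-coupling every equilibrium is formally a focus with a vanishing
  imaginary part, so a literal node/focus rule would mislabel the deep
  low-activity region.
* Saturated scans: excitabilities where the network LA state cannot be
  prepared (only the all-HA state remains) are flagged and excluded
  from threshold minimization, not treated as errors.
* All protocol randomness (synthetic connectomes, EZ draws, Gaussian
  excitabilities) flows through explicit integer seeds; identical
  configurations reproduce bit-identically.

## Problem sizes used by the tests

The shipped tests run the exactness check at $N = 10^4$ neurons over
4 s of biological time, the sweep protocols on a 90-region synthetic
connectome at the protocol's native grid ($\Delta\bar\eta = 1.5$, 2 s
settling), and the threshold scans on 20-region synthetic connectomes
with a coarsened grid ($\Delta\bar\eta = 0.5$); these sizes exercise
every code path at full fidelity while keeping a complete run on a
single CPU in the tens of minutes. The full-resolution protocols
(90 regions, $\Delta\bar\eta = 0.1$, $\sigma$ maps at $\Delta\sigma =
0.05$) are the documented defaults and run unchanged — they simply take
hours rather than minutes.

## Known limitations

* No synaptic kinetics, conduction delays, gap junctions, plasticity or
  stochastic input: recruited activity is instantaneous-synapse,
  delay-free, and seizure-like events terminate only by returning to
  LA (no self-sustained ictal oscillation, no spontaneous onset).
* The clinical evaluation layer scores *simulated* recruitment against
  EZ/PZ hypotheses; it does not read SEEG recordings or model
  electrode physics.
* The finite-$N$ voltage comparison is limited by Lorentzian tail
  truncation as described above; rates are unaffected at the percent
  level.
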