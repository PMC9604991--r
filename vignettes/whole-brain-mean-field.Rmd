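---
title: "A delayed mean-field Kuramoto model of whole-brain alpha dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A delayed mean-field Kuramoto model of whole-brain alpha dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oanet)
```

## The model

`oanet` simulates resting-state electrophysiological dynamics on a
connectome with one of the most parsimonious biophysically interpretable
constructions available: every cortical region (*ensemble*) is an infinite
population of Kuramoto phase oscillators with Lorentzian-distributed
natural frequencies (center $\Omega$, half-width $\Delta$), fully and
instantaneously coupled within the region with strength $L_n$. The
Ott--Antonsen ansatz reduces each such population exactly to one complex
Kuramoto order parameter $z_n = r_n e^{i\psi_n}$, whose modulus $r_n \in
[0,1]$ *is* the local synchrony of the region — the quantity whose
modulations appear in electrophysiology as event-related
(de)synchronization. Regions interact through fiber densities $A_{np}$
with conduction delays $\tau_{np} = D_{np}/v$:

$$
\dot r_n = -\Delta r_n + \tfrac{L_n}{2}(1-r_n^2)\,r_n
  + \tfrac{G}{2E}(1-r_n^2) \sum_{p\neq n} A_{np}\, r_p(t-\tau_{np})
    \cos\!\big(\psi_p(t-\tau_{np}) - \psi_n\big)
$$
$$
\dot\psi_n = \Omega + \tfrac{G}{2E}\Big(r_n + \tfrac1{r_n}\Big)
  \sum_{p\neq n} A_{np}\, r_p(t-\tau_{np})
  \sin\!\big(\psi_p(t-\tau_{np}) - \psi_n\big)
$$

Two closed forms anchor the numerics. An isolated ensemble ($G=0$) has the
stationary synchrony $r^{eq} = \sqrt{1 - 2\Delta/L}$ for $L > L^c = 2\Delta$
and decays to incoherence below $L^c$; and the mean phase of a decoupled
ensemble advances at exactly $\Omega$, so the neural signal
$\mathrm{Im}(z_n) = r_n \sin\psi_n$ peaks spectrally at $\Omega$. Both are
verified by the test suite, together with a brute-force check: a finite-$N$
network-of-networks Kuramoto simulator (`simulate_micro()`) whose $N \to
\infty$ limit is the reduced system, run on matched instances.

### Units

$\Delta$, $L$, $G$ are rates in s$^{-1}$ and $\Omega$ is given in Hz
(converted to rad/s internally). This is the only reading under which the
defaults $\Omega = 10.5$, $\Delta = 1$ place the spectral peak at 10.5 Hz
while keeping the critical coupling at $L^c = 2$. Distances are stored in
mm (MNI convention) and converted to meters only when delays are formed
from the velocity $v$ (m/s); `v = Inf` is the zero-delay sentinel.

## Numerical scheme

The system is a delay differential equation; it is integrated with the
time-delayed first-order Euler method at `dt = 1e-3` s. Design choices a
maintainer should know:

* **Delays on the step grid.** Each $\tau_{np}$ is rounded to the nearest
  whole number of steps; no interpolation is done in the history ring
  buffer, consistent with the first-order accuracy of the scheme.
* **History.** Because of the delays an initial *history* is needed on
  $[-\tau_{\max}, 0]$. Initial phases are drawn uniformly on $[-\pi,\pi)$,
  initial synchrony sits at the clamped decoupled equilibrium, and each
  ensemble is advanced independently (global coupling forced to zero) with
  the same Euler scheme to fill the buffer.
* **The $1/r$ singularity.** The phase equation contains $1/r_n$, which is
  undefined at full desynchronization. `r` is clamped to
  `[r_floor, 1]` with `r_floor = 1e-3` (configurable): small enough that
  desynchronized ensembles remain strongly phase-susceptible — the
  mechanism by which FC emerges — while bounding $\dot\psi$.
* **Phase wrapping.** $\psi$ is wrapped to $[-\pi,\pi)$ after every step;
  all phase differences are evaluated through complex products, so
  wrapping never introduces discontinuities in the dynamics.
* **Instability detection.** A non-finite state aborts with the step
  index; the remedy is a smaller `dt`.

The same kernel backs two entry points: `integrate_model()` returns full
trajectories; the fitness path accumulates the synchrony summaries inside
the compiled loop and records the neural signal at 250 Hz (the signal is
confined to the alpha band, so the 8--13 Hz envelope is unaffected; the
static-FC difference against the full-rate path is below $2\times10^{-5}$).

### Locating the critical coupling numerically

`find_critical_coupling()` recovers $L^c$ by bisecting on whether the
*stationary* synchrony exceeds $10^{-3}$. Near criticality transients decay
at rate $|1 - L/2\Delta|$, which is arbitrarily slow, so no fixed horizon
can classify reliably; each probe therefore integrates in 50 s blocks until
the trajectory either reaches the clamp floor (decayed), flattens out
(plateau), or shows a constant negative log-slope (pure exponential decay
with no plateau forming). This classifies correctly at the
$\pm 0.02$ level in well under a minute.

## The functional-connectivity pipeline

Simulated "MEG" analysis mirrors standard envelope FC:

1. band-pass 8--13 Hz, zero phase;
2. Hilbert envelope (analytic-signal magnitude);
3. low-pass the envelope at 0.5 Hz, zero phase;
4. discard 1 s at each end (filter edge artifacts);
5. downsample to 5 Hz;
6. static FC = pairwise Pearson correlations of the envelopes; time-resolved
   FC = correlations between the upper-triangle FC vectors of 15 s windows
   sliding by 3 s, compared between conditions by the two-sample
   Kolmogorov--Smirnov statistic on the raw recurrence samples (no
   histogram binning — this removes bin-width arbitrariness).

Both zero-phase filters have a fourth-order Butterworth magnitude response,
realized by evaluating the squared magnitude of a second-order digital
Butterworth on the FFT grid of the (2-3-5-smooth padded) signal. This
equals the steady-state forward-backward recursive filter; the difference
is confined to edge transients that step 4 discards. It is also what makes
a 20-run fitness evaluation affordable: recursive `filtfilt` costs roughly
20 s per 16-region run, the spectral route a few hundredths of a second.

Simulated signals are never orthogonalized (there is no source leakage in
a simulation); empirical inputs are assumed leakage-corrected upstream.

## Fitness and optimization

One fitness evaluation simulates a batch of (by default) 20 runs with
identical parameters and different initial phases (seeds fixed per batch,
so optimizers see a deterministic objective), takes the element-wise
median static FC, and gates on four batch medians of biological
plausibility: $0.25 < \langle R\rangle_t < 0.8$, $SD(R)_t > 0.05$ (and the
same pair for local synchrony), all strict. Feasible candidates score the
upper-triangle correlation with the target FC; infeasible ones score
$-2 - (\text{number of violated constraints})$ — strictly below every
correlation, yet graded so that an optimizer can descend the violation
count.

Two stochastic optimizers are provided: canonical inertia-weight PSO
(inertia $0.7298$, cognitive = social = $1.49618$, velocity clamped to half
the range) and a jDE-style self-adaptive DE (DE/rand/1/bin, per-individual
$F \in [0.1,1]$ and $CR \in [0,1]$ regenerated with probability 0.1,
strict greedy selection so ties keep parents). Scenario 1 searches
$(G, L, v)$ in $[0,10]\times[-5,6]\times[1,40]$; scenario 2 fixes $G, v$
and searches one coupling per homotopic pair.

## The synthetic connectome

Tractography-derived connectomes are outside the package's scope, so
`synthesize_connectome()` generates a stand-in with the features the model
cares about: hemispheric mirror symmetry (homotopic pairs), exponential
distance-dependent fiber density (`exp(-D/40 mm)`) with log-normal jitter
(SD 0.5 on the log scale — a moderate heterogeneity chosen once as
realistic for fiber-count data), pruning of the weakest 20% of edges, and
normalization to unit mean nonzero edge weight. Barycenters are drawn in a
140 × 180 × 120 mm box and mirrored across the midsagittal plane.

On normalization: descriptions of connectome scaling conflate "average
degree 1" and "average edge weight 1", which differ. The package adopts
mean *nonzero edge weight* = 1 as the default and offers mean row-sum
(degree) = 1 behind `method = "degree"`.

What the generator does **not** emulate: heavy-tailed streamline-count
distributions from probabilistic tractography, denser intra- than
inter-hemispheric wiring, and realistic barycenter geometry. Passing tests
therefore demonstrate correctness of the machinery on brain-*like*
networks, not fidelity to any empirical connectome.

## What the package verifies, and known limitations

The test suite pins: the critical coupling ($2\Delta \pm 0.02$ by
bisection), the closed-form equilibrium ($10^{-4}$), the 10.5 Hz spectral
placement, full global synchrony ($\bar R \approx 1$) when delays are
zeroed at FC-range couplings, finite-$N$/mean-field agreement (median
trajectory RMSE $< 0.05$ at $N = 5000$, shrinking with $N$), the exact
combinatorial surface of the trFC pipeline (96 windows and 4560 recurrence
pairs from 300 s at 15 s/12 s), and the penalty/feasibility ordering of the
fitness.

Limitations worth knowing:

* **Finite-size matching has a floor.** $N$ sampled phases cannot
  represent an order parameter below $\sim 1/\sqrt{N}$, so
  micro-vs-reduced comparisons are matched at $r_0 = 0.3$, above that
  floor; comparisons seeded at the incoherence floor measure the
  initial-condition gap, not reduction error. Similarly, the prescribed
  $\pm 20$-HWHM truncation of the Lorentzian tails (needed for a bounded
  Euler step) raises the locked fraction slightly, biasing the finite-$N$
  plateau $\approx 0.03$ above $\sqrt{1-2\Delta/L}$.
* **Parameter recovery on small synthetic networks is brittle.** On
  16-region synthetic connectomes the moderate-coupling FC regime is
  largely infeasible under the plausibility gate — e.g. $(G, L, v) =
  (3.5, 1, 3.5)$ produces near-full synchrony ($\bar R \approx 0.98$,
  $SD(R)_t \approx 0.02$) — and the dynamics near the feasibility boundary
  are bistable, so batch medians flip between branches. A feasible regime
  does exist at high global coupling ($G \approx 9.6$), where the
  explorative DE reaches a 20-run fitness of about 0.78 against a
  model-generated target within a pop-10 × 15-generation budget, while
  the exploitative PSO stalls on the flat penalty plateau. The recovery
  harness is kept in the acceptance tests with its target quality
  asserted as designed; the shortfall is a property of small homogeneous
  synthetic networks and the coarse penalty landscape, not of the
  optimizer implementations (both pass the standard sphere benchmarks).
* Heterogeneous $\Omega_n$, $\Delta_n$ across ensembles are accepted by
  the data structures but defaults are identical and sweeps are untested.
  Stochastic (noise-driven) variants and higher-order DDE solvers are out
  of scope.

## Problem sizes used by the checks

Desk-scale sizes keep the full suite affordable: bifurcation probes are
single-ensemble 50 s blocks; the oracle comparison uses 2 ensembles
× 10 s × $N \in \{500, 5000\}$ over 5 seeds; the whole-network synchrony
check is one 68-region 66 s run; the recovery harness uses a 16-region
connectome, a 20-run target batch, 6-run search batches and pop 10 ×
15 generations per optimizer, with each optimizer's best re-scored under
the full 20-run protocol.
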