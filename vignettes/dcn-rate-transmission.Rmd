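---
title: "Rate transmission from Purkinje cells to the deep cerebellar nuclei: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate transmission from Purkinje cells to the deep cerebellar nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnsim)
```

`dcnsim` models the last stage of the cerebellar cortical circuit: the
conversion of irregular Purkinje-cell simple-spike firing into the
inhibitory drive received by deep cerebellar nucleus (DCN) projection
neurons. This vignette explains each model component, its assumptions
and parameters, the design choices where the biology or the problem left
the design open, and what the simulations can and cannot say about real
tissue.

## 1. Spike generation: a synchronized probability, independent outcomes

The central coding hypothesis is that rate information is carried by a
*moment-to-moment spike probability shared across the Purkinje cells of
a microzone*, not by spike timing. Each cell is therefore an
inhomogeneous Bernoulli generator on a fine grid:

- **Timestep** `dt = 0.05` ms. A rate of `N` Hz converts to a spike
  probability of `N * dt / 1000` per timestep (`N`/20,000 at the default
  grid), clamped at 1. `rate_to_probability()` performs the conversion
  and its inverse holds exactly below the clamp.
- **Rate profiles.** `constant_rate()` and `sinusoid_rate(a, b, lambda)`
  with instantaneous rate `b + a*sin(2*pi*t/lambda + phase0)`. The
  sinusoid emulates the smooth rise and fall of simple-spike rates
  across a locomotor step cycle. The constructor rejects `b < a`, which
  would imply negative rates. The cycle start is genuinely unspecified
  by the phenomenon being emulated; the default `phase0 = 0` (baseline,
  rising) is exposed as a parameter. Two conventional ranges are used in
  the experiments: 50–250 Hz (amplitude 100, baseline 150) for the
  step-cycle decoding experiments, and a 50–200 Hz sweep for the
  linearity experiments.
- **Refractory period** 1 ms (absolute), applied sequentially: a
  candidate spike within 1 ms of the cell's previous spike is
  suppressed. The refractory period lowers the realized rate below the
  nominal `N` (mean interspike interval `refractory + dt/p`, so ~167 Hz
  realized at a nominal 200 Hz). No correction is applied: the generator
  is used as described, and the linearity results inherit the small
  compression it causes. The period can be set to 0 where a pure
  Bernoulli process is wanted.
- **Reproducibility.** Each cell draws from a deterministic substream
  derived from the root seed by Lehmer-style mixing, so a fixed seed
  gives a bit-identical raster and the first *k* cells are unchanged
  when the ensemble is enlarged.

The generator deliberately omits everything else about Purkinje cells:
no biophysics, no complex spikes, no correlation between cells beyond
the shared probability. Passing tests therefore show that the *coding
scheme* behaves as claimed, not that real Purkinje trains are Bernoulli.

## 2. Decoding by convergence: counts, integration, jitter, reliability

A DCN is first modelled as a counter: `bin_counts()` sums spikes across
all afferents in 1 ms bins; `rolling_mean()` (trailing, "valid" edges)
is a minimal proxy for postsynaptic integration. Three statistics
summarize decoding quality:

- **CV** of the binned counts (`cv()`): relative noise around the
  rate signal; falls as the convergence ratio rises.
- **Jitter** (`count_jitter()`): mean absolute difference between
  consecutive bins, divided by the convergence ratio, as a percentage.
  Absolute differences are used because the signed mean is ~0 by
  symmetry. Integration reduces jitter at every convergence ratio.
- **Reliability** (`reliability_curve()`): mean pairwise Pearson
  correlation between independently simulated cycles; rises with
  convergence with diminishing returns, most of the gain arriving below
  the physiological ~40:1.

Two open choices here were resolved as follows. The integration window
for "a rolling mean of consecutive counts" is 2 bins — the smallest
window that implements "consecutive" — and is exposed as `window`.
Correlations are computed on the integrated series by default (the
series the decoding argument is about), with `integrated = FALSE`
available; the qualitative ordering of the reliability curve does not
depend on this choice. Edges use the "valid" policy everywhere: no
padding values are invented.

## 3. Charge transfer: one spike, one quantum

`make_kernel(tau_ms, rise_ms, dt)` builds the unit current waveform: a
linear rise to peak 1 followed by `exp(-t/tau)` decay, truncated where
it falls below `1e-6` of peak so that convolution has bounded support
(the truncation bias is negligible at that threshold). The rise time is
one timestep (0.05 ms) by default — the minimal realization of a fast
rise — and configurable; only the rise/peak/decay constraints are fixed
by the model, not a specific analytic form such as an alpha function.
The decay constant is the key parameter: 1.25, 2.5, 5 and 7.5 ms span
the conditions studied, with ~2.5 ms the reported physiological value
in mice.

`superpose()` convolves the summed spike count per timestep with the
kernel (implemented with `stats::filter`, which matches a per-event loop
to machine precision). Linear superposition without saturation is a
*model assumption* — the claim that the quantum is inviolable — not a
numerical convenience. One quantum per spike per afferent is used;
bouton multiplicity is treated as normalized into the unit.

Consequences the tests verify: the long-run mean current is linear in
the discharge rate for every decay constant (R² ≈ 0.99 over a 50–200 Hz
sweep at 40 afferents; the small residual curvature is the uncorrected
refractory compression); absolute fluctuation around the mean *grows*
with the decay constant (longer quanta overlap into larger, smoother
excursions) while the relative CV shrinks as `1/sqrt(rate * tau)`, the
filtered-Poisson scaling; and a sub-millisecond trailing mean
(`rolling_current()`, 0.1–1 ms) removes proportionally more variance
for short decay constants, whose noise lives at high frequency.

## 4. Wiring a nuclear group: random samples and synchrony

`sample_wiring()` draws, for each of 50 DCNs, a uniform sample of 40 of
the 400 Purkinje cells afferent to the group — without replacement
within a DCN, independently across DCNs. `simulate_group()` drives all
400 cells with one shared sinusoidal probability over a 400 ms cycle and
builds each DCN's 1 ms-rolled current trace. Because each DCN estimates
the same population mean from its own sample, traces co-modulate tightly
(`group_synchrony()`); the spread of the per-afferent mean shrinks as
`1/sqrt(convergence)`, and the absolute across-DCN spread grows with the
decay constant, mirroring the single-cell result.

`simulate_subregions()` applies the same machinery within one soma: 40
somatic sites each sample 30 of a pool of 60 afferents (the pool
exceeds the ~40 "significant" afferents), giving 40 traces of 4,000
samples over 200 ms. `subregion_sweep()` shows the subdivision leaves
the linearity of the 200 ms mean essentially unchanged (ΔR² < 0.01,
seed-matched).

## 5. Collateral wiring analytics

With `m` presynaptic cells each contacting `z` of `n = 50` DCNs at
random (divergence 1:`z`), a given DCN is contacted by `y` of them with
the binomial probability `contact_pmf()`; `prob_at_least()` and
`joint_prob_x_dcns()` give the printed tail and joint forms. The joint
form assumes independence across DCNs, although the wiring fixes the
total contact count at `m*z`; it is implemented exactly as stated, and
`simulate_collateral_wiring()` — a direct Monte-Carlo draw of the wiring
— quantifies the (small, negatively-dependent) discrepancy rather than
correcting it. The per-DCN marginal distribution is exact either way,
so expectations such as the flagship *33 of 50 DCNs contacted by 10
cells at divergence 1:5* are exact.

`dcn_count_distribution()` reads out the number of spikes each DCN of a
wired group receives in one 1 ms bin at a shared constant probability
(147.5 Hz by default, a representative mid-cycle rate taken as a direct
parameter), raw or rolled. `resample_means()` then models
recurrent-collateral averaging: each DCN samples `sample_size = 5`
values of that distribution (the assumed 1:5 nucleo-nuclear divergence)
with replacement and averages them, narrowing the CV by ≈ √5.
With-replacement sampling matches the "anatomy simulates sampling with
replacement" picture; both the sample size and the replacement flag are
parameters.

## 6. The phase-shift model

Short-term depression and facilitation at the Purkinje–DCN synapse
cancel at a constant rate but not during rate changes; their net effect
is taken as *linear in the rate derivative*. With the rate
`f(t) = a*sin(2*pi*t/lambda) + b` (defaults a = 50, b = 75), the drive
is `f + w*f'`, where the weight `w` (ms) sets the relative influence of
plasticity. Since `f'` leads `f` by a quarter cycle, the sum is a
sinusoid of unchanged wavelength shifted left by `atan(2*pi*w/lambda)`
radians (`analytic_shift()`): in degrees the shift grows as the
wavelength shortens, in milliseconds it approaches the constant `w` for
`lambda >> 2*pi*w` — a fixed real-time advance, automatically adjusted
for cycle duration.

`measure_shift()` estimates the shift numerically — circular
cross-correlation via FFT, parabolic interpolation around the peak, a
positive sign meaning a leftward (earlier) shift — and agrees with the
closed form to well under 0.1° on a 10⁴-point grid. Both routes are
reported by `wavelength_sweep()` so that the estimator is always checked
against the closed form on the same grid. The time axis is taken in ms
throughout, so a curve written as `a*sin(z*x/pi)+b` has wavelength
`2*pi^2/z` ms (`wavelength_from_z()`). The derivative weights default to
`w = 1, 2.5, 5, 10` ms, spanning modest to strong plasticity influence;
no measured value exists for `w`, so it is always a free parameter list.
Mechanistic plasticity kinetics (the ~100 ms re-equilibration) and
multi-peaked cycles are out of scope.

## 7. Numerical choices and degenerate inputs

- Convolution: `stats::filter` on a zero-padded count vector — exact
  arithmetic, verified against a per-event loop at 1e-12.
- Rolling means: cumulative-sum differences; window 1 is the identity;
  windows larger than the series are rejected.
- Kernel truncation: `1e-6` of peak; quanta near the end of a trace are
  truncated by the trace boundary (charge conservation holds exactly for
  quanta that decay fully in-trace).
- Phase estimation: series must cover exactly one wavelength; the
  parabolic refinement is exact when the peak falls on the grid and
  O(grid²) otherwise; shifts are mapped to (−λ/2, λ/2].
- Degenerate inputs are rejected with errors: negative times or rates,
  zero wavelengths, convergence exceeding the population, bin widths
  not dividing the duration, windows below one timestep, empty sources.

## 8. Problem sizes and what the tests show

The test suite and the bundled experiments run the study conditions at
sizes chosen to make the statistical claims decidable in a few minutes
of CPU: 2–20 cycles per convergence ratio, 10–20 seeds per property,
a 5 Hz grid for the linearity sweep (the full 1 Hz sweep is the
`fig2` experiment default), 2×10⁴–10⁵ Monte-Carlo wiring replicates.
Monte-Carlo assertions use 3-standard-error bands around their
analytic oracles.

The synthetic generator emulates *rate-coded, probability-synchronized,
otherwise independent* afferent activity. Real Purkinje populations have
correlated irregularity, heterogeneous rates and boutons, non-stationary
cycles, and DCNs have intrinsic pacemaking and excitatory dendritic
input, none of which are modelled. Passing tests therefore validate the
statistical mechanism — convergence averaging, linear charge summation,
random-sample synchronization, derivative phase advance — under the
model's assumptions, not the physiological identification of those
assumptions.

## 9. Known limitations

- The DCN is a passive charge integrator here; no output spiking, so
  "synchronized firing" is read from synchronized somatic current.
- The refractory period makes the realized rate a slightly concave
  function of the nominal rate; linearity R² is ≈ 0.991, not 1.
- The joint collateral probability treats DCNs as independent (as
  stated); exact joint statistics would need the Monte-Carlo route.
- Group synchrony as mean pairwise correlation of rolled traces is
  ≈ 0.82–0.89 at the default conditions (one 400 ms cycle, τ ≤ 2.5 ms);
  it is asserted as a regression bound (> 0.85 at τ = 2.5), not as a
  physiological constant.
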