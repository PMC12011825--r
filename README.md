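# dcnsim

Simulation of rate transmission from cerebellar Purkinje cells to deep
cerebellar nucleus (DCN) projection neurons.

## The scientific problem

The cerebellum's output cells (DCNs) each receive convergent inhibition
from ~40 Purkinje cells, whose individual simple-spike timing is
irregular even when the underlying drive is smooth. `dcnsim` is for
computational neuroscientists who want to explore how a nuclear cell
group can nonetheless decode rate information quickly, linearly and
synchronously from such input, purely through the statistics of
convergence, random-sample wiring and linear charge summation — and how
short-term synaptic plasticity can phase-advance the decoded signal.

The model has four parts:

1. **Spike generation.** A Purkinje cell is a Bernoulli generator on a
   0.05 ms grid: at each timestep it spikes with probability
   *p = N·dt/1000* (i.e. *N*/20,000 at dt = 0.05 ms), where *N* is the
   instantaneous rate in Hz — constant, or a sinusoid
   *N(t) = b + a·sin(2πt/λ)* mimicking a locomotor step cycle. The
   probability is shared by every cell of a microzone ensemble; outcomes
   are independent. An absolute refractory period (1 ms) applies.
2. **Charge transfer.** Each spike injects a stereotyped unit quantum of
   inhibitory current: peak 1, fast rise, exponential decay with constant
   τ ∈ {1.25, 2.5, 5, 7.5} ms. Quanta superpose linearly, so the summed
   current per timestep is the convolution of the afferent spike count
   with the quantum kernel, and its 200 ms mean is linear in the
   discharge rate. Short trailing rolling means (0.1–1 ms) stand in for
   fast charge expulsion from the soma and dampen jitter.
3. **Population wiring.** Each of 50 DCNs samples 40 of the 400 Purkinje
   cells afferent to the group, uniformly and independently, so DCNs
   independently estimate the population mean rate and their currents
   co-modulate. Recurrent-collateral wiring is treated analytically: with
   *m* presynaptic cells each contacting *z* of *n* DCNs, a DCN is
   contacted by *y* of them with probability
   *P(y) = (z/n)^y (1−z/n)^(m−y) C(m,y)*, and resampling a distribution
   by means of samples of size *k* narrows its CV by ≈ √k.
4. **Phase shift.** Net short-term plasticity is modelled as a term
   proportional to the rate derivative; the drive *f(t) + w·f′(t)* is a
   sinusoid of unchanged wavelength shifted left by
   *atan(2πw/λ)* radians — a near-constant advance in milliseconds at
   physiological wavelengths, compensating transmission lag.

## Worked example

```r
library(dcnsim)

# one step cycle of 40 afferents, decoded by 1 ms binning + integration
profile <- sinusoid_rate(amplitude_hz = 100, baseline_hz = 150,
                         wavelength_ms = 200)
raster  <- generate_ensemble(profile, n_cells = 40, duration_ms = 200,
                             seed = 1)
counts  <- bin_counts(raster, bin_ms = 1)
count_jitter(counts)                          # 5.201005
count_jitter(rolling_mean(counts, 2), 40)     # 2.386364

# somatic current with the physiological ~2.5 ms decay constant
trace <- superpose(raster, make_kernel(2.5))
mean(trace)                                   # 12.68406
cv(as.numeric(rolling_current(trace, 1)))     # 0.4837057

# collateral wiring analytics: 10 Purkinje cells, divergence 1:5, 50 DCNs
expected_contacted(1, collateral_config(n = 50, z = 5, m = 10))
# $expected 32.56608   $rounded 33

# phase shift of rate + derivative, w = 5 ms on a 200 ms cycle
m <- phase_model(wavelength_ms = 200, w = 5)
t <- seq(0, 200, length.out = 1e4 + 1)[-(1e4 + 1)]
measure_shift(rate_curve(m, t), combined_curve(m, t), 200)
# <phase_shift> 8.927 deg = 4.959 ms = 2.480% of 200 ms wavelength
```

Interpretation: integrating consecutive 1 ms counts halves the bin-to-bin
jitter of the combined input (5.2% → 2.4% of the convergence ratio); the
1 ms-rolled current fluctuates with CV ≈ 0.48 around a mean that encodes
the rate; 10 presynaptic cells reach 33 of 50 DCNs on average; and a
derivative weight of 5 ms advances the 200 ms cycle by ≈ 5 ms (≈ 8.9°).

Figure-level experiments are bundled:

```r
run_experiment("fig5", out_dir = "out", seed = 1)
```

or from a shell:

```sh
Rscript inst/cli/dcnsim.R experiment fig5 --seed 1 --out out
Rscript inst/cli/dcnsim.R spikes --rate 200 --cells 40 --duration 200 --seed 1
```

Each experiment writes CSV tables plus a JSON metadata sidecar (full
configuration, seed, MD5 of the configuration); the same seed reproduces
byte-identical tables.

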