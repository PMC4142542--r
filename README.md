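# critnet

Criticality and attention in recurrent spiking networks.

Cortical local field potentials (LFPs) in visual area V4 show stronger
gamma-band (35–80 Hz) oscillations and better single-trial stimulus
decodability when the stimulus is attended. critnet implements a minimal
mechanistic account of that observation, for computational
neuroscientists who want to simulate it, probe it in parameter space, or
reuse its quantification chain on their own spike data: a sparse random
network of excitatory and inhibitory integrate-and-fire neurons, driven
by stimulus-specific Poisson input, in which attention is nothing but a
global change of coupling efficacy — a 10 % reduction of the inhibitory
scaling factor `j_inh` (with `J_inh = ε · J_exc · j_inh`). The package
then quantifies what that change does, with the same instruments used on
real recordings:

* **LFP synthesis** — exponential-kernel filtering (τ = 15 ms) of the
  summed recurrent + feedforward spiking activity;
* **spectra** — complex Morlet wavelet power at 20 log-spaced
  frequencies (5–200 Hz), time-averaged outside the cone of influence;
* **decoding** — leave-one-out linear SVM classification of single-trial
  spectra, and a closed-form discriminability index
  `DI = ⟨Φ(|p_i − p_j| / (σ_i + σ_j))⟩` over stimulus pairs,
  frequencies and trials, bounded in [0.5, 1] with a Gaussian null bias
  of `(1 + (2/π) arctan(1/√2))/2 ≈ 0.696`;
* **avalanche statistics** — cascade sizes/durations from a reduced
  simulation with separation of timescales, discrete power-law fits
  `P(s) ∝ s^(−τ)`, `P(T) ∝ T^(−α)` by Hurwitz-zeta maximum likelihood,
  the `⟨s⟩(T) ∝ T^(1/σνz)` slope by least squares, a Kolmogorov–Smirnov
  statistic, the crackling-noise relation `(α−1)/(τ−1) = 1/σνz`, and a
  binary supercriticality indicator γ that detects the tail bump of
  system-spanning events;
* **pattern entropy** — plug-in Shannon entropy of coarse-grained spike
  patterns at observation scales from single neurons (K = 1) to the
  population spike count (K = N);
* **phase-space drivers** — sweeps over `(J_exc, j_inh)` that locate the
  transition region `0 < ⟨γ⟩ < 1` between subcritical and supercritical
  dynamics, and the full attention contrast at an auto-tuned, marginally
  subcritical operating point.

## A worked example

Simulate one stimulus in the full 2500-neuron model, look at its
spectrum, then characterise a reduced network's avalanches:

```r
library(critnet)

cfg  <- network_config("full", j_exc = 0.4, j_inh = 0.8)
w    <- build_coupling(cfg$n, cfg$p, cfg$eps, seed = 1)
stim <- draw_stimulus_set(cfg$n, cfg$n_active, n_stimuli = 1, seed = 2)[[1]]
r    <- simulate_full(cfg, w, stim, seed = 3)
r
#> <spike_raster: full mode, 2500 neurons, 107350 spikes over 2500 ms (dt = 0.1 ms)>

spec <- lfp_spectrum(generate_lfp(r, c_mix = 0.2))
gamma_peak_prominence(spec)$excess
#> [1] 4.36891
```

The driven subnetwork fires at ~43 Hz and its LFP spectrum carries a
gamma peak ~4-fold above the 1/f background — the marginally
subcritical regime. The reduced model makes the avalanche picture
explicit:

```r
cfgA <- network_config("avalanche", j_exc = 0.6, j_inh = 0.8)
run  <- simulate_avalanche_mode(cfgA, build_coupling(1000, seed = 10), seed = 11)
fit  <- criticality_fit(collect_avalanches(run), n_system = 1000)
glance(fit)
#> # A tibble: 1 × 6
#>   tau_hat alpha_hat inv_snz   ks_d gamma n_events
#>     <dbl>     <dbl>   <dbl>  <dbl> <int>    <int>
#> 1    2.34      3.04    1.49 0.0309     0    86494
```

τ̂ = 2.34 and α̂ = 3.04 give `(α−1)/(τ−1) = 1.52` against
`1/σνz = 1.49` — the crackling-noise scaling relation holds to within a
few percent near the transition, the KS distance to the fitted power
law is 0.03, and γ = 0 says the size distribution has no supercritical
bump: this point sits just on the subcritical side. Raising `j_exc` to
1.0 flips γ to 1 as system-spanning cascades appear.

The attention experiment itself is one call
(`run_attention_contrast()`), and `run_coupling_sweep()` +
`locate_transition_region()` + `entropy_maxima()` reproduce the
phase-space portraits; `autoplot()` renders any of them.

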