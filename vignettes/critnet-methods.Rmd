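---
title: "Models and methods behind critnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind critnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

critnet simulates a stimulus-driven recurrent network of integrate-and-fire
neurons in which selective attention is modelled as a global change of
coupling efficacy, and quantifies how that change reshapes gamma-band
synchrony, single-trial stimulus decodability, neuronal-avalanche
statistics and the entropy of population spike patterns.  This vignette
explains the model, the estimators, the tunable parameters and their
defaults, the numerical choices, and what the synthetic study conditions
do and do not establish about real cortical data.

## The network model

Each of `N` neurons follows leaky integrate-and-fire dynamics,

$$\tau_{mem}\,\dot V_i = -(V_i - V_R) + \text{inputs},$$

with resting/reset potential $V_R = -60$ mV, threshold
$V_\theta = -50$ mV and membrane time constant $\tau_{mem} = 10$ ms —
textbook values for an average cortical neuron.  Inputs arrive as
voltage jumps: each external (feedforward) spike adds
$J_{ext} = 0.1$ mV, each recurrent spike adds $J_{exc}$ (excitatory
presynaptic neuron) or subtracts $J_{inh}$ (inhibitory).  The coupling
graph is a directed Erdős–Rényi graph with connection probability
$p = 0.02$, self-connections allowed; a fixed fraction
$\epsilon = N_{exc}/N_{inh} = 4$ of neurons is excitatory, identified by
index (the first 80 %) for determinism.  Inhibition is always
parameterised relative to excitation,

$$J_{inh} = \epsilon \cdot J_{exc} \cdot j_{inh},$$

so the dimensionless factor $j_{inh}$ moves the network along an
excitation–inhibition balance axis; $j_{inh} = 1$ balances the mean
recurrent drive exactly.  *Attention* is a global excitability increase,
implemented as a 10 % reduction of $j_{inh}$ from 0.80 to 0.72.

A stimulus drives a random subset of $N_{active} = 1000$ of the
$N = 2500$ neurons with independent Poisson spike trains at
$f_{max} = 10$ kHz (≈1000 afferents at 10 Hz each).  With
$\Delta t = 0.1$ ms each driven neuron receives on average one external
spike per step, and the mean asymptotic drive $V_R + \tau_{mem} J_{ext}
f_{max}$ sits exactly at threshold: firing is fluctuation-driven.
Different stimuli drive different (overlapping) subsets, so stimulus
identity lives purely in the connectivity of the activated subnetwork.

Integration is forward Euler at $\Delta t = 0.1$ ms.  In **full mode**
recurrent spikes are delivered at the next integration step (the
one-step delay stands in for synaptic latency; the instantaneous rule is
reserved for cascade bookkeeping below).  Runs last 2.5 s and the first
500 ms are discarded as transient.

**Avalanche mode** implements the separation of timescales needed for
exact cascade statistics in the reduced network ($N = N_{active} =
1000$, every neuron driven, architectures standing in for stimuli):
within a step, any threshold crossing starts a cascade that propagates
instantaneously through successive generations of postsynaptic neurons
until no new neuron crosses; each neuron fires at most once per cascade
and is held at $V_R$ for its remainder.  One cascade is one avalanche
with size $s$ = distinct neurons fired and duration $T$ = generations.
Simultaneous crossings in the same step seed a single avalanche
(generation 1): under separation of timescales, simultaneous triggers
are one event.  Reduced runs last 12 s.

**Membrane initialisation.**  Neurons start in an asynchronous state:
each potential is drawn so that, under a constant suprathreshold drive,
the neuron would reach threshold at a uniform-random phase of its
period.  The model's own mean drive asymptotes *exactly at* threshold
(infinite period), so the initialiser uses a suprathreshold asymptote,
by default twice the rest-to-threshold gap ($V^* = -40$ mV, period
$\tau_{mem}\ln 2$).  The choice only shapes the first few tens of
milliseconds, well inside the discarded transient.

## LFP synthesis and spectra

The LFP proxy is the exponential-kernel-filtered superposition of all
recurrent spikes plus external spikes scaled by a mixing constant:
counts per step of $(\text{V4 spikes}) + c_{mix}\,(\text{external
spikes})$, convolved causally with $K(t) = e^{-t/\tau_k}/\tau_k$,
$\tau_k = 15$ ms.  The kernel is truncated at $10\,\tau_k$ (relative
weight $e^{-10}$) and 50 ms (≈3.3 $\tau_k$) are trimmed from both ends
of the filtered trace.  $c_{mix} = 0.2$ in the full model; in reduced
runs $c_{mix} = 0$ — external input still drives the neurons but is
excluded from the signal so that trial-to-trial spectral variance
originates in the recurrent population.  Each external spike is counted
once per delivered spike (it targets exactly one neuron).

Spectra are computed with complex Morlet wavelets at $N_f = 20$
log-spaced frequencies between 5 and 200 Hz.  The centre frequency is
$\omega_0 = 6$ cycles — the standard admissible choice; analyses of this
kind conventionally cite the wavelet family without fixing the
parameter, so absolute power is convention-dependent.  Every downstream statistic (SVM, DI) is
invariant to monotone per-frequency rescalings, which removes that
dependence.  The scale–frequency map and the cone of influence (COI,
e-folding time $\sqrt{2}s$ of wavelet power) follow the Torrence–Compo
convention; power is averaged over time using only samples outside the
COI, and a frequency whose COI swallows the whole trace is flagged
invalid and dropped from all downstream statistics (on 12-s reduced runs
cut into 36 trials this removes the lowest 3 of 20 frequencies — a
geometric consequence of 300-ms trials, not a numerical accident).

Long reduced-mode runs are segmented into $N_{tr} = 36$ contiguous
equal trials *before* wavelet analysis, so each trial excludes its own
COI.

## Decoding: SVM and the discriminability index

Single-trial decodability is measured two ways.

1. **Leave-one-out linear SVM** (libsvm via e1071, one-against-one,
   cost $C = 1$, a recorded package constant; features are the raw per-frequency
   time-averaged powers, unnormalised).  Each of $N_{tr}$ folds holds
   out one randomly assigned trial per stimulus, trains on the remaining
   $(N_{tr}-1)N_a$ spectra and classifies the held-out $N_a$.

2. **Discriminability index (DI).**  For every unordered stimulus pair,
   frequency and trial,
   $$Z = \frac{|p_i(f,tr) - p_j(f,tr)|}{\sigma_{tr}(p_i(f)) + \sigma_{tr}(p_j(f))},$$
   scored as $\Phi(Z) = (\operatorname{erf}(Z/\sqrt2)+1)/2$ and averaged
   over pairs, frequencies and trials.  $\Phi(Z)$ is the
   area-under-ROC of two unit-variance normals at separation $Z$ — the
   scoring fixed here because it is the one with that ROC
   interpretation, and it gives the estimator's finite-trial null bias
   in closed form: with all stimuli drawn from one Gaussian
   distribution, $DI \to (1 + \tfrac2\pi \arctan(1/\sqrt2))/2 \approx
   0.696$ (`di_null_bias()`), the characteristic ≈0.69 floor of this
   index on finite trial counts.  A zero denominator scores 1 when the
   numerator is positive and 0.5 when it is zero.

## Avalanche criticality statistics

Avalanche sizes are fitted with the discrete power-law maximum
likelihood of Clauset and colleagues: log-likelihood
$-n\ln\zeta(\tau, s_{min}) - \tau\sum\ln s_i$ with the Hurwitz zeta
normalisation, maximised on a grid over $[1.1, 4]$ with spacing 0.001
(ties toward the smaller exponent; the grid resolution is our
documented choice).  The zeta function is evaluated by a 2000-term
partial sum with an Euler–Maclaurin tail, accurate to well below
1e−12, and checked in the tests against the Riemann zeta and the
recurrence $\zeta(\tau,a)-\zeta(\tau,a+1)=a^{-\tau}$.

Data are windowed to $s_{min} = N/100 \le s \le s_{max} = 0.6N$;
durations use $[5, 30]$.  Two
normalisations are available:

* `"tail"` (default, used in the avalanche pipeline): $\zeta(\tau,
  s_{min})$ over the unbounded support.  The upper cut-off only windows the data, which keeps the
  exponent representative of the mid-range when a supercritical bump is
  present.  On genuinely truncated samples this estimator is biased
  upward by the missing tail mass (≈+0.16 at $\tau = 1.5$ on
  $[10,600]$).
* `"window"`: $\zeta(\tau,s_{min}) - \zeta(\tau,s_{max}+1)$, the
  matched normalisation that is consistent for draws living on the
  finite window; parameter-recovery checks use it.

$\langle s\rangle(T)$ is fitted on $T \in [2,20]$ with the closed-form
least-squares slope in log–log coordinates, giving $1/\sigma\nu z$, and
the crackling-noise relation $(\alpha-1)/(\tau-1) = 1/\sigma\nu z$ is
evaluated as a residual.

The goodness-of-fit statistic is $D = \max_{s \ge N/100} |F(s) -
F_{fit}(s)|$.  $F$ is the empirical CDF *conditioned on $s \ge
s_{min}$* (the standard convention when a power law is fitted above a
cut-off); the unconditional reading would saturate $D$ at every
subcritical point with the never-fitted mass below the cut-off,
contradicting the low-and-noisy subcritical $D$ landscape this analysis
is meant to reproduce.  Empirically the conditional $D$ is ~0.02–0.03
near the transition and 0.7–0.96 deep in the supercritical regime.

The binary supercriticality indicator is
$$\gamma = \mathbb 1\left[F(N) - F(0.6N-1) >
F'_{fit}(N) - F'_{fit}(0.6N-1)\right],\qquad
F'_{fit}(s) = F_{fit}(s)\frac{F(N/100)}{F_{fit}(N/100)},$$
with non-integer arguments floored: supercritical distributions carry
more tail mass beyond $0.6N$ than their rescaled mid-range fit.  Grid
points where the stimulus-averaged $\langle\gamma\rangle$ lies strictly
between 0 and 1 form the *transition region*.

## Pattern entropy and observation scale

Spike patterns are read at an observation scale $K$: neurons are
permuted once by a fixed random order (drawn per architecture,
persisted, reused across every $K$ and every grid point, so the scales
nest) and summed in consecutive blocks of $K$, giving $N/K$ channels.
$K=1$ is the raw binary pattern; $K=N$ the population spike count.
Entropy is the plug-in $H = -\sum p\log_2 p$ over post-transient steps,
deliberately without bias correction: the $K=1$ regime is undersampled
by construction and all comparisons are relative across a grid computed
at equal sample sizes.  In avalanche mode a whole cascade occupies one
step, so patterns contain complete avalanches.  The default ladder
$K \in \{1,2,5,10,50,100,250,500,1000\}$ spans single-neuron to
whole-population read-out; scans in the tests use the sub-ladder
$\{1,10,100,1000\}$.

## The coupling-plane sweep

`run_coupling_sweep()` evaluates a rectangular $(J_{exc}, j_{inh})$
grid with the reduced model: per point and architecture it runs the
cascade simulation, fits the criticality statistics, computes DI across
architectures from the segmented LFP spectra, and the entropy ladder.
Per-point seeds derive deterministically from the master seed and the
grid coordinates, so results are independent of execution order.  The
test grid uses six values per axis chosen to straddle the sub- to
supercritical border at each inhibition level ($J_{exc} \in \{0.3,
0.43, 0.6, 0.85, 1.2, 1.7\}$ mV, $j_{inh} \in \{0.3, 0.45, 0.6, 0.75,
0.9, 1.0\}$), with three architectures and 12-s runs: the transition
is sharp in $J_{exc}$, and a grid that does not straddle the border
contains no mixed-$\gamma$ cells to analyse.  The number of
architecture realisations in reduced sweeps is a free design size;
three is the affordable choice that still distinguishes
mixed from unanimous cells ($\langle\gamma\rangle \in \{0, \tfrac13,
\tfrac23, 1\}$).

**Scaling-relation check.**  At each transition point the residual
$(\alpha-1)/(\tau-1) - 1/\sigma\nu z$ (stimulus means) is compared with
the bootstrap spread of the left side.  The bootstrap resamples *both*
levels — architectures, the unit of replication, and each architecture's
avalanches — because the estimand is a stimulus average and the
across-architecture component dominates its uncertainty.  A known
limitation: near $\tau \to 1$ the left side has derivative
$-\,\text{lhs}/(\tau-1)$ in $\tau$, so small tail-normalisation bias in
$\hat\tau$ can move the residual beyond any variance-based spread; this
is a bias effect that no bootstrap width captures, and it shows up at
strongly-inhibited transition cells.

## The attention experiment and the operating point

`run_attention_contrast()` reruns the full model at $j_{inh} = 0.80$
(non-attended) and 0.72 (attended) with shared architectures, stimulus
sets and simulation seeds, so the conditions differ only in inhibitory
efficacy, and reports SVM accuracy and DI per condition for each
requested $c_{mix}$, from the same network runs.  Points where
stimulus-nonspecific (undriven) neurons exceed a mean rate of 1 Hz are
flagged excluded — the runaway co-activation regime is epileptic and
physiologically out of scope; the 1 Hz value is the package's
documented choice.

The excitatory coupling of the experiment has no canonical value; it
must be tuned to the intended *marginally subcritical* operating
regime.  `tune_operating_point()` (method `"full"`) scans a grid of
$J_{exc}$ with short full-model probes and selects the smallest value
whose architecture-averaged non-attended spectrum shows a gamma-band
peak at least 3-fold above the fitted 1/f trend — the onset of
collective synchrony — subject to the exclusion rule in both
conditions.  The 3-fold prominence constant operationalises "a clear
peak above the background"; prominence fluctuates strongly between
architectures, hence the averaging, and when no grid value reaches the
threshold the selection falls back to the onset of the profile's own
plateau (90 % of its maximum).  The alternative rule — smallest
$J_{exc}$ whose *reduced-model* $\langle\gamma\rangle$ exceeds zero
(method `"reduced"`) — lands around 1.1 mV, deep inside the full
model's excluded epileptic regime: the reduced cascade network
transitions at much higher coupling than the full network, which
recruits its undriven pool first.  It is retained for phase-space
exploration only.

**Known limitation — size of the attention effect.**  At the tuned
gamma-onset operating point the attended condition reliably strengthens
gamma-band power (the monotone excitability effect holds replicate by
replicate), but its decoding advantage is small — of the order of a few
accuracy points at scaled-down replicate counts, and occasionally
reversed by trial noise.  Large attention-driven accuracy boosts appear
in this model only at stronger coupling, close to the exclusion border,
where the baseline accuracy is already high.  Reported contrast
accuracies should therefore be read jointly with the operating point
the tuner selected.

## What the synthetic conditions do and do not show

All inputs are generated internally: random coupling graphs, Poisson
feedforward trains, random driven subsets.  The generator reproduces
the study conditions (sizes, rates, durations, replicate counts above),
so passing tests show that the estimators behave correctly *under those
conditions* — Gaussian trial-to-trial power variation for the DI null,
homogeneous random connectivity, stationary Poisson drive.  Real
cortical data differ in ways the model deliberately omits: structured
(non-Erdős–Rényi) connectivity with heavy-tailed degrees, heterogeneous
synaptic weights, conductance-based synapses, transmission delays
beyond one step, electrode/volume-conduction physics in the LFP, and
non-stationary behavioural states.  Quantities that depend on these —
absolute spectral power, absolute decoding accuracy, the location of
the transition in physical coupling units — should not be read as
cortical predictions; the robust objects are the relative ones
(sub/supercritical structure, the confinement of discriminability
enhancement to the transition neighbourhood, entropy-maximum shifts
with observation scale).

## Numerical choices and degenerate inputs

* Euler step fixed at 0.1 ms; external input realised as one Poisson
  total per step assigned uniformly over the driven subset (exactly
  equivalent to independent per-neuron Poisson counts, cheaper to draw).
* Cascades assert termination within $N$ generations (guaranteed by
  once-per-cascade refractoriness).
* The LFP convolution runs via FFT and matches the direct truncated-
  kernel sum to ~1e−13.
* Wavelet transforms zero-pad to the next power of two against
  wraparound; the mean is removed per trace.
* Exponent grid ties break toward the smaller exponent (first maximum).
* Empty fitting windows, single-support $\langle s\rangle(T)$ fits and
  all-inside-COI frequencies return flagged invalids, not errors;
  degenerate all-identical spectra classify at chance and give
  $DI = 0.5$ exactly.
* All stochastic entry points take explicit seeds; per-task streams are
  derived by an integer hash (`derive_seed()`) so sweeps are
  order-independent and bit-reproducible.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run scaled-down replicate
counts chosen as the package's own study sizes: the attention contrast
uses 2–3 architectures × 6 stimuli × 10 trials per condition (a
full-scale study would use 5 × 6 × 20), direction-of-effect replicates use
1 × 4 × 3, and the sweep uses the 6 × 6 grid above with 3
architectures.  DI-bias and estimator-recovery checks use 200
replicates and 1e5 draws respectively, where runtime is negligible.
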