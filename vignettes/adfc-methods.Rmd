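---
title: "Adaptive delayed feedback control: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive delayed feedback control: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adfc)
```

This vignette is the package's own account of the science it implements:
the control law and its assumptions, the activity metrics, the simulated
testbed, and the choices we made wherever the design was genuinely open.

## The control law

Populations of neurons that should fire sparsely and independently can
lock into quasiperiodic network bursts. Delayed feedback control treats
the population firing rate FR(t) — spikes per active electrode per second
in a sliding square window — as the controlled variable. FR is filtered by
a damped oscillator

$$\ddot x + \omega \dot x + \omega^2 x = k\,\mathrm{FR}(t), \qquad k=\omega ,$$

whose derivative output $\dot x$ isolates the rhythmic component of the
rate around the natural frequency $\omega$. The actuation signal is

$$\mathrm{SF}(t) = K\,\bigl(\dot x(t - T/2) - \dot x(t)\bigr),$$

the gained difference between the half-period-delayed and the current
oscillation. Two properties make this the right feedback signal:

* for a rhythm of period $T$, $\mathrm{SF}$ is maximal exactly in
  antiphase with the oscillation (for $\dot x = \sin(2\pi t/T)$ the
  difference is $-2K\sin(2\pi t/T)$), so stimulation counteracts the
  rhythm rather than reinforcing it;
* for constant (asynchronous) activity the difference vanishes, so a
  desynchronised network is not stimulated — control is minimal
  intervention, not a pacemaker.

The choice $k=\omega$ keeps the loop gain period-invariant: the transfer
function from FR to $\dot x$ is $ks/(s^2+\omega s+\omega^2)$, which at
$s=i\omega$ equals $k/\omega = 1$ — unit gain, zero phase — for every
$\omega$. Networks with 0.5 s rhythms and networks with 5 s rhythms see
the same effective gain.

Stimuli are emitted when $t > t_{last} + 1/\mathrm{SF}(t)$, gated by
bounds `sf_min` < SF < `sf_max` (defaults 1 and 20 Hz). The lower bound
keeps background actuation from triggering; above the upper bound SF is
*clipped* to `sf_max` rather than suppressed — the bound exists because an
actuation chain has finite latency, and a rhythm strong enough to saturate
the controller should be stimulated at the maximal safe rate, not ignored.
Clipping also guarantees the inter-stimulus refractory interval
$1/\texttt{sf\_max}$, which the tests verify on every schedule.

### The adaptive component

Fixed-$T$ DFC assumes a stationary rhythm. Living networks drift, and a
delay tuned to the wrong half-period moves the stimulation phase away
from antiphase; when the true period passes $T/2$ resonance conditions the
sign of the actuation flips and stimulation lands in phase — the regime in
which feedback stimulation *reinforces* the oscillation. aDFC closes this
gap: network bursts are detected online as debounced upward threshold
crossings of FR (threshold typically 10 Hz, minimum separation 0.1 s),
and at each detected burst the period estimate is refreshed as the
**median of the last 3 inter-burst intervals**, with
$\omega = 2\pi/T$ updated simultaneously. The median is robust to one
missed or spurious burst; three intervals is the shortest window that
still has a meaningful median, keeping adaptation lag at roughly two
burst cycles. Both the interval count and the detector parameters are
configuration fields. Before the first two bursts the operator-supplied
initial period is used, mirroring the pre-experiment monitoring with
which such controllers are deployed.

### Numerical choices

* **Discretisation.** The filter is advanced with the exact zero-order-hold
  propagator of the linear system (the $2\times2$ matrix exponential in
  closed form, input held constant over each sample). This is
  unconditionally stable, costs the same as an Euler step, and agrees with
  the closed-form impulse response (decay $\omega/2$, ringing
  $\omega\sqrt3/2$) to machine precision; a first-order Euler scheme at
  the same step leaves an $\mathcal O(\omega\,\mathrm{d}t)$ bias in the
  decay rate that is visible at the $10^{-3}$ level.
* **Delay with time-varying T.** The delayed sample is read at
  $t - T(t)/2$ with the *current* estimate, linearly interpolated between
  stored samples; history before the stream start is zero, so the first
  half-period of actuation is a transient.
* **Causality.** The controller consumes one FR sample at a time and never
  looks ahead; the test suite verifies truncation equivalence (the
  schedule up to $t$ is unchanged if the input ends at $t$).

## Activity metrics

**χ synchrony.** Each active channel is binarised into an occupancy
signal $V_i(t)$: 1 wherever a 50 ms box centred on any spike covers the
sample, on a 1 ms grid (the grid is ours to choose; 1 ms is well below
the box width so discretisation is negligible). Then

$$\chi^2 = \frac{\operatorname{Var}\bigl(\tfrac1N\sum_i V_i\bigr)}
                {\tfrac1N\sum_i \operatorname{Var}(V_i)} .$$

Binarisation makes the measure one of *co-activation*: an electrode
contributing many spikes per burst counts the same as one contributing
few. We report $\chi$ (the square root), which lives on the interpretable
$[0,1]$ scale used by the asynchronous-state threshold of 0.5; $\chi^2$
is attached as an attribute. Identical trains give exactly 1; $N$
independent trains give $\approx N^{-1/2}$; perfectly interleaved
activity gives 0. All-silent inputs return `NA` with a warning rather
than dividing by zero.

**Oscillation intensity.** The SNR (dB) of the fundamental of the Welch
PSD of the mean-removed FR. Welch parameters — segment length
$\min(n/8, 2048)$ samples, 50% overlap, Hann taper — are recorded in the
output, since only the estimator, not its parameters, is canonical. The
fundamental is the PSD maximum outside the DC band. For the noise power,
DC, the fundamental and its first 6 harmonics are excluded, each band
widened **from its centre bin out to the local minima of the PSD**
(minimum half-width 1 bin). A fixed one-bin guard is not enough: with a
Hann taper a line midway between bins spreads over $\pm2$ bins, and the
leaked power would be counted as noise — large enough to destroy the
defining property that doubling the oscillation amplitude adds
$20\log_{10}2 \approx 6$ dB. Local-minimum delimitation is also how the
classic SNR estimators delimit harmonic regions. The excluded bands are
back-filled at the mean noise density, so the reported ratio is
fundamental-band power over total noise power. The tests hold this
estimator to within 1 dB of an independent raw-periodogram bookkeeping
oracle and to $6.0 \pm 0.5$ dB under amplitude doubling.

**Wavelet spectrogram.** An analytic Morlet transform
($\omega_0 = 6$) over log-spaced frequencies, 0.05–5 Hz by default — the
period range of network bursts in the seconds scale. Used
qualitatively: the ridge (per-time argmax) tracks the instantaneous burst
frequency, e.g. under period drift.

**Sliding-window metrics.** Firing rate and χ in a moving window whose
width spans five periodic events (five median inter-burst intervals),
stepped by half a width; burst-free recordings fall back to a fixed 10 s
window (logged). Activity flags are inherited from the whole recording so
windows remain comparable.

## The in silico testbed

All-to-all networks of Izhikevich neurons: regular-spiking excitatory
cells ($a=0.02, b=0.2, c=-65, d=8$) and fast-spiking inhibitory cells
($a=0.1, b=0.2, c=-65, d=2$), $v$ advanced at 1 ms steps with the
conventional two 0.5 ms half-updates, reset at $v \ge 30$ mV. Base
weights are uniform on $[0, 0.5]$ (excitatory columns) and $[-1, 0]$
(inhibitory), multiplied by a global `weight_scale`; each neuron receives
independent Gaussian noise per step (SD 5 excitatory / 2 inhibitory, the
conventional thalamic drive). Self-connections are excluded by default —
biologically motivated, configurable. A random pool (default 100 neurons)
receives the stimulation current, +20 model units for exactly one step
per pulse; the model has no physical current scale, so "20" is
dimensionless.

A closed-loop run simulates 500 ms of stabilisation (discarded), an OFF
segment of spontaneous activity and an ON segment under aDFC driven by
the online population rate, 2000 ms each by default. Two tuning steps
mirror how such experiments are actually run:

* the burst threshold is set per simulation, midway between the median
  and the peak OFF-segment firing rate;
* the initial period is the median OFF-segment inter-burst interval.

In silico bursts recur roughly ten times faster than in cultured
networks, so the controller defaults rescale the in vitro parameters by
ten: FR window 10 ms, burst debounce 10 ms, SF bounds 10–200 Hz (the
20 Hz in vitro cap reflects hardware latency that a simulation does not
have). Only the positive part of the actuation drives stimulation here,
and gain 5 is the package default for the testbed.

The controllability map sweeps excitatory fraction × weight scale. For
tractable test and acceptance runtimes we run the map at $N=300$ neurons
on the grid $\{0.5, 0.7, 0.9\} \times \{1.5, 3, 4.5\}$ with 5 repetitions
per cell, sizes chosen once as the smallest preserving the regime
structure: the low corner is asynchronous ($\chi \approx 0.1$), the high
corner strongly synchronised ($\chi \approx 0.97$), and the intermediate
bursting regime is where aDFC reduces synchrony — the gradient and the
intermediate-regime rescue that the acceptance checks verify. A
zero-gain run is the matched null: identical loop, no stimuli.

## Trial analysis

OFF-ON-OFF trials yield a metric triplet per segment. Normalisation to
the pre-stimulation baseline is a *ratio* for synchrony and firing rate
and a *difference* for oscillation intensity (dB is already a log scale);
the identity trial maps to $(1, 1, 0)$ exactly.

Controllability is a one-way MANOVA (Wilks' lambda) of the per-trial
normalised ON metrics with protocol as factor, requiring at least three
trials per protocol; $p < 0.05$ labels the network controllable. We use
the *fold-change* triplet (synchrony, firing rate, oscillation dB) as the
response: normalisation removes between-trial baseline drift, which is
exactly what a controllability statement should ignore. Raw ON metrics
can be passed instead by building the trial table from unnormalised
values; oscillation *frequency* fold change is computed and can be added
as a fourth response column by the caller. The classifier's type-I error
is verified by simulation to sit at the nominal 5% and its power at
5-SD protocol separation is ~1.

State structure is found by Gaussian mixtures on the (firing rate,
synchrony) window table, full covariances, 1–4 components, selected by
BIC. Initialisation is model-based agglomerative (deterministic given the
data), plus 10 extra EM starts from random responsibilities seeded from
the user seed — the best BIC wins, so restarts can only improve on the
deterministic solution. Clusters with mean synchrony < 0.5 **and** mean
firing rate below the recording average are flagged as the asynchronous
state; time-in-AS is the percentage of window centres in a segment
carrying the flag.

## Synthetic data: what it does and does not emulate

The generators produce the *statistical shell* of cultured-network
recordings: quasiperiodic network bursts (rectangular rate envelope,
Gaussian onset jitter, per-burst channel participation), Poisson
background firing, regime concatenation for multi-stability, and linear
period drift. Rectangular envelopes are the simplest shape that exercises
every metric correctly; burst onsets are laid down at period intervals
with jitter and sorted, so ordering is preserved.

What they deliberately do **not** model: intra-burst rate profiles
(ramp-up/decay), electrode-specific amplitudes and noise, refractoriness,
spatial structure, slow non-stationarities, and any feedback of
stimulation on the generated activity. Consequently, passing tests show
that the *algorithms* behave as specified on inputs with known ground
truth — they do not certify performance on biological recordings, where
burst shapes are heterogeneous and stimulation perturbs the dynamics.
The closed-loop claims that need a reactive plant are tested on the
Izhikevich networks instead.

For the multi-stable round trip we plant 240 s of bursting and 60 s of
asynchronous activity (20% dwell) with realistic within-regime
variability (participation 0.6, period jitter 0.2 s, weak residual
bursting in the asynchronous regime). Degenerately clean regimes are
*harder* for model selection, not easier: with near-zero within-regime
variance the few windows straddling the regime switch sit many SDs away
from both clusters, and BIC correctly spends a third component on them.
Windows straddling a transition are a property of sliding-window
analysis, not of the clustering.

## Known limitations

* The delay buffer is zero-initialised, so the first $T/2$ of any run is
  a transient; quiescence claims are asserted after it.
* Online burst detection has no hysteresis; a threshold cutting through
  within-burst rate fluctuations can double-count a burst unless the
  debounce exceeds the burst envelope. The per-simulation midpoint
  threshold avoids this regime in the testbed.
* χ compares occupancy variances on a common grid; recordings shorter
  than a few boxes, or with fewer than two active channels, are rejected
  rather than estimated.
* The Izhikevich map at $N=300$ preserves regime ordering but not the
  absolute synchrony values of larger networks; weight scales are not
  transferable across $N$ without recalibration.
* MANOVA assumes within-group multivariate normality; with the minimum
  of three trials per protocol the test is exact only under that
  assumption, which the calibration suite samples from by construction.
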