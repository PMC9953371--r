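---
title: "Methods: CW Doppler radar vital-signs estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CW Doppler radar vital-signs estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The measurement model

A continuous-wave radar transmits an unmodulated tone at carrier frequency
$f_c$ (2.4 GHz by default, wavelength $\lambda = c/f_c = 12.5$ cm with the
rounded propagation speed $c = 3\times10^8$ m/s). Breathing and heartbeat
move the chest wall periodically; periodic motion has no net velocity and
therefore produces no Doppler frequency shift, but it phase-modulates the
reflection. With respiration displacement $x(t)$ (mm scale) and heartbeat
displacement $y(t)$ (sub-mm), the received baseband channels are

$$
I(t) = A\cos\phi(t) + V_I + n_I(t), \qquad
Q(t) = A\,g\,\sin(\phi(t) + \epsilon) + V_Q + n_Q(t),
$$

$$
\phi(t) = \underbrace{\frac{4\pi d_0}{\lambda}}_{\theta}
        + \frac{4\pi}{\lambda}\bigl(x(t) + y(t)\bigr) + \Delta\varphi(t),
$$

where $\theta$ is the constant round-trip path phase at standoff distance
$d_0$, $\Delta\varphi$ is oscillator (VCO/PLL) phase noise, $V_I, V_Q$ are
DC offsets, $g$ is the Q-vs-I gain imbalance, $\epsilon$ the quadrature
error and $n_I, n_Q$ additive thermal noise. `synthesize_quadrature()`
implements exactly this model; `vital_profile()` carries the ground truth
and `noise_spec()` the corruption terms, so every downstream stage can be
validated against a known answer.

Model choices worth stating explicitly:

* **Respiration waveform.** $x(t)$ is a harmonic series
  $a_r \sum_k w_k \sin(2\pi k f_r t + \varphi_r)$; the default is a pure
  sinusoid ($w = 1$). The harmonic weights exist to reproduce a real
  failure mode: harmonics of breathing landing inside the heart band and
  masquerading as a heartbeat. $y(t)$ is a pure sinusoid.
* **Displacement amplitudes.** Defaults of 4 mm (respiration) and 0.3 mm
  (heartbeat) follow the order of magnitude that radar studies of
  chest-wall motion commonly assume; they are configuration, not
  constants.
* **Phase noise.** A Gaussian random walk (per-sample increment std
  `phase_walk_std`). Real oscillator spectra are hardware specific; a walk
  reproduces the essential feature, noise power concentrated at low
  frequency.
* **Baseband, not IF.** The receiver that motivated this package
  downconverts via a low intermediate frequency to escape $1/f$ noise; the
  simulator emits baseband I/Q directly at the 200 Hz vital-signs sample
  rate, because the IF stage contributes nothing testable to the
  demodulation and estimation algorithms.
* **Propagation speed.** Defaults to the rounded $3\times10^8$ m/s so the
  derived geometry lands on the textbook values (12.5 cm wavelength,
  3.125 cm null spacing); pass the exact value if preferred.

## Demodulation

`arctan_demodulate()` computes the four-quadrant arctangent
$\operatorname{atan2}(Q, I)$ and unwraps it (adding $2\pi$ corrections at
jumps larger than $\pi$). The unwrapped output equals $\phi(t)$ up to a
global $2\pi k$; a noiseless round trip through synthesis and demodulation
agrees to better than $10^{-9}$ rad RMS, and the test suite asserts this.

One deliberate deviation from common advice: subtracting each channel's
sample mean before the arctangent is **disabled by default**. For mm-scale
motion the I/Q samples sweep a short arc of the constellation circle, and
the mean of an arc lies well inside the circle — re-centering on it
distorts the phase so strongly that respiration harmonics out-power the
heartbeat line (we measured the heart-band peak moving to the 5th
respiration harmonic on a noiseless record). Mean subtraction only
estimates the true DC offsets when the phase sweeps many full cycles, so
it is an option (`remove_channel_dc = TRUE`), not a default. Circle
fitting, the robust offset estimator, is out of scope.

`remove_dc_streaming()` reproduces the deployed receiver's bookkeeping: at
a 200 Hz sample rate and 25 Hz refresh rate, every 0.04 s update appends 8
samples to a stored dataset, recomputes its mean, and emits the block
minus that mean. The buffer grows without bound by default (matching the
receiver's description); a `window` argument caps it. The growing mean of
a pure tone decays toward zero like $a/(\omega t)$ — about 0.02 rad after
60 s for a unit 0.25 Hz tone — which is why the convergence test uses a
10-minute record.

`single_channel_phase()` exists to demonstrate why the quadrature
architecture matters. Using only $I$, small-signal demodulation divides
the centered channel by the sensitivity $A\,|\sin\theta|$, which vanishes
whenever $d_0$ is a multiple of $\lambda/4$ — a *null point* every
3.125 cm at 2.4 GHz. The function reports the sensitivity and flags
records at an exact null as degenerate. The quadrature arctangent estimate
is distance invariant, and the tests sweep $d_0$ across a full wavelength
to prove it.

## Rate estimation

`spectral_rate()` band-limits the phase, then peaks its power spectrum:

1. **Filtering** (`bandpass()`): demean, then an order-4 Butterworth
   high-pass at the band's low edge and an order-4 low-pass at the high
   edge, each run forward and backward (zero phase). A single order-8
   band-pass polynomial is numerically unstable at a normalized low edge
   of $0.05/100 = 5\times10^{-4}$ — its filtered output overflows — which
   is why the stable high-pass/low-pass cascade is used. Default bands:
   0.05–2 Hz combined (the deployed filter range), 0.05–0.5 Hz for
   respiration (RR < 30 BPM), 0.8–2 Hz for heartbeat (HR < 120 BPM,
   extensible to 2.5 Hz / 150 BPM). The heart band's 0.8 Hz low edge is
   ours: it excludes respiration fundamentals while keeping bradycardic
   rates down to 48 BPM.
2. **Spectrum**: the zero-padded periodogram $|\mathrm{FFT}(x)|^2/N$,
   identically the DFT of the biased (positive-semidefinite)
   autocorrelation estimate. Padding to at least 8 times the record length
   provides the dense grid for sub-bin interpolation.
3. **Detection gate**: a rate is reported only when the in-band peak of a
   segment-averaged (Bartlett) spectrum exceeds 3 times the in-band
   median. Averaging is essential: the raw periodogram of pure noise has
   an in-band max/median ratio of 5–10 over a few dozen resolution cells,
   so an unaveraged 3× gate would "detect" rates in noise. The number of
   segments (8, 6 or 4) is the most that still leaves at least 3 spectral
   resolution cells inside the band, so a real tone's main lobe cannot
   inflate the median it is compared against.
4. **Peak refinement**: three-point log-parabolic interpolation around the
   largest in-band bin (ties broken toward the lower frequency), then
   conversion to BPM. With a 30 s window the raw DFT bin is 2 BPM;
   interpolation brings pure-tone errors below 0.03 BPM, which is what
   makes a 0.5 BPM respiration-accuracy target reachable at all.
5. **Three-cycle rule**: a peak is only credible if the window holds at
   least three of its cycles, so the search floor is
   $\max(\text{band low}, 3/T)$ for a window of length $T$; a window too
   short to hold three cycles of any in-band frequency is an error. This
   replaces a fixed minimum-duration precondition, which would have
   forbidden the default 30 s window for the 0.05 Hz band edge.

`estimate_rates_streaming()` applies the same estimator per refresh tick
(every 0.04 s) on the trailing window, with `NA` during the warm-up. For
tractability each band is filtered once over the whole record and then
decimated — the band filter itself is the anti-alias filter — before the
per-tick spectra; a test verifies the decimated path agrees with the
full-rate batch estimator. `harmonic_mask()` optionally zeroes heart-band
bins within ±0.03 Hz of integer multiples of the current respiration
estimate before the heart peak search.

## Signal quality

Operators judge a subject's posture from the live I/Q traces: a slouched
subject reflects less power toward the receive antenna. `peak_swing()`
reads each channel's swing as the 99th-minus-1st percentile span (robust
to spikes, unlike min/max), `combined_magnitude()` folds the two swings
into $\sqrt{(I^2+Q^2)/2}$, and `posture_quality()` labels the record Good
only when that magnitude strictly exceeds 3 mV. The printed combination
formula in the source material is typographically ambiguous between
$\sqrt{(I^2+Q^2)/2}$ and $\sqrt{I^2+Q^2}/2$; the RMS reading is adopted,
and the headline conclusion — a 5–10× amplitude gain is
$20\log_{10}(\cdot) = 14$–$20$ dB of SNR — is identical under either.

## Synthetic-cohort evaluation

`generate_cohort()` draws subjects with the covariate ranges of the
motivating clinical population (weight 123–285.8 lb, height 57–73 in, age
29–79 yr, 8 male / 12 female at $n = 20$) and true rates RR ~ U(12, 25),
HR ~ U(55, 120) BPM. Covariates are decorative by construction — they do
not influence measurement difficulty — which the tests confirm by
regressing absolute errors on them and finding slopes indistinguishable
from zero; `noise_weight_slope` is an explicit hook that *does* couple
thermal noise to weight, for power analyses. `run_trial()` composes the
full pipeline and takes the median of post-warm-up streaming estimates as
the measurement; the reference is the generator's ground truth, or a
manual-count emulation that rounds RR to whole breaths. `error_stats()`
reports medians, $n-1$ standard deviations and five-number summaries of
signed errors (absolute errors on request), grouped by gender, posture or
binned continuous covariates; `drop_outliers()` formalizes removing the
single worst heart-rate case.

The bench-conditions experiment (`lab_accuracy_experiment()`): 30 subjects
with RR ~ U(10, 25) and HR ~ U(55, 110) BPM, default displacement
amplitudes, thermal noise at 10% of the received amplitude,
$10^{-3}$ rad/sample oscillator walk, 120 s records, 30 s windows. Under
these conditions the pipeline holds median absolute errors around
0.005 BPM (RR) and 0.01 BPM (HR) — far inside the 0.5 / 3 BPM targets —
because the simulation contains none of the unmodeled disturbances of a
live measurement.

### The high-heart-rate outlier mechanism

A subject whose true HR sits at the heart band's 2 Hz upper edge is
attenuated by the filter (×0.50 in amplitude at the cutoff after the
forward-backward pass); if anything else lives in the band — here a 4th
respiration harmonic at 1.2 Hz with 5% relative amplitude — the estimator
locks onto it instead, mis-reporting ~72 BPM for a 120 BPM subject.
Raising the cutoff to 2.5 Hz (150 BPM) restores the true peak (×0.86
amplitude, above the harmonic). The interferer amplitude was chosen from
the filter's computed response so both inequalities hold with ~30%
margin; the scenario is exercised in the tests in both directions.

## What the simulation does and does not show

Passing tests demonstrate that the *algorithms* are correct and that the
method's claimed accuracies hold under the stated synthetic conditions.
The generator does not model body-type-dependent reflectivity, motion
artifacts, multipath or wall reflections, interfering movers in the room,
or non-simultaneous reference measurements — the factors that dominate
real clinical error budgets. Simulated accuracies should therefore be
read as upper bounds on the signal-processing chain, not as predictions
of clinical performance.

## Numerical and design notes

* All randomness flows from explicit integer seeds (`noise_spec(seed=)`,
  `generate_cohort(seed=)`); identical seeds give bit-identical records.
* Problem sizes: unit tests use 30–120 s records; the cohort tests use 20
  subjects at 60 s and the bench experiment 30 subjects at 120 s.
* CSV serialization uses scientific notation at 12 significant digits;
  undetected-rate ticks serialize as empty fields.
* Degenerate inputs: empty records, rate/band mismatches and non-positive
  parameters raise errors; an exact single-channel null returns a flagged
  degenerate record rather than dividing by ~0; pure-noise windows return
  `NA` rates rather than a number.
* Whether the deployed receiver unwraps phase or operates in the
  small-signal regime is not public; both paths are exposed
  (`arctan_demodulate()` and `single_channel_phase()`), and RR/HR are
  estimated from separately filtered streams (two-band design).
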