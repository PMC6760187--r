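---
title: "wormstim: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormstim: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormstim)
```

## The preparation and the measurement model

The earthworm ventral nerve cord carries three giant axons grouped into
two functional classes: the Medial Giant Fiber (MGF), fast and recruited
by anterior stimulation, and the Lateral Giant Fibers (LGF), slower and
recruited posteriorly. Their APs are large enough to record with
macroscopic electrodes inserted through the body wall. Two bipolar pairs
are aligned longitudinally at 1 cm spacing — anode, cathode, anode,
cathode, anodes nearer the stimulation site — so each passing AP produces
a biphasic deflection per pair: a positive peak as the AP passes the
anode and a negative peak at the cathode.

Three quantities summarize a response to a stimulus at onset $t_0$:

- conduction velocity $v = d_{aa} / (t_2 - t_1)$, from the inter-anode
  distance $d_{aa}$ (2 cm by default) and the positive-peak times at the
  two sites;
- the arrival delay $\Delta t$ from $t_0$ to the positive peak at the
  first anode;
- its decomposition $\Delta t = \mathrm{TOP} + \mathrm{TOG}$, where
  $\mathrm{TOP} = d/\bar v$ is the propagation time over the axonal
  distance $d$ at the trial-mean class velocity $\bar v$, and the time of
  generation TOG absorbs everything upstream of the giant axon
  (transduction, afferent conduction, synaptic integration).

Assumptions inherited from the preparation: conduction velocities are
steady over a trial (so a trial-mean $\bar v$ is meaningful), the two
classes are separable by velocity, and stimulus onsets are observable on
a dedicated artifact channel (electromagnetic transient for EStim,
contact artifact for MStim, trigger tick for UStim) whose positive peak
is the time reference.

## What the synthetic generator emulates

`simulate_recording()` renders, per planted AP, one biphasic waveform per
bipolar channel: raised-cosine lobes of opposite sign (default full width
1.5 ms, keeping spectral content inside the 120–1200 Hz analysis band)
centred on the anode- and cathode-passage times, additive white Gaussian
noise (default SD 5e-5 V, 5% of the MGF peak amplitude — the source
reports SNR only qualitatively), and 40 kHz sampling (the acquisition
system's stated 8-channel maximum).

Because the opposite-sign cathode lobe overlaps the anode lobe, the sum
of the two lobes peaks slightly before the anode-lobe centre. The
renderer pre-compensates this shift numerically so that the *composite*
positive peak falls exactly on the anode-passage time — which is what
"the positive peak corresponds to anode passage" means operationally.
Without this the fixed EStim latencies (~1.3 ms TOG) would carry a
rendering bias of order 0.1 ms.

Latency calibration (defaults in `default_study_models()`): TOG is
log-normal per modality — non-negative support and right skew, matching
the reported scatter — with the median pinned to the printed median and
the log-scale spread fitted from the printed quartiles,
$\sigma = \log(q_3/q_1)/(2 \times 0.6745)$:

| modality | median TOG | sdlog | note |
|---|---|---|---|
| EStim MGF / LGF | 1.3 / 2.4 ms | 0.012 / 0.032 | near-fixed latency |
| UStim | 11.8 ms | 0.116 | intermediate |
| MStim | 33.0 ms | 0.251 | long, variable |

A log-symmetric law cannot reproduce slightly asymmetric printed
quartiles exactly; the fitted quartiles land within ~3% of the printed
ones (tested at 5%). Fiber defaults: MGF 16.6 m/s (jitter SD 0.22 m/s,
from the printed IQR), LGF 9.0 m/s (SD 0.07), amplitudes 1.0 / 0.4 mV
(the source gives no amplitudes in volts; only their ordering matters),
refractory period 4 ms — half the 8 ms pulse period chosen at 125 Hz PRF.

The UStim dose response is a logistic in $\log PRF$, $P_A$ (MPa) and
$\log$ pulse duration (ms) with positive coefficients (hence monotone in
each argument) and a hard 4.0 MPa floor below which the probability is
exactly zero. Coefficients were fixed once so that the reference burst
(1.1 MHz, 175 cycles, 125 Hz, 20 pulses, 6.6 MPa) succeeds ~0.85 of the
time and the same burst at 25 Hz ~0.45 — a clearly monotone PRF effect of
the size the comparative figures suggest — and were not revisited.

Within-burst dynamics: the expected AP count per response decays
geometrically across consecutive bursts (ratio 0.7 per burst, resetting
after ≥1 s of rest) and the interval between successive APs of one
response grows by 1.3 per AP, starting from max(pulse period, refractory
period). Adaptation acts on the count given a response, not on the
success probability; this reproduces the qualitative per-burst decay
while keeping success-rate statistics stationary across a randomized
design (the alternative — decaying success probability — would confound
every dose-response analysis run on closely spaced stimuli).

What the generator does **not** emulate: muscle/movement artifacts,
electrode drift, slow nerve fatigue ("the nerve eventually stops
responding"), waveform differences between fiber classes beyond amplitude,
or any acoustic/biophysical mechanism. A green parameter-recovery test
therefore establishes that the analysis inverts the stated statistical
model of the preparation — not that it would survive every pathology of
real recordings.

## Numerical choices

- **Filter realization.** Only the band (120–1200 Hz) is given; we apply
  the squared magnitude response of a 4th-order analog Butterworth
  band-pass in the FFT domain. This is the transfer function that
  forward–backward (filtfilt) application of that filter realizes: exactly
  zero phase (no peak-time bias), flat passband, DC removed, and no
  state-initialization transients. Traces shorter than three periods of
  the low cutoff are rejected as shorter than the filter warm-up.
- **Detection threshold.** $k \times 1.4826 \times \mathrm{MAD}$ of the
  filtered channel, default $k = 4$, with a floor at 10% of the channel
  maximum so that noiseless traces (MAD ≈ 0) do not detect filter
  ripple.
- **Biphasic pairing.** The negative partner must lie 0.3–3 ms after the
  positive peak (1 cm anode–cathode span at 3–33 m/s) and reach at least
  40% of its magnitude; unpaired lobes are counted, not silently dropped.
- **Tie-breaks.** Overlapping candidates within 3 ms: the larger
  amplitude wins; suppressed candidates go to a diagnostics attribute.
  Peak times are refined by three-point parabolic interpolation, which is
  what lets per-pair velocities reach ~0.1% accuracy at 40 kHz (raw
  sample quantization alone would be ~4% on an MGF inter-site delay).
- **Blanking.** 2 ms after EStim/MStim onsets, none after UStim trigger
  ticks; configurable.
- **Matching.** Greedy one-to-one in time order with a 3–30 m/s velocity
  window; a zero-delay coincidence implies infinite velocity and is
  rejected. Overlaid MGF/LGF events are excluded from velocity
  estimation rather than deconvolved.
- **Degenerate inputs.** Negative TOGs are flagged implausible and
  excluded from summaries, never clipped; saturated events are flagged,
  not dropped; colliding waveforms (closer than one lobe width) warn and
  are flagged `overlap` in the ground-truth log.

## Statistical conventions

- Quantiles use linear interpolation between order statistics
  (`quantile` type 7); the convention is pinned by tests because printed
  quartiles depend on it.
- The Jarque–Bera screen uses the asymptotic $\chi^2_2$ reference with a
  recorded small-$n$ caveat below 50.
- "Wilcoxon–Mann–Whitney for paired samples" is implemented as the
  Wilcoxon signed-rank test, the standard paired analogue. Zero
  differences are dropped and counted.
- Exact branches: rank-sum enumeration when both groups have ≤ 12
  observations without ties; signed-rank sign-permutation enumeration
  (average ranks, so ties are handled exactly) up to 15 pairs. Larger or
  tied cases use the tie-corrected normal approximation with continuity
  correction, tie counts computed on ranks (computing them on floating
  point values is a subtle bug: values equal by rank can differ in
  binary). All alternatives are two-sided.

## Open design decisions

- $\Delta t$ and TOP are referenced to the **first** (closer) anode,
  since the anodes sit nearer the stimulation region.
- $\bar v$ for TOP is the trial-level mean of instantaneous velocities of
  the AP's fiber class.
- The 12 m/s classification boundary is the midpoint of the two printed
  velocity ranges; boundary values go to the faster class. An optional
  amplitude criterion can veto to `UNKNOWN`.
- UStim latencies are referenced to the burst onset (not the first
  intra-burst pulse); with an 8 ms pulse period the distinction is below
  the TOG spread.
- The threshold-search null rule "more than 5 attempts" is implemented as
  ≥ 6 administered stimuli per candidate level, ladder walked
  independently per duration.
- The 200 ms response window is deliberately conservative (observed
  delays are < 50 ms).

## Limitations

Calibration targets are printed summary statistics, not raw data, so the
generator is a stated world: acceptance tests check internal consistency
(parameter recovery, calibration of the tests, monotone dose response)
at the tolerances of that world. Animal-level results (92%/88% response
rates, per-trial medians) are not reproducible without the original
recordings and are not claimed. The exact UStim printed values are not
mutually consistent at printed precision (median TOG 11.8 ms vs median
delay − median TOP = 12.0 ms); per-AP computation before taking medians
is used and no agreement is forced.
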