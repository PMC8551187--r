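---
title: "Heart rate from a multi-point FBG seismocardiography patch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart rate from a multi-point FBG seismocardiography patch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scghr)
```

## The measurement problem

Seismocardiography (SCG) records the small vibrations the beating heart
imprints on the chest wall. Each ejection produces a short vibration burst
whose most prominent fiducial is the aortic valve opening (AO); counting AO
events gives the heart rate without electrodes. `scghr` models a soft
wearable patch in which four fiber Bragg gratings (FBG1..FBG4) are embedded
in a thin silicone strip, sensing chest strain at four sites at once. An FBG
reflects a narrow optical band centered at its Bragg wavelength
$\lambda_B$; axial strain $\epsilon$ shifts it linearly,

$$\Delta\lambda_B = S_\epsilon\,\epsilon + S_T\,\Delta T,$$

with $S_\epsilon$ the calibrated strain sensitivity (nm per millistrain) and
$S_T$ a temperature sensitivity that is carried in the type but defaulted to
zero: the intended recordings are ~20 s constant-temperature breath-holds,
where thermal drift is negligible on the signal band of interest. The
packaged default array (`default_array()`) has $\lambda_B$ =
1525/1533/1541/1549 nm, $S_\epsilon$ = 0.044/0.045/0.045/0.046 nm/mε, four
10 mm gratings spaced 20 mm edge-to-edge in a 230 × 36 × 1 mm matrix.
Sensitivities of this magnitude are sometimes printed with the µε symbol
where mε is meant; the package treats all four as nm per millistrain, which
is the only reading consistent with millimetre-scale chest displacements
producing picometre-to-nanometre wavelength shifts.

Calibration support is deliberately minimal: `fit_calibration()` is an
ordinary least-squares line with a free intercept (calibration rigs rarely
guarantee a true zero), and `hysteresis_error()` is the maximum
loading/unloading discrepancy as a percentage of the loading branch's
full-scale output — the standard sensor-metrology convention, adopted here
because "percent hysteresis" is otherwise ambiguous.

## The processing chain

The pipeline follows the classical SCG envelope approach:

1. **Band filtering.** FBG channels are band-passed 10–30 Hz (the SCG
   vibration band), the ECG 0.5–100 Hz, and AO envelopes 0.5–2 Hz. All
   filters are zero-phase Butterworth (forward–backward). Each band-pass is
   realized as a cascade of an order-4 high-pass and an order-4 low-pass
   rather than a single direct-form band-pass: at 1 kHz sampling the 0.5–2 Hz
   band has a normalized width of 0.0015, where a direct-form band-pass of
   this order is numerically unstable under forward–backward filtering, while
   the cascade keeps every section well conditioned and preserves the
   Butterworth magnitude and the zero-phase property (verified by the
   symmetric-pulse test).
2. **Envelope.** The amplitude envelope is the magnitude of the analytic
   signal, computed with a Hamming-windowed type-III FIR Hilbert transformer.
   The default length is 201 taps: at 1 kHz a 101-tap transformer is ~16 %
   low at 10 Hz — the lower edge of the SCG band — while 201 taps are flat to
   within 0.4 % over 10–30 Hz. The first/last filter length of samples carry
   the convolution edge transient; closed-form checks in the test suite
   exclude that margin.
3. **Dominant frequency.** `dominant_frequency()` takes the argmax of a
   Welch PSD (4 s Hann segments, 50 % overlap, per-segment mean removal)
   restricted to a search band. 4 s segments give 0.25 Hz resolution —
   enough to place the cardiac fundamental while averaging out noise in a
   15–20 s record.
4. **Peak detection.** `detect_peaks()` min–max normalizes the signal to
   [0, 1], keeps strict local maxima above the mean of the normalized signal,
   and greedily thins them (highest first, ties to the earlier sample) to a
   minimum spacing of $\mathrm{round}(0.7\,f_s/f_{dom})$ samples — 70 % of
   the dominant period as a refractory window. Min–max normalization makes
   the mean threshold scale- and offset-invariant; the detector is checked
   against an exhaustive brute-force reference on a thousand random signals.

Heart rate is then the arithmetic mean of the instantaneous beat-to-beat
rates $60/\mathrm{IBI}$ over a 15 s analysis window that starts at the
synchronization trigger (mean of rates, not beat count over duration — the
order matters with jittered beats). The ECG reference runs through the same
detector after its own band-pass.

Two detector details deserve emphasis:

* **Reading of the spacing rule.** "70 % of the dominant frequency times the
  sampling rate" is dimensionally a frequency squared; the only reading that
  produces a sensible refractory window is 70 % of the dominant *period* in
  samples, $0.7 f_s / f_{dom}$ (583 samples at 1.2 Hz and 1 kHz), which is
  what the package implements.
* **Octave-error correction (ECG path only).** A strictly periodic R-wave
  train spreads power almost evenly across harmonics of the beat rate, so
  the raw Welch argmax in 0.5–2 Hz can land on the second harmonic (e.g.
  2.0 Hz at 60 bpm). That halves the refractory window and admits spurious
  noise maxima between beats. `hr_reference_from_ecg()` therefore asks
  `dominant_frequency()` to prefer the subharmonic when the bin nearest
  $f^*/2$ holds at least half the peak power — a standard octave
  disambiguation in rate tracking. The correction is *not* applied to SCG
  envelopes: their subharmonic bins contain mostly noise, and a false
  correction would double the refractory window beyond the beat interval and
  suppress alternate beats. The cardiac search band is 0.5–2 Hz for both
  paths, matching the envelope band.

## The synthetic-data generator

No public recordings exist for this device class, so the package ships a
simulator whose defaults encode the study conditions it emulates: supine
~20 s breath-holds, cardiac rates in the 1–1.34 Hz band, chest-displacement
amplitudes of 0.2–0.5 mm, AO-locked vibration bursts with energy inside
10–30 Hz, a reference ECG whose R peaks precede AO, and a push-button
trigger edge marking the start of the apnea.

Per beat, the event model draws inter-beat intervals $60/\mathrm{HR}$ plus
zero-mean Gaussian jitter (sd 0.02 s, redrawn if non-positive), places the
first R peak at 0.5 s, and puts AO a fixed 0.10 s after each R — a typical
pre-ejection period. Each AO launches a decaying burst
$A e^{-(t-t_{AO})/\tau}\cos(2\pi f_b (t-t_{AO}))$ with $f_b = 20$ Hz
(mid-band of the 10–30 Hz SCG filter) and $\tau = 50$ ms; the cosine phase
makes $A$ the true peak amplitude at burst onset, so `displacement_amp`
(default 0.35 mm, mid-range of 0.2–0.5 mm) is exactly the simulated peak
chest displacement. Displacement couples to strain through a single scalar
(default 1 mε/mm) times a per-channel gain; the four-gain presets

| preset | gains (FBG1..FBG4) | placement rationale |
|---|---|---|
| Position1 | 1.00, 0.90, 0.60, 0.50 | horizontal over the left sternum; strongest coupling, graded toward the apex |
| Position2 | 0.35, 0.30, 0.30, 0.25 | vertical xiphoid-to-umbilicus; weakest coupling overall |
| Position3 | 0.70, 0.60, 0.50, 0.45 | horizontal periumbilical; intermediate |

encode the qualitative placement physics (horizontal precordial placement
couples best; a vertical abdominal strip worst). Channel noise is additive
Gaussian on the wavelength signal, default sd 0.01 nm. That figure is the
total effective in-band perturbation — interrogator peak-fit noise at 1 kHz
plus unmodelled body micro-vibrations — chosen so that the weakest-coupling
channels operate near detection threshold: a 0.35 mε burst through the
weakest Position2 gain yields ~4 pm of in-band signal against ~2 pm of
in-band noise, the regime where sensor placement and fusion genuinely matter.
With quieter noise every channel detects perfectly and all comparative
questions degenerate to ties. The ECG noise sd is 0.01 of the unit R
amplitude (a clinical-grade reference is nearly noise-free relative to the
QRS). Baseline drift is available (`baseline_drift_amp`) but defaults to 0:
breath-holds suppress the respiratory strain that would otherwise dominate
drift, and the 10–30 Hz filter removes what little remains.

What the simulator does **not** model: respiration (the recordings are
apneas by design), motion artifacts, posture changes, SCG morphology beyond
the AO burst (no MC/IM/AC fiducials), ECG P/T waves, inter-subject
anthropometry, wavelength-spectrum effects (chirp, peak splitting), and
thermal drift. Passing tests therefore demonstrate that the *pipeline*
recovers known ground truth under controlled SNR — not that the device
performs identically on real chests.

## The comparative experiments

`fusion_benefit_experiment()` and `position_ordering_experiment()` restate
the two study-level findings at simulator level:

* **Fusion.** For each of 100 seeded replications, five independent
  recordings are simulated under the weak-coupling (Position2) preset; each
  channel's MAE against the ECG reference is computed across the five, and
  the fused channel (FBGsum, the sample-wise sum of the four raw channels)
  is compared with the best individual channel. Summing the raw channels
  adds the four coherent burst trains and only $\sqrt{4}$ of the incoherent
  noise, so FBGsum enjoys up to twice the amplitude SNR of the best single
  channel. MAE is aggregated over several recordings per replication because
  that is how the evaluation is defined (an MAE over repeated tests); a
  single-recording comparison is degenerate — in clean replications all
  channels are error-free and the comparison reduces to meaningless
  sub-0.1 bpm jitter with a selection bias favouring the minimum over four
  channels.
* **Position ordering.** For each of 50 replications, two recordings per
  position preset are simulated; the per-position MAE is the mean over the
  five channels (FBG1..4 and FBGsum). The expected strict ordering is
  Position1 < Position3 < Position2, which follows from the gain presets
  through the monotone SNR-to-error relation of the detector.

Both experiments run the *full* pipeline (simulation, transduction, trigger
synchronization, filtering, envelope, detection, windowed HR) — nothing is
short-circuited. Problem sizes (100 × 5 and 50 × 3 × 2 recordings of 20 s at
1 kHz) keep each suite within a couple of minutes on a single core while
leaving comfortable binomial margins on the majority criteria.

`simulate_study()` reproduces the full evaluation design — 7 subjects × 3
tests × 3 positions, subject rates drawn uniformly from 60–80.4 bpm — and
`comparative_report()` groups its output into the per-(position, channel)
MAE table with 21 values per cell, flagging the best channel per position
and the best position per channel.

## Numerical choices and degenerate inputs

* Filters: Butterworth order 4 per cascade section; designs cached per
  (order, cutoff) pair. Band edges must satisfy $0 < f_{lo} < f_{hi} < f_s/2$.
* Hilbert transformer: 201 taps, Hamming window; envelope of an all-zero
  signal is all-zero.
* Welch: segment length is clipped to the signal length (a short signal
  degrades to a single modified periodogram); an empty or all-zero search
  band raises an error; a weak spectral peak (< 2× in-band median) is
  flagged `low_confidence` rather than rejected.
* Peak detection: a constant signal cannot be min–max normalized and raises
  an error; ties in the greedy suppression resolve to the earlier sample;
  `min_distance_samples` is floored at 1.
* HR estimation: fewer than two peaks in the window is an error at the
  operation level; `estimate_hr()` converts per-channel failures to `NA` so
  one dead channel does not abort a recording, and `comparative_report()`
  counts per-cell `n` over the values actually present.
* Trigger: the rising edge is the first sample > 0.5 following one ≤ 0.5; a
  trigger that is already high at sample one counts as an edge at the start
  (synchronization is then the identity). Ground-truth beat times are
  shifted with the crop; beats before the trigger are dropped.
* Reproducibility: every stochastic operation takes its seed from the
  configuration and restores the caller's RNG state; identical
  configurations give bit-identical recordings.

## Known limitations

The simulator's coupling model is a scalar gain per channel, not chest-wall
mechanics; its noise is white, while interrogator noise has structure; the
burst waveform is a single damped cosine rather than the multi-component SCG
complex. The MAE figures produced by the synthetic experiments characterize
the pipeline under these assumptions and should not be read as device
accuracy claims. The CSV dialect stores one recording per file and is meant
for inspectability, not throughput.
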