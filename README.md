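# scghr — multi-point seismocardiography heart rate from an FBG array

`scghr` is an R package for estimating heart rate (HR) from
seismocardiography (SCG): the tiny vibrations that each heartbeat imprints
on the chest wall. The sensing model is a soft wearable patch with **four
fiber Bragg gratings (FBG1–FBG4)** embedded in a thin silicone strip, so
the same heartbeat is sensed at four chest sites simultaneously and the
four channels can be fused into a multi-sensor signal (**FBGsum**, their
sample-wise sum). A single-lead ECG provides the reference beat times, and
a push-button trigger synchronizes the optical and electrical acquisition
chains.

It is aimed at researchers in wearable cardiac monitoring and fiber-optic
sensing who want a tested, reproducible implementation of the full chain —
from strain transduction to the position / single-vs-multi-sensor error
analysis — plus a calibrated synthetic-data generator to exercise it, since
no public recordings exist for this device class.

## The model and the pipeline

**Transduction.** An FBG reflects a narrow optical band at its Bragg
wavelength λ_B; axial strain ε shifts it linearly:

    Δλ_B = S_ε · ε        (S_ε in nm per millistrain)

The packaged default array (`default_array()`) has λ_B =
1525/1533/1541/1549 nm and S_ε = 0.044/0.045/0.045/0.046 nm/mε for
FBG1..FBG4 (four 10 mm gratings, 20 mm edge-to-edge, 230 × 36 × 1 mm
matrix). Calibration fitting (`fit_calibration()`) and full-scale-output
hysteresis error (`hysteresis_error()`) cover sensor characterization.

**Processing chain**, per channel:

1. zero-phase Butterworth band-pass — 10–30 Hz for SCG channels,
   0.5–100 Hz for the ECG;
2. amplitude envelope = |analytic signal| via an FIR Hilbert transformer,
   then band-passed 0.5–2 Hz;
3. dominant frequency f_dom = argmax of the Welch PSD in the cardiac band;
4. adaptive peak detection on the min–max-normalized signal: local maxima
   above the signal mean, thinned to a refractory spacing of
   `round(0.7 · fs / f_dom)` samples (70 % of the dominant period);
5. HR = mean of instantaneous beat-to-beat rates 60/IBI over a 15 s window
   starting at the trigger edge.

Detected SCG peaks mark aortic valve opening (AO); ECG R peaks give the
reference. Accuracy is summarized as the **mean absolute error (MAE, bpm)**
between SCG-derived and ECG-derived HR, grouped by body position
(Position 1/2/3) and channel (FBG1..4, FBGsum).

## Worked example

Simulate a 20 s supine-apnea recording at 72 bpm with the patch in
Position 3, then run the whole pipeline:

```r
library(scghr)
arr <- default_array()
strain_to_shift(arr$gratings[[1]], 1)   # 1 me on FBG1
#> [1] 0.044

cfg <- sim_config(hr_bpm = 72, position = "Position3", seed = 42)
rec <- simulate_recording(arr, cfg, meta = list(subject = "S1", test = "T1"))
rec
#> <scg_recording> 6 channels (FBG1, FBG2, FBG3, FBG4, ECG, TRIGGER), 20 s @ 1000 Hz
#>   meta: subject=S1, test=T1, position=Position3
#>   truth: 24 beats

estimate_hr(rec)
#>   channel   hr_bpm n_peaks subject  position test hr_true_bpm
#> 1    FBG1 65.36960      16      S1 Position3   T1    71.94833
#> 2    FBG2 56.70921      13      S1 Position3   T1    71.94833
#> 3    FBG3 68.05209      16      S1 Position3   T1    71.94833
#> 4    FBG4 70.89994      17      S1 Position3   T1    71.94833
#> 5  FBGsum 71.43988      18      S1 Position3   T1    71.94833
#> 6     ECG 71.27006      18      S1 Position3   T1    71.94833
```

At this noise level single channels mistime or miss beats (FBG2 reads
56.7 bpm against a 71.9 bpm truth), while the fused FBGsum — four coherent
burst trains against √4 of the incoherent noise — lands within 0.2 bpm of
the ECG reference. The study-level comparison aggregates this over a
subjects × tests × positions grid:

```r
df <- simulate_study(n_subjects = 2, n_tests = 2, seed = 99)
comparative_report(df)
#> <mae_report>
#>   MAE by (position, channel):
#>   position channel n    mae_bpm
#>  Position1    FBG1 4  0.6724377
#>  Position1    FBG2 4  0.2597940
#>  ...
#>   Best channel per position:
#>   position best_channel   mae_bpm
#>  Position1       FBGsum 0.1036445
#>  Position2       FBGsum 3.4182592
#>  Position3       FBGsum 0.1223838
```

FBGsum is the most accurate channel in every position, and Position 1
(horizontal, over the left sternum) is the most favourable placement. The
dedicated experiments `fusion_benefit_experiment()` and
`position_ordering_experiment()` replicate these comparisons over many
seeds; `vignette("scg-hr-pipeline")` documents the models, defaults and
their rationale.

A thin command-line front end is included at
`inst/scripts/scg-hr.R` (`simulate` / `process` / `evaluate` subcommands
over the same functions), and recordings round-trip through a documented
plain-text CSV dialect (`write_recording()` / `read_recording()`), with
`synchronize()` cropping all channels at the trigger's rising edge.

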