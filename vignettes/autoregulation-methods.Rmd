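---
title: "Assessing cerebral autoregulation: models and methods in autoregkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cerebral autoregulation: models and methods in autoregkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoregkit)
```

## The problem

Cerebral autoregulation (CA) is the vasomotor mechanism that holds cerebral
blood flow (CBF) approximately constant while cerebral perfusion pressure
(CPP = MAP − ICP) varies. When CA fails — under deep volatile anesthesia,
traumatic brain injury, or hydrocephalus — flow becomes pressure-passive and
the brain is exposed to both ischemia and hyperemia. Three assessment
families dominate the field, and `autoregkit` implements all three on one
preprocessing backbone:

* **Static CA** — Lassen's curve: steady-state ΔCBF against CPP, flat
  between the lower and upper limits of autoregulation (LLA, ULA).
* **Pseudo-dynamic CA** — the pressure reactivity index (PRx): a moving
  5-minute Pearson correlation between slow MAP and ICP fluctuations.
  Negative PRx means vasomotor activity converts pressure rises into volume
  (hence ICP) falls; PRx above ~0.3 indicates a passive bed.
* **Dynamic CA** — the phase lag between ABP and ICP at externally induced
  oscillation frequencies (0.009–0.059 Hz). With intact CA below the
  autoregulatory cutoff f~c~ ≈ 0.03 Hz, ICP moves in anti-phase with ABP
  (lag ≈ 180°); a passive bed transmits pressure in phase (lag ≈ 0°).

Because no public recordings accompany the protocol this package targets,
a seeded lumped-parameter simulator generates complete multimodal study
recordings (ABP and ICP waveforms at 100 Hz, an optical blood-flow index
with its β quality value at 1 Hz, vitals, event markers), with the
autoregulation state as an explicit dial (`ca_gain` from 0 = passive to
1 = intact). Every pipeline is validated end to end against recordings
whose ground truth is known by construction.

## Preprocessing

Beat-wise systolic/diastolic pressures are extracted as extrema over 2-s
non-overlapping windows (at least two cardiac cycles at the heart rates
simulated here); MAP is the clinical 2/3 diastolic + 1/3 systolic; CPP is
MAP − ICP sample-wise. All channels are aligned and down-sampled to 5 Hz by
block (boxcar) averaging — which is also anti-aliasing for the ≤ 0.06 Hz
analysis band — with slower channels held constant between samples.

Optical samples are screened on the β quality value with two rules applied
jointly: reject when the per-recording z-score exceeds 0.5 in magnitude, or
when β falls more than 0.01 below the recording median. Thresholds use
strict inequalities, and a zero-variance channel defines z = 0 (nothing
rejected), so constant fixtures remain testable. Flow data are then
averaged in 10-s bins (trailing partial bins dropped — they would carry
respiration and cardiac leakage with a biased variance), and any bin with
|z| > 2 across the subject's bins is rejected.

## Static pipeline

Clean 10-s flow means are averaged within half-open 1 mmHg CPP bins. The
subject curve is built on the raw flow-index scale and only then normalized
(mean-subtracted, mean-divided over populated bins), which makes curves
dimensionless and comparable across subjects; the group curve is the
unweighted per-bin mean with SD where at least two subjects contribute.

The plateau estimator is a deliberate addition: a continuous three-segment
piecewise-linear least-squares fit (rising / flat / rising, middle slope
pinned at zero, outer slopes clamped non-negative), with breakpoints
searched on a 1 mmHg grid and polished by Nelder–Mead only when the polish
actually lowers the SSE — on an all-flat curve the simplex otherwise
wanders on a flat objective. Ties in SSE resolve to the widest plateau. A
plateau narrower than 10 mmHg is flagged degenerate ("no resolvable
plateau"), which is the expected outcome on pressure-passive data. The
estimate is reported alongside, never inside, the curve.

Group pressure distributions are compared with a rank-sum (Mann–Whitney)
test: exhaustively enumerated for combined n ≤ 20, normal approximation
with tie correction above. The test is run on per-subject means rather than
pooled samples — pooling hundreds of autocorrelated samples per subject
pseudo-replicates wildly; a pooled mode exists behind a flag for
comparison, documented as statistically dubious. Histograms, by contrast,
intentionally pool samples: they describe exposure, not evidence.

## Pseudo-dynamic pipeline (PRx)

MAP and ICP are reduced to 0.1 Hz by 10-s block means (the block mean is
the slow-wave smoothing), correlated over 5-minute windows stepped by 60 s
(the step is a design choice — "moving" implies overlap; it is
configurable), paired with the window-mean CPP, and sorted into 150
half-open CPP groups spanning [0, 180) mmHg (width exactly 1.2 mmHg).
Group averages go through Fisher's Z (`tanh(mean(atanh(r)))`); unit
correlations from noise-free fixtures are clipped to ±(1 − 1e-12) before
the transform. Windows with missing points or zero variance are skipped
and counted; out-of-range windows are dropped and counted — the QC report
accounts for every window.

## Dynamic pipeline (phase lag)

Each oscillation frequency gets its own linear-phase equiripple
(Parks–McClellan) bandpass filter, applied identically to ABP and ICP so
the group delay cancels in the phase subtraction. The analytic signal
(frequency-domain Hilbert construction) yields instantaneous phase and
envelope; the segment delay is the circular mean of (ABP phase − ICP
phase) over the marked segment minus one full cycle at each end, mapped to
(−180°, 180°]. Envelope medians below 0.5 mmHg flag the delay unreliable.
Per-subject delays are circular means over repeated segments (the ICP
baseline staircase); group summaries are circular means and circular SDs
over subjects — arithmetic averaging of wrapped angles is simply wrong at
±180°.

Two numerical choices deserve emphasis:

* **Passband geometry.** A fixed half-width of 0.03 Hz on either side of
  the center frequency cannot work across this protocol: it is negative
  territory for f₀ = 0.009 Hz, and it would swallow neighboring protocol
  frequencies only 0.008 Hz away. The half-width used is
  `min(0.03, 0.4 f₀, 0.3 gap)` with the transition band filling the gap to
  the nearest frequency that must be rejected, giving every filter unit
  gain (±1%) at its own frequency and ≤ 1% gain at DC and at every other
  protocol frequency.
* **Analysis rate.** The filters are designed and run at 1 Hz after
  block-mean decimation from 5 Hz. The protocol band sits far below the
  0.5 Hz Nyquist limit, so the decimation is exact for these components;
  and the required ~0.005 Hz transitions then need ~450 taps, where the
  exchange algorithm is robust — the equivalent 5 Hz designs need well over
  1800 taps and fail to converge reliably.

The filter spans (~450 s) exceed the shorter oscillation segments, so
segment-edge transients overlap the evaluation window. Because both
channels pass through the same filter and the same segment window, the
distortion cancels almost entirely in the phase *difference*: an injected
lag sweep (0°–350°, SNR 10) is recovered with < 5° maximum circular error
at every protocol frequency, which the test suite re-verifies.

## The simulator

A discrete-time lumped-parameter model stepped at 100 Hz:

* **Systemic pressure.** MAP = operating point (optionally ramped for
  steady-state sweeps) + Cushing coupling to ICP + PEEP coupling
  (1.8 mmHg/cmH₂O) + Ornstein–Uhlenbeck slow waves (SD 3 mmHg, τ 30 s —
  the natural fluctuations PRx feeds on). The Cushing term (gain
  0.3 mmHg/mmHg) is split 80% fast / 20% low-passed at τ = 60 s: the fast
  share stands for mechanical venous-return transmission, the slow share
  for the sympathetic response; a purely slow coupling would make the ABP
  component during ICP oscillations both immeasurably small and ~70°
  lagged, contradicting the near-zero phase a passive bed shows.
* **Vascular tone.** A radius state tracks the static Lassen-style curve
  (piecewise-linear; plateau 1 flow unit between 60 and 100 mmHg, slopes
  0.015 and 0.008 /mmHg outside; blended toward a proportional passive
  line by `1 − ca_gain`) through a rate-sensitive first-order law with
  time constant 1/(2π f~c~) ≈ 5.3 s and lead fraction 0.9 — the myogenic
  response is fast; without the lead term the closed elastance loop
  amplifies the tracking lag into a ~15–25° phase deficit that intact
  animals do not show. The active tone targets the *total* radius net of
  passive elastic distension (strain 5 × 10⁻⁴ per mmHg of CPP, always
  present): autoregulation regulates flow, whatever the mechanism mix.
  At `ca_gain = 0` the tone is frozen outright and only the passive path
  remains. Resistance follows Poiseuille (R ∝ r⁻⁴), blood volume the
  cylinder law (CBV ∝ r²); the Grubb exponent is kept only as a
  steady-state consistency diagnostic, not as a model ingredient.
* **ICP.** A reservoir state (baseline staircase plus protocol sinusoids,
  first-order equilibration τ = 5 s) + elastance × CBV change
  (120 mmHg per unit relative CBV) + cardiac/respiratory pulsatility +
  noise.
* **Waveforms.** The cardiac pulse shape places its extrema at +2/3 and
  −1/3 of pulse pressure around the systemic mean, so the clinical MAP
  formula recovers that mean exactly — a symmetric sinusoid would bias
  estimated MAP by a sixth of the pulse pressure.
* **Optics.** The flow index is proportional to model CBF at 1 Hz with 5%
  multiplicative noise; β jitters around 0.5. Laser-instability artifacts
  (a seeded Poisson process) depress β well below the median−0.01
  rejection threshold and corrupt the co-timed flow index with 50%
  multiplicative noise for 5–30 s stretches.

All stochastic draws descend from one integer seed; identical
configurations give bit-identical recordings.

### What the simulator does and does not emulate

It reproduces the protocol structure (frequency order fixed at 0.025,
0.059, 0.017, 0.033, 0.009 Hz; 4 cycles per segment, 8 at 0.059 Hz; ICP
staircase 3–40 mmHg; PEEP 6 ± 4 cmH₂O converted at 1 cmH₂O =
0.7355 mmHg), the sign structure of intact versus passive responses, slow
waves, measurement noise and DCS dropouts. It does not attempt vascular
network realism, CO₂ reactivity (end-tidal CO₂ is emitted as a monitored
covariate only), baroreflexes beyond the Cushing term, or beat-morphology
realism. Passing tests therefore demonstrate that the *pipelines* recover
known ground truth under realistic signal and noise structure — not that
the model is a substitute for animal physiology.

## Validation scale and expectations

The test suite and the acceptance script run reduced-scale studies chosen
as realistic desk-scale experiments: 2–5 subjects per arm, one to four ICP
baselines, 1500–3600 s of baseline recording for PRx and static sweeps.
At these sizes the pipelines separate the two autoregulation states with
wide margins: intact ABP-oscillation delays pool near 174°, passive delays
stay within a few degrees of zero, passive PRx on the 50–80 mmHg span
exceeds +0.75 while intact PRx on the plateau is strongly negative, and a
steady-state CPP sweep recovers the configured (60, 100) mmHg limits
within ~2 mmHg. Headline group statistics from the original animal
experiments (absolute CPP distributions and their p-values) depend on
unreleased recordings and are outside what a simulation can or should
reproduce.

## Known limitations

* The ±0.03 Hz passband the protocol literature quotes is replaced by the
  feasible geometry described above; users comparing against legacy
  implementations should expect narrower filters.
* PRx windows spanning protocol segment boundaries are kept (the index is
  defined over the whole recording); a segment-restricted mode exists but
  changes window counts.
* The plateau estimator assumes a single contiguous plateau; exotic
  curves (double plateaus, hysteresis) will be flagged degenerate rather
  than resolved.
* With fewer than two subjects per group the Lassen SD and circular SD
  columns are reported as missing, not zero.
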