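# autoregkit

Tools for assessing **cerebral autoregulation (CA)** — the vasomotor
mechanism that holds cerebral blood flow (CBF) roughly constant across a
range of cerebral perfusion pressures (CPP = MAP − ICP) — from multimodal
pressure and optical blood-flow recordings. The package is aimed at
neurophysiology and neurocritical-care researchers who work with
arterial-pressure (ABP) and intracranial-pressure (ICP) waveforms plus a
diffuse-correlation-spectroscopy (DCS) blood-flow index, and implements
the three classical CA assessment families on one preprocessing backbone:

* **Static CA — Lassen's curve.** Quality-screened 10-s flow means are
  averaged in half-open 1 mmHg CPP bins, normalized per subject
  ((v − m)/m over populated bins), and group-averaged. A three-segment
  piecewise-linear fit (rising / flat / rising, middle slope pinned to 0)
  estimates the lower and upper limits of autoregulation (LLA, ULA); a
  plateau narrower than 10 mmHg is flagged as "no resolvable plateau".
* **Pseudo-dynamic CA — the pressure reactivity index.**
  PRx = moving Pearson correlation of 10-s-mean MAP and ICP over 5-min
  windows stepped by 60 s; windows are sorted into 150 CPP groups over
  [0, 180) mmHg and averaged through Fisher's Z:
  `PRx_group = tanh(mean(atanh r))`. Negative PRx ⇒ intact CA,
  PRx ≳ 0.3 ⇒ pressure-passive.
* **Dynamic CA — ABP–ICP phase lag at induced oscillation frequencies**
  (0.009, 0.017, 0.025, 0.033, 0.059 Hz). Per-frequency linear-phase
  equiripple (Parks–McClellan) bandpass filters feed an analytic-signal
  (Hilbert) phase extraction; the delay is the circular mean of
  (ABP phase − ICP phase) over each marked segment. Intact CA below the
  ~0.03 Hz cutoff shows ≈180° lag; a passive bed transmits in phase (≈0°).

Because the animal recordings behind this protocol are not public, the
package ships a **seeded lumped-parameter cerebrovascular simulator**
(`simulate_hemodynamics()`) with the autoregulation state as an explicit
dial (`ca_gain` 0…1), reproducing the full perturbation protocol:
reservoir-driven ICP oscillations (5 mmHg, 4 cycles per frequency, 8 at
0.059 Hz), an ICP baseline staircase (3–40 mmHg), PEEP-driven ABP
oscillations (6 ± 4 cmH₂O), DCS β-quality artifacts, vitals and event
markers. Every analysis is validated end to end against recordings whose
ground truth is known by construction; see the methods vignette
(`vignettes/autoregulation-methods.Rmd`) for the model and the reasoning
behind every threshold.

## Worked example

Simulate one intact-CA subject (fentanyl-style operating point, CPP near
the middle of the plateau) and one pressure-passive subject
(isoflurane-style, lower CPP), then run the full study pipeline:

```r
library(autoregkit)

proto <- oscillation_protocol(frequencies = c(0.017, 0.033),
                              icp_baselines = 6)
intact <- simulate_hemodynamics(
  simulation_config(seed = 1, subject_id = "fent01", group = "fentanyl",
                    abp_baseline = 95),
  ca_parameters(ca_gain = 1), proto)
impaired <- simulate_hemodynamics(
  simulation_config(seed = 2, subject_id = "iso01", group = "isoflurane",
                    abp_baseline = 70),
  ca_parameters(ca_gain = 0), proto)

cfg <- study_config(
  list(list(subject_id = "fent01", group = "fentanyl", recording = intact),
       list(subject_id = "iso01", group = "isoflurane", recording = impaired)),
  out_dir = "study_out", seed = 1)
res <- run_study(cfg)
res$phase[, c("modality", "freq_hz", "group", "mean_delay_deg")]
#>   modality freq_hz      group mean_delay_deg
#> 1  abp_osc   0.017   fentanyl    -173.873606
#> 3  abp_osc   0.033   fentanyl    -165.294057
#> 5  abp_osc   0.017 isoflurane       5.872161
#> 7  abp_osc   0.033 isoflurane       2.261295
#> 2  icp_osc   0.017   fentanyl       4.597794
#> 4  icp_osc   0.033   fentanyl      -7.718841
#> 6  icp_osc   0.017 isoflurane     -17.166455
#> 8  icp_osc   0.033 isoflurane      43.091282
```

The intact subject shows the anti-phase (≈ ±180°) ABP→ICP response during
ABP oscillations that marks active vasomotion; the passive subject
transmits pressure nearly in phase. The PRx profiles separate the same
way — Fisher-Z means over the populated CPP groups:

```r
prx <- res$prx_profile
fisher_mean(prx$mean_prx[prx$group == "fentanyl"])    # -0.70  (intact)
fisher_mean(prx$mean_prx[prx$group == "isoflurane"])  #  0.74  (passive)
```

`run_study()` writes `lassen.tsv`, `prx_profile.tsv`, `phase.tsv`,
`histograms.tsv`, `vitals.tsv`, `plateau.json` and a `qc_report.json`
that records every threshold and every dropped sample/window count into
`out_dir`; reruns with the same configuration are byte-identical. A thin
command-line wrapper lives at `inst/scripts/autoregkit`
(`autoregkit simulate|run|static|prx|phase --config <yaml>`).

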