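# iemgkit

Acquisition-side processing for multi-channel **intramuscular EMG (iEMG)**
sessions recorded alongside isometric hand forces — the kind of data used to
develop and benchmark control algorithms for myoelectric hand prostheses.

Fine-wire iEMG is selective enough that individual **motor unit action
potentials (MUAPs)** are visible on each channel. A session pairs iEMG
sampled at 10240 Hz by one device with finger/wrist forces sampled at 200 Hz
by another, while an automated cue protocol (maximal contractions, 0.1 Hz
sinusoidal force tracking, circular tracking, synergistic grasps) stamps
every sample with a movement code. `iemgkit` implements the computations
this acquisition pipeline needs:

* **Containers** — read/write the session layout
  (`Data`/`Channels`/`Movements`/`fs`) and spike-sort metadata
  (`samples`/`times`/`template`/`fs`) as MAT-5 files, with a reader/writer
  authored in R and cross-checked against scipy.
* **Force calibration** — the sensor transfer function
  `F = 40·v − 100` N maps the 0–5 V span onto ±100 N (flexion negative).
* **Pre-processing** — a bank of 100 narrow Butterworth stop-bands at
  50 Hz harmonics up to 5 kHz (2 Hz wide, applied forward–backward for zero
  phase, with per-recording selection of active harmonics), sync-pulse edge
  detection by differentiation, dual-stream alignment with a pulse-count
  check, and linear force up-sampling.
* **Spike sorting** — the three-pass chronological template matcher: events
  are aligned to templates at the cross-correlation lag and accepted when
  the correlation coefficient exceeds 0.9 **and** the mean square
  difference is below half the template power; templates holding under 5%
  of events after the first two passes are discarded; pass 3 labels events
  to their best accepted template or "unknown".
* **Features & QC** — 250 ms sliding RMS envelopes (zero-phase, or causal
  = delayed 1280 samples at 10240 Hz), pairwise channel cross-correlation
  (max |r| within ±100 ms lags, median with 5th/95th percentiles across
  movement segments), Welch spectral percentile summaries, and a
  channel/force pairing table with signs.
* **Synthetic sessions** — a ground-truth generator emulating the protocol,
  motor-unit physiology (recruitment thresholds, rate coding, distinct MUAP
  shapes), powerline interference and the 5 V / 200 ms / 0.5 Hz sync
  train, so every stage is testable without real recordings.

## Worked example

```r
library(iemgkit)

syn <- synthesize_session(default_session_config(), seed = 1)
print(syn$session)
#> Session record: 921600 samples x 7 channels at 10240 Hz (90.0 s)
#>   iEMG channels: FDP, EDC, APL
#>   force channels: force_little, force_thumb_aa

clean <- notch_filter_record(syn$session)   # active notches: 50, 100, 150 Hz

res <- spikesort(clean$data[, 1], clean$fs)
summary(res)
#> Spike sorting summary (10240 Hz):
#>   unit 1: 180 spikes, mean rate 4.3 Hz, template peak 0.443 mV
#>   unit 2: 74 spikes, mean rate 1.8 Hz, template peak 0.872 mV
#>   unknown: 8 event(s)

pair_channels_with_forces(clean)[, 1:5]
#>   emg_channel  force_channel movement_code sign     score
#> 1         FDP   force_little             4   -1 0.7375412
#> 2         EDC   force_little             4    1 0.8318877
#> 3         APL force_thumb_aa             6    1 0.7650547

volts_to_newtons(5)
#> [1] 100
```

The sorter found the channel's two simulated units (the small
low-threshold unit firing throughout, the larger high-threshold unit only
near the force peaks — note the mean rates), and the pairing table recovers
the construction: FDP drives little-finger flexion (sign −1), EDC its
extension (+1), APL thumb abduction (+1), each during its own protocol
stage (base codes 4 and 6).

## Command line

A thin CLI over the same functions ships in `inst/cli/iemg.R`:

```sh
Rscript inst/cli/iemg.R simulate   --seed 1 --out session.mat --truth truth.json
Rscript inst/cli/iemg.R preprocess --in session.mat --out clean.mat
Rscript inst/cli/iemg.R sort       --in clean.mat --channel FDP --out spikes.mat
Rscript inst/cli/iemg.R qc         --in clean.mat --report qc.json
```

## Scope

The package processes signals; it does not attempt expert judgment. The
qualitative good/questionable/bad channel grading that accompanies real
recordings requires a neurophysiologist, and the pairing table produced
here is labelled a computational surrogate. The sorter does not resolve
superimposed MUAPs and does not sort across channels.
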