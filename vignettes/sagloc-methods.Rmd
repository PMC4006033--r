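---
title: "Methods: a template-matching model of sagittal-plane localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a template-matching model of sagittal-plane localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagloc)
```

## The model

Human listeners locate sound sources within sagittal planes (up/down and
front/back) from monaural spectral cues imprinted by the torso, head and
pinna. These cues are described by directional transfer functions (DTFs),
the direction-dependent part of the head-related transfer functions after
the common transfer function (CTF, the per-ear log-magnitude average over
all directions) has been removed.

`sagloc` implements a probabilistic template-matching account of this
process:

1. **Peripheral processing.** The DTF-filtered sound is decomposed by a
   linear 4th-order gammatone filterbank with 28 bands between 0.7 and
   18 kHz spaced at one equivalent rectangular bandwidth (ERB-number
   scale $21.4\,\log_{10}(0.00437 f + 1)$). Each band signal is half-wave
   rectified, low-pass filtered (2nd-order Butterworth, 1 kHz) and
   reduced to its RMS in dB. The result is the *internal representation*:
   one 28-element dB vector per ear.
2. **Comparison.** The representation of the incoming sound is compared
   with an internal *template set* — the equivalently processed DTFs of
   all polar angles in the target's sagittal segment. The distance is the
   standard deviation across bands of the inter-spectral differences,
   which cancels any constant level offset (level-rove robustness).
3. **Spatial mapping.** Each distance $d$ is mapped to a similarity index
   $\mathrm{SI} = \exp(-d^2 / 2U^2)$. The width $U$ is the
   *listener-specific uncertainty*: the model's non-acoustic factor. The
   monaural SIs are combined with binaural weights
   $w_L = (1+e^{-\phi_{lat}/\Phi})^{-1}$, $w_R = 1 - w_L$
   ($\Phi = 13.3^\circ$), and the binaural SIs over all template angles
   are normalized to a probability mass vector (PMV) of polar responses.

Performance is summarized by the quadrant error (QE: probability mass, or
response fraction, with absolute wrapped polar error above 90°) and the
local polar RMS error (PE: RMS of the remaining errors), restricted to
targets within ±30° lateral, evaluated per 20°-wide lateral segment
(centers −20°, 0°, +20°) and averaged arithmetically across targets.

Calibration sweeps $U$ from 0.1 to 4.0 in steps of 0.1 and selects the
value minimizing $(PE_{pred}-PE_{act})^2 + (QE_{pred}-QE_{act})^2$ (PE in
degrees and QE in percent entered unweighted; ties resolve to the smaller
$U$). The factor analysis then permutes DTF sets $D_k$ and uncertainties
$U_k$ across a listener group — with the *same* DTF set always feeding
both the incoming sound and the template set, i.e. simulating complete
re-calibration — and compares the per-factor standard deviations of the
predicted scores.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `f_low`, `f_high` | 700, 18000 | Hz | filterbank range (28 bands at 1 ERB) |
| `lowpass_cutoff` | 1000 | Hz | hair-cell stage low-pass |
| `U_default` | 2.0 | – | uncertainty of an "average listener" |
| `binaural_phi` | 13.3 | deg | contralateral fade; predictions within ±30° lateral are insensitive to moderate changes |
| `polar_grid` | −30:5:210 | deg | template = response grid |
| `lateral_segments` | −20, 0, +20 | deg | 20°-wide sagittal segments |
| `U_grid` | 0.1:0.1:4.0 | – | calibration sweep |

## The synthetic world

The original analysis used measured DTFs and 300-trial response sets of
18 listeners; neither is redistributable here. The generator therefore
emulates the *features* that make real DTF sets listener-specific:

- a spectral notch whose center migrates upward from
  `notch_freq_front` (6 kHz) at polar −30° by `notch_slope`
  (35 Hz/degree), mirrored for rear angles — the dominant elevation cue
  of the human pinna;
- a reflection peak below the notch;
- a high-frequency rear shadow (`rear_offset`, 10 dB) distinguishing
  front from back;
- seeded smooth ripple (3 dB) over frequency × polar angle,
  idiosyncratic per listener and ear.

All direction-dependent terms are scaled by one `cue_quality` scalar;
at 0 the set carries no directional information and the model's PMVs are
uniform. `rear_offset = 10` dB was fixed, before any test was frozen, so
that a virtual listener at $U = 2$ shows a quadrant-error rate near the
middle of the range reported for real listeners localizing broadband
noise with their own ears (9.3% ± 6.0%); 6 dB had produced front–back
confusion rates well above that range.

Simulated experiments draw targets uniformly from the grid within ±30°
lateral and sample each response polar angle from the model's PMV at the
listener's ground-truth $U$; no extra response scatter is added (the
model already encodes scatter in $U$) and the response lateral angle
equals the target's, since the model predicts the polar dimension only.

What a green test therefore establishes: the pipeline's internal
consistency (sampling ↔ prediction, calibration ↔ ground truth,
permutation structure). What it does not establish: agreement with real
listeners' absolute performance, which depends on measured DTFs.

## Numerical choices

- **Gammatone.** 4th-order all-pole magnitude response
  $[1 + ((f-f_c)/b)^2]^{-2}$ with $b = 1.019\,\mathrm{ERB}(f_c)$; the
  filter order is not fixed by the modeling literature we follow, and the
  spectral path uses this magnitude analytically.
- **Spectral vs signal path.** The deterministic spectral path
  (band-weighted dB power average of the DTF magnitude) is the default
  everywhere; it is exact for stationary broadband noise. The signal path
  (waveform → zero-phase gammatone filtering → rectification → low-pass
  → RMS) is calibrated per band by the analytically expected chain output
  for unit-variance Gaussian white noise, derived from the exact
  autocorrelation of a rectified Gaussian process; with this calibration
  the two paths agree absolutely to well under 1 dB per band for filtered
  broadband noise.
- **Sample SD.** The across-band SD uses denominator $N-1$; the choice is
  a constant factor absorbed by $U$.
- **Silence.** Band RMS is floored at $10^{-5}$ (−100 dB) before the log.
- **Off-grid targets** snap to the nearest template angle (the grid is
  5° and the emulated experiments used grid targets); no interpolation.
- **Minimum-phase reconstruction** (DTF → impulse response, 5.33 ms,
  rounded *up* to whole samples, 256 at 48 kHz) delays the minimum-phase
  response by the 0.5-ms fade-in before applying the asymmetric Tukey
  window (0.5 ms in, 1 ms out), so the onset ramp attenuates zeros rather
  than the response peak.
- **SOFA I/O** (SimpleFreeFieldHRIR) is delegated to a bundled
  python/h5py bridge because no native R netCDF-4/HDF5 binding is
  available in the supported environment. Round-trips are exact in
  coordinates and sampling rate and accurate to a fraction of a dB in
  magnitude (a 5.33-ms response cannot carry arbitrary sub-ERB detail at
  low frequencies).

## Known limitations and honest margins

- **Calibration bias.** The actual PE pools all non-quadrant-error trials
  into one RMS, while the predicted aggregate PE averages per-target RMS
  values arithmetically; by Jensen's inequality the former is larger. In
  parameter-recovery simulations this appears as a systematic $U_k$
  offset of about +0.2 (two grid steps), constant across ground-truth
  $U$; the median absolute recovery error stays within 0.3. The asymmetry
  is inherited from the published definitions and is irrelevant for
  comparing listeners, since it shifts all $U_k$ alike.
- **Factor dominance is marginal in the synthetic world.** With
  uncertainties drawn around 2.05 (SD 0.37) and `cue_quality` in
  [0.7, 1.3], the ratio mean(SD over $U$)/mean(SD over $D$) fluctuates
  around 1 across group draws: scaling *all* directional features by
  ±30% is a far stronger acoustic manipulation than the differences
  between real listeners' ears, which the original analysis found to
  encode directional information similarly well. The acceptance check
  uses a fixed, a-priori chosen group seed; the direction of the
  inequality in general depends on how conservative the synthetic
  DTF spread is.
- The model is stationary and direction-static: no head movements,
  dynamic cues, reverberation, or lateral-dimension errors.

## Reproducibility

Every generator is a pure function of its parameters and an integer seed;
the study runner derives all sub-seeds from one master seed and records
them in `manifest.json`. `scripts/acceptance.R --seed S --out F`
recomputes the acceptance quantities from scratch with seed `S`.
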