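---
title: "An auditory-nerve loudness model with a central gain stage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An auditory-nerve loudness model with a central gain stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`anloud` simulates loudness perception from the auditory periphery upward
and uses the simulation to ask which kind of central gain change can
reproduce the uniformly lowered loudness discomfort levels (LDLs) seen in
hyperacusis patients with normal audiograms. This vignette documents the
model, the calibration procedure, every place where a design choice had to
be made, and what the shipped tests do and do not demonstrate.

## Model structure

The signal chain has four stages.

1. **Outer/middle ear.** Sound pressure (Pa, calibrated in dB SPL re
   20 µPa) passes a parallel three-band filter: 1900–4200 Hz at −2 dB,
   4500–6300 Hz at −3 dB, and 8000–12000 Hz at −19 dB. Each branch has a
   Butterworth magnitude response and the bank is applied as a single
   zero-phase frequency-domain filter (see *Numerical choices*). The output,
   scaled by a stapes constant, is the stapes-velocity input to the cochlea.

2. **Basilar membrane (DRNL filterbank).** Each of the 500 channels
   (64 in the desk profile), with characteristic frequencies (CFs) spaced
   evenly on the ERB-number scale from 40 Hz to 13 kHz, is a dual-resonance
   non-linear filter: a linear path (gain, two first-order gammatones, four
   second-order Butterworth low-passes) summed with a compressive path
   (three gammatones, the broken-stick non-linearity
   `y = sign(i) min(a|i|, b|i|^c)`, three gammatones, three low-passes).
   All per-CF coefficients come from the published human parameter
   regressions `log10(p) = p0 + m log10(cf)` stored in
   `inst/extdata/drnl_human_params.yaml`; the linear-path gain uses
   `log10(g) = 4.20405 − 0.48 log10(cf)`, with the slope magnitude written
   as the parameter `g0 = 0.48`. The sign convention matters: a *positive*
   gain slope would make the linear path swamp the compressive path and
   abolish compression, so `g0` enters with a minus sign.

3. **Inner hair cell / auditory nerve.** Every channel drives three
   leaky-integrate-and-fire (LIF) fibers — the three spontaneous-rate (SR)
   classes: low-threshold/high-SR (35 sp/s), medium (8 sp/s), and
   high-threshold/low-SR (2 sp/s). The input current is the half-wave
   rectified BM velocity times a global drive scale, plus class-specific
   white noise that produces the spontaneous firing.

4. **Gain stage.** A frequency-dependent healthy-control gain
   `g_hc(cf) = a + b (u(cf) − c)²` (with `u` the ERB-number of the CF)
   weights each fiber's output; a hyperacusis gain, one of eight variants
   (linear vs power-law × sub- vs supra-threshold × frequency-independent
   vs quadratic), can be applied after it.

The central assumption throughout is that perceived loudness is
proportional to the summed activity of all fibers at the gain-stage
output. Binaural integration is not modelled.

## Loudness readout and calibration

Loudness in sones is
`Ldn(f, L) = ((ΣR − R_sp) / (ΣR(1 kHz, 40 dB) − R_sp))^x`, so the 1-kHz
40-dB tone is exactly 1 sone on its own calibration responses. The
exponent `x` is fitted by least squares (MSE in sones) so that the
normalized summed response to 1-kHz tones at 30–90 dB SPL matches the
sone-scale law `2^((L−40)/10)`; at the shipped defaults the fit gives
`x ≈ 1.62`. A negative numerator (a response below baseline, possible by
chance in spiking mode) clamps to 0 sones.

Equal-loudness contours (ELCs) follow from matched activity: a tone has a
loudness of `P` phon when it evokes the same total activity as a 1-kHz
tone at `P` dB SPL *in the healthy configuration*. Anchoring the
reference to the healthy model is essential — a gain applied to both
sides of the match would cancel — and it is what lets a hyperacusis gain
shift contours downward. "Model dB HL" subtracts the healthy 2-phon
contour (the model's hearing-threshold proxy) per frequency.

## Calibration sequence and chosen constants

`calibrate_model()` runs, in order:

1. **Drive scaling and thresholds.** The deterministic mean rectified
   drive of the on-CF channel is measured for 1-kHz tones; the drive scale
   and the three class thresholds are set so the deterministic activation
   thresholds sit at 10, 35 and 60 dB SPL — the characteristic threshold
   spread of high-, medium- and low-SR fibers.
2. **Noise levels.** Per class, the noise current is root-found
   (stochastic scan plus secant refinement) so the spontaneous rates hit
   35/8/2 sp/s.
3. **Rate transfer tables.** For the deterministic *rate mode*, the
   spiking rate of each class is tabulated against the mean rectified
   drive (1-kHz rectified-sinusoid carrier, monotonized, anchored at the
   target SR at zero drive) and interpolated at evaluation time. Rate mode
   is exact at the SR point, agrees with spiking class means to within
   ~10 % at moderate CFs, and is less accurate for very low carrier
   frequencies (the membrane no longer averages over cycles).
4. **Spontaneous baseline.** The per-fiber `R_sp` is measured with the
   probe the loudness formula prescribes: a 1-kHz tone at −10 dB SPL
   (spiking, seeded).
5. **Exponent and reference.** `x` and the 1-kHz/40-dB reference sum are
   fitted/stored from seeded spiking runs.

Constants that the source architecture leaves open, and the values chosen
here:

| Parameter | Value | Rationale |
|---|---|---|
| sample rate | 44.1 kHz | resolves the 13-kHz top CF with margin |
| on/off ramps | 10 ms raised cosine | avoids spectral splatter; negligible for mean rates |
| stapes scale | 3.5e-3 | puts the 1-kHz broken-stick knee near 35 dB SPL, the physiological onset of BM compression |
| LIF τ | 5 ms | fast point-neuron approximation of the IHC/synapse chain |
| refractory | 4 ms | saturation ≈ 250 sp/s, as in real AN fibers |
| thresholds | 10/35/60 dB SPL | AN threshold spread across SR classes |
| reset | 0, absolute refractory | standard LIF |

τ, the refractory period and the threshold placements also shape the
emergent loudness exponent; they were fixed, within physiological ranges,
during model design and are exposed as arguments of
`calibrate_fiber_classes()`.

## Numerical choices

* **Outer/middle-ear realisation.** Summing causal IIR branches is
  phase-sensitive: with plain second-order branches, coherent cancellation
  between branch skirts pushes the measured 9–11-kHz band power to
  −24.7 dB instead of −19 dB, and no single causal order fixes all three
  bands without also steepening the below-band skirt of the lowest branch —
  which is the model's only low-frequency pathway (it sets the thresholds
  at 125–1000 Hz). The bank is therefore applied zero-phase in the
  frequency domain, each branch magnitude a Butterworth bandpass magnitude
  with separate edge orders (low edge of branch 1 at order 2, keeping the
  ~12 dB/oct low-frequency skirt; inner edges at orders 6–12 so bands do
  not leak into each other). The measured white-noise band gains are then
  −2.00, −2.94 and −19.00 dB.
* **Gammatone stages** are cascades of complex one-pole resonators with
  per-stage unit gain at the resonator frequency; the digital realisation
  is verified through behaviour (tuning, compression slope), not through
  sample-exact comparison with any particular reference filter.
* **Compression window.** The two DRNL paths interfere near the level
  where the linear path catches up with the compressive one (a genuine
  DRNL feature), so the compressive slope is measured by regression over
  `[knee + 5, crossover − 15]` dB, both bounds computed from the channel
  coefficients (`drnl_compression_window()`).
* **Contour search.** Summed activity is evaluated on a 10-dB coarse grid
  over −20…130 dB SPL, refined to 2-dB steps around the model hearing
  threshold (where the evoked response first exceeds 1 % of the
  spontaneous sum); the search interpolates *activity versus level*
  linearly and inverts for the level, returning the smallest crossing.
  Targets outside the searched range are flagged (`below-range` /
  `above-range`), mirroring clinical equipment ceilings. Every
  (frequency, level) evaluation derives its own seed from the base seed,
  so contours are reproducible point-wise.
* **Fitting.** The healthy gain is fitted by Nelder–Mead from a
  deterministic multi-start grid, with an inner continuous search over the
  LDL-matching phon level; out-of-range contour points are imputed just
  beyond the level range during optimization so the objective keeps a
  gradient off the feasible region. The overall scale of `g_hc` is a gauge
  freedom (both the activity match and the sone ratio are
  scale-invariant), so the offset is fixed at `a = 1` and only the shape
  `(b, c)` is fitted. Quadratic gains are clipped at a small positive
  floor (1e-3) with a warning. The power-law exponent `z = 1.1` is never
  fitted per variant.

## Profiles and problem sizes

The **desk** profile — 64 channels, 1-s grid stimuli, rate-mode contour
searches, 4-s spiking calibration runs, 6–10-s spontaneous-rate probes —
is what the test suite and the acceptance script use; a full contour/fit
cycle runs in a few minutes on one core. The **full** profile (500
channels, 10-s stimuli, spiking searches) reproduces the original scale
and is available through `build_model("full")`.

## The synthetic audiometric fixtures

The clinical cohorts are emulated, not shipped: controls have 0 dB HL
thresholds and flat 100 dB HL LDLs (reported at 0.5–4 kHz, as is typical
for control groups), patients have normal thresholds and LDLs uniformly
20 dB lower across 0.125–8 kHz — the canonical group-mean hyperacusis
pattern. Optional per-subject jitter is seeded. The fixtures reproduce the
*group-mean pattern* only: they contain no inter-subject structure, no
frequency-dependent LDL shape, and no measurement ceiling censoring
(though per-frequency ceilings are carried and can down-weight the fit via
`ceiling_weights()`). Passing tests on these fixtures therefore shows that
the machinery discriminates gain mechanisms under the idealised pattern,
not that it fits any particular clinical data set.

## What the model does and does not reproduce

* The three SR classes calibrate to 35/8/2 sp/s within a few percent; the
  loudness exponent emerges at ≈ 1.62; the sone-doubling contract holds
  within sampling error; contours are monotone and non-crossing.
* The eight-variant comparison reproduces the headline discrimination:
  supra-threshold variants leave the no-stimulus summed activity exactly
  unchanged, fitted linear sub-threshold variants amplify the spontaneous
  baseline above the healthy 40-phon evoked level (a permanent
  "tinnitus" at high loudness), and power-law sub-threshold variants
  *depress* the baseline (`(R_sp/R_max)^1.1 ≪ 1`), distorting the
  threshold region — both artifact classes the supra-threshold power-law
  gain avoids.
* The near-threshold "step" of linear supra-threshold gains is a
  spiking-mode phenomenon: per-fiber `max(0, R − R_sp)` gating rectifies
  finite-window measurement noise into an activity floor that swamps the
  low-phon references, so the 2–30-phon contours collapse onto the bottom
  of the level range. In deterministic rate mode the same span is ~22 dB;
  `near_threshold_contour_range()` therefore measures it with a spiking
  sweep.
* **Known limitation — absolute contour flatness.** With the gain
  restricted to a quadratic (deliberately, against over-fitting), the
  fitted healthy model matches flat control LDLs to ~4 dB RMS but not
  better: the 1-kHz contour point is rigidly `phon − 2` in model HL while
  the 3–4-kHz dynamic range stays several dB too large (the −2-dB band of
  the outer/middle-ear filter makes 3–4 kHz comparatively hyper-sensitive
  at threshold, and activity-ceiling effects raise its LDL-level contour).
  A frequency-independent hyperacusis fit inherits this pattern, so its
  per-frequency error against the −20-dB fixture reaches ≈ 5 dB at the
  worst frequency. Quadratic *frequency-dependent* variants absorb part of
  it. Relaxing the quadratic restriction would remove the limitation at
  the cost of the over-fitting protection.
* Temporal fine structure, adaptation, efferent feedback, hearing-loss
  audiograms and binaural integration are out of scope by design.

## A compact end-to-end run

```{r example}
library(anloud)

model <- calibrate_model(build_model("desk", seed = 1))
grid  <- compute_response_grid(model)

healthy <- fit_healthy_gain(make_control_table(), grid)
model$g_hc <- healthy$g_hc

patient <- make_patient_table()
report  <- compare_variants(patient, grid, healthy,
                            weights = ceiling_weights(patient))
report[, c("variant", "residual_db", "baseline_change", "score")]
```
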