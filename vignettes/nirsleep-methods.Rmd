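---
title: "Sleep-stage-stratified analysis of infant fNIRS responses: models and methods"
author: "nirsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-stage-stratified analysis of infant fNIRS responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsleep)
```

## Scientific problem

Functional near-infrared spectroscopy (fNIRS) in very young infants is
almost always acquired during natural sleep. Infant sleep alternates between
two behaviourally distinct stages — quiet sleep (QS, the NREM precursor) and
active sleep (AS, the REM precursor) — with different respiration, eye and
muscle activity, and different cerebral hemodynamics. If stimulus-evoked
hemodynamic responses depend on the stage an infant happens to be in,
"group" effects in infant fNIRS studies can be confounded by behavioural
state. `nirsleep` implements an analysis pipeline that takes multichannel
dual-wavelength intensity recordings and behavioural sleep-stage coding
sheets, and produces sleep-stage-stratified activation statistics for two
auditory block designs:

* **social selectivity** — 8 vocal (V) and 8 non-vocal (N) trials of 8 s in
  a fixed pseudo-random order with 10–12 s silent baselines;
* **habituation and novelty detection ("hand")** — 25 spoken-sentence trials
  of 8 s with 10-s baselines: trials 1–15 a female speaker
  (epochs Fam1/Fam2/Fam3), 16–20 a male speaker (novel), 21–25 the female
  again (post).

Because comparable infant recordings are under restricted access, the
package ships a first-class synthetic-data generator whose defaults encode
the study conditions the analysis assumes, so every stage of the pipeline is
testable end to end.

## Forward model of the synthetic generator

Each simulated subject has an 18-channel bilateral frontal–temporal array
(9 channels per hemisphere), two wavelengths (780/850 nm), 2 cm
source–detector separation and a 10 Hz sampling rate.

**Hemodynamics.** Each trial contributes a boxcar (the 8-s stimulus)
convolved with a double-gamma HRF, peak-normalised so that a planted
amplitude *A* (µM HbO) is the peak concentration change of an isolated
trial. The infant HRF is not firmly established; the default peak time of
7 s, undershoot peak of 16 s and undershoot ratio of 1/6 are configurable
package choices (`subjectParams()`). The amplitude depends on the condition
and on the sleep stage at trial onset; familiarization epochs decay
multiplicatively (`habituationDecay`, default 0.95 in QS and 0.15 in AS, so
active sleep habituates strongly while quiet sleep barely does — the
regime the group contrasts are designed to detect). Novel and post trials
sit at the Fam3 level by default: the emulated conditions include no
group-level novelty response. HbR is a scaled negative copy of HbO
(`hbrRatio`, default −0.35). Default Fam1 amplitudes are 0.15 µM (QS) and
0.62 µM (AS); social amplitudes are 0.30 µM (V) and 0.50/0.40 µM (N in
QS/AS). These are simulation settings chosen to match the order of
magnitude of the reported group summaries, not claims about any
individual dataset.

**Optics.** Concentrations map to optical density through the modified
Beer–Lambert law (tabulated extinction coefficients at 780/850 nm,
differential pathlength factors 5.22/4.23, 2 cm separation) and to
intensity via \(I = I_0 e^{-\Delta OD}\).

**Noise.** A cardiac oscillation (2.2 Hz, inside the 1.5–3.5 Hz infant
band used by channel QC) is shared across the two wavelengths of a channel,
which is what makes a well-coupled channel's wavelengths correlate;
respiratory (0.4 Hz) and slow drift (0.012 Hz) components are added in OD
space, white instrument noise in intensity space. Motion artifacts — brief
spikes and persistent baseline steps of 0.6–1.5 OD affecting 20–70 % of
channels — occur as a Poisson process whose rate depends on the sleep
stage (defaults 0.4/min in QS, 1.5/min in AS), reproducing the reported
pattern of lower data quality in active sleep. Artifact amplitudes are
deliberately above the motion-detection amplitude threshold: sub-threshold
steps are indistinguishable from hemodynamics at a single channel and no
pipeline can remove them.

**Sleep.** Stage timelines are first-order Markov chains over
{QS, AS, awake} in 15-s epochs; coding sheets observe each behavioural
criterion with probability `meanObservability` and score the epoch by the
summed weights of observed criteria.

**What the generator does not emulate.** Spatially structured physiology
(systemic superficial signals), subject-specific HRF shape variation,
wavelength-dependent artifact shapes, coder disagreement beyond random
criterion visibility, and any cortical anatomy. Passing tests therefore
demonstrate that the pipeline's logic and numerics are correct under the
stated assumptions — not that the pipeline is robust to everything real
infant data can contain.

## Preprocessing chain and numerical choices

1. **Channel QC.** The scalp coupling index (SCI) is the cross-wavelength
   correlation after zero-phase band-pass to 1.5–3.5 Hz; the peak spectral
   power (PSP) is the maximum of the unit-normalised power spectrum of the
   standardised cardiac-band signal. Both are computed in non-overlapping
   30-s windows and summarised per channel by the median, so brief motion
   episodes do not dominate (the cited QC tool is likewise windowed; its
   exact windowing and the PSP unit are not public, so the printed
   "0.1 µV" threshold is treated as a normalised-power threshold of 0.1).
   A channel is bad if SCI < 0.7 or PSP < 0.1; a dataset is excluded if
   more than 40 % of channels are bad.
2. **Optical density.** \(\Delta OD = -\ln(I/\bar I)\) per
   channel/wavelength — the common convention of the field's tooling; the
   reference \(\bar I\) only shifts OD by a constant, which baseline
   referencing later removes.
3. **Motion detection.** Sliding 1-s windows; a channel-time is flagged
   when the OD excursion exceeds 15 × the channel's whole-record SD or
   0.5 OD, and flags are dilated by 1 s. The whole-record SD convention is
   a documented choice; the amplitude criterion is what catches the large
   artifacts in practice.
4. **Trial rejection.** A trial is invalid if at any moment in its
   peristimulus window more than 50 % of channels are flagged
   (9/18 flagged channels keep the trial; 10 reject it).
5. **Motion correction.** Flagged segments are fitted with a smoothing
   spline and the fit subtracted; the spline parameter is the csaps-style
   p = 0.99, converted to `smooth.spline`'s penalty by λ = (1−p)/p · L⁻³
   (R standardises the abscissa to [0, 1], so the raw-scale penalty must be
   rescaled by the cube of the segment length). Corrected segments are
   re-anchored to the preceding clean sample, and the data after a segment
   are shifted to remove residual steps. A per-level IQR-thresholded
   (0.8 × IQR) Haar discrete-wavelet filter is then applied — but only to
   channels that carried motion flags: on a clean channel the per-level
   coefficient IQR collapses toward zero and the fence would zero genuine
   hemodynamics. Segments shorter than four samples are passed through.
6. **Low-pass.** Zero-phase 5th-order Butterworth at 0.6 Hz (the design
   order is a package choice; only the cutoff is prescribed). All filters
   demean and reflect-pad before `filtfilt` to suppress edge transients.
7. **Chromophore conversion.** The 2×2 extinction/DPF/separation system is
   inverted per time point; DPF 5.22 is mapped to 780 nm and 4.23 to
   850 nm (DPF decreases with wavelength; the mapping is configurable and
   flagged as an assumption).
8. **Block averaging.** The concentration series is linearly detrended
   as a whole (a per-segment detrend would absorb part of the unimodal
   response and bias amplitudes down ~35 %); valid-trial segments over the
   paradigm window (−4…20 s social, −4…18 s hand) are baseline-referenced
   to the −4…0 s mean and averaged. Conditions with fewer than three valid
   trials are dropped; losing a required condition raises a typed
   subject-exclusion condition.
9. **Windowed mean response.** Default analysis window 8–16 s post-onset,
   bracketing the HRF peak of an 8-s trial; the originating studies import
   cluster-derived windows that are not published, so the window is a
   configurable package default.

**Overlap attenuation.** With 10–12 s baselines, successive responses
overlap (the HRF tail of one trial leaks into the next trial's baseline
window), attenuating block-average amplitudes by roughly a third relative
to an isolated trial. This affects all conditions and stages alike, so
group contrasts are preserved; the forward/inverse recovery tests therefore
use isolated trials (≥ 40 s spacing), where the chain recovers planted
amplitudes to well under 1 %.

## Sleep staging and trial allocation

Epoch scores sum the weights of observable criteria (weights per
stage-scheme sum to 100; mutually exclusive behaviours — REM vs no REM,
regular vs irregular respiration — carry the higher weights). The shipped
weight table is a package default honouring that ordering: the original
supplementary table is not available, and every weight is overridable
(`codingSchemeFromYAML()`). A recording is excluded when the mean epoch
score over **all** epochs (including awake ones — a flagged
interpretation) is strictly below 65 %; a mean of exactly 65 is included.
Inter-rater reliability uses the single-measure, absolute-agreement,
two-way random-effects ICC(2,1); the single-measure variant is a package
choice.

Trials take the stage of the timeline interval covering them; trials
straddling a stage change are `mixed` and never retained. Stage-constant
subjects join their stage's group. For subjects who changed stage:

* **social** — retained if some window of six consecutive trials lies
  entirely in one sleep stage and contains ≥ 3 valid N and ≥ 3 valid V
  trials. "Six consecutive trials" counts positions, not valid trials
  (motion-invalid trials occupy positions but contribute nothing), the
  window may not straddle awake or mixed trials, and the earliest
  qualifying window decides the group — the tie-break is not prescribed.
* **hand/fam1** — ≥ 3 valid Fam1 trials in one stage;
  **habituation** — one stage across trials 1–15 plus ≥ 3 valid Fam1 and
  ≥ 3 valid Fam3; **novelty** — ≥ 3 valid Fam3 directly followed by ≥ 3
  valid novel in one stage, read strictly: a contiguous all-valid,
  one-stage run across the trial 15/16 boundary (an invalid trial at the
  junction breaks adjacency). A subject may contribute different stages to
  different analyses but never two stages to one analysis.

Data-quality comparisons (percentage of motion-free samples; valid trials
per condition) use only subjects who remained in one sleep stage
throughout the paradigm.

## Statistics

* **t-tests** accept raw samples or `(mean, sd, n)` summaries, so printed
  group summaries can be re-analysed. Data-quality comparisons default to
  Welch (recomputing the published table confirms Welch reproduces the
  printed t statistics); ROI comparisons default to pooled variance
  (printed integer degrees of freedom imply the pooled formula). Both are
  configurable.
* **Cohen's d** is always the pooled-SD variant; its CI is a stratified
  percentile bootstrap (5000 resamples by default) — the percentile method
  is a package choice where only "bootstrap CI" is prescribed.
* **Outlier handling** is the 1.5 × IQR rule per sleep-stage group with
  type-7 (linear-interpolation) quartiles — the convention changes the
  fences and is therefore documented. Note a known property: trimming
  per group slightly shrinks the SD estimate, so filter-then-t has a true
  level of about 0.08 at n ≈ 15/group rather than the nominal 0.05; the
  package applies the rule faithfully and reports it here rather than
  hiding it.
* **Permutation tests** (5000 label permutations, difference of means;
  sign flipping for the one-sample analogue) enumerate exhaustively
  whenever the number of arrangements fits in the budget, and include the
  identity arrangement in the p-value so that p is never 0. Normality and
  variance screening (Shapiro–Wilk) is computed and attached but never
  gates the parametric tests.
* **Channel-wise analysis** runs 18 one-sample t-tests per chromophore
  against zero (block averages are baseline-referenced, so zero is the
  baseline), Benjamini–Hochberg-corrected across the 18 channels; contrast
  (paired) tests run only on channels significant against baseline, with
  BH over that significant set (reading the scoping rule literally;
  configurable to the full-18 family). HbO and HbR families are corrected
  separately. Activation calls: HbO increase and/or HbR decrease is
  activation; both chromophores significant in the same direction is
  atypical and excluded from interpretation.
* **ROI analysis** uses the shipped registry of published channel lists
  (per cohort and analysis) as fixed inputs; they are not recomputed.

## Problem sizes and determinism

Every seeded operation is a pure function of its seed and restores the
caller's RNG state. The test suite exercises: full-chain recovery on
isolated-trial recordings (18 channels, ~6 min at 10 Hz); the FDR null
simulation at 18 channels × 20 subjects × 1000 replicates; power/level of
the ROI comparison at n = 15/16 × 200–400 replicates; bootstrap coverage at
n = 50/50 × 500 experiments (2000 resamples each); and exact-agreement
checks of the allocation rules against brute-force enumeration on
500–1000 random trial configurations. These sizes were chosen to estimate
each quantity to the precision its tolerance needs.

## Known limitations

* The synthetic forward model is linear and stationary; it cannot expose
  failures specific to nonstationary physiology or optode-tissue coupling
  changes that are not step- or spike-like.
* Overlapping block designs attenuate absolute amplitudes (above); the
  package reports windowed means, not deconvolved responses.
* The PSP unit convention and QC windowing of the original tooling are not
  public; the normalised-power variant here is calibrated to behave
  sensibly (tone ≫ 0.1 ≫ broadband noise) but is not numerically identical
  to it.
* The behavioural coding simulation treats criterion visibility as
  independent Bernoulli draws; real codability failures (wrapping, camera
  angle) are correlated across epochs.
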