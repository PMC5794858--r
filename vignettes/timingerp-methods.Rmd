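---
title: "Methods: interval-timing ERP analysis and its synthetic validation cohorts"
author: "timingerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval-timing ERP analysis and its synthetic validation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timingerp)
```

## The analysis in one paragraph

`timingerp` implements a complete analysis chain for event-related
potentials (ERPs) recorded during a visual time-production task: the
participant sees a cue, internally estimates 1200 ms, and presses a key;
every press is followed by evaluative feedback. Three neurophysiological
readouts are quantified from 60-channel EEG. The *contingent negative
variation* (CNV) is the slow negative ramp at the vertex that builds up
while the interval is being timed; it is scored as mean amplitudes in four
pre-response windows at Cz. The *feedback-related negativity* (FRN)
indexes feedback processing; it is scored at FCz as the peak-to-peak
amplitude of the two post-response negative deflections and then as the
difference of that amplitude between correct- and error-feedback trials.
Early visual processing is checked with the posterior P1/N1 components.
Group comparisons (healthy controls vs. the predominantly inattentive and
the combined ADHD presentation) use mixed repeated-measures ANOVAs with
Greenhouse-Geisser correction, partial eta squared effect sizes,
Bonferroni-corrected follow-ups, and Pearson correlations between timing
accuracy and symptom ratings.

No public recordings exist for this paradigm, so the package ships a
first-class synthetic-cohort generator whose group profiles encode the
published group-level results. Every stage of the pipeline can therefore
be validated by *parameter recovery*: generate cohorts whose ground truth
is known, run the full analysis, and check that the published values come
back out.

## Task model and trial classification

A response at latency $t$ (ms after cue onset) is classified as

* early for $400 \le t < 1000$,
* correct for $1000 \le t \le 1400$,
* late for $1400 < t \le 2000$,
* miss otherwise (including no response within 3000 ms).

The published windows share their endpoints; `classification_boundaries()`
adopts the half-open convention above (1000 ms and 1400 ms both count as
correct) so that every latency maps to exactly one category. This is an
assumption -- the original analysis does not state how boundary latencies
were counted -- but it only affects a measure-zero set of idealized
latencies and, on the sampled-time grid, a fraction of trials far below
the behavioral tolerances used anywhere in the package.

## Pipeline stages

1. **Resampling** to the 256 Hz analysis rate (the acquisition rate is
   500 Hz). Anti-aliasing uses an order-4 Butterworth low-pass at
   0.45 of the target rate applied forward-backward (so 48 dB/oct of
   magnitude roll-off), followed by linear interpolation onto the new
   grid; all signal content of interest lies far below the new Nyquist
   frequency, so both the pass-band error and the aliased residual are
   negligible. Events are remapped to the nearest new sample.
2. **Band-pass filtering** 0.5--20 Hz, implemented as order-8 Butterworth
   high- and low-pass cascades (48 dB/oct asymptotic slope per edge)
   applied forward-backward as second-order sections. See
   *Why the recovery configuration skips the band-pass* below.
3. **Segmentation.** Three schemes: stimulus-locked $[-2000, 3000]$ ms
   with a $[-200, 0]$ ms pre-stimulus baseline; response-relocked
   $[-2000, 1000]$ ms windows cut from the baselined stimulus epochs with
   *no* re-baselining (the fixed pre-stimulus baseline is the reference
   for the CNV); and feedback-locked $[-200, 1500]$ ms epochs cut from
   the continuous record and baselined to the $[-200, 0]$ ms pre-response
   interval. Windows are closed intervals; sample indices come from
   round-half-away-from-zero of $t \cdot f_s / 1000$.
4. **Artifact rejection**, separately per segmentation scheme, at the
   microvolt stage: a trial is rejected if *any* channel (a) leaves
   $\pm 200\,\mu V$, (b) spans more than $200\,\mu V$ within any sliding
   200 ms window, or (c) stays within $0.5\,\mu V$ for 100 ms. One bad
   channel rejects the trial; no interpolation is attempted.
5. **Spatial transform.** Either the spherical-spline current source
   density (CSD, surface Laplacian) producing reference-free
   $\mu V/m^2$ values, or the identity measurement mode used for
   parameter recovery (see below).
6. **Quantification.** Windowed means of the trial-average waveform for
   P1/N1 (parietal average) and the four CNV windows at Cz
   ($[-825,-775]$, $[-625,-525]$, $[-225,-175]$, $[-50,0]$ ms); FRN
   peak-to-peak scoring at FCz with group-specific 10 ms peak windows
   (controls & ADD 200--210 / 300--310 ms, combined type 225--235 /
   320--330 ms). "Mean peak amplitude" is implemented as the windowed
   mean of the condition-average waveform: the windows are narrow, and a
   literal per-trial peak search would only add noise-maximum bias. The
   FRN peak is the minimum of the condition average within its window
   (earliest sample on ties); the peak-to-peak value is
   $v(\text{peak}_2) - v(\text{peak}_1)$ and the FRN proper is
   peak-to-peak(correct) $-$ peak-to-peak(error). Because it is a
   within-waveform difference, the score is invariant to constant
   offsets, which also makes it robust to the choice of feedback-epoch
   baseline.
7. **Statistics.** `mixed_anova()` fits balanced split-plot designs (up
   to two within-subject factors, one between-subject factor) via the
   classical sums-of-squares decomposition. Every within-subject effect
   carries its Greenhouse-Geisser epsilon, computed from the pooled
   within-group covariance of subject-by-cell scores projected on the
   effect's orthonormal contrasts; the corrected p value is always
   reported *alongside* the uncorrected one, and the table flags which of
   the two crosses 0.05 -- no silent switching. Partial eta squared is
   $SS_\text{effect} / (SS_\text{effect} + SS_\text{error}) =
   F\,df_1 / (F\,df_1 + df_2)$. Subjects missing a within cell are
   excluded listwise with a message; structurally unbalanced designs
   (replicated cells) are an error rather than being silently averaged.

### Electrode/time-window validation

`validate_selection()` reproduces the electrode-validation procedure:
for a candidate window, each electrode's per-subject window mean is
compared against the per-subject mean of all other electrodes with a
paired two-tailed t-test, and an electrode is selected only if it is
significant at the Bonferroni-derived critical threshold *and* larger in
the expected polarity. The default critical threshold is 0.0007, the
published constant (note that $0.05/60 \approx 0.00083$; the published
value is adopted as-is). On default synthetic cohorts the procedure
selects Cz for the CNV windows and FCz for the FRN peaks, matching the
electrodes the analysis quantifies.

## The synthetic cohort generator

The generator is calibrated so that the *analysis pipeline's outputs*
match the published group-level values, which makes the targets
recoverable by construction in the noise-free limit and unbiased under
noise.

**Behavior.** Group category rates (correct/early/late/miss: controls
64/17/18/1 %, inattentive type 44/30/23/3 %, combined type 49/30/18/3 %)
are reproduced by a two-stage model. A latent standard-normal subject
factor shifts the subject's correct-rate by the published between-subject
spread (12/15/16 percentage points); trial categories are drawn from the
subject's rates, and latencies are then drawn from the group's calibrated
shifted-lognormal model *truncated to the drawn category's window*, so
classification always reproduces the category. `calibrate_rt_model()`
finds the shifted-lognormal parameters whose window masses match the
target rates by deterministic Nelder-Mead over multiple starts; the shift
is parameterized as $1000 - e^b$ so that near-symmetric (light-tailed)
targets remain approachable. Perfectly tail-free targets such as
$(0.5, 0.25, 0.25, 0)$ are representable only up to the family's tail
mass (about 0.7 % even in the Gaussian limit), in which case the
calibrator either reports the balanced best fit (within a user-supplied
tolerance) or raises a calibration-failure error.

**Symptom scores and the performance coupling.** Parent-rated
inattention/hyperactivity/impulsivity scores are drawn from the published
group moments, truncated to the 0--3 scale. Within each group the
subject's timing-precision latent and the inattention latent are coupled
through a Gaussian copula. The latent correlation is calibrated
*analytically* (no tuning loop): the realized correct count adds
multinomial noise to the latent rate, attenuating the count-score
correlation by
$\rho_{cu} = T\sigma_p / \sqrt{T^2\sigma_p^2 + T\,\bar p(1-\bar p)}$,
so the copula uses $\rho = r_\text{target} / \rho_{cu}$. The default
target is $r = -0.54$ for the inattentive group and 0 elsewhere.

**CNV.** Injected at the vertex (spatial Gaussian around Cz, unit weight
at Cz) as a piecewise-linear ramp that is zero before the stimulus,
*constant within each of the four analysis windows* at the group's target
amplitude, linearly interpolated between windows, and released to zero
within 100 ms after the response. Holding the value constant across each
window makes the window mean equal the target exactly regardless of
sample-grid quantization. The inattentive group's window-3 value is only
published pooled with window 2 ($0.03 \pm 12.4\,\mu V/m^2$); the default
uses 0.0 for window 3 and is flagged as pooled-derived. A per-subject
multiplicative amplitude factor (mean 1, SD 0.2, symmetrically truncated
at $\pm 3$ SD so cohort means stay unbiased) provides between-subject
amplitude variability.

**Feedback complex.** Two negative Gaussian deflections (SD 25 ms) at
the group's peak latencies, with the first peak at $-20\,\mu V/m^2$ in
both conditions and the second at $-20 + \text{p2p}_\text{condition}$.
Only the correct-minus-error *difference* is published (controls $-18.2$,
inattentive $-6.8$, combined $+4.9\,\mu V/m^2$); the per-condition
peak-to-peak levels are the package's own choice (correct condition
$-24/-14/-8\,\mu V/m^2$ respectively) with the error condition derived
from the published difference, which is the quantity the analysis
recovers. The CNV release completes before the earliest peak window and
the deflections are 100+ ms apart at SD 25 ms, so the components do not
leak into each other's measurements.

**P1/N1.** Posterior Gaussian deflections ($+10 / -12\,\mu V/m^2$,
SD 10/12 ms) centred in the group-specific windows over P7/P8/P9/P10.
No group differences are injected, matching the published null results.

**Background activity.** A rank-16 spatially correlated $1/f$ process
(12 µV per channel; Kasdin AR shaping of white noise, smooth random
spatial mixing patterns), four posterior amplitude-modulated 10 Hz alpha
sources (4 µV), and 1 µV white sensor noise. These levels are realistic
for band-limited pediatric EEG and are configuration fields, not
constants.

**Artifacts.** Frontal blink transients (220--300 µV raised cosines,
1.2 s), single-channel slow drifts (210--260 µV half-sines over 3 s) and
2 s flatlined channels, at Poisson rates 0.02, 0.002 and 0.001 per
second. Blinks and drifts trip the amplitude criterion, flatlines the
low-activity criterion; a genuinely sub-0.5 Hz artifact cannot trip the
max-diff criterion without also crossing the amplitude bound, so that
rule is exercised by dedicated step-transient tests instead. At the
default rates roughly 8--12 % of stimulus epochs are rejected, in the
band expected from the published preprocessing yields.

**Timing.** 300 trials; feedback is modelled at the response sample
(display duration 500 ms), followed by the published 800--2200 ms
inter-trial interval. Epoch padding guarantees all segmentations fit.

**Determinism.** Per-subject seeds are fanned out from the master seed by
a deterministic integer hash; all R-level draws use R's RNG and the bulk
compiled-code noise stream is seeded from it, so a fixed seed yields
bit-identical subjects.

### What the generator does *not* emulate

There is no volume-conduction forward model (components are injected with
idealized spatial profiles), no ocular/pulse artifact morphology beyond
what the rejection rules need, no trial-to-trial learning dynamics, no
latency jitter of the feedback complex, and no realistic scalp topography
beyond smooth spatial mixing. Passing recovery therefore shows that the
*pipeline arithmetic* is faithful -- segmentation, baselining, rejection,
averaging, scoring and statistics do what they claim -- not that the
pipeline would be robust to every pathology of real pediatric EEG.

## The identity spatial measurement mode

The published amplitudes are in $\mu V/m^2$ *after* a spherical-spline
CSD whose parameters (spline order, regularization, head radius) are not
published; absolute CSD amplitudes depend on those choices and on the
electrode geometry, which is also unpublished (the deterministic
golden-angle layout used here is a stand-in). Calibrating the generator
through an assumed CSD would therefore bake two unpublishable unknowns
into every target. Instead, the generator's amplitude targets are defined
in the *post-baseline identity-spatial measurement space*: the pipeline
runs with `identity_spatial_mode()`, which leaves the data numerically
unchanged and only relabels them to the nominal measurement scale, and
the recovered window means are compared with the published numbers on
that scale. The real CSD transform (order $m = 4$, $\lambda = 10^{-5}$,
50 Legendre terms, 8.75 cm head radius, scaled by $1/r^2$ -- the
conventional spherical-spline defaults) is implemented in full and
validated separately against brute-force spline fits, numerical surface
Laplacians, and its invariance properties. The spatial mode used by a run
is recorded in the provenance log.

## Why the recovery configuration skips the band-pass

The 0.5 Hz high-pass edge (48 dB/oct) has an impulse-response time
constant of roughly a third of a second, while the preparatory ramp it
would be applied to evolves over 1.4--3.9 s: most of the CNV's energy
lies below the high-pass edge. A zero-phase application of the designed
filter to the injected ramp therefore attenuates the window amplitudes by
several $\mu V/m^2$ -- a well-known interaction between steep high-pass
filtering and slow cortical potentials, and several times the recovery
tolerance. The generator emits signals already confined to the analysis
band (no DC offset, no drift unless injected as an artifact, no line
noise), which makes the band-pass structurally a no-op for synthetic
data except for this one distorting effect on the ramp. `recovery_config()`
therefore disables the band-pass stage; externally recorded data analyzed
with `pipeline_config()` keep it, and the filter itself is tested against
its frequency-response contract (pass-band flatness, stop-band slope, DC
removal).

## Numerical choices and degenerate inputs

* Filters are built as cascaded second-order sections; a direct-form
  order-16 band-pass with a 0.5 Hz corner at 500 Hz is numerically
  unstable.
* The two analysis paths in `analyze_subject()` are interchangeable: the
  modular path materializes every epochs array; the fused path evaluates
  the rejection criteria and condition averages directly against the
  continuous record (the sliding-window criteria are offset-invariant and
  every epoch window is a continuous-record window, with the amplitude
  criterion handled per-trial-baseline). The test suite asserts
  bit-equality of the two paths, and the fused path is what makes
  cohort-scale recovery runs cheap.
* `resample_recording(destructive = TRUE)` lets the cohort pipeline
  filter in the recording's own memory because it owns and immediately
  discards each subject; the default keeps inputs intact.
* A strictly noise-free recording has silent channels by construction;
  `rejection_criteria(low_activity_uV = 0)` disables the dead-channel
  rule for that limiting case (thresholds are otherwise required
  positive).
* Zero kept trials in a condition yield `NA` with a warning and the
  subject is excluded from that cell; constant inputs to `pearson_r()`
  and zero-variance pairwise contrasts are errors/flagged degenerate
  rather than silent numbers.
* Test problem sizes: unit tests run 16--24 channel montages with 20--80
  trials, where every property under test is size-invariant; the
  acceptance suite runs the full study conditions (60 channels, 300
  trials, 16 subjects per group, ten replicate cohorts).

## Known limitations

* The equidistant montage is a deterministic stand-in, not the original
  cap; CSD amplitudes on it are internally consistent but not comparable
  in absolute terms to the published ones (hence the identity measurement
  mode for recovery).
* Classic EDF cannot carry event annotations; the exporter writes a
  plain-text event sidecar next to each EDF.
* The behavioral model has no sequential structure (no post-error
  adjustments, no block effects); the published analysis did not use any.
* Only balanced split-plot ANOVA designs are supported, which is what the
  published analysis requires.
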