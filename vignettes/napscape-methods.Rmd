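---
title: "Methods: infant nap EEG microarchitecture and sensory reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infant nap EEG microarchitecture and sensory reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napscape)
```

## Scope

`napscape` implements an end-to-end analysis of infant daytime-nap
polysomnography under auditory stimulation: detection of the NREM
micro-elements thought to support sensory decoupling during sleep (slow
waves, evoked K-complexes, sleep spindles), band-power measures,
stimulus-locked event-likelihood statistics, detector evaluation against
manual annotations, macroarchitecture summaries, questionnaire-based
sensory-reactivity scoring, and mixed-effects models relating reactivity
and stimulation to sleep structure. Because clinical infant recordings
cannot be redistributed, the package ships a synthetic polysomnography
generator that reproduces the statistical structure every stage assumes,
so the full pipeline is exercised and tested without any external data.

## Pre-processing

EEG is band-passed 0.2–40 Hz with a first-order Butterworth filter.
Filtering is applied forward–backward (zero phase): event detection relies
on peak and zero-crossing latencies, and a causal single pass would shift
them by a frequency-dependent group delay. The squared magnitude response
of the two-pass filter is what the unit tests check against the analytic
form. Notch filters at 50–200 Hz are retained in the interface for
fidelity with standard acquisition chains but are no-ops behind a 40-Hz
low-pass; the implementation skips them with a message rather than
silently pretending to apply them.

Re-referencing offers linked mastoids (the analysis reference: the mean of
TP9/TP10 subtracted everywhere) and contralateral mastoids (the staging
reference: lateral channels referenced to the opposite mastoid, midline
channels to the linked average). A recording whose mastoid channels are
flagged bad is *excluded* with a typed condition rather than silently
re-referenced, since a corrupted reference contaminates every channel.

Automatic artifact rejection operates on 1-s windows: the cross-channel
mean log-RMS of each window is standardized within each sleep stage and
windows with |z| > 3 are flagged. The stage-wise standardization prevents
deep-sleep amplitude from being mistaken for artifact. This is a
deliberately simple, covariance-free detector with one interpretable knob
(`z = 3` by default); on stationary Gaussian data it flags well under 2%
of windows, and real-world rejection rates of a few percent are the
expected regime.

## Band power

Power spectral densities use Welch's method with 4-s Hann windows and the
*median* across segment periodograms, which resists transient artifacts
that survive masking. Two conventions are not dictated by the method
description and were fixed as package decisions: 50% segment overlap (the
standard Welch convention) and per-segment mean removal. Segments are
drawn only from contiguous runs of stage-eligible, artifact-free samples,
so no segment spans an excision boundary. Slow-wave activity (SWA) is the
0.5–2 Hz band integral over N2+N3 on a ten-channel fronto-central-occipital
region of interest; sigma power is 9–16 Hz over N2 only on the
eight-channel fronto-central subset. Both are medians across their ROI.

## Slow-wave detection

The signal is band-passed 0.5–2 Hz; a candidate is a negative half-wave
followed by a positive half-wave between consecutive zero crossings, and
is accepted when the negative half-wave lasts 0.3–1.5 s, the positive one
0.1–1 s, the negative peak exceeds 40 µV, the positive peak 10 µV, and
peak-to-peak 75 µV, with no upper amplitude limits (infant slow waves are
larger than adults'). Amplitudes are measured on the band-passed signal,
matching the detector family this adapts; event onset is the negative-going
zero crossing, the negative peak time is the half-wave minimum (needed for
evoked K-complex windows), and candidates touching an ineligible sample
are discarded rather than clipped. The test suite holds the implementation
to *event-for-event equality* with an independent exhaustive half-wave
enumerator on one hundred 60-s synthetic signals.

## Spindle detection

Spindles are detected from three features on a common per-sample grid:
moving RMS of the 9–16 Hz sigma-filtered signal (0.3-s window), moving
broadband–sigma correlation (0.3-s window), and relative sigma power from
a 2-s/0.2-s-step short-time spectrum. Each feature votes when above its
threshold; votes are smoothed over 0.1 s; candidates are runs with ≥ 2 of
3 votes, merged when closer than 750 ms, and kept when 0.5–4 s long. The
RMS threshold is soft: mean + 1.275 SD of the moving RMS over eligible
sleep; correlation and relative power use absolute thresholds 0.52 and
0.13. These are the infant-adjusted values (85%, 80% and 65% of the
family defaults 1.5, 0.65, 0.2).

Two details are the package's own: the broadband partner for the
correlation and the relative-power denominator is the preprocessed band
(0.2–40 Hz), and candidate boundaries are refined to the extent of a
short-window (50 ms) sigma envelope before the duration rule is applied.
The moving features smear an event's edges by roughly half a feature
window; without refinement a strong 0.3-s burst acquires an apparent
0.5-s footprint and defeats the minimum-duration rule, which exists
precisely to reject such bursts.

ROI spindle density aggregates per-channel counts per artifact-free N2
minute; the aggregation defaults to the median for consistency with the
slow-wave measures, with `aggregate = "mean"` available since "averaged"
is ambiguous for this measure.

## Detector evaluation and threshold tuning

Event-level agreement uses greedy one-to-one matching by overlap amount;
any temporal overlap counts by default, with a minimum-overlap fraction
exposed. Precision, recall and F1 are reported pooled across naps
(micro-averaged) — the convention used for the headline numbers — with the
per-nap mean also returned. The threshold grid search computes the three
features once per nap and re-thresholds per cell, returns the argmax of
pooled F1 with ties broken toward higher precision and then higher
thresholds, and persists the full F1 surface for audit. Dependent
correlations sharing the manual-density variable are compared with
Steiger's (1980) z using the back-transformed average correlation; the
test suite checks it against a Monte-Carlo simulation of the Fisher-z
difference distribution.

## Stimulus-locked statistics

The paired-tone design (1-s tones, 700-ms intra-pair gap, 12–18-s jittered
inter-pair interval) fixes the window geometry: the spindle ON window is
S1 + gap + S2 + an equal post-S2 interval = 3.4 s; the OFF window is its
pre-S1 mirror; the analysis segment adds 1-s buffers (8.8 s total). The
K-complex ON window is 450–700 ms after S1 (where the negative peak of an
evoked K-complex falls), with the equal-length −1250 to −1000 ms control
window. All windows are half-open `[low, high)` in stimulus-relative time.
A stimulus is eligible when its full segment lies in artifact- and
arousal-free N2; likelihoods divide the count of events (K-complexes by
negative-peak time, spindles by start time) by the number of eligible S1.
Only S1 responses are counted, reflecting the refractory period after an
evoked K-complex. The K-complex detection segment is −4.15 to +12.35 s
(the detector's minimum-length requirement); the package detects slow
waves over the pooled eligible mask, which is equivalent to per-segment
detection because events must lie fully inside eligible runs.

## Macroarchitecture and sensory reactivity

Sleep onset is the first non-wake epoch after lights-off (a first-N2 rule
is available), offset the end of the last non-wake epoch; nap duration is
total sleep time; efficiency uses the lights-off–to–offset denominator
(configurable, since the convention is not uniquely determined). Arousal
density divides the arousal count by the sleep period minus arousal time;
arousals attributed to known external causes are excluded from the count
and, by default, their duration from the denominator as well.

Reactivity scoring reverses the 1–5 frequency scale (`6 − raw`) so high
scores mean high reactivity and averages all items not marked "not
applicable"; respondents are never dropped for missingness, and optional
labels mark composites above 1.9 ("more reactive") and 2.5 ("much more
reactive"). Cronbach's alpha uses listwise deletion.

## Statistical models

Outliers beyond 4 SD are Winsorized to one measurement unit beyond the
most extreme non-outlier (the unit defaults to 1 and is configurable,
since the natural granularity is variable-specific). The nap-level model
is `outcome ~ stimulation + reactivity + sex + age + (1 | subject)` by
maximum likelihood with Satterthwaite degrees of freedom; the interaction
variant adds `stimulation × reactivity`, sensitivity variants add autism
likelihood, and the arousal-density model adds sleeping arrangement. The
reporting convention takes main effects from the base model and the
interaction from the interaction model. Standardized coefficients refit
the model with the outcome and continuous predictors z-scored, binary 0/1
predictors untouched; with an interaction present the *main effect* of a
crossed binary term legitimately changes under centring, so the
sign-agreement between scales is guaranteed (and tested) for the base
model. ON/OFF likelihood outcomes use the stimulus window as the 0/1
regressor within stimulation naps. Stage proportions are modelled long
(nap × stage) with a zero-inflated beta GLMM, logit link, N1 reference,
stage crossed with condition and reactivity, and a subject random
intercept, delegated to `glmmTMB`.

## The synthetic generator

`simulate_nap()` builds multichannel recordings whose background is
spectrally shaped Gaussian noise with power ∝ 1/f² above a 0.3-Hz knee,
scaled by stage-dependent amplitude (N3 > N2 > N1/REM > W, base 20 µV
wake RMS). The exponent of 2 matches the low-frequency-dominated spectrum
of NREM sleep: it puts most variance in the slow-wave band and about 1%
relative power in sigma, which is what makes the relative-power feature
discriminative on real sleep EEG; a shallower slope would park the
background at the detection threshold. The knee keeps the calibration from
being absorbed by sub-band drift that the 0.2-Hz high-pass removes anyway.
Spindles are raised-cosine-windowed 11–15 Hz bursts of 0.6–2 s planted in
N2 at 3/min; their peak amplitude is `SNR ×` the broadband background RMS
of the stage (SNR 3 by default), with 0.7–1.3× per-event jitter so the
planted population spans easy and hard events. Slow waves are
half-sine pairs satisfying the printed amplitude criteria; evoked
K-complexes follow S1 tones that fall in N2 with probability
`p_evoked = 0.3` and a negative-peak latency drawn truncated-normal
(0.55, 0.04) on [0.45, 0.70] s, so the enrichment window is reproducible
by construction. Hypnograms come from a stage-transition chain with short
sleep-onset latency; arousals (≥ 3 s), 1-s artifact windows, paired-tone
trains, and a cohort layer (shared per-subject reactivity calibrated to
the 1.1–2.8 composite range, counterbalanced condition order, planted
fixed effects with subject random intercepts, questionnaire items with
elevated "not applicable" rates on three age-inappropriate items) complete
the picture.

What the generator does *not* emulate: ultradian cycle dynamics, infraslow
spindle-density fluctuations, topographic gradients (planted events are
identical across channels up to amplitude jitter), volume conduction, or
realistic infant spectra beyond band-power ordering. Passing tests
therefore demonstrate that the pipeline recovers what it is defined to
recover under controlled conditions — not that detector performance
transfers to clinical recordings.

## Problem sizes and numerics

The test suite runs on scaled-down problem sizes chosen to keep the
feedback loop tight while leaving every estimator in its working regime:
3–10-minute naps at the native 500 Hz (60-s signals at 250 Hz for the
slow-wave oracle equivalence), 20 naps for spindle recovery, 50 naps for
the evoked-likelihood checks, cohorts of 35 subjects × 2 conditions with
200 replicates for interaction-recovery bias/coverage and 1000 for type-I
error. Detector evaluation against planted ground truth restricts to
events fully inside the eligible mask, which is the detector's domain by
definition. Degenerate inputs are handled explicitly: constant signals
yield zero power; zero-SD vectors Winsorize to themselves; all-NA
questionnaires, all-wake hypnograms, empty grids and missing annotations
raise typed errors; one-nap-per-subject designs collapse to OLS.

## Known limitations

The EDF writer targets the subset of EDF the pipeline needs (16-bit, 1-s
records, single sampling rate). The artifact detector is a stand-in with
matched 1-s granularity for the unpublished parameters of the original
chain. The zero-inflated beta model pins family, link, inflation and
random-effects structure but not a specific software parameterization.
F1-based tuning inherits the ambiguity of any-overlap matching when events
are dense; the minimum-overlap fraction is exposed for stricter regimes.
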