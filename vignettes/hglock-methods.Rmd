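---
title: "Separating stimulus-locked from behavior-locked high-gamma activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating stimulus-locked from behavior-locked high-gamma activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hglock)
```

## The problem

During an auditory target-detection task, a cortical recording site can
increase its high-gamma (70–150 Hz) activity for two quite different
reasons: because a stimulus just arrived (activity time-locked to stimulus
onset), or because the listener is about to act on it (activity time-locked
to the button press). Because reaction times vary from trial to trial, the
two components can be pulled apart by aligning the same trials two ways and
asking, at every recording site, where the significant activity lives.

`hglock` implements that analysis for event-related intracranial EEG
(iEEG/ECoG): single-trial high-gamma event-related band power (ERBP),
two-window site classification, regional prevalence and hemispheric
asymmetry statistics, power-versus-reaction-time correlations, and
region-level envelope summaries — together with a ground-truthed synthetic
generator so the full pipeline can be exercised and validated without
patient recordings.

## Signal model and ERBP

Recordings (microvolts, ~2 kHz) are downsampled to 1 kHz with a zero-phase
anti-aliasing FIR, bandpassed to 70–150 Hz with a 100th-order Hamming-window
FIR applied forward–backward (zero phase, so window timing is unbiased), and
converted to an amplitude envelope by the analytic-signal (Hilbert) method.
Event-related band power is log power normalized to a prestimulus baseline:

$$\mathrm{ERBP}(t) = 10\log_{10}\!\big(a(t)^2 + \varepsilon\big) - B,$$

where $a(t)$ is the envelope, $\varepsilon$ is a floor of $10^{-12}$ times
the maximal envelope power (so silent channels stay finite), and $B$ is the
mean of the same quantity over the 50–200 ms window before stimulus onset.
By default $B$ is computed per trial; a block-pooled variant is available
via `baseline_mode = "pooled"` because the convention is not uniquely
determined by "normalization to a prestimulus baseline". Press-aligned
matrices reuse the stimulus-aligned baselines of the same trials, since the
baseline window is defined relative to the stimulus.

The zero-phase filtering is realised in the frequency domain (the spectrum
is multiplied by the squared magnitude response of the FIR, the transfer
function of forward–backward filtering). This is numerically identical to
time-domain forward–backward filtering away from the block edges and an
order of magnitude faster on long blocks; epochs never touch the edges.

## Trial selection and artifact rejection

Only correct target (hit) trials enter the site analysis. Hits with
reaction time at or below 550 ms are excluded so the two analysis windows
cannot overlap (550 ≥ 300 + 250); the retained-hit rule is strict
(`rt > 550 ms`). A trial is discarded when any sample of its epoch deviates
from the within-block mean by more than 5 SD in raw voltage or more than
10 SD in band-filtered voltage. Artifact masks are computed in both
alignments and combined, so exactly the same trials enter the post-stimulus
and pre-response tests; epoch extents are −500..+2000 ms around stimulus
onset and −750..+500 ms around the press, wide enough to contain every
analysis window plus filter settling.

## Site classification

Per retained trial, ERBP is averaged over two 250 ms half-open windows:
post-stimulus (50–300 ms after onset, stimulus-aligned) and pre-response
(250–0 ms before the press, press-aligned). Each window's means are tested
against zero with a one-sample one-tailed t-test (H1: mean > 0), and the
site is labelled by the strict rule at α = 0.05:

* significant post-stimulus only → **stimulus-related**
* significant pre-response only → **behavior-related**
* both → **intermediate**
* neither → **none**

No site-level multiple-comparison correction is applied, deliberately: the
site census favours sensitivity, and the inferential corrections happen at
the regional level instead.

## Regional statistics

Prevalence (percent of sites with a pattern) is tabulated per hemisphere at
whole-brain, ROI-group, and ROI level over a fixed 51-region,
9-group auditory-centric parcellation (`roi_table()`). Hemispheric
differences are tested with two-sided Fisher exact tests; the sample
(cross-product) odds ratio with left-hemisphere odds in the numerator is
primary, and the conditional-MLE estimate with its exact 95% CI is reported
alongside because published odds ratios mix the two estimators.
Benjamini–Hochberg correction is applied across all ROI-group × pattern
tests as one family (24 tests for 8 groups); this family choice reproduces
the reference group-level adjusted p-values exactly, and a per-pattern
family is available as an option. Whole-brain comparisons are reported raw.

The stimulus/behavior balance of an ROI is summarised by the SB index
$(n_{behav} - n_{stim}) / (n_{behav} + n_{stim}) \in [-1, 1]$, computed
only for ROI × hemisphere cells with at least five sites of either
responsive pattern spanning at least two participants. A pooled-variance
two-sample t-test on MNI z-coordinates supports the sensorimotor coverage
check.

## Reaction-time correlation

For sites with significant post-stimulus activation (stimulus-related or
intermediate — behavior-only sites are excluded), the per-trial
post-stimulus window means are rank-correlated with reaction times
(Spearman, average ranks for ties). ROIs with at least 10 such sites are
tested for a nonzero median rho with two-tailed one-sample Wilcoxon
signed-rank tests (exact for n ≤ 25 without ties, normal approximation with
tie correction otherwise; zero rhos dropped, the signed-rank convention),
BH-corrected across tested ROIs.

## Envelope summaries

Region-level ERBP envelopes average each qualifying site across its
retained trials first and then across sites, with a pointwise across-site
95% t-interval. The stimulus-aligned display window is −100..300 ms; the
press-aligned window defaults to −400..+200 ms (a display convention — the
press-aligned extent is not pinned down by the analysis itself) and is
configurable.

## The synthetic generator

`simulation_config()` encodes the study conditions the analysis assumes:
~2 s Gaussian inter-stimulus intervals (SD 10 ms), 300 ms stimuli,
lognormal reaction times with median 819 ms (σ of log RT 0.25, truncated
below 400 ms), 8% misses, 3% false alarms, 1/f background noise at 2 kHz,
and sporadic 10 ms artifact pulses of 8–12 block SDs (2% of trials). Site
activity is injected as 70–150 Hz tone bursts (carrier drawn per trial from
85–135 Hz, random phase) with Gaussian amplitude envelopes of SD 60 ms,
centred 150 ms after stimulus onset for the stimulus component and 125 ms
before the press for the behavior component — both centres sit inside their
analysis windows, a generator convention since site-level latencies are
free parameters.

Burst peak amplitudes are calibrated so that the *measured* window-mean
ERBP matches the requested dB value: the expected log Rician power
$E[\ln(Y/b^2)] = \ln\lambda + E_1(\lambda) + \gamma$ (with $\lambda$ the
burst-to-noise envelope power ratio and $b^2$ the noise envelope power
through the exact analysis chain, measured once per configuration on a
reference realization of the same block length) is inverted numerically.
The residual bias from the filter's temporal smearing of the burst envelope
is below 0.25 dB at the default settings, within the generator's stated
0.5 dB contract. Per-trial amplitude multipliers are lognormal (σ = 0.35 in
log); the stimulus component's multiplier can be tied to reaction time
through a Gaussian copula, with the normal correlation chosen as
$2\sin(\pi\rho_S/6)$ so that the requested level is a Spearman correlation.

The default site plan places 20 sites per intended pattern in single ROIs
(stimulus → STGP with Spearman −0.3 amplitude–RT coupling, intermediate →
IFGop uncoupled, behavior → MFG, none → MTGM) across 3 participants and
both hemispheres, with 6 dB bursts. One 140-trial block with half targets
yields ≈60 retained hits per site, the regime the recovery analyses are
specified in; the clinical task reaches the same retained-hit count with a
smaller target fraction spread over two blocks, at twice the simulation
length.

What the generator does *not* emulate: acoustic or phonetic structure,
semantic novelty effects, spatially correlated noise across channels,
non-stationary epileptiform activity, or re-referencing artifacts. Passing
recovery tests therefore demonstrate the correctness of the pipeline's
arithmetic and inference on data that satisfy its assumptions — not
robustness to everything real recordings can do.

## Numerical and design choices

* **Windows** are half-open `[start, end)` in ms relative to the alignment
  event; event times are seconds from block start.
* **Strict boundaries**: `p < α` counts as significant; `rt > 550 ms` is
  retained (a reaction time of exactly 550 ms is excluded).
* **d′ clipping**: hit/false-alarm rates of 0 or 1 are clipped to
  `[1/(2N), 1 − 1/(2N)]` before the normal quantile.
* **Press attribution**: a press belongs to the most recent onset; a press
  after the next onset is kept with its attributed trial and logged. Fast
  hits are excluded later, not re-attributed.
* **Degenerate inputs**: zero-variance window means yield p = 0 or 1 with a
  warning; zero-margin Fisher tables report an undefined odds ratio and
  p = 1; an all-zero rho set reports p = 1.
* **No re-referencing** is applied: the montage beyond the recording
  reference is taken as given, and none is implemented.
* **Right-hemisphere x coordinates** are stored as-is; mirroring is purely
  a display concern.

## Problem sizes used by the test suite

The recovery study runs ten independent sessions (seeds 1–10) of the
default 80-site generator, about half a minute per session. Unit tests use
reduced sessions (1–2 sites per pattern, 40-trial blocks) and closed-form
fixtures; the envelope CI coverage check uses 400 replicates of 10
synthetic sites. The acceptance script touches no simulation at all — its
targets are exact arithmetic on published site counts.

## Known limitations

* The EDF dialect is a minimal continuous-EDF implementation (16-bit, one
  or 1 s data records) intended for interchange of synthetic and test data,
  not a general EDF(+) reader.
* ERBP assumes the 70–150 Hz band is analysed as a whole; no within-band
  spectral decomposition is provided.
* The classifier's "none" label inherits the two-test false-positive rate
  (≈ 1 − (1 − α)² ≈ 9.8% of unresponsive sites get an active label at the
  default α); this is a property of the published procedure, not a tunable
  of this implementation.
* Electrode localization and ROI assignment are inputs; the package never
  touches imaging data.
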