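---
title: "Detecting and tracking neuronal co-activation ensembles with cofire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking neuronal co-activation ensembles with cofire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofire)
```

## Scope

`cofire` analyses chronic multi-area extracellular recordings: it detects
neuronal ensembles (cell assemblies) from sorted spike trains, quantifies
when each ensemble is active and how its activation couples to hippocampal
sharp-wave ripples (SWRs), follows both across recording sessions spread
over weeks, and provides waveform-based metrics for deciding whether a
sorted unit recorded on different days is the same neuron. A seeded
synthetic-data generator with complete ground truth accompanies every
stage, so the whole pipeline is testable without any recording.

## The ensemble model

Spikes of each of $n$ neurons are counted in 25 ms bins — the time scale
at which co-activation is defined — and each neuron's counts are z-scored
over the concatenated sessions, giving $Z$ ($n \times N$, $N$ bins; rows
have mean 0 and variance 1, using the population s.d. so that the
correlation matrix below has an exactly unit diagonal). The correlation
matrix is

$$C = \frac{Z Z^{\mathsf T}}{N}.$$

For pure noise, the eigenvalues of $C$ stay (asymptotically) below the
Marcenko–Pastur upper edge $(1+\sqrt{q})^2$ with $q = n/N$; eigenvalues
above the edge indicate non-random co-activation, and their number $k$
estimates the number of ensembles. The activity is then projected onto the
top-$k$ eigenvectors, whitened, and unmixed with fastICA (deflation,
logcosh contrast, tolerance $10^{-6}$, at most 1000 iterations). Each
independent component is back-projected to neuron space, scaled to unit
norm, and sign-fixed so its largest-magnitude weight is positive. Because
deflation can stall in mixed fixed points when sources are weak, the whole
decomposition is repeated from `ica_restarts` (default 5) starting seeds
and the run with the largest total negentropy is kept; with a fixed seed
the result is deterministic. Membership is called with Otsu's method on
the absolute weights: a 256-level grid of candidate thresholds spans
$[0, \max|w|]$, the threshold maximizing the between-class variance is
selected (ties resolved to the plateau midpoint, so two well-separated
values yield a threshold strictly between them), and the high-weight class
are the members.

Two caveats matter in practice. First, the MP edge is asymptotic: at
$100 \times 10{,}000$ the largest noise eigenvalue exceeds the edge in
roughly 15% of realizations (by under about 1%), which is the expected
finite-size fluctuation; we deliberately apply no finite-size correction,
so very occasional single false components at threshold-grazing
eigenvalues are normal. Second, near the detectability limit the
independent component carries angular estimation noise spread over the
non-members, and Otsu's criterion is nearly flat around the member/noise
gap, so a borderline neuron can be included; member sets should be read
with that one-neuron resolution in mind.

## Activation strength and its threshold

For an ensemble with member weight vector $w$ (restricted to members and
re-normalized; a configuration flag switches to the all-neuron variant),
the per-bin activation strength is the quadratic form

$$A(t) = z(t)^{\mathsf T}\, P \, z(t), \qquad
  P = w w^{\mathsf T} - \operatorname{diag}(w^2),$$

i.e. the outer product with the diagonal zeroed, so a single neuron firing
alone contributes exactly nothing (the implementation computes both terms
from the same products so this cancellation is exact in floating point).
$A$ can be negative for anti-correlated members and is not clipped. An
ensemble counts as active where $A$ exceeds its mean plus
`activation_sd_multiplier` (default 2) times its s.d.; since "s.d. of
values above the baseline" is ambiguous, a `supra_baseline` mode that
takes the s.d. over supra-mean values only is also provided, with the
whole-trace mode as the documented default.

## Sharp-wave ripple detection and alignment

Ripple channels are band-passed 130–200 Hz with a zero-phase 4th-order
Butterworth filter (forward–backward, so peak timing is unbiased). The
normalized squared signal (NSS) is the z-scored, channel-averaged squared
band-passed signal, smoothed with a centered moving average of 11 frames
at 1250 Hz scaled to the sampling rate — the convention of the classic
NSS detectors; without smoothing, single noise cycles cross any practical
peak threshold. Detection: candidate intervals where NSS exceeds
`baseline_sd` (2) are merged when closer than `merge_gap` (30 ms), kept
when their NSS peak exceeds `peak_sd` (5) and their duration lies in
30–100 ms. The event peak is the supra-baseline power centroid of the
interval, which is symmetric and therefore immune to the smoothing window
beating against the ripple carrier. None of these thresholds is printed
in the source literature; they are the defaults of the widely used
detection scripts and are all configurable.

Alignment is two-step: events are first centered on their power peak; a
template is the mean band-passed window (±25 ms) over events, and each
event shifts to the lag maximizing its cross-correlation with the
template, clamped to ±`align_max_shift` samples (10 samples = 5 ms at
2 kHz, less than one period of a 200 Hz oscillation, so alignment cannot
jump ripple cycles). One refinement pass recomputes the template from the
aligned windows; the cumulative shift respects the clamp. On synthetic
ripples planted at 5 baseline s.d. the median aligned-center error is
about 0.1 ms.

## SWR tuning, lifetimes, and classification

SWR tuning is the peri-event average of $A$ over lags −20…+20 bins around
each ripple center, summarized as the peak within ±2 bins of lag zero
minus the mean over the −20…−10 flank. The window sizes are package
conventions; the flank subtraction makes the statistic zero for a flat
trace and robust to slow drifts.

A session counts as active when at least `min_active_bins` (default 5) of
its bins are supra-threshold. For realistic session lengths ($10^4$ bins
and more) chance co-firing alone crosses a mean + 2 s.d. threshold tens
to hundreds of times per session, so the count criterion is optionally
calibrated: `chance_crossing_rate()` circularly shifts each member's
z-scored row (preserving rates and autocorrelation, destroying
co-firing), measures the null supra-threshold rate at the real threshold,
and a session must then exceed the binomial $1-\alpha$ bound
($\alpha = 0.001$) of that rate for its bin count. The pipeline uses the
calibrated rule. Lifetime is the calendar span from first to last active
session; dormant sessions inside the span are reported but do not shorten
it, because ensembles can fall silent for days and re-emerge. Member
detectability is the longest consecutive-session span in which strictly
more than two-thirds of members have at least one spike, in days.

Ensembles are classified by two data-driven cutoffs, mean + s.d. of the
SWR tunings and of the lifetimes: `short_lived_high_tuning` above the
tuning cutoff and below the lifetime cutoff, `long_lived_low_tuning` the
converse, `other` otherwise. One structural property deserves emphasis:
in a balanced cohort (half the ensembles in each group) the mean + s.d.
cutoff necessarily lies at or above the high group's mean — at most 3 of
8 values can exceed mean + sample s.d. — so the specific quadrant labels
can only single out minorities of a skewed population, as they do in real
data. On balanced synthetic cohorts the package therefore reports, besides
the labels, whether the groups separate in rank on both axes; in our
dichotomy simulations they separate perfectly (coupled ensembles: tunings
≈ 3–5, lifetimes 7 days; uncoupled: tunings ≤ 0.4, lifetimes 30 days).

## Unit-tracking metrics

Quality metrics per sorted unit: SNR (peak absolute mean-waveform
amplitude at the center contact over that contact's RMS noise),
percentage of inter-spike intervals under 2 ms (units above 2% are
flagged), and the nearest-neighbor Mahalanobis distance in a per-contact
PCA space (3 components per contact; neighbors are clusters whose center
contact lies within ±3 contacts; the neighbor cloud's covariance is used,
ridge-regularized with $10^{-6}$ of its mean diagonal since the source
method does not state a covariance choice).

Cross-session identity uses two pair metrics on (unit, time-block)
clusters: the Pearson correlation of flattened mean waveforms,
$R_{ij} = C_{ij}/\sqrt{C_{ii} C_{jj}}$, and the standardized mean
difference of PCA features,

$$\mathrm{SMD}_{kl} = \sqrt{\sum_d
  \left(\frac{m_{k,d} - m_{l,d}}{2\sqrt{\sigma_{k,d} + \sigma_{l,d}}}\right)^2},$$

with per-dimension means and variances across spikes. Dimensions with
zero pooled variance and zero mean difference contribute zero (so
identical noiseless clusters give SMD = 0 exactly); a mean difference
with zero spread is an error. Pairs are partitioned into same-unit
(same unit, different blocks), neighboring-different-unit (different
units within ±3 contacts) and different-unit (the rest); note the
"different" categories are disjoint here, so the union of the two
recovers the conventional all-different grouping. Per-category
medians/IQRs and Wilcoxon rank-sum comparisons are reported. All PCA
features for these comparisons share one per-contact basis fitted on the
pooled spikes, otherwise SMD between clusters would be meaningless.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth:

* **Spike trains** — homogeneous Poisson background per unit (default
  5 Hz over six cortical/hippocampal area labels); each planted ensemble
  activates at Poisson events snapped to bin centers, so a planted
  co-activation always falls inside one 25 ms bin (with member spike
  jitter s.d. below half a bin, straddling is impossible by
  construction — this is the ground truth the detector is meant to
  recover); each member then emits one extra spike with probability
  `p_participate`. SWR-coupled ensembles instead activate at planted
  ripple centers, each taken with probability `event_rate/swr_rate` and
  jittered (default 10 ms), which preserves the configured event rate.
  Dropout is all-or-none per unit per session, mirroring the binary
  detectability notion of the >2/3 rule. Defaults (60 units, 3 ensembles
  of 8 members, 0.1 Hz events, 80% participation, one 20-minute session)
  are the recovery conditions exercised by the test suite.
* **LFP** — 8 laminar channels of 1/f-shaped noise at 2 kHz; each planted
  SWR adds a Gaussian-enveloped 180 Hz ripple (10 ms envelope s.d.) on
  the pyramidal channels, a negative sharp-wave deflection on radiatum
  channels and a positive one on oriens channels, with amplitude in units
  of the baseline s.d. 180 Hz sits inside the 130–200 Hz band away from
  its edges.
* **Waveforms** — per unit, a biphasic temporal template with Gaussian
  spatial decay across contacts (64 contacts × 41 samples by default),
  distinct center contacts across units; per block the template drifts
  multiplicatively (random walk, default 2% s.d. per block) and
  individual spikes add Gaussian noise at `peak_uv/snr`.

All generators draw from per-operation seed streams derived from one
seed, so adding a generator or a session never perturbs other outputs.
What the generator does **not** emulate: refractoriness and bursting,
theta modulation and place fields, electrode drift of spike *timing*,
correlated noise across contacts, and non-stationary firing rates.
Passing tests on this synthetic data therefore demonstrate the
correctness and calibration of the algorithms under their own model
assumptions, not performance on real recordings — the published
real-data values (e.g. same-unit waveform correlation 0.98, or median
ensemble lifetime 4 days versus 24 days of neuron trackability) come
from chronic recordings in behaving animals and are not reproduced here.

## Numerical and design choices

* Marcenko–Pastur bound: plain $(1+\sqrt q)^2$, no Tracy–Widom
  correction (see the calibration caveat above).
* Z-scoring and the correlation matrix are computed over the
  concatenated sessions, matching how multi-session excerpts are
  analysed; per-session z-scoring would erase slow cross-session rate
  changes that are part of the signal.
* Zero-variance (silent or constant-count) units are dropped with a
  warning rather than an error — expected under session dropout.
* ICA determinism: fixed seed, fixed restart schedule, deterministic
  pattern order (descending largest absolute weight).
* Otsu on a 256-level threshold grid with class statistics from the raw
  values; an exhaustive brute-force maximization is kept as an oracle in
  the test suite to guard the discretization.
* Undefined quantities (tuning without ripples, lifetime without active
  sessions, ISI rate under 2 spikes) propagate as `NA` sentinels and are
  excluded from summaries, never silently zeroed.
* Problem sizes in the tests (20-minute single sessions for recovery,
  100 s of LFP with 50 ripples, 10-session cohorts of 400 s sessions,
  10 tracked units × 6 blocks) were chosen so each check completes in
  seconds to a few minutes on one CPU while leaving the planted effects
  far from the margins of detectability.

## Known limitations

* Assemblies are assumed synchronous within one bin; time-lagged or
  sequence patterns are out of scope.
* The MP + ICA count is a global statistic: two ensembles sharing most
  of a ripple stream can merge into one component (we decorrelate
  coupled ensembles in simulation through partial per-ripple
  participation and coupling jitter; real strongly co-activating
  assemblies would merge the same way).
* Near the detection limit, membership has one-neuron resolution (see
  the Otsu caveat).
* The SWR detector is threshold-based and expects a laminar channel
  layout; it is not a learned detector and inherits the usual
  sensitivity of NSS methods to broadband artifacts in the ripple band.
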