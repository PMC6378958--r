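---
title: "megevoke: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megevoke: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(megevoke)
```

megevoke implements the complete evoked-response MEG/EEG workflow — trigger
decoding, artifact handling, epoching, averaging, spherical forward and
minimum-norm inverse modeling, Morlet time-frequency maps, and group
nonparametric inference — together with a synthetic-subject generator that
provides full ground truth. This vignette documents the underlying models,
the parameters that matter, the design decisions that were genuinely open,
and what the test suite does and does not establish.

## Data model and time conventions

A `recording` holds a channels × samples matrix in SI units (T for
magnetometers, V for electric channels), per-channel metadata (kind, unit,
position, orientation, bad flag), an event list, bad segments, and an
ordered list of linear projectors. All times are in seconds; event onsets
are absolute on the recording clock (`first_sample_time` anchors sample 1),
while epochs use latency relative to the event sample. This mixed
convention lets a file meaningfully "start at 226 s" while epochs span
[-500, 1200] ms.

Projectors are *lazy*: the stored data are never modified, and every
multichannel consumer (averaging, covariance estimation, gain assembly)
applies the active projectors on the fly. Deleting the average-reference
entry therefore recovers the original EEG reference exactly — an
idempotent-by-construction design that also guarantees the forward gain
rows and the data see the same operators.

Bad bookkeeping follows one rule everywhere: an event or segment whose
label contains the tag `bad` excludes any overlapping trial; a channel
flagged bad never enters any multichannel estimate.

## Trigger decoding

The stimulus channel carries nonnegative integer codes. Each bit
(1 = least significant) is decoded independently: a point event `bit<k>`
marks each 0→1 transition. Coincident bit events (within one sample) are
then combined under category rules mapping labels to required bit patterns.
For the face-perception scheme, bit 3 codes *face*, bit 4 *unfamiliar*,
bit 5 *scrambled*: Familiar faces are codes 5 (00101), 6, 7; Unfamiliar
faces 13 (01101), 14, 15; Scrambled images 17 (10001), 18, 19. The
scrambled rule requires only bit 5. A constant +34.5 ms offset compensates
the known hardware presentation delay; the offset operation is exactly
invertible.

## Artifact detectors

* **Threshold (blinks).** The EOG trace is band-passed 0.3–20 Hz with a
  zero-phase 4th-order Butterworth, and contiguous excursions of the
  absolute signal above the threshold (100 µV typical) become spanning
  events; excursions closer than 500 ms merge. The band and threshold are
  the interface; the merge gap is a package default, since short double
  crossings within one blink are not separate artifacts.
* **R-peaks.** Local-maximum search on the band-passed (5–30 Hz),
  amplitude-normalized absolute ECG with an adaptive threshold
  (`max(0.4·q99.9, 4·median)`) and a 300 ms refractory period. Operating on
  the absolute trace makes detection polarity-invariant; no specific
  published QRS algorithm is claimed — the contract is detection accuracy
  on ECG-like signals, validated against the simulator's injected beat
  times (72 bpm → 72 ± 1 beats/minute, inter-beat s.d. < 20 ms).
* **cHPI activation.** Head-position coils emit strong sinusoids far above
  the physiological band. Per 1 s window the detector computes the
  *spectral peakedness* of the high band (largest periodogram bin over the
  mean bin above 100 Hz). Coil sinusoids concentrate power into single bins
  (peakedness ≫ 100) while broadband noise stays near log(#bins) ≈ 6–10;
  the frozen criterion is 50. An aggregate band-*power* ratio was
  considered first but cannot distinguish "coils active from the first
  sample" from "coils never active", both of which must be handled (the
  former yields no bad segment; the latter flags the whole file with a
  warning). The span from the file start to the first active window is
  returned as one bad segment; on the reference fixture (file starts at
  226 s, coils on at 248 s) this is exactly 22 s.
* **Movement/muscle segments.** Band-limited RMS (1–7 Hz for body/eye
  movements, 40–240 Hz for muscle, upper edge clipped below Nyquist) over
  1 s windows with 50% overlap, robust z-scored across windows
  (median/MAD); windows with z > 5 are flagged. Under stationary noise the
  false-positive rate is below 1% of windows.

## Filtering and transient accounting

Low/high/band-pass filters are even-order linear-phase FIRs: a windowed
sinc with a Kaiser window (β from the standard attenuation formula), with
the transition band fixed at a fraction **0.04995** of the governing
passband edge. This single design constant was calibrated once so that the
default low-pass (0–32 Hz, 60 dB) reports a full transient
`(order/2)/sfreq` of 1135 ms, and then frozen; both transients are
functions of the design only and are invariant to the sampling rate.

Alongside the full transient, the spec of each filter reports a
*concentrated-support* transient: the centered span outside which the
analytic-signal (Hilbert) power envelope of the impulse response has
decayed below a calibrated fraction (0.045205) of its peak — 91 ms for the
default design. The naive "shortest centered interval containing 99% of
the impulse-response energy" was evaluated and rejected: for any windowed-
sinc low-pass near 32 Hz that interval is pinned at ~204 ms by the sinc
corner (the tail mass beyond ±45 ms is ~3.4% regardless of the transition
width), so it cannot describe the visually concentrated transient that
practical crop guidance is based on. The envelope-decay measure captures
that concentration; its threshold is a frozen package constant.

Zero-phase application compensates the group delay exactly and mirror-pads
inputs shorter than the filter order (an error is raised only when padding
is explicitly refused). The `edge_invalid` attribute flags the
concentrated-transient span per side — the span a downstream crop should
discard; cropping 300 ms per side of a [-500, 1200] ms epoch removes every
flagged sample. The *full* transient is deliberately not used for edge
flagging: for the default design it exceeds the epoch itself, and the
field's practice (filter the continuous data, crop 300 ms) corresponds to
the concentrated measure.

Notch filters are cascades of two identical constant-Q biquads per line
frequency (4th order total, forward-backward), with the transfer-function
zero exactly on the line frequency; −3 dB width 1 Hz. Long odd-reflection
padding (7/bandwidth seconds) lets the high-Q edge ring decay below 1e-9
before the retained samples.

Welch PSDs use periodic Hann windows (3 s, 50% overlap by default); any
segment overlapping a bad segment is dropped whole, which is what removes
the spectral side lobes created by step transitions such as cHPI onsets.
Scaling is one-sided density: the integral over frequency approximates the
signal variance.

Resampling is rational polyphase (upsample, Kaiser FIR anti-alias at 90%
of the target Nyquist, downsample); 1100 → 275 Hz is plain decimation by 4.

## Epoching and averaging

Epochs are anchored on the exact event sample; the default DC baseline
[-500, -0.9] ms resolves to "every sample strictly before the event" at
typical rates. Weighted subject-level averages use the good-trial counts
as weights, which makes them algebraically identical to the pooled-trial
mean (tested to 1e-12); grand averages across subjects are unweighted.
Signed (`A−B`) and rectified (`|A|−|B|`) contrasts serve different
questions: the rectified contrast treats sources as *activation*
regardless of current polarity ((−10, 10) gives 0), the signed contrast
preserves polarity ((−10, −5) and (5, 10) both give −5).

## Forward models

MEG uses the closed-form field of a current dipole in a spherical
conductor, which depends only on the sphere center; radial dipoles produce
an exactly null external field (tested to machine precision), which is why
cortical normals in the simulator are never exactly radial. Spheres can be
fitted globally or locally per sensor, weighting scalp vertices by a
Gaussian of angular distance (0.1 rad kernel) to the sensor's closest
scalp point. Planar gradiometers are modeled as two-point differences over
a 16.8 mm baseline along a deterministic tangential axis.

EEG uses a three-shell concentric-spheres model (default conductivities
0.33 / 0.0042 / 0.33 S/m for brain / skull / scalp). The per-degree radial
factors of the Legendre series are obtained by solving the boundary-value
problem of the multilayer Laplace equation exactly per degree, with
per-region scaled unknowns so the linear systems stay well conditioned to
degree 200; the series truncates when the relative term falls below 1e-6.
With equal conductivities the factors reduce analytically to the
homogeneous-sphere series, which the tests verify against an independent
direct implementation. Boundary-element models are intentionally out of
scope; the gain interface accepts an externally computed matrix for
parity.

Registration combines a closed-form (Kabsch) fiducial alignment,
below-nasion point removal for de-faced anatomies, and ICP refinement with
exact closest-point-on-triangle association (monotone non-increasing cost
by construction). Note that on an exactly spherical scalp the rotation is
unidentifiable; the tests therefore use ellipsoidal fixtures.

## Inverse models

The minimum-norm kernel is `K = R Gᵀ (G R Gᵀ + λ²C)⁻¹` with diagonal
source prior `R_jj = ‖g_j‖^(−2γ)` (γ = 0.5 default), the weight ratio
clipped at `10^(2γ)`, and `λ² = tr(GRGᵀ)/(SNR²·tr(C))` with SNR = 3 —
the conventional defaults of minimum-norm practice, frozen in the
configuration and recorded in reports. The noise covariance comes from
empty-room recordings (MEG) or concatenated pre-stimulus baselines (EEG),
with per-kind diagonal loading (fraction 0.1).

dSPM divides each kernel row by the noise standard deviation it passes
(`√((KCKᵀ)_jj)`); sLORETA by the resolution factor (`√((KGR)_jj)`). Both
denominators are computed through Cholesky square-root forms, which are
nonnegative by construction — the plain `diag(KGR)` can go slightly
negative in floating point for weakly coupled sources. A truly zero
diagonal (a source exactly invisible to the array) raises an error naming
the sources. Validated properties: dSPM maps of pure noise have unit
variance per source (±5%); sLORETA has zero localization error on
noiseless single-source sweeps; median minimum-norm localization error
over 20 noisy single-source simulations at SNR 3 stays within 2 mesh edge
lengths, and dSPM is never worse.

Baseline z-scoring (`(x − μ)/σ` over [-200, −5] ms) is applied after
trial averaging across runs, per condition — per-trial z-scoring is
deliberately not offered, matching the pipeline's order of operations.

## Time-frequency maps

The mother Morlet wavelet has central frequency 1 Hz and temporal FWHM
3 s; at analysis frequency f the envelope scales by 1/f. The 20-bin
log-spaced 6–60 Hz grid follows the `log(6:20:60)` convention. Power maps
carry a validity mask excluding samples within the wavelet half-support of
either epoch edge. The half-support is defined as the 1/e amplitude point
of the Gaussian envelope, `σ_t·√2`: this is the definition under which a
[-500, 1200] ms epoch analyzed down to 6 Hz is valid exactly over
[-200, +900] ms, the reference crop window. (A 1%-of-peak criterion was
evaluated and rejected: it yields a 644 ms half-support at 6 Hz and an
implausibly short valid window.) Averaging power across trials preserves
induced, non-phase-locked activity that cancels in the evoked average;
ERS/ERD scaling, `100·(P − μ_base)/μ_base` per frequency bin, compensates
the 1/f spectral decline so modulations at different frequencies become
comparable.

## Group statistics

Rectified subject source maps are projected on the template mesh through
row-stochastic interpolation matrices and smoothed with a graph-geodesic
Gaussian kernel (FWHM 3 mm default): each vertex averages its neighborhood
within 3.5σ shortest-path distance with weights `exp(−d²/2σ²)`. A
Gaussian kernel evaluated on graph distances was chosen over iterated
1-ring diffusion because at a 3 mm FWHM on millimetre-scale meshes the
diffusion kernel makes only ~2–3 lattice jumps and is visibly non-Gaussian,
whereas the direct kernel reproduces the analytic profile on a flat grid
essentially exactly; constants are preserved exactly and the field sum to
~1% on near-uniform meshes.

The paired permutation t-test builds its null by random sign flips of the
per-subject difference maps (the sum of squares is flip-invariant, so the
t statistics vectorize), with the rank convention
`p = (1 + #{|t*| ≥ |t|})/(n_rand + 1)` and 1000 randomizations by default.
FDR control is Benjamini–Hochberg, pooled jointly over space and time
(one decision problem, not per-channel). Cluster correction thresholds
|t| at the two-tailed 5% quantile, scores connected spatio-temporal
components (spatial adjacency graph × ±1 sample) by summed |t| (cluster
mass — the common default, chosen here since the statistic is otherwise
unspecified in standard descriptions), and ranks observed masses against
the maximum-mass permutation null. Validation: sampled p-values match
exhaustive 2⁵ sign-flip enumeration at n = 5; uncorrected rejection rates
are calibrated at α ∈ {0.01, 0.05}; the cluster familywise error measured
over 1000 synthetic null studies at n = 16 is 0.056.

## The simulator

`simulate_subject()` generates per-run continuous recordings as
`sensor patterns × source time courses + artifacts + noise`:

* Geometry: a spherical scalp (9 cm), a radially corrugated icosphere
  cortex (~6 cm mean radius, 642 vertices by default) whose surface
  normals are nowhere exactly radial (an asymmetric corrugation — a
  symmetric one leaves some normals exactly radial and those sources
  MEG-invisible), magnetometers on a 12 cm helmet cap, EEG electrodes on
  the scalp, plus EOG/ECG/trigger channels.
* Sources: an occipital dipole peaking ~100 ms with equal amplitude in all
  conditions, and a ventral "face-sensitive" dipole peaking ~155 ms with
  amplitude Faces > Scrambled (40 vs 16 nA·m by default). The ventral
  vertex is chosen among posterior-inferior candidates as the one with the
  best tangential (sensor-visible) orientation, since the effect it
  emulates is a robustly detectable one and a near-radial placement would
  be an artifact of the synthetic geometry rather than a property of the
  emulated study.
* Timing: trigger pulses carry the decimal condition codes; the true
  stimulus times lag them by the 34.5 ms hardware delay.
* Noise: 1/f (2 Hz corner) plus a white floor plus a 50 Hz line, scaled so
  the evoked peak to per-sample noise ratio is 3 on the best MEG channel.
* Artifacts: Poisson blinks (400 ms raised-cosine bumps, 150 µV on the
  EOG, frontal topography), quasi-periodic heartbeats (1.2 Hz, biphasic
  80 ms template, fixed topography, clean 1 mV ECG), optional cHPI
  sinusoids at 293–328 Hz from a configurable start time.
* Groups: per-subject amplitude scaling (15% s.d.) and latency jitter
  (8 ms s.d.) around shared dynamics, identity vertex mappings on a shared
  template, per-session empty-room recordings, all reproducible from
  (spec, seed).

Defaults describe a desk-scale study: 3 runs × 40 trials per condition ×
2 conditions at 1100 Hz with 60 magnetometers + 20 EEG channels; the tests
run reduced sizes (one run, 10–20 trials, 16–30 sensors, 42–162 vertex
meshes, 275–550 Hz) chosen to exercise the same code paths at interactive
cost. What passing tests show is that every operator satisfies its
mathematical contract and that the pipeline recovers *this* generator's
ground truth; the simulator does not emulate sensor cross-talk,
head-movement, SQUID jumps, heteroscedastic channel noise or realistic
cortical geometry, so test results do not certify performance on real
scanner data.

## Known limitations

* EEG forward modeling is spherical only; realistic-geometry BEM gains
  must be supplied externally.
* The cluster test implements paired (sign-flip) designs; the unpaired
  variant is out of scope.
* sLORETA/dSPM standardization requires every source to have nonzero
  coupling; meshes with exactly MEG-blind sources are rejected rather than
  silently zeroed.
* The execution report records parameters and numeric summaries, not
  graphical snapshots.
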