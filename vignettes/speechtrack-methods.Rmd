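---
title: "Models and methods behind speechtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speechtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling choices in `speechtrack`: the
linear systems view of speech tracking, what each tunable parameter
means and why its default is what it is, what the synthetic-data
generator does and does not emulate, and the numerical decisions a
maintainer would otherwise have to reverse-engineer from the code.

## The linear model

Both analyses treat low-frequency EEG as a linear time-invariant
response to features of the speech stimulus.

The **forward (encoding) model** for one feature `s(t)` and channel `c`
is

$$ r_c(t) = \sum_{\tau} w_c(\tau)\, s(t-\tau) + \varepsilon_c(t), $$

with lags $\tau$ spanning $-100$ to $500$ ms. A small acausal margin is
included deliberately: it gives the estimator room to show that nothing
precedes the stimulus, a useful diagnostic. The **backward (decoding)
model** inverts the direction, reconstructing $s(t)$ from all channels
jointly at lags $0..500$ ms; the **baseline decoder** uses $-100..0$ ms
instead. Under a causal response the pre-onset window carries no
stimulus information beyond what stimulus autocorrelation leaks into
it, so the baseline score is the honest floor against which a target
reconstruction score should be judged.

### Estimation

Weights are estimated per trial by ridge regression,

$$ \hat w = (X^\top X + \lambda m I)^{-1} X^\top y, $$

where `X` is the lagged design matrix (zero-padded at the edges, no
trial truncation) and `m` is the mean diagonal of $X^\top X$ *of that
fit*. Scaling $\lambda$ by `m` makes the grid
$\lambda \in \{10^{-1},\dots,10^{6}\}$ meaningful regardless of the
data's units; the grid itself is the conventional eight-decade sweep.
The intercept is never penalized (fits are centered). When the design
has more columns than rows — always true for backward models, where
$p = \text{lags} \times \text{channels}$ — the numerically identical
kernel (dual) form $\hat w = X^\top (X X^\top + \lambda m I)^{-1} y$ is
used, which turns a $4000^3$ solve into a $T^3$ one.

Both feature and EEG are z-scored per trial before fitting, so weights
are in z-units; correlation-based quality measures are unaffected, and
recovery of a ground-truth kernel is assessed per channel (z-scoring
rescales each channel by a positive constant, which leaves per-channel
correlations intact — see `kernel_similarity()`, which additionally
weights channels by the true kernel's RMS, since a channel carrying no
kernel energy has nothing to recover).

### Cross-validation

$\lambda$ is chosen by leave-one-out across trials: at each candidate,
every trial is fitted separately, each held-out trial is predicted (or
its feature reconstructed) using the *average of all other trials'
weights*, and the mean held-out Pearson correlation — over channels and
trials for forward models, over trials for backward models — is the
selection criterion. Ties go to the larger $\lambda$ (prefer the
stronger prior when the data cannot distinguish). All reported
correlations are cross-validated; training correlations are never
reported. The final model is the average of the per-trial fits at the
selected $\lambda$.

## Preprocessing

The conditioning chain has a fixed, logged order: broadband band-limit
(zero-phase 1 Hz high-pass, 57 Hz low-pass) at the acquisition rate,
downsample to 256 Hz, epoch $-500..2500$ ms around stimulus onsets,
amplitude rejection, optional channel interpolation, zero-phase 1–15 Hz
order-5 Butterworth band-pass, downsample to 128 Hz. Filtering precedes
the final downsampling step so the band edges are defined at the higher
rate. Choices worth recording:

* All IIR filtering is Butterworth run forward–backward
  (`signal::filtfilt`), so group delay is zero; "order" refers to the
  design order per pass. The broadband stages use order 2 (high-pass)
  and order 4 (low-pass): at a 2048 Hz rate the 1 Hz corner sits at a
  normalized frequency of 0.001, where higher-order IIR designs become
  numerically fragile under double precision, and order 2 already
  attenuates 0.1 Hz drift by more than 20 dB per pass.
* Resampling is a hand-written zero-phase FIR polyphase stage
  (windowed-sinc anti-alias filter, rational ratios only). The `signal`
  package's resampler showed ~8% passband ripple, which would violate
  the 2% amplitude-preservation contract the tests enforce.
* Amplitude rejection drops a trial when any channel *exceeds* 200 uV —
  a strict inequality, so a sample exactly at threshold survives. The
  rejection log always satisfies kept + dropped = input.
* Bad channels are supplied explicitly; a robust log-variance detector
  (`detect_bad_channels()`, |z| > 3.5) exists but is off by default,
  because automated detection thresholds are dataset-dependent.
  Interpolation is inverse-distance weighting on the 2-D sensor layout;
  it refuses to run when more than 25% of channels are bad.
* Component-based artifact removal is a pass-through hook
  (`remove_artifacts()`): no defensible automatic selection criterion is
  built in, and the synthetic cohorts contain no ocular artifacts. The
  skip is logged.

## Speech features

* **Envelope**: magnitude of the FFT-based analytic signal, then a
  zero-phase order-5 15 Hz low-pass, then resampling to 128 Hz. The
  envelope is decimated to 512 Hz *before* the 15 Hz filter: a 15 Hz
  IIR corner at 8 kHz (normalized 0.004) is numerically fragile, and
  both stages are zero-phase so timing is unchanged. Tiny undershoot is
  clipped at zero.
* **Surprisal** is in bits (base-2 logs), the convention of the
  cohort-model literature; prefix frequencies come from the lexicon,
  the prefix resets at word boundaries, and the per-word surprisals sum
  exactly to $-\log_2$ of the word-form prefix probability (tested as
  an identity). An unseen prefix continuation errors by default;
  add-one smoothing over the lexicon's symbol inventory is available.
* **Semantic dissimilarity** is $1 - r$ between a word's vector and the
  mean vector of its preceding sentence context. The sentence-initial
  word has no context and emits no impulse — the alternatives
  (sentence-level mean, unit value) would inject an arbitrary constant.
  Out-of-vocabulary words are skipped and recorded by default. No
  content-word filter is applied.
* Onset-to-sample mapping is nearest-sample with half-up rounding; two
  onsets landing on one sample is an error (it would violate the
  generator's 40 ms spacing floor).

## The synthetic generator

`sim_config()` defaults describe the canonical passive-listening study
the package is aimed at: two groups of 20 subjects, 10 sentences of
1.8 s (SD 0.2), 50 presentations each, 64 channels analyzed at 128 Hz,
a 1.5x multiplicative gain on the envelope response kernel for the
non-native group, and pink-noise background at 0 dB SNR.

What it emulates, and how:

* **Stimuli** are multi-tone carriers (12 tones, 300–3100 Hz)
  amplitude-modulated by a stored parametric modulator (raised-cosine
  bumps at phoneme onsets over a low base), so envelope extraction can
  be checked against exact ground truth. Phoneme labels are drawn with
  probabilities proportional to the inventory's utterance counts;
  onsets keep a 40 ms floor (natural articulation-rate scale, and it
  keeps epochs resolvable); words are contiguous groups of 2–5
  phonemes.
* **Response kernels** are multiphasic P1–N1–P2-style time courses
  (for the envelope: peaks near 50/120/220 ms) projected on a smooth
  amplitude topography with a smooth ±25 ms latency gradient across
  channels. The early sharp component and the latency gradient are
  deliberate: both are physiologically routine, and together they make
  the kernel invertible inside a causal 0–500 ms decoder window, so the
  noiseless decoder sanity property (reconstruction r ≥ 0.95) is
  achievable. A kernel made only of slow, channel-identical components
  spans a low-dimensional lag subspace that no decoder window can
  invert — a property of the simulation, not of the estimator.
* **Noise** is 1/f ("pink") per channel, mixed through a random
  orthonormal channel map, with expected unit power shaped analytically
  so realized trial SNR fluctuates naturally around the target. The
  SNR is defined against the *unit-gain* reference response: the noise
  floor is shared across groups, so the group gain raises signal above
  a common background. (Scaling noise to each group's own signal would
  make the two groups' trials exact scalar multiples of each other and
  erase the very group difference the generator exists to produce; at
  infinite SNR the scalar-multiple relation still holds exactly and is
  tested there.)
* **Group structure**: the only group difference is the envelope-kernel
  gain, mirroring the finding the package is designed to probe — that
  envelope tracking, not linguistic-feature tracking, separates groups.
  Noise draws depend on subject, sentence and trial but never on group,
  so matched seeds isolate the gain.

What it does **not** emulate: realistic acoustic phonetics, ocular or
muscle artifacts, head-volume conduction (the channel mixing is
orthonormal, not a leadfield), between-subject kernel variability, or
attention and proficiency effects. Passing recovery tests therefore
shows the estimators are correct and well-conditioned under the stated
model — not that real cohorts will behave this cleanly: real
between-subject variance will lower power relative to the simulated
cohorts, where subjects differ only in noise.

## Phoneme-related potentials

Channels are z-normalized over the concatenation of all of a subject's
trials (whole-recording statistics, not per-epoch), then epoched
$-50..500$ ms around each onset. No baseline subtraction is applied by
default — the whole-channel normalization is the only normalization in
the canonical procedure — but a pre-onset baseline-correction flag
exists. Category and grand averages are *epoch-weighted* (every epoch
counts equally, so frequent phonemes weigh more); a phoneme-weighted
variant is exposed via `weighting = "phoneme"` since the convention is
genuinely ambiguous. Overlapping epochs from adjacent phonemes are all
retained, as in natural-speech analysis. The bookkeeping identity
(grand average computed via categories equals the direct epoch-weighted
average) is tested exactly.

## Statistics

* Two-sample comparisons use Student's pooled-variance t (not Welch):
  with 20 + 20 subjects this gives the canonical 38 degrees of freedom.
  Zero-pooled-variance points get t = 0, p = 1 with a warning rather
  than NaN.
* FDR families: all channels x time points jointly for TRF weights; all
  time points for channel-averaged PRPs. `fdr_bh()` delegates to
  `stats::p.adjust(method = "BH")`; the brute-force step-up enumeration
  lives in the tests as an independent oracle.
* A time point is "significant" for interval-finding when at least one
  channel survives FDR; maximal runs are reported longest-first with
  the number of distinct channels significant anywhere in the run —
  chosen because interval extents and channel counts are conventionally
  reported separately.
* Permutation tests shuffle group labels (default 5000 iterations) and
  use the add-one correction $p = (1 + \#\{|s| \ge |obs|\})/(n+1)$, so
  p is never exactly zero. Two-sided by default; one-sided alternatives
  are a flag, as the sidedness convention differs between reports.
  Dominance stores both signed means and mean magnitudes, and flags
  ties, since "higher amplitude" is ambiguous between the two readings.
* N1/P2/N2 search windows default to 50–150, 120–280 and 220–400 ms —
  standard auditory evoked-response nomenclature — and are arguments,
  not constants. A window containing no sample of the expected polarity
  yields a peak flagged missing rather than a sign-violating extremum.

## Problem sizes used by tests and the acceptance script

Simulation sizes were chosen once, as the package's own working scale,
so the full suite runs comfortably on a laptop core: forward-TRF kernel
recovery runs at the full canonical scale (64 channels, 10 sentences x
50 trials, 0 dB); decoder-vs-baseline uses ten single-subject cohorts
(3 sentences x 6 trials, 16 channels) spanning noiseless to 0 dB; the
group-difference suite keeps the full 20 + 20 subjects and the 1.5
envelope gain but reduces each subject to 2 sentences x 5 trials on 8
channels with 1000 permutation iterations, and pairs it with 200
statistics-level null comparisons; PRP recovery uses sparse-phoneme
cohorts (minimum gap 0.5 s) because exact kernel recovery presumes
non-overlapping epochs — at natural spacing, deterministic overlap from
neighboring phonemes, not estimator error, bounds the attainable
correlation.

## Known limitations

* Each feature's model is fitted separately; joint multi-feature
  (banded) TRFs and nonlinear encoders are out of scope.
* EDF/BDF and WAV ingestion are not implemented; recordings enter as
  in-memory arrays or via the package's own container round-trip, and
  annotations via the TextGrid subset the writer emits.
* Channel interpolation is inverse-distance on a 2-D layout, not a
  spherical spline on measured 3-D electrode positions.
* The permutation statistic is the mean difference; studentized or
  cluster-based variants are not provided.
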