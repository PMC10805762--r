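---
title: "Methods: models, parameters, and design choices in phonorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in phonorf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When English /t/ or /d/ occurs between a stressed and an unstressed
vowel, both are pronounced as a coronal tap: two abstract phonemic
categories collapse onto one acoustic surface form. A recording site
whose evoked responses group the two kinds of taps together (apart from
a plainly articulated [t]) is tracking *surface acoustics*; a site
whose responses group tap-/t/ with [t] — i.e., with its abstract
category — and apart from tap-/d/ is tracking *underlying phonemic
identity*, which cannot be read off the sound alone. phonorf implements
the full analysis chain needed to find and validate such sites in
multichannel intracranial recordings, together with encoding models
that quantify how much phone-label information adds to spectrographic
information, and second-order receptive-field models that locate that
contribution in the stimulus covariance. Because the real recordings
are large and access-controlled, the package ships a synthetic-data
generator with planted ground truth; every stage is exercised and
scored against that truth.

# The synthetic-data generator

`make_inventory()` builds a phone inventory that always contains the
neutralization structure: phones `dxT` and `dxD` share the surface
class "tap" (one spectral prototype) while belonging to underlying
categories /t/ and /d/; phone `T` shares /t/ with `dxT` but has its own
surface form. Every surface class gets a spectral prototype — 16
nonnegative weights over the analysis spectrogram's frequency rows,
a smooth bump at a class-specific center plus a small jittered
baseline, so prototypes are pairwise distinct. A silence phone with a
near-zero prototype is always present so inter-token gaps carry an
explicit label (the responsiveness test needs silent epochs).

`synthesize_excerpt()` concatenates phone tokens: white noise shaped in
the FFT domain by the token's surface prototype (the 16 bands tile
0–8 kHz in 500 Hz steps, matching the spectrogram's frequency
resolution), with 10 ms raised-cosine ramps and 20–80 ms silent gaps.
Token durations are uniform on 50–250 ms — the underlying corpus
documents excerpt lengths but not token-duration distributions, so this
range was fixed once as typical of conversational phone durations.
Under the "foreign" tag, acoustics are generated from a permuted
phone-to-surface mapping (at least half the phones displaced), so
labels no longer predict acoustics under the native grammar while the
acoustics themselves are statistically unchanged — mirroring the logic
that an unfamiliar language's labels should not help a listener's
encoding model even though its sounds still drive auditory responses.

`plant_ensemble()` simulates channels through the same logistic
response law the receptive-field models assume: response =
logistic(a + h·s + s'Js) + Gaussian noise, clipped to [0, 1]. Surface
channels are driven by the indicator "current phone's surface class is
tap"; underlying channels by "current phone's underlying category is
/d/" (so tap-/d/ and [d] separate from tap-/t/ and [t]); acoustic
channels by "any non-silence"; null channels by nothing. Defaults
(offset −1, gain 2, noise SD 0.15) put the selective contrast at
roughly logistic(1) − logistic(−1) ≈ 0.46 response units against 0.15
noise — a strong but not degenerate effect, fixed once as the planted
condition for all recovery experiments. `ensemble_to_lfp()` turns
bin-rate responses into a voltage-like signal by using the response as
the amplitude envelope of broadband carrier noise; this places the
planted signal in band power (what the analyses measure) rather than in
a DC offset the 0.1 Hz high-pass would remove.

What the generator does *not* emulate: formant structure,
coarticulation, token-to-token acoustic variability within a surface
class, 1/f spectral structure of field potentials, or spatial
correlation between channels. Passing recovery tests therefore show
that the statistical machinery is correct and calibrated under its own
assumptions — not that real cortical data will be as compliant.

# Preprocessing

`preprocess_lfp()` follows the standard intracranial front end: common
average reference, notch filters at 60 and 120 Hz (zero-phase
order-2 Butterworth band-stops, ±2 Hz; harmonics above the 170 Hz
low-pass corner are unnecessary), band-pass 0.1–170 Hz, and resampling
to three times the low-pass corner (510 Hz). The band-pass is
implemented as a cascade of an order-2 high-pass and an order-4
low-pass: a single IIR band-pass whose lower corner sits at 1e-4 of
Nyquist is numerically ill-conditioned. Resampling is linear
interpolation onto the 510 Hz grid; the 170 Hz low-pass has already
removed everything that could alias.

`band_power()` uses the canonical band table (delta 1–3, theta 4–7,
alpha 8–12, beta 13–30, gamma 31–50, high-gamma 70–150 Hz; where a
source lists delta as 1–4 Hz elsewhere, the tabled 1–3 Hz is adopted).
Within a band, eight Gaussian filters with log-spaced center
frequencies are applied in the frequency domain; adjacent filters cross
at half power (the count and spacing are prescribed, the bandwidth rule
is this package's choice). The analytic amplitude of each sub-band is
the modulus of the analytic signal (negative frequencies zeroed,
positive doubled), and band power is the mean over the eight
amplitudes.

`epoch_and_zscore()` cuts −100…+500 ms epochs at token onsets and
z-scores each epoch against its own 100 ms pre-onset baseline; an epoch
with zero baseline SD is reported as an error with its token index
rather than silently propagated. `speech_responsive()` compares 500 ms
silent against speech epochs (equal counts, each baselined by its
preceding 100 ms) with a two-sample t-test in nine 100 ms windows with
50 ms overlap; a channel is responsive if any window has p below alpha.
"One-way t-test" is read as a two-sample unpaired test, since two epoch
populations are compared, and no multiple-window correction is applied —
the at-least-one-window criterion is deliberate, which also means the
family-wise false-positive rate under the null exceeds alpha (the suite
verifies the per-window rate is near alpha instead). Note that for
*sustained* responses the per-epoch baseline absorbs part of the
effect, so detection rates on the synthetic ensemble are conservative.

# Stimulus features

`compute_spectrogram()` resamples audio to 16 kHz and computes
consecutive 128-sample (8 ms) Hann-windowed DFT power spectra — 65
one-sided bins; the DC bin is dropped, the rest log-transformed
(log(x + 1e-10) guards silent frames) and pairwise-averaged twice in
frequency (64→32→16 rows) and three times in time, giving 64 ms bins at
15.625 Hz. The printed bin rate and the "32–33 samples per bin at
510 Hz" bookkeeping are treated as normative; the analysis frames are
laid on a non-overlapping 8 ms grid before time-averaging (a
half-overlapped frame grid would land at 31.25 Hz instead, which
contradicts the normative rate). Pairwise averaging drops a trailing
odd bin.

`chunk_context()` maps every bin from the sixteenth onward to the
16 × 16 chunk (1024 ms) ending at it; `truncate_recent()` keeps the
eight newest columns (512 ms, 128 features) for the mixed-model
designs; `flatten_chunks()` keeps all 256 for receptive-field models.
`align_response()` averages 510 Hz responses within each 64 ms bin.
`label_features()` averages one-hot phone labels onto the same grid, so
each bin's label vector holds time proportions summing to one.

`label_embed_chunks()` writes a 16-bit phone code into each chunk: the
8-bit code of the label occupying the plurality of the 1024 ms window,
concatenated with the runner-up's code (with itself for single-label
windows); plurality ties break toward the earlier onset within the
window. Zero bits become m − sd and one bits m + sd, where m and sd are
the chunk's pre-replacement mean and standard deviation, written over
the highest-frequency row — so at most 16 of 256 entries change, within
the chunk's existing dynamic range, leaving its variance and covariance
structure essentially intact. The code book itself is arbitrary in the
source material; here the vocabulary is sorted lexicographically and
label i gets the 8-bit binary representation of i — determinism
matters, the particular values do not.

# Site classification and its permutation null

`sliding_anova()` runs a one-way ANOVA over the three roles (anchor A,
cognate Bx, contrast By) on token values averaged within each of the
nine windows, with Tukey HSD pairwise tests computed only where the
window ANOVA is significant. A channel is a *surface* site if some
window has A≠Bx and A≠By significant with Bx≈By, and an *underlying*
site if some window has By≠Bx and By≠A significant with A≈Bx. The two
flags are deliberately independent. For speed over thousands of null
draws, the ANOVA and Tukey statistics are computed in closed form
(group sums of squares and `ptukey`), vectorized across channels; the
test suite checks this route against `aov()` + `TukeyHSD()` directly.
Whether the original window values were time-averaged for the ANOVA
exactly as for the t-test is not stated in the source; averaging is
assumed for consistency.

`permutation_null()` rebuilds the full analysis on arbitrary material:
each draw picks two phones (A, B), splits B's tokens arbitrarily into
Bx and By, classifies every channel, and records the (surface count,
underlying count) pair. Because the null runs on the same recorded
responses, spatially correlated activity is preserved in it. The
compressed description of the null's decision rule is expanded to the
same three-way template as the real comparison, so the null statistic
is exchangeable with the observed one. Token counts are not matched
between draws and the real comparison (the source is silent; draws use
all tokens of the chosen phones), and draws with too few tokens are
resampled. `joint_tail_probability()` is the plain proportion of draws
at least as extreme in both counts — no add-one smoothing — and
`in_null_region()` calls an observation inside the 95% region when that
proportion is at least 0.05.

# The mixed-effects encoding family

`build_designs()` produces seven fixed-effect designs: spectrographic
(s1, 128 columns), phone-label (p1, vocabulary-sized), both (s1p1), and
shuffle controls created by permuting rows within excerpts (s2, p2) or
across the session (s3, p3). `fit_lme()` fits each with channel and
speaker random intercepts via `lme4::lmer` under maximum likelihood —
not REML, because AICs are compared across different fixed-effect sets.
Random slopes are not used ("random effects" without further
specification is read as intercepts). The parameter count k is the
number of fitted fixed effects plus two variance components plus the
residual variance, matching `logLik`'s own bookkeeping; aliased columns
(the label block sums to one and is collinear with the intercept) are
removed by pivoted QR before fitting so k is well defined.
`rank_models()` computes ΔAIC, relative likelihoods
exp((AICmin − AICi)/2), and normalized Akaike weights.

`predict_and_correlate()` reconstructs the within-sample prediction
*conditioning on* the estimated random intercepts (per-channel
correlation traces require channel-specific predictions; whether the
original analysis conditioned is unstated, and this choice is flagged
here), then reports per-channel Pearson r, its Fisher Z (r clipped to
±(1 − 1e-6)), and a sliding-window r series. The correlation window is
500 ms with 50% overlap on the bin time base — unspecified in the
source, chosen to match the epoch analysis span.

One identifiability note that matters for model selection: with only a
handful of label columns, the superset model s1p1 can beat a
spectrogram-only generator's s1 by AIC chance (adding p unneeded
parameters wins when the likelihood-ratio statistic exceeds 2p, a ~5%
event for p ≈ 7). At a realistic conversational vocabulary (several
dozen labels) this probability is negligible, so the model-selection
experiments use a 59-phone inventory (~48 labels present), matching the
scale of real transcriptions.

# Maximum Noise Entropy receptive fields

`mne_model()` holds the logistic stimulus–response law
P(y|s) = 1/(1 + e^{−z(s)}), z(s) = a + h's + s'Js, with J symmetric;
order 1 drops the quadratic term. `fit_mne()` minimizes the mean
logistic log loss with a nonlinear conjugate-gradient optimizer and
analytic gradients, parameterizing only the upper triangle of J so the
returned kernel is exactly symmetric. The data are split into four
contiguous temporal batches (contiguity avoids leakage between train
and test through overlapping context chunks — the original fold
assignment is unstated); each jackknife trains on three and monitors
log loss on the fourth. An "epoch" for early stopping is defined as 20
CG iterations between test evaluations (the batch optimizer has no
natural epoch); training halts after ten consecutive non-improving
epochs, or when the training loss stops changing (relative improvement
below 1e-11, which is how noiseless recovery runs terminate), and the
weights at the best test loss are kept. Weights start at zero —
deterministic and unbiased. The four folds' weights are averaged into
the final model.

The continuous response must live on [0, 1] for the log loss;
`normalize_response()` scales each channel between its 1st and 99th
percentiles and clips, so isolated artifacts do not compress the scale.
This transform is a declared convention of this package — the source
never states how band power was mapped to the logistic target.

`decompose()` eigendecomposes J (eigenvalues ascending); the
eigenvectors are the receptive fields, `rf_fields()` reshapes the six
most negative / most positive into frequency × time images, and the
reported magnitude threshold marks the top 5% of eigenvalue magnitudes.
`shuffle_control()` permutes the entries of h (linear control) or
permutes the eigenvalues of J over fixed eigenvectors and recomposes
(quadratic control, with h permuted as well): the fields themselves and
the spectrum are preserved, only their weighting is randomized, a
deliberately strong chance benchmark. `fit_quality_meta()` fits the
five-member meta-family (baseline shuffle-only up to the
model × label interaction) and the six-member language family (up to
the full model × label × language crossing) on Fisher-Z fit-quality
records with subject and channel random intercepts;
`language_contrast()` is the three-member family for the encoding
models. Grouping factors with a single level are dropped from a
formula rather than fitted degenerately.

# Orchestration and problem sizes

`run_config()` / `run_pipeline()` chain synth → preprocess → features →
classify → encode → receptive fields from one root seed;
`derive_seed()` gives every stage a logged, deterministic sub-seed, and
the manifest records configuration, seeds, and MD5 digests of all
outputs, so identical configurations yield identical digests. The
"desk" preset bounds the feature dimension at 64 and the null at 200
draws.

The shipped experiments use desk-scale sizes chosen as the package's
own defaults: recovery fits at D = 16 with N = 50,000 bins
(noiseless), classification ensembles of 60 channels with 260-token
excerpts and 200-draw nulls, encoding experiments of ~300 bins × 6
channels with 20 seeds, and meta-model grids of a few thousand records.

# Known limitations

The synthetic acoustics are envelope-shaped noise; nothing here
validates performance under formant dynamics or coarticulation. The
permutation null inherits whatever spatial correlation the input has —
with independent synthetic channels it is narrower than it would be on
real arrays. Sustained planted responses interact with per-epoch
baselining, making the responsiveness test conservative on this
generator. The LME designs treat bins as exchangeable residuals
(no temporal autocorrelation model), as in the standard approach this
package follows. Analyses live at desk scale; the full-scale settings
(1000-draw nulls, D = 256 labeled chunks) are supported but not run by
default.
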