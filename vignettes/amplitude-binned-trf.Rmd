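---
title: "Amplitude-binned temporal response functions: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-binned temporal response functions: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A temporal response function (TRF) describes the EEG channel response $y(t)$
as a convolution of a stimulus feature $x(t)$ with an unknown kernel
$w(\tau)$ over a range of time lags $\tau$, plus noise:

$$y(t) = \sum_\tau w(\tau)\, x(t-\tau) + \varepsilon(t).$$

A univariate TRF driven by the acoustic envelope can only scale its response
linearly with envelope amplitude. Real auditory responses do more: as
intensity rises, response magnitude grows and latency shrinks, and the
waveform changes shape. The amplitude-binned (AB) envelope makes this
expressible within a linear model. The envelope, normalised to $[0,1]$, is
split into $B$ logarithmically spaced amplitude bins; sample $t$ activates
only the bin containing its amplitude, carrying the within-bin position as
its value. Fitting a multivariate TRF on this $B$-feature representation
gives each amplitude range its own kernel — magnitude, latency and
morphology are all free to vary across bins — while the model stays linear
in its parameters.

Estimation is ridge regression on the lagged design: weights minimise
$\lVert y - Xw\rVert^2 + \lambda s \lVert w \rVert^2$ per channel, where
$X$ holds all lagged copies of all features plus an unpenalised intercept.
The penalty scale $s$ is the mean diagonal of the penalised block of $X^TX$,
so a single $\lambda$ grid behaves comparably across representations with
very different numeric ranges (a one-column envelope versus an 8-column
binned coding); $\lambda$ is optimised per representation regardless, so
this scaling affects grid coverage, not the comparison.

## Stimulus representations

* **envelope** — modulus of the analytic (Hilbert) signal of the audio,
  decimated to 128 Hz with zero-phase anti-alias filtering.
* **SPL envelope** — $20\log_{10}$ of the envelope, clipped at a
  configurable floor (default $-80$ dB) because silence has no logarithm.
  The floor only matters for samples quieter than $10^{-4}$ of full scale.
* **onset / offset / derivative envelopes** — half-wave-rectified positive
  part, rectified negative part, and the raw first difference of the
  envelope. The plain first difference is used without a sampling-rate
  factor: any constant scale is absorbed by the TRF weights and the
  penalty's diagonal rescaling.
* **AB envelope** — bin edges are $10^{k\,w/20}$ for bin width $w$ dB
  (default 8 dB, $k = 1..B-1$), anchored below at 0, with the whole range
  rescaled to $[0,1]$. Anchoring at zero makes the edges a partition of the
  normalised amplitude axis: everything quieter than the first dB edge falls
  in bin 1. Membership is half-open $[\mathrm{lo}, \mathrm{hi})$ with the
  top bin closed. Within its bin a sample is mapped affinely onto $[0,1]$
  using the bin's own edges — a deterministic, data-independent and
  invertible choice (the alternative, normalising by each bin's observed
  min/max, depends on the corpus and cannot be inverted without it). The
  binned coding is therefore lossless: the affine inverse reproduces the
  normalised envelope to machine precision.
* **combined models** — feature-wise concatenation (AB + onset, AB + AB
  onset), sharing one intercept.

Default bin count is $B = 8$ (a 64 dB span): the bin width is the
empirically motivated 8 dB, and 8 bins cover the dynamic range of the
synthetic stimuli exactly. Before binning, envelopes are divided by the
corpus-wide maximum (not per trial), so one edge set applies to every trial.

## Evaluation

Model comparison uses nested leave-one-out cross-validation. With $M$
trials: each trial serves once as the outer test set; within the remaining
$M-1$, each serves once as validation. Per $\lambda$, single-trial models of
the $M-2$ training trials are averaged and scored on the validation trial by
per-channel Pearson correlation; $\lambda$ maximising validation accuracy
(averaged over inner folds and the analysis channel set) is then used to
score the average of all $M-1$ non-test models on the test trial. Averaging
single-trial models rather than refitting pooled regressions keeps each
trial's contribution identical and makes the procedure embarrassingly
cacheable: everything reduces to per-trial Gram matrices $X^TX$, $X^TY$ and
the response moments, from which every correlation in the CV is assembled
exactly (the test suite verifies equality with the literal
fit-average-predict-correlate loop to $10^{-8}$).

Analysis channels are the $n$ (default 7) best-predicted channels of the
*envelope* model, ties broken by channel index. This reuses the evaluation
data for selection — a circularity inherited from the procedure being
replicated; it is shared by all models being compared, so comparisons remain
paired, but absolute accuracies are optimistic. $\lambda$ selection averages
over this same channel set.

Chance level comes from permutation. For repeated-stimulus data the
envelope is circularly shifted by $k L/M$ samples ($k = 0..M-1$, the
original included), and each of 100 repetitions draws $M$ pool members with
replacement and reruns the entire nested CV; for distinct-stimulus data,
trial-envelope assignments are resampled with replacement. The null
threshold is the maximum over repetitions; a one-sample t test against the
null mean is reported alongside the stricter beats-the-maximum criterion.
Because the pool includes the unshifted envelope, a small fraction of null
trials is genuinely aligned; with $M = 20$ this biases the null mean by well
under 0.01 — visible in principle, negligible in practice at the default
trial counts.

Paired model comparisons report the two-sided paired t statistic, Cohen's
$d = t/\sqrt{n}$ (the paired-test effect size convention with $n$ subjects),
a Wilcoxon signed-rank fallback, and Anderson–Darling normality checks
(which require $n \ge 8$ and are reported as missing below that). AIC
comparisons use the Gaussian form $n\ln(\mathrm{RSS}/n) + 2k$ with $k$ the
total weight count (lags × features + intercept), computed on test-fold
residuals and averaged over folds and analysis channels.

## Peak analysis

Per amplitude bin, the N1 is the largest negative local peak at lags
70–210 ms and the P1 the largest positive local peak at 0–130 ms. A trace
with no local extremum of the right polarity in the window (flat or
monotone) returns the windowed global extremum with a flag rather than
failing — "largest negative peak" does not define behaviour there, and a
flagged fallback keeps batch analyses total. Exact ties resolve to the
earliest latency. The latency-vs-bin relationship is summarised by ordinary
least squares of latency on ascending bin index; the slope is also reported
as its negative ("ms per unit decrease in amplitude bin"), the form in which
the intensity-latency effect is usually quoted. Note that with 8 bins a
permutation of even strongly linear latencies retains $R^2 > 0.3$ in roughly
15% of shuffles — small-sample $R^2$ has a heavy null tail — so the package
assesses shuffle degradation against the observed $R^2$ rather than a fixed
cutoff.

## The synthetic generator

The generator exists so that every stage is testable against known ground
truth. It emulates the statistics of amplitude-modulated broadband noise
stimuli: discrete amplitude levels drawn log-uniformly over 64 dB (so each
8 dB bin receives roughly equal time), held for truncated-exponential
durations (mean 0.3 s, range 0.1–2 s, giving a right-skewed modulation
spectrum concentrated below a few hertz), joined by 80 ms raised-cosine
transitions in the dB domain. Holding the levels rather than splining
through them keeps the amplitude marginal at the drawn law. A speech-like
variant draws levels from a left-skewed law in dB
($-64 \cdot \mathrm{Beta}(2,5)$), concentrating time in the upper amplitude
bins.

EEG is generated forward through the same convolutional model the fitter
assumes: one biphasic kernel per bin (Gaussian P1 lobe at 45 ms, larger
Gaussian N1 lobe at 110 ms), with gain rising linearly (0.35 → 1) and
latency falling (11 ms per bin step) toward the loudest bin; kernel
positions are chosen so the most-shifted bin's peaks stay inside the
P1/N1 search windows (bin-1 N1 at 187 ms, P1 at 122 ms). The summed source
projects to channels through a smooth unimodal (fronto-central-like)
topography, and $1/f$ Gaussian noise is added at a broadband power SNR
(default 0 dB), then each channel is z-scored per trial as preprocessing
would. An optional additive pathway convolves an onset kernel with the
onset envelope, used to probe the combined-model comparisons. The default
conditions — 20 trials × 60 s at 128 Hz, 32 channels, repeated stimulus —
mirror a repeated-presentation AM-noise experiment at a size that runs on a
single CPU in minutes.

What passing tests on this generator do **not** show: the generator's
forward model is exactly the model class being fitted (plus noise), so
recovery there is a check of correctness and power, not of biological
validity; real EEG has non-Gaussian artifacts, session drift, volume
conduction with channel-correlated noise, and response components no
envelope representation captures. Model *rankings* on synthetic data show
the evaluation machinery can detect the built-in amplitude dependence at
realistic SNR, nothing more.

## Numerical choices

* Decimation uses zero-phase order-8 Chebyshev type I stages (0.05 dB
  ripple, cutoff 0.8× the target Nyquist, factors ≤ 10 per stage), the
  classic IIR decimator design; each stage's numerator is renormalised to
  unit DC gain, since the even-order Chebyshev ripple otherwise attenuates
  the passband by ~0.6% per pass, which forward-backward application and
  staging compound into a visible amplitude bias. Non-integer rate ratios
  (44.1 kHz → 128 Hz) finish with one anti-aliased cubic-spline resample
  onto the exact output grid; output length is
  $\lceil n \cdot f_{out}/f_{in} \rceil$.
* Zero-phase filtering pads with odd reflection at both ends before
  filtering to suppress edge transients (the high-pass pads by ~3 time
  constants of its cutoff).
* The lagged design zero-pads outside the trial (silence beyond the
  recording), matching the generative convolution, rather than trimming
  rows; predictions and accuracies are therefore reproducible functions of
  the trial alone.
* The ridge system is solved by Cholesky factorisation of the normal
  equations; a singular system at $\lambda = 0$ is reported as rank
  deficiency rather than silently regularised. Factors are shared across
  trials with identical designs (repeated-stimulus data, permutation
  pools).
* $\lambda$ ties during selection resolve to the smaller value; channel
  ranking ties resolve to the lower index.
* Zero-variance channels yield undefined correlations, reported as missing
  and excluded from averages.
* The default lag window is $-100$ to $400$ ms: it must contain the
  baseline interval ($-20$–$0$ ms), both peak search windows, and the
  longest synthetic kernel (~240 ms) with margin.
* All randomness funnels through explicit seeds; permutation repetitions
  draw per-repetition seeds from the master seed and record them.

## Problem sizes

The validation suite runs miniature versions of every analysis (3–8 trials
of 5–30 s) plus three study-scale computations chosen as the package's
reference conditions: noiseless identifiability on 5 × 30 s distinct-
stimulus trials; a 100-repetition permutation null and matched comparison
at the default 20 × 60 s preset; and parameter recovery (latency slope,
gain ordering, model ranking over 10 seeded replicates) at the same preset.

## Known limitations

* Bad-channel repair is neighbour-mean interpolation by channel index, not
  geometry-aware spline interpolation; the neighbourhood size is a knob
  because "surrounding channels" is montage-specific.
* Backward (decoding) models, banded or per-feature penalties, and
  spectrogram-resolved amplitude binning are out of scope.
* The exact lag window and $\lambda$ grid used in published analyses of
  this kind are rarely reported; the defaults here are reasoned choices,
  and both are configurable.
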