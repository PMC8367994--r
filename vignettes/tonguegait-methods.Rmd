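---
title: "Methods: tongue-gait kinematics from articulometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tongue-gait kinematics from articulometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguegait)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the numerical decisions
taken where the method description leaves room, and what the synthetic
cohort generator does and does not emulate.

## The measurement problem

Electromagnetic articulometry tracks small sensor coils glued to the
tongue tip (TT), tongue body (TB), tongue dorsum (TD), lower incisor (LI)
and lips (UL, LL) at 100 Hz in the midsagittal plane. The utterances of
interest contain double flap sequences — two rapid tongue-tip contacts
with the palate, as in *editor* — produced after reiterant-speech prompts
at 3–7 syllables per second. Two questions drive the analysis: does a
wider tongue-front displacement range buy a speaker a wider speech-rate
range, and does effort (measured as critical fluctuation of the movement
direction) concentrate early in the token (end-state comfort, a signature
of motor planning), in the middle, or late?

## Preprocessing

**Smoothing and gap restoration.** Sensor dropouts are common (wire
flexion, detachment). The smoother minimizes a penalized least-squares
criterion whose solution is diagonal in the DCT-II basis: transform,
shrink coefficient $k$ by $1/(1 + \lambda L_k^2)$ with
$L_k = -2 + 2\cos((k-1)\pi/n)$, and invert. Missing samples are restored
by fixed-point iteration on the weighted residual, so smoothing and
restoration are one operation. $\lambda$ defaults to `"auto"`: chosen per
coordinate by generalized cross-validation on the gap-filled series. The
smoother is linear at fixed $\lambda$, reproduces constants exactly
(including through gaps), and never alters the time base. Gaps longer than
`max_gap` samples (default 20, i.e. 200 ms) are refused rather than
invented. x and y are smoothed per coordinate; a joint bivariate penalty
would couple the axes through a single $\lambda$, which is undesirable
when one axis is much more active than the other.

**Occlusal alignment.** All analyses use a common coordinate frame: bite
plane at $y=0$, anterior positive $x$. The transform is estimated from
recorded bite-plane points (first point anterior) by principal-axis
rotation and vertical translation; only proper rotations are used, so a
head-reference point set is checked (not enforced) to lie above the
plane. A single per-session transform is applied; per-sample head-motion
correction is not modelled — a documented limitation, acceptable when the
head is stabilized during recording.

**Palate trace.** Per 1 mm bin of $x$, the maximum $y$ over tongue-sensor
samples after discarding samples more than 3 median absolute deviations
from the bin median — a robust, parameter-light outlier rule. Empty bins
are omitted, never interpolated.

## Time normalization

Each token is resampled at 31 landmark-anchored slice times: 11 spanning
first-vowel onset to the first flap's intensity minimum (both endpoints
included), then 10 completing uniform coverage to the second flap's
minimum, then 10 to the third-vowel end. This is the only reading of an
11/10/10 subdivision that yields exactly 31 points with all four landmarks
on the grid. Positions are interpolated at the slice times with a cubic
spline on the smoothed trajectory (linear fallback when a landmark segment
holds fewer than 5 raw samples); interpolating rather than taking nearest
raw samples keeps the result invariant to sampling phase up to curvature
terms of order $\Delta t^2$. Token duration is the v1-onset-to-v3-end
span.

## Displacement and displacement range

Per sensor path over the 31 slices, cumulative distance $D$ (mm, 30
steps) and cumulative unsigned turning angle $\Theta$ (rad, 29 angles,
each the smaller of the two possibilities and so at most $\pi$). Two
numerical conventions: a zero-length step makes the turning angle
undefined and contributes 0 (a stationary articulator adds no turning);
all z-scores use the sample ($n-1$) standard deviation so results are
reproducible bit for bit. Millimetres and radians are unrelated scales, so
each metric is z-scored over the entire dataset before they are summed;
the tongue-front sum $z(\Theta_{TT}) + z(D_{TT}) + z(\Theta_{TB}) +
z(D_{TB})$ is z-scored once more, giving the combined displacement $T$ in
standard-deviation units. Four sensor-set variants mirror the same
sum-then-z structure — tip, tongue front, whole tongue, whole vocal tract
— with the z-parameters refit per variant, since each variant defines its
own pooled population. The displacement range per participant and token
type is mean $T$ at the 3 syl/s prompt minus mean $T$ at 7 syl/s;
cells lacking tokens at either extreme rate are reported absent, never
imputed.

## The critical-fluctuation statistic

Fluctuation is computed on the *signed* turning angles
(counter-clockwise positive, range $(-\pi, \pi]$ and hence scale width
$s = 2\pi$), in sliding windows of $m = 7$ consecutive angles (stride 1:
29 angles yield 23 fluctuation time slices per token). Within a window,
points of return split the series into monotone periods; each period
contributes its absolute value change divided by its time extent, and the
sum is normalized by $s(m-1)$.

Two decisions needed care:

* **Plateaus.** A zero first difference continues the previous direction
  and creates no point of return; a leading plateau takes the direction of
  the first nonzero difference; an all-constant window is a single period
  (F = 0). This avoids spurious periods from flat spans.
* **Non-uniform window times.** Procrustean slices are uniform within a
  landmark segment but not across segment boundaries, so window times must
  enter the formula. Each window's times are mapped affinely so that the
  *smallest* inter-sample gap equals 1. On a uniform grid this reduces
  exactly to the classic integer-index formula, it is invariant to affine
  changes of the raw time axis, and it preserves the guarantee
  $0 \le F \le 1$ for any strictly increasing times: every period then has
  time extent at least 1 and value change at most $s$, and there are at
  most $m-1$ periods. (Normalizing the window *span* instead would allow
  mapped gaps below 1 and break the upper bound on clustered times.)
  The extremes are attained: a constant window gives $F = 0$ and maximal
  alternation between the scale bounds on a uniform grid gives $F = 1$.

TT and TB fluctuation series are averaged elementwise into the
tongue-front series used by the models.

## Statistical models

**Duration model.** `Duration ~ DisplacementRange * Rate +
(1 + DisplacementRange | Participant)`, REML, treatment coding with the
3 syl/s prompt as reference, Satterthwaite degrees of freedom.
Duration is modelled in seconds, untransformed. Rows default to cell means
per participant × token type × rate (token-level fitting is available via
`aggregate = "token"`). Marginal and conditional r² are computed by the
standard variance-partition approach: fixed-effect variance is the
variance of $X\hat\beta$; random-effect variance is the mean diagonal of
$Z G Z^\top$. A singular random-effects fit is recorded as a note rather
than an error — with few participants the random-slope variance often
estimates at the boundary. The four sensor-set variants are compared by
refitting with maximum likelihood and ranking information criteria; the
variants share one model structure, so AIC ordering equals log-likelihood
ordering.

**Fluctuation model.** `Fluctuation ~ te(FTS, TFd) +
s(FTS, TFd, Participant, bs = "fs", m = 1) + s(SPS, Participant, bs = "re")
+ s(TokenType, Participant, bs = "re")`, fitted with `mgcv::bam`
(fast REML). `TFd` is the tongue-front displacement range per
participant × token type, z-scaled across cells — the per-cell range, not
the per-token displacement, since the quantity of interest is a property
of the speaker–token-type combination. Consecutive windows of one token
overlap in 6 of 7 angles, so residuals are strongly autocorrelated; the
model is fitted twice, with the lag-1 residual autocorrelation of the
first pass supplied as the AR(1) parameter of the second
(`AR.start` marks each token's first window). Default basis dimensions are
`k_te = c(8, 5)` and `k_fs = 5`, sized for the validation cohorts used
here: the FTS margin needs enough resolution to separate early-, mid- and
late-token effort, and the TFd margin enough to represent three
displacement-range bands; both are exposed in the configuration and should
be raised for larger cohorts (exact reproduction of any particular basis
dimensioning is not promised).

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
truth without any recordings. It emulates, per speaker profile:

* a programmed tongue-front displacement range (`base_range`), spread
  evenly across speakers (default 0.5–3.5) and modulated ±15% across token
  types — flap-excursion amplitude grows at slower prompts in proportion
  to this range;
* a duration range that widens with `base_range`
  (`duration_range_slope`, default 0.14 s per unit), which programs the
  negative displacement-range × rate interaction on duration;
* a second, categorically different slow gait (an added path loop) for
  speakers above `gait_threshold = 2.4`, engaged below 5 syl/s. The loop
  is a path-topology change rather than amplitude scaling, and it sits
  mid-token, between the flaps, so it does not overwrite the programmed
  effort placement at the token edges;
* effort placement: a localized direction-reversal wiggle (≈6 cycles per
  token, i.e. 6–12 Hz — a physiological rate that survives smoothing
  without aliasing at the 31-slice resolution) whose envelope sits early
  in the token for end-state-comfort speakers (both range extremes) and
  over the second flap for mid-range speakers. The wiggle amplitude scales
  with excursion size, reflecting signal-dependent motor noise;
* sensor noise (Gaussian, 0.3 mm) and bounded missing runs
  (probability 0.05, up to 10 samples), matching common EMA error
  magnitudes.

Everything is a pure function of the seed. Paths are raised-cosine stroke
primitives — smooth, bandlimited, analytic — so noiseless output equals a
closed form that tests compare against directly.

What the generator does **not** emulate: realistic palate-contact
flattening of flap strokes, coarticulation across token types, acoustic
landmark measurement error (landmarks are emitted at construction),
per-sample head motion, and gait-transition hysteresis (the study design
could not observe transition speeds, so none is modelled). Passing
recovery tests therefore shows the pipeline recovers programmed structure
of this kind at realistic noise levels — not that any particular real
cohort will show the same effect sizes.

## Validation scales

The test suite validates at sizes chosen to exercise every code path while
keeping a full run in minutes: analytic bounds of F on $10^5$ randomized
windows; oracle equivalence on $10^3$ random series/paths (integer-grid
fluctuation transcription to $10^{-12}$; brute-force path metrics to
$10^{-9}$); 20 replicate cohorts of 6 participants × 4 token types × 5
rates × 4 blocks for duration-model recovery (all-negative interactions;
programmed-vs-recovered rank correlation); 10 replicates for
fluctuation-surface recovery (early-vs-late contrast sign by
displacement-range band, read from the fitted model). The full default
cohort (11 × 8 × 5 × 10 = 4400 tokens) runs end-to-end through the
command-line wrapper in a few minutes.

## Known limitations

* Landmark times are treated as absolute on the recording's time base;
  dialects storing phrase-relative times must be shifted before import.
* The per-session rigid alignment cannot correct within-trial head
  motion.
* The GCV-selected smoothing penalty is chosen per coordinate and per
  trajectory; heavily corrupted channels can keep too much noise, which
  inflates the turning-angle total — the displacement range is then noisier
  than the distance component alone.
* Interval-tier annotation import supports the long TextGrid format only;
  short-format files should be converted first.
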