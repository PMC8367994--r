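# tonguegait

Kinematic "gait" analysis for tongue movement during speech, from midsagittal
electromagnetic articulometry (EMA) recordings of double-flap utterances
(e.g. *editor*, *auditor*).

Speakers differ in how far and how fast they can move the tongue front when
asked to speak at prompted rates from 3 to 7 syllables per second. This
package implements the full analysis chain that quantifies those
differences and tests whether, like walking versus running, tongue movement
organizes into distinct *gaits*:

1. **Preprocessing** — discrete-cosine-transform penalized-least-squares
   smoothing of 100 Hz sensor trajectories, with missing-sample restoration
   in the same pass; rigid alignment to an idealized flat occlusal (bite)
   plane with the tongue tip facing forward (+x anterior, +y superior,
   bite plane at y = 0); palate-trace estimation from the highest tongue
   sensor positions.
2. **Time normalization** — each token is reduced to 31 landmark-anchored
   "Procrustean" time slices: 11 from first-vowel onset to the first flap's
   acoustic intensity minimum, 10 more to the second flap's minimum, 10
   more to the third-vowel end, so tokens at different speech rates are
   compared at the same relative timing.
3. **Displacement** — per sensor path, the cumulative distance
   `D = sum_{i=1}^{30} d_i` (mm) and cumulative unsigned turning angle
   `Theta = sum_{i=1}^{29} |theta_i|` (rad, each angle <= pi). Both are
   z-scored over the whole dataset, summed over the tongue-front sensors
   (tip TT and body TB), and z-scored again:
   `T = z( z(Theta_TT) + z(D_TT) + z(Theta_TB) + z(D_TB) )`.
   The **displacement range** per speaker and token type is the mean `T`
   at the 3 syl/s prompt minus the mean at 7 syl/s. Variants over four
   sensor sets (tip, tongue front, whole tongue, whole vocal tract) are
   computed for model comparison.
4. **Critical fluctuation** — over each token's 29 signed turning angles,
   a sliding 7-sample window yields the bounded fluctuation statistic

   ```
   F = [ sum over monotone periods |x_{n_{k+1}} - x_{n_k}| / (n_{k+1} - n_k) ] / (s (m - 1))
   ```

   with scale width `s = 2*pi`, window length `m = 7`, and window times
   normalized so the smallest inter-sample gap is 1 (integer grids reduce
   to the classic formula; `0 <= F <= 1` is guaranteed). TT and TB series
   are averaged into the tongue-front fluctuation. High `F` reads as
   greater articulatory effort/instability.
5. **Models** — a linear mixed model of token duration,
   `Duration ~ DisplacementRange * Rate + (1 + DisplacementRange | Participant)`
   (treatment coding, 3 syl/s reference), with marginal/conditional r²;
   an AIC comparison of the four sensor-set variants; and a generalized
   additive mixed model of fluctuation over the token time course,
   `Fluctuation ~ te(FTS, TFd) + s(FTS, TFd, Participant, bs="fs", m=1) +
   s(SPS, Participant, bs="re") + s(TokenType, Participant, bs="re")`,
   fitted twice with an AR(1) residual correction estimated from the first
   pass.
6. **Synthetic cohorts** — a deterministic generator builds full study-shaped
   cohorts (11 participants x 8 token types x 5 rates x 10 blocks) from
   raised-cosine stroke primitives, with programmed displacement ranges,
   duration ranges, two-gait slow-rate path changes, and effort placement
   (end-state comfort at the range extremes, mid-token effort in between),
   so every stage is testable against known ground truth.

## Worked example

```r
library(tonguegait)

cfg <- run_config(list(
  synthetic = list(enabled = TRUE, n_participants = 4,
                   n_token_types = 2, n_blocks = 2),
  seed = 7))
res <- run_pipeline(cfg, "readme_run", qc_plots = FALSE)
print(res$glmm)
```

```
Duration GLMM: Duration ~ DisplacementRange * Rate + (1 + DisplacementRange | Participant)
                        Estimate Std. Error      df  t value p value
(Intercept)               0.5582     0.0228 13.8024  24.5269  0.0000
DisplacementRange         0.1496     0.0112 19.4677  13.3711  0.0000
...
DisplacementRange:Rate7  -0.1614     0.0150 28.4869 -10.7288  0.0000
r2 (marginal) = 0.961, r2 (conditional) = 0.963
```

The positive `DisplacementRange` estimate says wide-range speakers speak
more slowly at the reference (3 syl/s) prompt; the negative
`DisplacementRange:Rate*` interactions say their durations also shrink
faster as the prompt speeds up — i.e. a wider tongue-front displacement
range buys a wider speech-rate range. The generator programmed exactly this
structure, and the recovery report confirms the pipeline gets it back:

```r
print(res$recovery)
```

```
<recovery_report>
  displacement range: rank correlation 0.952, sign agreement 1.00 (n = 8 cells)
  duration range: correlation 0.993
  effort placement: early>late in 100% of end-state-comfort cells, late>early in 100% of mid-token cells
```

```r
print(res$gamm)
```

```
Fluctuation GAMM: te(FTS, TFd) + fs/re participant smooths, AR(1) rho = 0.693
                            edf Ref.df      F p-value
te(FTS,TFd)              18.858 21.954 19.355   0.000
...
lag-1 residual acf: 0.693 (uncorrected) -> 0.129 (corrected)
```

The tensor smooth over fluctuation time slice (FTS) and scaled tongue-front
displacement range (TFd) is strongly supported, and the AR(1) second pass
removes most of the within-token residual autocorrelation. The output
directory holds every stage table as CSV with a hash manifest, the model
summaries, a JSON run record, and QC plots.

A thin command-line wrapper is installed at `inst/cli/tonguegait.R`:

```sh
Rscript inst/cli/tonguegait.R run-all --seed 5 --out out_dir
Rscript inst/cli/tonguegait.R simulate --seed 5 --out cohort_dir
```

## Methods

See the methods vignette (`vignettes/tonguegait-methods.Rmd`) for the
model details, parameter choices, numerical decisions, and the synthetic
generator's design and limitations.
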