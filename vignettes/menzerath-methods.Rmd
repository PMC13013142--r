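---
title: "Methods: mixed models, Monte-Carlo nulls, and boundary prosody for vocal sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed models, Monte-Carlo nulls, and boundary prosody for vocal sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menzerath)
```

## The scientific question

Menzerath's law predicts that the constituents of longer constructs tend to
be shorter: in vocal sequences, calls in sequences with more calls should be
shorter. The package operationalizes this as the sign and magnitude of a
log-log slope, estimated jointly with an ordinal-position effect, and asks
two further questions that a raw slope cannot answer: would the slope arise
by chance from the durations alone (Monte-Carlo nulls), and is the temporal
organization concentrated at sequence boundaries (first/last-call
correlations, final lengthening)?

## The model

The core estimator, `fit_menzerath()`, fits

$$\log(d_{ijk}) = \beta_0 + \beta_1 \log(n_j) + \beta_2\,\mathrm{pos}_{ijk}
  + u_j + v_k + w_{\mathrm{pos}} + \epsilon_{ijk}$$

with $d_{ijk}$ the duration (seconds) of the call at position
$\mathrm{pos}$ of sequence $j$ by individual $k$, and $n_j$ the sequence
size. The random intercepts are **crossed**, not nested: $u_j$ per sequence
(repeated measures within a sequence), $v_k$ per individual (bird,
recording, or participant), and $w$ per ordinal-position *category*.
Position therefore enters twice by design — once as a numeric fixed effect
(the trend $\beta_2$) and once as a categorical random intercept (absorbing
idiosyncratic associations of calls with particular positions). Menzerath's
law corresponds to $\beta_1 < 0$; final lengthening appears as $\beta_2 > 0$.

Model fitting is delegated to `lme4::lmer()`; the package's contribution is
the surrounding machinery, not a mixed-model solver.

Choices the model statement leaves open, and what this package does:

* **Log base.** Natural logarithms for both the response and the sequence
  size. The base only rescales $\beta_1$'s intercept-side interpretation;
  slope signs and t statistics are base-invariant for the log-log term.
* **REML vs ML.** REML by default (`reml = FALSE` gives ML). This affects
  variance components far more than the $\beta$s.
* **Degrees of freedom.** `df_method = "satterthwaite"` by default. This is
  not cosmetic: the position slope's sampling uncertainty is dominated by
  the position-category random intercept, which has only as many levels as
  there are distinct positions (4 in a 1–4 cue range). Its Satterthwaite df
  is ≈ 2, and intervals built on residual df (≈ n) undercover badly — in a
  50-replicate simulation at study scale, nominal-95% residual-df intervals
  for $\beta_2$ covered the generating value only ~82% of the time, while
  Satterthwaite intervals covered ≥ 94%. `df_method = "residual"` is kept
  for comparability with tools that apply no correction; the method used is
  recorded in the fitted object.
* **Singletons.** A sequence of one call contributes $\log 1 = 0$ to the
  size term and position 1; no special casing. Because singleton-driven
  compression is a known artefact in this literature, `include_singles =
  FALSE` refits after removing them, and the pipeline reports both.
* **Degenerate groupings.** A single individual (or a single position
  category) makes that variance inestimable; the term is dropped with a
  warning rather than silently absorbed.

Group comparisons (`fit_group_interaction()`) pool two tables under a
two-level factor (context or species), estimate
`group * log(size) + group * position`, and report the interaction
coefficients. Sequence and individual identifiers are namespaced per group
internally so random-effect levels never leak across datasets.

## Monte-Carlo null models

Negative size slopes can arise from chance or from duration bookkeeping
alone, so observed slopes are compared against two nulls, both refitting the
*identical* model specification per iteration:

* **Shuffle null** (`shuffle_null()`): durations are permuted among all
  calls of the same individual; the sequence scaffold (sizes, positions,
  ids) is untouched. This conserves each individual's duration multiset and
  destroys any duration–structure association, so its slope distribution
  centres on zero. Because the design matrices are unchanged,
  iterations use `lme4::refit()` on the permuted response — the standard
  fast path for permutation tests.
* **Production-constraint null** (`production_constraint_null()`): each real
  sequence is rebuilt by sampling durations *with replacement* from that
  individual's pooled duration distribution until the cumulative duration
  strictly exceeds the real sequence's total; if the overshoot exceeds half
  the last sampled call, the last call is removed. Pseudo-sequences match
  real sequences in total duration but are free to vary in call count, so a
  negative slope under this null means compression follows from
  duration-matching alone. "Exceeds" is strict, and a tie at exactly 50%
  overshoot keeps the call (removal requires *more than* half). Replacement
  sampling is used because pools must represent each individual's duration
  *distribution* and stay unchanged across sequences; pools are per
  individual, not per trial type. A pseudo-sequence can come out empty when
  a single oversized draw is removed by the 50% rule; such sequences are
  dropped and counted.

Empirical p-values are two-sided with the finite-sample correction
$(r+1)/(n+1)$, where $r$ counts null slopes at least as extreme in absolute
value; this keeps $p \ge 1/(n+1)$. The default 1000 iterations is a
configurable convention, not an estimate of anything.

## Boundary prosody

`first_last_correlation()` reduces each sequence to two points — first-call
duration and last-call duration against sequence size — and reports Pearson
r and p for each. Singletons count as both first and last by default (a
documented switch excludes them). Zero variance in either margin raises a
classed error rather than propagating NaN.

`final_lengthening_test()` follows the relative-duration procedure used for
phrase-final lengthening in music and birdsong: within each sequence of at
least two calls, durations are divided by the sequence mean (so relative
durations average to 1), and the relative final call is compared with the
mean relative non-final call by a paired t-test with sequences as the unit
of analysis (df = sequences − 1). Singletons are excluded because their
only call *is* the sequence mean, leaving no pair. If every paired
difference is exactly zero the result is reported as t = 0, p = 1 rather
than an error.

## Audio pre-screening and segmentation

Noisy field recordings defeat spectrogram-based segmenters, so recordings
are screened before segmentation with two dimensionless metrics and
conventional bioacoustics definitions (the thresholds are fixed by the
screening protocol; the windowing is not, so defaults are documented and
configurable):

* **Spectral flatness (Wiener entropy)**: per 512-sample Hann frame (50%
  overlap), geometric over arithmetic mean of the power spectrum, averaged
  over frames with nonzero energy. Near 1 for broadband noise, near 0 for
  tonal signals. Exclusion threshold 0.05.
* **Temporal entropy**: Shannon entropy of the distribution of energy over
  non-overlapping frames, normalized by log(number of frames). Exactly 1
  for temporally uniform power, 0 for a single active frame. Exclusion
  threshold 0.85.

Both metrics are invariant to amplitude scaling; an all-zero signal raises a
classed error rather than returning a number. A file passes the screen only
if both metrics are at or below their thresholds — note a clean constant
tone *fails* (temporal entropy 1) because the screen is looking for sharp
onset/offset structure, not signal purity.

`detect_calls()` is a deliberately simple amplitude-envelope detector for
clean laboratory recordings: Hilbert-magnitude envelope, 10 ms moving
average, noise floor at the 10th envelope percentile, threshold at 3× the
floor, merging of gaps under 30 ms, and a 20 ms minimum duration. On
synthetic tone bursts in low noise it recovers onset/offset boundaries to
within one 10 ms smoothing frame in ≥ 95% of seeded trials (the acceptance
suite measures this). These defaults suit sound-attenuated chamber
recordings; field recordings need the screen above plus manual review, and
no neural segmentation is attempted. WAV input uses a minimal 16-bit PCM
RIFF codec implemented in base R.

## The synthetic generator

`simulate_call_table()` is the exact generative inverse of the estimator:
Gaussian random intercepts on the log-duration scale, with the
position-category effects $w$ drawn once per position and shared across all
sequences (the crossed structure). That makes parameter recovery a
meaningful end-to-end test: any systematic bias or CI miscalibration in the
pipeline shows up directly.

Defaults mirror the study conditions: a "trained crow" preset (3
individuals × 1500 sequences, sizes uniform on 1–4, $\beta_1 = -0.022$,
$\beta_2 = 0.034$), a "human" preset (26 × 156, sizes uniform on 1–8,
$\beta_1 = 0.033$, $\beta_2 = -0.023$), and a "wild" preset with a
truncated-geometric size distribution (mean ≈ 2.8, matched to ~3 calls per
sequence) and $\beta_1 = -0.164$. Variance components are not published for
these datasets; the defaults ($\sigma_{seq} = \sigma_{ind} = 0.1$,
$\sigma_{pos} = 0.02$, $\sigma_\epsilon = 0.3$ on the log scale) were chosen
once as values typical of call-duration variability (a residual log-SD of
0.3 is ~35% duration variability) and are not tuned thereafter. The wild
size distribution is a stand-in — it is not reported for the source
recordings — so the wild preset supports software testing, not quantitative
claims about wild data.

What the generator does *not* emulate: call-type heterogeneity, serial
correlation of durations within a sequence beyond the shared intercepts,
non-Gaussian duration tails, measurement error in segmentation, and any
dependence of sequence size on duration. Passing recovery tests therefore
demonstrates estimator correctness under the model's own assumptions, not
robustness to their violation.

`simulate_trials()` generates cued-number trial outcomes with a *linear*
probability model (clipped to [0, 1], with the clip count reported), because
the accuracy analysis is linear on the proportion-correct scale — its cue
coefficient is a change in success probability per cue increment, which is
how a printed decline from 99.8% (cue 1) to 94.9% (cue 8) maps onto a slope
of about −0.007. The accuracy model (`fit_accuracy_model()`) regresses
per-participant, per-cue proportion correct on cue number with correlated
random intercepts and slopes per participant.

## Problem sizes and numerical choices

Simulation-based checks in the test suite run at the scale of the study
design they probe: recovery uses 50 replicates of 3 × 1500 sequences;
shuffle nulls use 200 iterations at that scale (via `refit`);
production-constraint nulls, which rebuild the grouping structure and need
full refits, are exercised at 200 iterations on smaller tables and at 100
iterations at moderate scale in the acceptance script. Singular fits
(variance components estimated at zero) are expected on degenerate inputs
and are reported via the `singular` flag rather than treated as failures;
optimizer non-convergence is flagged separately and never silently
swallowed. Ties in `generate_pseudo_sequence()` at exactly 50% overshoot
keep the last call; comparisons use a 1e-12 guard where floating-point sums
are compared against the band.

## Known limitations

* The deposited benchmark datasets are not redistributed; the benchmark
  tests locate them via a documented path and fail with a pointer when
  absent (see the README on reproducing the published analysis).
* Exact t and p replication against other tools is not guaranteed — log
  base, df method, and REML/ML conventions vary; coefficient estimates are
  the stable comparison surface.
* Sequence membership is taken as given in the input table; no silence-gap
  criterion for bout segmentation is imposed.
* The envelope detector is not a substitute for modern neural segmentation
  on noisy field audio; it is the laboratory-grade baseline.
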