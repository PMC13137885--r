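---
title: "Methods: network segregation, speech disfluency, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network segregation, speech disfluency, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segspeech)
```

## What the package models

Fluent speech degrades subtly with age: unfilled pauses, repetitions, and
revisions become more frequent, while filled pauses (um/uh and lexical
fillers such as "you know") become rarer. One candidate neural substrate is
the age-related *dedifferentiation* of large-scale resting-state networks:
as within-network coupling weakens and between-network coupling grows,
network **segregation** — `(within − between) / within` on Fisher
z-transformed connectivity — declines, and with it the brain's ability to
keep self-monitoring, planning, and linguistic computation functionally
distinct.

`segspeech` implements the complete analysis chain for testing this idea in
an adult lifespan cohort:

1. **Connectivity metrics.** ROI time series → pairwise Pearson
   correlations → Fisher z → negative-value rectification → per-network
   within-FC, between-network connectivity (BNC), and segregation.
2. **Disfluency coding.** CHAT-style transcripts → five subtype counts →
   percentages of words produced → task-averaged profiles; Stroop
   interference (incongruent − congruent mean RT, ms) as the executive
   function (EF) proxy.
3. **Moderated regression battery.** For each of 3 networks × 6 outcomes:
   `outcome ~ age + Stroop + metric + age×Stroop + age×metric + education +
   project`, with mean-centered continuous predictors, single-pass
   Cook's-distance screening (threshold 4/n), and Benjamini–Hochberg FDR
   over two families (metric main effects; age × metric interactions).
4. **Effects inference.** Simple slopes and Johnson–Neyman regions for
   significant interactions; nonparametric bootstrap mediation (ACME, ADE,
   total effect, proportion mediated) for age → segregation → disfluency
   pathways, plus a prerequisite check for serial mediation through EF.
5. **Synthetic cohort.** A calibrated generator that reproduces the
   documented effect structure with recorded ground truth, so each stage is
   validated by parameter recovery rather than by fixture snapshots.

## Connectivity metric definitions and numerical choices

The three networks are treated asymmetrically, reflecting their roles:

* `BNC_language` = mean of the two pair-means FC(language, DMN) and
  FC(language, MD). We average the two pair-means rather than pooling all
  cross edges (the pooled variant is available via
  `network_bnc(pooled = TRUE)` for sensitivity analysis); with 11 DMN and
  20 MD ROIs, pooling would weight the MD pair almost twice as heavily.
* `BNC_DMN` = `BNC_MD` = FC(DMN, MD): the two domain-general networks are
  scored against each other only, so their segregation is not diluted by
  coupling with the specialized language system. The language network uses
  left-hemisphere ROIs only (8 ROIs); DMN (11) and MD (20) are bilateral.

Numerical conventions, chosen once and not configurable:

* The diagonal is excluded from every average; no self-correlation ever
  enters a metric.
* Correlations with `|r| ≥ 1 − 1e−7` (duplicated series) are clipped before
  `atanh` so all metrics stay finite.
* Negative values are zeroed *after* the z transform. Because
  `atanh(0) = 0` and `atanh` is odd and monotone, rectifying before or
  after the transform yields identical results; the implementation
  documents this rather than exposing an option.
* `segregation(within, bnc)` refuses `within ≤ 0` (a degenerate,
  fully-rectified network) instead of returning ±Inf.

## The transcript subset and counting conventions

The parser covers the subset of CHAT conventions needed for disfluency
coding: main tiers (`*PAR:`), filled-pause tokens (`&-um`), timed pauses
(`(1.5)`), retrace groups (`<…> [/]` repetition, `<…> [//]` revision),
and colon prolongation marks (`s:oup`). Unknown markers become warnings,
never errors; a structurally malformed tier is an error naming the line.

Counting decisions, each documented and (where noted) configurable:

* **Word total**: spoken words, excluding `&-` filler tokens, pause marks,
  markers, and retraced material; an unmarked verbatim run (`the the the`)
  counts as **one** word and **one** repetition event, so repeated material
  enters the denominator exactly once. Runs never cross utterance
  boundaries, which also makes percentages invariant under transcript
  concatenation.
* **Unfilled pauses** require duration strictly greater than 1.0 s
  (`pause_threshold`, seconds); a pause of exactly 1 s does not count.
  Durations come from transcript annotations, not audio.
* **Filled pauses** include lexical fillers from a configurable lexicon
  (default `um`, `uh`, `you know`, `like`), matched longest-first and
  non-overlapping in the word stream; lexical fillers remain in the word
  total because they are real spoken words.
* **Prolongations** count toward the total disfluency percentage (their
  inclusion is inconsequential for age effects, which are null for this
  subtype, but keeps `total = sum of subtypes` exact).
* **Stroop**: error trials are excluded by default (`correct_only`).

## Regression battery conventions

* Age, Stroop, and the network metric are mean-centered; education enters
  in raw years; project is reference-coded (two indicators for three
  cohorts). The full design has 9 columns, so interaction coefficients are
  interpretable as cross-derivatives at the sample means.
* OLS is QR-based with `SE² = s²·diag((XᵀX)⁻¹)`, t on `n − p` df, and 95%
  t-intervals; rank deficiency is an error listing the collinear columns.
* Cook's screening is a single pass: fit, flag `D_i > 4/n`, refit once.
  Iterating to a fixed point could cascade exclusions; one pass matches the
  documented participant-level screening flow and keeps the exclusion log
  interpretable.
* The two FDR families (18 metric main effects; 18 age × metric
  interactions) are adjusted independently; `q < 0.05` is the significance
  criterion.
* Missing data are handled by listwise deletion per model; no imputation.

## Interaction probing and mediation

Simple slopes are evaluated by default at the moderator's mean and ±1 SD
(for age, ±17.1 y), the conventional probe points when no substantive ages
are prespecified; `conditional_slope()` exposes the bare formula
`b_focal + b_int·offset` so published coefficients can be checked by hand.
The Johnson–Neyman boundary solves
`(b_f + b_i·x)² = t²_crit (V_ff + 2x·V_fi + x² V_ii)` in closed form;
a negative discriminant yields an empty boundary set (not an error), and
boundaries are reported only within the observed moderator range.

Mediation uses three OLS models on the same complete-case sample with the
same covariates (education, project) in each: mediator on treatment,
outcome on treatment + mediator, outcome on treatment. In this linear
setting `ACME = â·b̂` and `ACME + ADE = ĉ` hold exactly, and the test suite
asserts them at machine precision. Uncertainty comes from a nonparametric
bootstrap that resamples whole participants (preserving the joint
treatment–mediator–outcome distribution), with **percentile** 95% intervals
— the plain choice when no interval family is prespecified — and
`p = 2·min(share ≤ 0, share ≥ 0)`. The default is B = 5000 resamples;
the test suite uses B = 100–500, which is ample for the calibration
properties it checks. Serial mediation through EF is gated on its
prerequisite path: if the network metric does not predict EF, the serial
decomposition is reported as not licensed rather than estimated.

The proportion mediated `ACME/(ACME + ADE)` is flagged unstable when the
direct and indirect effects have opposite signs, and undefined when the
total is zero.

## What the synthetic cohort emulates

`generator_params()` encodes the study conditions:

| component | default | unit |
|---|---|---|
| cohort size | 252 | participants |
| age | mean 46.83, SD 17.1, range [20, 81] | years |
| Stroop interference | 60.45 + 1.72·(age − 46.83) + N(0, 73.3) | ms |
| segregation slope per year | language −0.002, DMN −0.0023, MD −0.002 | seg units |
| segregation residual SD | 0.27 | seg units |
| filled/unfilled age slopes | −0.025 / +0.017 | %/yr |
| repetitions: DMN-seg main, age×seg | −0.63, +0.042 | %/seg, %/(yr·seg) |
| mediation (a, b, c′) | −0.0023, −0.59, 0.0046 | mixed |
| ROI series | 180 timepoints, block z-targets 0.5 within | — |

Noise is calibrated from reported precision: each residual SD is
`SE · SD(predictor) · √n`, which makes recovery tests honest about the
actual sampling uncertainty — e.g. the Stroop residual SD of ≈ 73 ms is
consistent with the observed marginal SD of ≈ 78 ms. For the interaction
term the predictor is the age × segregation product, so its SD
(≈ 17.1 × 0.274 ≈ 4.7) replaces the age SD in the calibration.

Design choices inside the generator:

* **Age distribution.** The reported moments describe the observed,
  range-limited sample, so the truncated-normal *parent* is solved
  numerically so that the truncated distribution has mean 46.83 and
  SD 17.1 on [20, 81]. The solution (parent ≈ N(2.9, 62.1)) is nearly flat
  across the range — exactly what a deliberate lifespan sampling design
  looks like. Naively truncating N(46.83, 17.1) would shrink the sample SD
  to ≈ 14.1 and silently decalibrate every SE-derived noise level.
* **Outcome baselines.** Intercepts (rates at mean age) are not reported
  quantities; they are set to plausible naturalistic-speech rates chosen
  high enough (filled 7%, unfilled 6%, repetitions 3.5%, revisions 3%)
  that the zero floor on percentages truncates a negligible (< 0.1%) share
  of draws, keeping the generative model effectively linear — slopes, not
  baselines, are what the recovery tests measure. Prolongations keep a low
  baseline (1%), so their floor produces realistic zero-inflation for a
  rare subtype.
* **Block targets on the z scale.** The time-series generator expresses
  within/between block targets on the Fisher-z scale, the scale on which
  every downstream metric is averaged, so the expected downstream
  segregation is exactly `(within − between)/within` in those units. In
  age-targeted mode the cross blocks are solved per participant from the
  target segregation; the DMN target fixes the shared DMN–MD block and the
  MD within-block is solved back from the MD target (the two BNCs are
  identical by definition).
* **Total disfluency** is generated as the sum of the five subtypes, which
  preserves the profile identity `total = Σ subtypes` at the cost of not
  giving the total its own independent coefficients.
* **Project effects** default to zero: the covariate machinery is fully
  exercised, but no cohort-level differences are asserted.
* Ground truth (exact coefficients, latent segregation, flooring counts,
  seed) is attached to every simulated cohort and round-trips losslessly
  through JSON.

What the generator deliberately does **not** emulate: BOLD
autocorrelation, motion and scanner artifacts, scrubbing/denoising
residue, lexical content of real narratives, or non-Gaussian RT
distributions. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated for the assumed data-generating
process — not that real resting-state data meet those assumptions.

## Problem sizes and reproducibility

Recovery checks use 400 replicate cohorts of n = 252 in the test suite
(Monte-Carlo SE comfortably below each tolerance) and 200 replicates in
`scripts/acceptance.R`; calibration checks use 500 null replicates
(type-I) and 200 datasets × B = 500 (bootstrap coverage); block-structure
consistency uses T = 5000 series averaged over 8 seeds. Every stochastic
path is seeded: the same seed gives byte-identical cohorts, transcripts,
bootstrap intervals, and pipeline reports.

## Known limitations

* One participant reported both instrument counts in the source cohort
  (n = 252 vs 253); the generator uses 252.
* The Johnson–Neyman age boundary and the bootstrap ACME are
  data-dependent quantities; simulations reproduce their qualitative
  behavior (a boundary in the upper-40s, an indirect-effect interval
  excluding zero), not their exact values.
* Whether between-network connectivity for the language network pools
  cross edges or averages pair-means is not fully determinate from the
  metric's typography; pair-mean is the default, pooled is available.
* The parser targets the documented CHAT subset, not full CLAN
  compatibility; audio-derived pause timing is out of scope.
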