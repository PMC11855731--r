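---
title: "Methods and design of the seedstress pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the seedstress pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedstress)
```

`seedstress` analyses factorial seed-priming experiments: unprimed (UP) or
hydroprimed (HP) seeds, each either unstressed (NT, 8 h imbibition at 25 °C)
or exposed to a heat wave (HW, 4 h at 25 °C then 4 h at 40 °C), with gene
expression additionally sampled in dry seeds (DS) and after post-priming
dry-back (DB). This vignette records the statistical models, the parameter
choices, and the design decisions behind the implementation.

## Germination kinetics

A germination schedule records, per replicate tray, the number of seeds
`n_i` newly germinated (radicle protrusion > 1 mm) at each inspection time
`t_i` (hours since sowing). Germinability is the final cumulative
percentage, `G = 100 Σ n_i / N`, and mean germination time is the
count-weighted mean `MGT = Σ n_i t_i / Σ n_i`. Both treat the replicate
tray as the statistical unit: group summaries are arithmetic means with
sample (n−1) standard deviations over trays, and the same replicate values
feed the inference layer. MGT is undefined for a tray in which nothing
germinated; such trays are excluded from the MGT summary with a warning
rather than imputed, because any imputation (e.g. the test horizon) would
bias group means by an arbitrary amount. The default design is 3 trays of
20 seeds per accession × treatment cell, but seed count is declared
metadata on the design object: the validator warns, never errors, on
mismatches, since screening-scale experiments legitimately use fewer seeds.

## Comet-assay scoring

Nucleoid images are classified upstream into damage classes 0–4; the
package starts from the class counts. A slide's score is
`a.u. = [Σ_c (N_c · c) · 100] / N_tot`, which is 100 × the mean class and
ranges 0–400. Two aggregations are provided because scored slides and
biological replicates are different units: `per_slide_mean` (default)
averages slide scores — the replicate-level value entering ANOVA — while
`pooled` sums class counts first. For equal nucleoid totals per slide the
two coincide exactly, which the tests verify as an algebraic identity.
Scores are held at full precision and conventionally reported to one
decimal.

## qPCR relative expression

Technical replicates (triplicate reactions) are collapsed to a mean Ct per
gene × group. Quantities are calibrator-relative,
`Q = E^(Ct_cal − Ct_sample)`, with a single standardized amplification
efficiency `E = 1.8` (per-gene overrides allowed, constrained to
1 < E ≤ 2). The calibrator defaults to the group with minimum mean Ct per
gene — making Q ≤ 1 and the most-expressed group the reference point — and
can be pinned to a named group such as DS; the choice only rescales each
gene's profile, so fold-changes between groups are unaffected.

Reference stability uses the geNorm measure: for candidates j, k the
pairwise variation `V_jk` is the SD over samples of `log2(Q_j / Q_k)`, and
`M_j` is the mean of `V_jk` over k ≠ j. Selection takes the two lowest M
values in a single pass; the stepwise-exclusion ranking is also available
(`genorm_rank()`) for panel inspection. M-ranking is applied to a declared
*candidate reference panel*, not to the full gene set: strongly co-regulated
targets can present low pairwise variation among themselves and would
otherwise displace genuine references — a known failure mode of
stability-by-agreement measures. Normalized expression divides each target
by the geometric mean of the selected references, and heat-map matrices are
per-gene Z-scores over groups (zero-variance rows flagged and set to zero).
Because expression is measured on pooled embryo axes, its replication is
the reaction triplicate, not biological trays; inferential letters on
expression therefore describe technical precision only.

## Inference

The temperature screening uses Welch's heteroscedastic two-tailed t-test
(via `stats::t.test`) with stars at 0.05/0.01/0.001. The factorial
comparisons use one-way ANOVA followed by Duncan's multiple range test:
means are ordered, and a pair spanning p ordered means differs when its
difference exceeds `LSR_p = q_p √(MSW/n_h)` and no wider non-significant
span contains it (the containment rule of range tests). The critical value
`q_p` is the studentized-range quantile at Duncan's protection level
`α_p = 1 − (1−α)^(p−1)`, computed numerically with `stats::qtukey` rather
than from embedded tables; the tests check it against published 5% table
values at several error degrees of freedom, and for p = 2 it reduces
exactly to Fisher's LSD. Unequal group sizes use the harmonic mean `n_h`
(Kramer-style); balanced designs are unaffected. Letters are built by
insert-and-absorb from the pairwise decisions, so that sharing a letter is
exactly equivalent to "not significantly different"; ties in means are
broken by group label for determinism. Letters are reported even when the
omnibus F is not significant — the output flags the omnibus outcome instead
of gatekeeping, since practice in this literature pairs ANOVA and Duncan
without a stated rule. With zero within-group variance the F statistic is
reported as `Inf` (p = 0) for unequal means and 0 (p = 1) otherwise, with a
degeneracy flag.

## Multivariate view

PCA operates on the column-Z-scored feature matrix (equivalent to
correlation-matrix PCA, i.e. autoscaling), with variables G, MGT, shoot
length (SL), root length (RL), strand breaks (SB, a.u.) and one column per
gene. Observations are replicate trays; expression, measured once per
group, is broadcast to that group's replicates — a documented compromise
that lets per-replicate phenotypes and per-group expression share one
ordination, at the cost of understating expression variance. Components
carry a deterministic sign (largest-magnitude loading positive); no
rotation. Biplot tables scale loadings into the score range while recording
the factor, so directions are exact and the raw loadings recoverable.

## The synthetic-data generator

The generator's defaults (`default_config()`) encode the study
conditions the pipeline is designed around: 2 accessions × 4 treatment
groups × 3 trays × 20 seeds, inspections every 12 h to 168 h, 3 slides of
100 nucleoids per replicate, triplicate reactions over the six expression
groups.

* *Germination*: each seed germinates with probability π (0.92/0.30 UP,
  0.95/0.38 HP under NT/HW) at a log-normal time (medians 44/64/36/56 h,
  sdlog 0.25), right-censored at 168 h and recorded at the first inspection
  at or after the true time — mimicking how discrete scoring inflates MGT.
* *Comet*: class counts are Multinomial with Binomial(4, θ) class
  probabilities, so `E[a.u.] = 400θ` in closed form; θ defaults
  (0.3295/0.3825 UP, 0.2860/0.2975 HP) place expected scores in the
  115–155 a.u. range typical of embryo axes.
* *qPCR*: `Ct = baseline − effect · log(2)/log(E) + N(0, 0.15)` per
  reaction, with effects in log2 units so planted fold-changes are exact
  powers of two; the candidate panel holds two zero-effect references and
  one mildly regulated decoy, giving reference selection a recoverable
  ground truth.
* *Biometry*: seed categories follow π and a per-group conditional
  aberrancy probability; lengths are truncated-at-0 normal, stunted for
  aberrant seedlings.

What the generator does **not** emulate: between-tray overdispersion
(trays are exchangeable given the group), seed-lot ageing effects,
dependence between a seed's germination time and its seedling size,
slide-to-slide scorer bias, and inter-plate qPCR calibration error.
Passing recovery tests therefore demonstrate that the estimators invert the
assumed data-generating process, not that real data meet those
assumptions.

## Numerical and testing choices

All randomness flows from a single master seed; `simulate_study()` derives
per-stage seeds by fixed small offsets so stages stay reproducible
independently, and two pipeline runs with the same config and seed are
byte-identical. Tolerances: oracle-equivalence checks (explicit sums of
squares, double-loop geNorm, eigendecomposition PCA) at 1e-8 or tighter;
studentized-range quantiles against published tables at 0.005 (table
granularity). Test problem sizes are desk-scale by choice — Monte-Carlo
checks use 1000–10,000 units where a closed-form expectation exists, the
letter-display contract is exhausted over 1000 random significance
matrices (k ≤ 6), and parameter recovery runs the full default design 100
times — keeping the whole suite in the tens of seconds while leaving every
statistical claim tested at 3-standard-error precision.

## Known limitations

Duncan's test controls per-comparison error at its protection level, not
the family-wise rate; it is implemented because it is the convention in
this literature, not as a recommendation. Expression inference on reaction
triplicates cannot speak to biological variability. The PCA broadcast of
per-group expression makes expression variables artificially noiseless
within groups, which inflates their apparent alignment with group
separation; interpret loadings accordingly.
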