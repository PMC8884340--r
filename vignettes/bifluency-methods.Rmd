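---
title: "Methods: scoring, simulating and analysing bilingual verbal fluency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, simulating and analysing bilingual verbal fluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifluency)
```

This vignette documents the models and conventions implemented by
`bifluency`: what exactly is computed, which choices were genuinely open
and how they were resolved, what the synthetic-data generator does and
does not emulate, and the package's known limitations. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The tasks and conditions

Category generation: produce words from a semantic category (animals,
clothing, food, transportation) in 60 s, under four language conditions —
NS-L1 and NS-L2 (one language exclusively), SS (switch between languages
at will), FS (alternate languages after every response). Each condition
is administered twice with counterbalanced categories. Letter fluency:
produce words beginning with F/A/S (English) or P/M/R (Spanish), per
language (LF-L1, LF-L2). Groups: bilingual people with aphasia (BPWA)
and healthy bilinguals (HB). All L1/L2 coding follows the participant's
self-reported first-acquired language.

## Correctness scoring

A response is **correct** when it is a unique word in the target
category (letter task: begins with the target letter), produced in the
required language, is not a repetition of a previously produced
response, and lies within one phonemic substitution, omission or
addition of a lexicon entry — Levenshtein distance 1 on phoneme
sequences, never orthography. Statuses are assigned with a fixed
precedence: `unknown` (unresolvable even at distance 1) beats
`category_error`/`letter_error` (resolved entry violates the target),
which beats `language_error`, then `repetition`, then `form_error`
(resolvable only at distance > 1), else `correct`. Error and repetition
responses stay in the sequence because the clustering and switching
analyses include them.

Open choices and how they were fixed:

- **Exact vs. in-target search.** Exact orthographic lookup is
  lexicon-wide (so an out-of-category real word becomes a
  `category_error`), while the distance-1 phonemic search is restricted
  to in-target candidates of the produced language — a nonword is only
  credited against a word the speaker could plausibly have aimed at.
  Ties at the minimal distance break deterministically by lexicographic
  concept id.
- **Translation equivalents.** The repetition rule is word-form level by
  default ("perro" after "dog" is creditable in dual-language
  conditions); `scoring_config(concept_repetition = TRUE)` treats
  translation equivalents as repetitions instead. Repetition checks
  operate within a single administration only, since each administration
  is scored separately before averaging.
- **Forced-switch anchoring.** The alternation schedule is anchored at
  the language of the *first* response; each position is then judged
  against strict alternation by parity. A mid-trial alternation failure
  is a `language_error`, and the following response is judged against
  the original schedule, not the failed one. Who chose the starting
  language in the original administration is unknown; anchoring on the
  transcript is the only convention that needs no extra metadata.
- **Out-of-lexicon tokens** must carry their own phoneme column in the
  transcript to be resolvable; otherwise they are `unknown`. No
  grapheme-to-phoneme conversion is attempted.

Condition scores are the mean correct count across the two
administrations (a single available administration is used and flagged
incomplete). Letter conditions aggregate their three letters by the
mean per default (`lf_aggregate = "mean"`), keeping the letter score on
the scale of one trial; the sum is available. This choice affects the
magnitude of the fluency difference score but not its sign.

## Clustering and switching

Semantic clusters are maximal runs of consecutive responses in which
each adjacent pair shares a semantic subcategory tag; phonemic clusters
are runs in which each adjacent pair satisfies any of: (i) identical
first two phonemes, (ii) equal length differing only at vowel
positions, (iii) identical suffix from the final vowel (rhyme),
(iv) identical phonemes with different spelling (homonyms). Cluster
size counts from the second word (`span − 1`); mean cluster size is the
sum of sizes over the number of clusters, singletons included in the
denominator (so *dog, cat / horse, pig, cow* gives (1 + 2)/2 = 1.5);
switches are transitions between clusters, `n_clusters − 1`.

Conventions:

- **Pairwise-adjacent linkage**, not a whole-cluster common tag; this is
  the only reading consistent with the printed worked examples. A
  whole-cluster rule is left as a configuration flag.
- **Singletons count in the denominator** with size 0 (the standard
  Troyer convention; the printed example contains no singleton, so this
  is a convention, and it is flagged as such).
- Semantic linkage is **concept-level and language-blind** (translation
  equivalents carry identical tags by lexicon invariant); phonemic
  linkage is evaluated **only between words of the same language** —
  rhyme and vowel identity are not well defined across phoneme
  inventories.
- `unknown` responses participate as always-unlinked items: they are
  productions and therefore break clusters.
- Cluster metrics are averaged across the two administrations with the
  same rule as correct counts. Whether the original analysis averaged
  metrics the same way is not stated; using one rule for both keeps the
  analysis table coherent.
- The subcategory taxonomy is **data** (a lexicon column), not code.
  The packaged lexicon uses Troyer-style animal subcategories and
  analogous taxonomies for the other categories; users substitute their
  own by editing the TSV. Words may carry several tags; any shared tag
  links.

## Fluency difference score

`FDS = (NS_correct − LF_correct) / NS_correct` per language, undefined
(`NA`, logged) when the category-generation count is zero, negative
when letter fluency exceeds category generation. Arithmetically, FDS is
monotone decreasing in letter-fluency performance at fixed category
performance; the package asserts nothing beyond the arithmetic.

## The synthetic cohort generator

The generator is a **statistical test harness, not a model of
aphasia**. Retrieval in one trial is a two-level Markov process: the
number of retrieval attempts is Poisson(`lambda`); a current
subcategory is maintained; each attempt continues within it with
probability `p_continue` (emitting an unused word) or attempts a
subcategory switch that succeeds with probability `p_switch` (failure
emits nothing; an exhausted subcategory forces a switch attempt).
Intrusions, repetitions, paraphasias (half one-edit — still creditable
— and half two-edit) and language errors are injected per emission.
Letter trials use first-two-phoneme neighbourhoods as their retrieval
units, so phonemic clusters emerge from the same mechanism.

**Calibration.** The packaged calibration
(`inst/extdata/cohort_calibration.json`) fixes `p_continue = 0.4` for
both groups and carries all condition effects through `p_switch` and
the language-error rates — encoding, as a generative assumption, that
switching is the control-sensitive component while clustering is
automatic. Per-condition `p_switch` values are derived analytically
from the published group-by-condition mean correct counts: expected
correct ≈ `lambda · (p_continue + (1 − p_continue) p_switch) · (1 − ε)`
with `ε` the per-emission error proportion. This derivation ignores
subcategory exhaustion and the attempt cost of failed switches, so
realized means undershoot the targets somewhat — most visibly for
conditions with small `p_switch` and for the healthy group's largest
targets, where category pools (20–36 concepts per language) truncate
production. The acceptance battery therefore checks *orderings*
(healthy > aphasia switches; the published condition ordering of
aphasia-group correct counts), not the target values themselves.
Group sizes default to 35 BPWA and 22 HB; 80% of participants are
Spanish-L1; the self-switch condition picks each cluster's language
with 0.7 dominance for L1.

Participant heterogeneity: a latent ability `z ~ N(0, 1)` scales
`lambda` log-normally (mean-preserving) and shifts `qlogis(p_switch)`
by `0.5·z`; standardized assessment scores (naming and semantic
batteries in both languages, nonverbal semantic matching, and matrix
reasoning for the aphasia group only) load
0.7 on the same ability and are otherwise drawn around the published
group norms, clipped to [0, 100]. This single shared factor is what
gives the downstream regressions signal.

Language-use-questionnaire metrics are generated from planted linear
latent-factor structures — the published rotated loading patterns for
each group × language (three factors for aphasia L1, two for aphasia
L2, one for healthy L1, two for healthy L2) — with uniqueness
`1 − communality` (floored at 0.05) on standardized scale, then
rescaled into instrument ranges (percentages to [0, 100] with
post-injury variables shifted down; acquisition age to years).

What the generator does **not** emulate: response latencies, real
lexical frequency or typicality gradients, perseveration dynamics,
cross-category intrusion structure, or any mechanism of aphasia. A
green recovery test establishes that the pipeline can detect planted
structure at the study's scale — not that the cognitive claims hold.

## Statistical battery

- **Mixed ANOVA**: one between- and one within-subject factor,
  listwise deletion of incomplete participants (logged). Both
  conventions for the within-subject tests are reported: the univariate
  split-plot F and the multivariate test on successive-difference
  contrast scores (Wilks' lambda with sum-to-zero group coding, exact F
  since each hypothesis has one degree of freedom; df pattern
  `(k − 1, n − g − k + 2)`). The published df pattern is consistent with
  the multivariate form, but the original choice is not stated, so
  neither is asserted as "the" method. Partial eta squared is
  `SS_effect / (SS_effect + SS_error)`; `1 − Λ` for multivariate rows.
  No sphericity correction is applied (the original report shows
  uncorrected df).
- **Planned contrasts**: paired t within groups, Welch t between
  groups, Cohen's d (pooled-SD or difference-SD), Benjamini–Hochberg
  adjustment within each declared family. Family membership is a
  configuration (the analysis plan), since the original families are
  implied but not enumerated.
- **PCA**: correlation-matrix eigendecomposition, retention strictly
  above eigenvalue 1, varimax with Kaiser normalization, component
  signs fixed by the dominant loading, salience threshold 0.6,
  regression-method factor scores `Z R⁻¹ L` (pseudo-inverse when the
  correlation matrix is singular, with a warning about instability when
  `n ≤ p`).
- **Backward stepwise OLS**: drop the predictor with the largest
  coefficient p-value above `removal_alpha = 0.10` until none
  qualifies. The elimination criterion is not stated in the original;
  0.10 is a conventional default and a parameter. Aliased
  (perfectly collinear) predictors are dropped first. Final-model
  coefficient p-values get BH adjustment, intercept included, matching
  how such tables are reported.

## Numerical conventions

Tolerances in tests: ANOVA F vs. hand-computed sums of squares at
1e-10; communality preservation under rotation at 1e-8; rotation
orthonormality at 1e-10; BH vs. its definition at 1e-12. Degenerate
inputs are values, not crashes: empty partitions yield `NA` metrics
(never zero); zero category-generation counts yield `NA` FDS; a
constant column aborts the PCA naming the column; saturated regressions
treat untestable coefficients as removable.

## Limitations

- The phoneme transcriptions in the packaged lexicon are simplified
  (quasi-ARPAbet English, a compact Spanish set) and the lexicon is a
  synthetic fixture — real studies should supply their own lexicon and
  taxonomy file.
- Scoring trusts the transcript's language tags; no language
  identification is attempted.
- The calibration reproduces group-mean orderings, not variances or
  correlations between conditions; between-condition correlations in
  the synthetic data arise only through the shared ability factor.
- No time-stamped (latency-based) clustering, no mixed-effects or
  Bayesian variants of the battery.
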