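---
title: "Screening depression from interview transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening depression from interview transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The screening problem

In a Wizard-of-Oz clinical interview a virtual agent asks a participant a
sequence of open questions; the transcript records, for every turn, its
start and stop time, the speaker, and the utterance. The screening task is
binary: predict whether the participant's PHQ-8 total exceeds 10 (the
depressed label, 1) from the transcript alone. Corpora of this kind are
small (on the order of 188 sessions), imbalanced (roughly 56 of 188
depressed), and access-restricted, which shapes every design choice below:
features are few, hand-crafted and interpretable; model search is
exhaustive rather than stochastic; and evaluation guards explicitly
against degenerate majority-class predictors.

`depscreen` implements the pipeline in five stages — transcript I/O and
validation, utterance cleaning, feature extraction, exhaustive wrapper
search, and F1-constrained selection — plus a synthetic corpus generator
that stands in for the restricted data.

## Cleaning and tokenization

Utterance cleaning proceeds in a fixed order: annotation-marker spans
(bracketed content such as `[laughter]` that was never actually spoken)
are removed whole; then the basic punctuation characters
`, . [ ] ? ! ; : "` are deleted (character deletion, not token splitting,
so contractions like "what's" survive as single words); then text is
lowercased and whitespace normalised. The operation is idempotent. Stop
words are *retained* by default: the filler-word feature counts them, and
removing them degrades downstream classification. A configurable stopword
list can still be removed via `cleaning_rules(stopword_removal = TRUE)`;
since no canonical list exists for this setting, the list is a parameter.
A word is a maximal non-whitespace run of the cleaned text.

Sessions whose transcript contains no bot turns are structurally invalid —
most features depend on the interviewer's questions — and are excluded
before splitting. Validation-then-split ordering is deliberate: with 188
sessions of which 3 are broken, `round(0.8 × 185)` gives exactly 148
training and 37 testing sessions, matching the reference corpus counts
deterministically rather than approximately.

## The feature bank

Each session yields 30 features.

**Per-question answer sentiment (19).** Each bot utterance is matched
against a canonical question pool by substring containment of the cleaned
question (first match in pool order). The answer span for a question is
every participant turn up to the next bot turn; its concatenated text is
scored by the lexicon scorer (mean polarity of tokens with lexicon
entries; 0 when none match). Questions absent from a session — or asked
but unanswered — contribute an exact 0. Only nine canonical questions are
publicly attested for this interview style; the pool is padded with ten
generic interview questions to fill the 19 slots, and is fully
configurable.

**Global features (11).** `avg_sentiment` scores the concatenation of all
participant turns as one text (a per-comment-average switch exists, since
either reading of "sentiment of all the comments" is defensible; whole-text
is the default). `avg_response_time` is the mean gap between a bot turn's
stop time and the immediately following participant turn's start time,
negative gaps (overlapping speech) clamped to 0. `speech_speed` is the
unweighted mean over participant turns of word count divided by turn
duration. The remaining eight are per-comment ratios — unique words,
filler words, characters per word, four POS roles, first-person words —
each computed per participant turn and averaged with equal weight per
comment rather than pooled; the unweighted reading follows the stated
"average of that calculation for all comments". Character counts exclude
whitespace (sum of token lengths), making `avg_characters` a mean word
length.

The sentiment lexicon, POS tagger, filler list and first-person list are
injected through `feature_spec()`. The shipped defaults are deterministic
dictionary components over a closed vocabulary, chosen so that every
feature value is exactly recomputable by hand; production engines (a
corpus lexicon, a statistical tagger) can be swapped in without touching
the extraction code.

## Exhaustive wrapper search and selection

The experimental feature pool holds 17 of the 30 features. Which 17 were
used originally is not fully attested; the default pool takes the five
global features that recur in published top-model feature sets
(`speech_speed`, `avg_characters`, `avg_nouns`, `avg_response_time`,
`adj_freq`), three further global features (`avg_sentiment`, `fp_avg`,
`avg_sw_frequency`) and the nine attested per-question features, and is
configurable.

For each classifier family every k-subset of the pool (lexicographic
enumeration via `combn`) is crossed with every hyperparameter setting:

| family | subset size | grid | models |
|---|---|---|---|
| random forest | 5 | fixed (`max_depth` 12, seed) | C(17,5) = 6,188 |
| gradient-boosted trees | 4 | `n_estimators` ∈ {100, 300, 500}; fixed `eval_metric` auc, `learning_rate` 0.01, `max_depth` 12 | 2,380 × 3 = 7,140 |
| SVM | 4 | gamma {1, 0.1, 0.01, 0.001} × C {1, 10, 100, 1000} × kernel {rbf, linear} | 2,380 × 32 = 76,160 |

Two grid details are interpretive. The random-forest `max_depth` was set
to a non-default value originally but never printed; 12 mirrors the
gradient-boosting depth and is exposed in the spec. For the SVM, the
published prose mentions only gamma and kernel, but only the full
gamma × C × kernel product (32 settings) reproduces the printed 76,160
total, so the C grid is included. The adapters run `ranger` (max.depth,
per-fit seed), `xgboost` and `e1071::svm` (rbf = radial kernel, no
internal rescaling) behind a uniform fit/predict contract, and any
`function(x_train, y_train, x_test, params, seed)` can replace them.

Every candidate is trained on the fixed training split and scored only on
the held-out split — a single fixed split, no cross-validation, matching
the original protocol (a development-set option is deliberately out of
scope). Candidates failing to fit are marked and skipped, never fatal.
Metrics come from the 2×2 confusion matrix: per-class precision, recall,
F1 and support, accuracy, macro (unweighted) and weighted
(support-weighted) averages. Averages are always computed from unrounded
per-class values; the 2-decimal figures in rendered tables are display
rounding only.

**Selection.** The primary criterion is held-out accuracy, *subject to* a
minority-class F1 constraint: candidates whose F1 on the rarer test class
does not strictly exceed a floor (default 0) are discarded first. This
reproduces the observed failure mode of imbalanced screening: an
all-majority predictor reaches accuracy equal to the majority prevalence
(e.g. 29/38 ≈ 0.76) with a minority F1 of exactly 0, and must lose to a
lower-accuracy model that actually detects the minority class. Whether
the original study filtered by a floor or by the argmax of minority F1 is
ambiguous; both are implemented (`selection_policy(constraint =)`), floor
being the default. Ties in accuracy break by higher minority F1, then
fewer features, then the lexicographically smallest subset, making the
ranking a total order and the winner unique and reproducible. "Minority
class" means the label with the smaller test support (tie: class 1).

The constant-class baseline predicts one label for every test instance;
its accuracy is that label's prevalence, reported for both classes.

## The synthetic corpus generator

The generator exists so that every stage has ground truth. It emulates:

- **Corpus shape.** 188 sessions, 56 depressed, 3 sessions without bot
  turns (the defaults; all configurable). Labels are exact, not sampled:
  prevalence is 56/188 for every seed. PHQ-8 scores are drawn consistently
  with the binary rule (depressed: 11–24, control: 0–10).
- **Dialogue structure.** Each valid session asks each pool question
  independently with probability 0.9 (so most sessions share most
  questions but no question appears in every session), in pool order; each
  question gets one or two participant answer turns. Timing is strictly
  increasing and non-overlapping: bot turn, a response gap drawn from a
  shifted log-normal (0.1 s + log-normal with class-conditional mean),
  then answer turns whose duration is word count divided by a
  per-comment speech rate ~ Normal(class mean, 0.35 w/s, truncated at
  0.5). These constructions make `avg_response_time` and `speech_speed`
  recoverable by design.
- **Utterance content.** Words are drawn from a closed vocabulary
  partitioned into positive/negative sentiment words, first-person words,
  fillers, and POS-tagged neutral words, with class-conditional category
  rates (control: 10% positive, 10% negative, 12% first-person, 8%
  filler). Comment length is 3 + Poisson(13) words. With probability 0.15
  an utterance carries one bracketed annotation marker, exercising the
  marker-removal rule; raw utterances are capitalised and period-terminated
  so cleaning is never a no-op.
- **Class effects.** Depressed sessions shift the speech rate (default
  −0.5 w/s), response latency (+0.6 s), negative-word rate (+0.06) and
  first-person rate (+0.05). The default magnitudes are chosen to be
  large relative to session-level sampling noise (a session mean pools
  ~20 comments, so the speech-rate shift is many standard errors) —
  deliberately strong planted signal, since the generator's role is to
  make recovery testable, not to calibrate clinical effect sizes. Setting
  all effects to 0 yields exchangeable classes, which the test suite
  verifies by rank-test calibration (≤5 rejections at α = 0.01 over 100
  replicate corpora).
- **Determinism.** Each session is generated from a substream seeded by
  `(48271·seed + 104729·index) mod (2³¹−1)`, so corpora are byte-identical
  across runs and independent of generation order.

What the generator does *not* emulate: syntax, semantics, discourse,
acoustic features, or any natural-language property beyond category
counts and timing. A pipeline that passes every test here is verified as
*software* — correct feature arithmetic, correct search mechanics, correct
selection — but nothing is implied about predictive accuracy on real
clinical interviews, and the published real-data accuracies (≈84% random
forest, ≈82% gradient boosting, 68% SVM) are not reproduction targets.

## Numerical and edge-case choices

- Transcript times are seconds; ties in start time keep file order
  (stable sort). Generated times are rounded to 4 decimals so that
  write → read round-trips are exact.
- The label rule is implemented exactly as documented for the reference
  corpus (`score > 10` ⇔ label 1) with the threshold configurable, since
  standard PHQ-8 practice uses ≥ 10. Inconsistent records warn by
  default and error in strict mode. The label convention (1 = depressed)
  follows the reference label table.
- A feature whose precondition fails on a given session (e.g. timing
  features without a usable adjacency) is set to 0 with a warning, so one
  malformed session never aborts a corpus run.
- `f1_from_pr(0, 0)` is 0 by convention; a class absent from truth or
  prediction gets precision/recall/F1 of 0.
- Problem sizes in the test suite (corpora of 15–200 sessions, pools of
  3–6 features, subset sizes 2–3, 20-seed recovery loops, 100-replicate
  calibration) are chosen so the full suite completes in a few minutes
  while keeping every statistical check adequately powered; the
  published-count combinatorics (6,188 / 7,140 / 76,160) are verified by
  enumeration, which needs no model fitting.

## Known limitations

The default question pool, feature pool and random-forest depth encode
documented but unverifiable choices about the original experimental
setup; all three are configuration, not constants. The search is a single
fixed-split protocol and therefore optimistically biased when its maximum
is read as a performance estimate — faithful to the original design, but a
development set (out of scope here) would be needed for unbiased model
selection. Sentiment and POS components are dictionary stubs at desk
scale. Gender is parsed and carried but never enters any model.
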