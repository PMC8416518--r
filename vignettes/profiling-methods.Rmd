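---
title: "Profiling decision makers from mental functioning patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling decision makers from mental functioning patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfpattern)
library(dplyr)
```

## The model

The package operationalises a psychometric profiling method in which a
person's way of learning, thinking and deciding — their *mental
functioning pattern* — is summarised as a composition over three
behavioural tendencies:

* **adaptive** — accommodation to circumstances to avoid discomfort;
* **reactive** — struggle to restore a previous state of well-being;
* **creative** — generation of new alternatives in the face of
  difficulty.

The instrument is a questionnaire of characteristics ("metrics"), each
answered on an integer scale from 1 to 10 between two linguistic
anchors. Because behavioural characteristics have no crisp boundaries,
each answer $r$ is scored by fuzzy *pertinence* (membership) functions
$\mu_a, \mu_r, \mu_c : [1,10] \to [0,1]$, one per pattern. A
respondent's profile over $m$ questions is the normalised sum

$$v \;=\; \frac{1}{Z}\Big(\textstyle\sum_{j=1}^m \mu_a(r_j),\;
\sum_{j=1}^m \mu_r(r_j),\; \sum_{j=1}^m \mu_c(r_j)\Big),
\qquad Z = \text{grand total},$$

so that $v$ is a proportion vector summing to one. Profiles are
validated against expert (psychologist) ratings $v_p$ by cosine
similarity $\cos(v, v_p) = v \cdot v_p / (\lVert v\rVert\,\lVert
v_p\rVert)$ with an acceptance threshold of 0.8, and used as features
to predict categorical decisions with a $k$-nearest-neighbour model
whose quality is expressed as the *gain* of its success rate over the
random-choice baseline $100/K$ for a $K$-class decision.

## The questionnaire catalog

The shipped catalog has 26 metrics — 8 *primary* (universal, innate
characteristics such as anxiety and self-esteem) and 18
*circumstantial* (context-dependent social characteristics such as
financial literacy) — and seven *drivers*, named analysis contexts
that select the metrics relevant to a decision scenario. A driver
contributes its ordered interest list first and then appends the
primary metrics attached to that context; the debt-collection driver
selects six interest metrics and four primary ones (self-esteem,
self-discipline, anxiety, learned resilience), a 10-question form.

Two catalog conventions deserve a note:

* **Interest lists may cross categories.** The published driver tables
  place a few primary-category metrics (beliefs, self-esteem) inside
  drivers' circumstantial interest lists. The catalog validator
  therefore requires interest-list entries only to *exist*; the
  appended `primary` list must genuinely be primary-category. This
  keeps the shipped drivers faithful to their published composition —
  in particular it is the only reading under which the debt-collection
  form has its 10 questions.
* **Reverse-keyed items.** One shipped item (beliefs) runs against the
  canonical scale direction (its left anchor is "Yes", its right "No").
  Rather than writing mirrored membership functions, the item carries a
  `reversed` flag and responses are mapped $r \mapsto 11 - r$ before
  fuzzification. Inspection of the remaining items' anchor polarity
  against their metric definitions did not justify reversing any other
  item, so only this one ships reversed; the flag is per-metric
  configuration and can be changed freely.

Only the debt-collection driver ships with primary appends, because
that is the only context whose primary selection is documented; other
drivers ship with empty primary lists and callers add their own.

## Membership functions

Two shapes are supported: `triangular(a, b, c)` and
`trapezoidal(a, b, c, d)`, piecewise-linear with degree 0 at and
outside the outer breakpoints and degree 1 at the apex (triangle) or on
the plateau (trapezoid). A zero-width edge makes a shoulder that holds
degree 1 at that end of the scale.

The per-metric breakpoints used by the original clinical instrument are
not published in recoverable form, so the package treats all membership
functions as configuration. The shipped default set applies one
canonical trio to every metric:

* adaptive = `triangular(1, 2.5, 5.5)`
* reactive = `trapezoidal(3.5, 5.5, 7.5, 9.5)`
* creative = `triangular(6.5, 10, 10)`

```{r, fig.width = 6, fig.height = 3}
plot_membership(default_fuzzifiers()$default)
```

The reactive function is trapezoidal — the one shape constraint the
method's description does fix, reflecting the observation that reactive
alignment saturates over a band of responses — and the adaptive and
creative functions anchor the two ends of the scale, with moderate
overlap so that intermediate answers carry graded evidence for two
patterns at once. Per-metric overrides are configured in the
`fuzzifiers:` section of a catalog document; results computed with the
defaults should be read as pipeline outputs under a documented,
replaceable scoring configuration, not as reproductions of the original
clinical scoring.

One degenerate case follows from these defaults: at $r = 1$ all three
degrees are zero (the adaptive triangle's foot sits at 1). A profile
whose *every* answer scores (0, 0, 0) has no direction; aggregation
then raises an error by default, or returns the uniform profile
$(1/3, 1/3, 1/3)$ flagged `degenerate` when the caller opts in. A
single zero triple among informative answers is harmless — it simply
adds nothing to the sums.

## Aggregation, dominance, ties

The published per-respondent vectors all sum to one, which is the
footprint of sum-then-normalise aggregation; the package uses exactly
that rule. It makes the profile invariant to rescaling all triples by
a common positive factor and to question order, and reduces to the
identity for a single already-normalised triple.

The *dominant* pattern is the arg-max component. Exact ties are broken
in the fixed order adaptive, reactive, creative and flagged, so
downstream consumers can distinguish a genuine dominance from a
coin-flip profile.

## Similarity validation

`similarity_report()` compares calculated and expert vectors pairwise.
Cosine similarity is scale-invariant, so expert ratings may be supplied
either as normalised proportions or as raw small-integer scores per
pattern (e.g. 4, 2, 1, which normalises to 4/7, 2/7, 1/7 — the form in
which expert ratings are typically collected). The acceptance
threshold defaults to 0.8 and the comparison is *inclusive*
(`similarity >= threshold`); the method description does not fix the
boundary, and the inclusive convention is the conventional, testable
choice. Tabular output prints three decimals with half-up rounding;
full precision is always returned in the tibble.

Because the published vectors are themselves printed at three decimals,
recomputing a similarity from them can legitimately differ from the
printed similarity by one unit in the third decimal; the package's
tests therefore compare at ±0.002.

**Disagreement counting.** The validation study also reported, per
respondent, a count of questions whose answer disagreed with the
expert's impression, without defining the criterion. The package makes
the criterion an explicit, pluggable *policy*: under the default
`"dominant"` policy a question disagrees when the dominant pattern of
its fuzzy triple differs from the dominant pattern of the expert
vector (all-zero triples are skipped as uninformative). This is a
reasoned guess, not a reconstruction; `policy = "none"` disables the
count, and the published per-respondent counts are not used as a
correctness target anywhere in the test suite.

## Decision prediction

For a decision context, each respondent becomes a feature vector plus a
categorical decision label. The default feature encoding is the raw
response vector (10 numbers for the debt-collection form) — the most
literal reading of a "vector of patterns with one position per
question"; the per-question fuzzy triples (30 numbers) or the
aggregated profile (3 numbers) can be substituted by passing different
feature columns, since the model takes any numeric feature set.

* **Split.** 70% train / 18% test / 12% validation, the published
  partition. Subset sizes follow largest-remainder apportionment (so
  1,204 rows split exactly as 843/217/144) and the shuffle is driven
  entirely by a seed.
* **Model.** $k$-nearest neighbours with Euclidean distance, the
  algorithm named by the method. $k$ is not published; the default is
  $k = 5$, the common library default, and is configurable. Vote ties
  are broken by the label of the single nearest neighbour, and
  equidistant neighbours rank by training order, which makes
  prediction fully deterministic.
* **Evaluation.** Success rate is the percent of correct validation
  predictions; the gain divides it by the random baseline $100/K$.
  Precision and recall are macro-averaged — unweighted means over the
  labels present in the validation truth, with precision 0 for a label
  never predicted — matching the published "mean value between labels"
  reading. Rates print to 2 decimals and gains to 4.
* **Feedback.** The human-in-the-loop step appends validator-reviewed
  predictions to the training sample: ratified records keep the
  predicted label, rectified records use the corrected one, pending
  records wait. The merge is idempotent per respondent, so periodic
  re-runs cannot inflate the training set.

The published end-to-end percentages for the debt-negotiation cohort
are *not* reproducible from first principles — they depend on a private
1,204-respondent dataset, an unpublished $k$ and an unrecorded random
split — so the package ships them as a reference table
(`debt_negotiation_results()`) and checks only their internal
arithmetic (baselines and gains), substituting a synthetic
signal-recovery study for the rest.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised with
known ground truth. It emulates three things:

1. **Respondents.** Each archetype is a Dirichlet concentration over
   the three patterns. The defaults — (8, 1, 1), (1, 8, 1), (1, 1, 8),
   mixed uniformly — mirror the method's three-way taxonomy with one
   clearly dominant component each. A respondent's ideal answer to a
   question is found by exhaustive search over the integers 1–10 for
   the response whose fuzzy triple is most cosine-similar to the true
   vector (exact inversion of a piecewise-linear triple is ill-posed;
   the grid search is exhaustive at this scale). Gaussian jitter with
   standard deviation 1 scale point — about the magnitude of
   test-retest inconsistency one expects on a 10-point item — is then
   added, rounded and clipped to the scale.
2. **Expert ratings.** The true vector is perturbed with Gaussian noise
   (sd 0.05 on the proportion scale by default), converted to integer
   scores 1–10 per pattern and renormalised, reproducing the
   small-integer-ratio structure of real expert ratings.
3. **Decisions.** A deterministic rule scores each true vector with
   the linear combination $0 \cdot a + 0.5 \cdot r + 1 \cdot c$ — an
   adaptive-to-creative gradient — and assigns classes by equal-mass
   quantile bins over the cohort; labels are then flipped to a random
   other class with probability `label_noise`. The four default
   decision variables (negotiation stance, discount tier, installments
   agreed, installments paid) span 3–6 classes. All have at least
   three classes by design: a binary outcome caps the attainable gain
   at 2, which would make gain-over-random uninformative as a
   signal-recovery measure.

What the generator does **not** emulate: real answer distributions
(none are published), demographic structure, item-specific membership
functions, correlated item noise, or deliberately distorted
self-presentation. Passing the synthetic recovery tests therefore
shows that the pipeline is *correct and sensitive* — it recovers
structure that is present — not that real cohorts contain that
structure.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 1,000-respondent cohort
(three well-separated archetypes, zero label noise, fixed seed) for the
signal-recovery study, and a 400-respondent cohort for the
similarity-degradation study (0–6 corrupted answers per respondent);
these sizes give stable estimates while keeping a full run inside a
minute or two. With identical feature vectors and zero distance ties,
1-nearest-neighbour self-prediction is ambiguous only when duplicated
features carry conflicting labels; the recovery test checks perfect
self-prediction on all unambiguous rows. Fixed-point printing uses
half-up rounding at the table precisions (3/2/4 decimals). All
randomness — archetype draws, response jitter, expert noise, label
flips, splits — flows from explicit seeds, and every CLI output writes
a manifest with the seed and a configuration hash.

## Known limitations

* The default membership breakpoints are a documented configuration,
  not the original clinical instrument's parameters; absolute profile
  values depend on them (cosine-based comparisons are less sensitive).
* The disagreement policy is a modelling choice; published
  per-respondent disagreement counts cannot be used to validate it.
* The nearest-neighbour model is the only classifier provided, by
  scope; no hyperparameter search is performed.
* Expert-rating emulation assumes unbiased Gaussian perturbation of
  the true composition; systematic rater bias is not modelled.
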