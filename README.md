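# mfpattern

Profiling decision makers from questionnaire responses via fuzzy
*mental functioning patterns* — and predicting their categorical
decisions from those patterns.

The package is for computational psychometrics and behavioural-decision
work in which a respondent answers Likert-style items on a 1–10 scale
and is summarised as a normalised composition over three behavioural
tendencies: **adaptive** (accommodates to avoid discomfort),
**reactive** (struggles to restore prior well-being) and **creative**
(generates new alternatives). Each answer $r$ is scored by fuzzy
membership functions $\mu_a, \mu_r, \mu_c : [1,10]\to[0,1]$; a profile
over $m$ questions is

$$v = \frac{1}{Z}\Big(\sum_j \mu_a(r_j), \sum_j \mu_r(r_j), \sum_j \mu_c(r_j)\Big), \qquad \sum v_i = 1 .$$

Profiles are validated against expert ratings $v_p$ by cosine
similarity with an inclusive 0.8 acceptance threshold, and used as
features in a $k$-nearest-neighbour model whose success rate on a held
out validation split (70/18/12 train/test/validation,
largest-remainder sizes) is reported as a **gain** over the
random-choice baseline $100/K$ for a $K$-class decision.

The package ships:

* a questionnaire **catalog** (26 metrics, 8 primary + 18
  circumstantial; 7 context drivers, including the 10-question
  debt-collection form), YAML/JSON-configurable;
* the **fuzzification/aggregation** pipeline with configurable
  triangular/trapezoidal membership functions and reverse-keyed items;
* **similarity validation** (per-pair reports, acceptance verdicts,
  pluggable per-question disagreement counting);
* the **prediction** stack (seeded splits, deterministic KNN,
  gain/accuracy/macro precision/recall, human-in-the-loop feedback
  merge);
* a seeded **synthetic cohort generator** (Dirichlet archetypes,
  expert-rating emulation, pattern-coupled decision labels) so every
  stage is testable with known ground truth;
* CSV/JSON I/O with manifests, ggplot2 `autoplot()`s, broom-style
  `tidy()`/`glance()`, and a small CLI (`inst/cli/mfp.R`).

## Worked example

Profile one respondent on the 10-question debt-collection form:

```r
library(mfpattern)
library(dplyr)

catalog <- default_catalog()
sheets <- tibble::tibble(
  respondent_id = "r1",
  metric_id = metrics_for_driver(catalog, "debt_collection")$metric_id,
  response = c(2, 3, 6, 8, 5, 7, 9, 4, 6, 5)
)
profile_respondents(sheets, catalog, driver_id = "debt_collection")
#> # A tibble: 1 × 7
#>   respondent_id adaptive reactive creative dominant tie   degenerate
#>   <chr>            <dbl>    <dbl>    <dbl> <chr>    <lgl> <lgl>
#> 1 r1               0.229    0.635    0.136 reactive FALSE FALSE
```

This respondent's answers put 63.5% of the fuzzified evidence on the
reactive pattern, so `dominant` is `reactive` (no tie, no degenerate
all-zero answers).

Validate the bundled 34-pair clinical comparison (calculated versus
psychologist-rated vectors) at the 0.8 threshold:

```r
report <- similarity_report(clinical_validation_pairs(), threshold = 0.8)
glance(report)
#> # A tibble: 1 × 5
#>       n n_accepted prop_accepted mean_similarity threshold
#>   <int>      <int>         <dbl>           <dbl>     <dbl>
#> 1    34         10         0.294           0.671       0.8
```

Ten of the 34 calculated profiles clear the acceptance threshold; the
per-pair similarities match the published column to three decimals
within ±0.002 (the published vectors are themselves rounded).

Simulate a cohort, train and evaluate a decision model:

```r
cohort <- simulate_cohort(catalog, "debt_collection", n = 1000, seed = 1)
features <- responses_to_features(
  cohort$sheets, metrics_for_driver(catalog, "debt_collection")$metric_id)

ds <- mutate(features, decision = cohort$decisions$installments)
parts <- split_dataset(ds, seed = 2)                  # 700 / 180 / 120
model <- train_knn(bind_rows(parts$train, parts$test), k = 5)
evaluate_model(model, parts$validation, default_decision_variables()$installments)
#>   decision_variable n_classes random_rate success_rate gain accuracy ...
#> 1      installments         6    16.66667           60  3.6       60
```

The model recovers the planted pattern-to-decision signal: 60% correct
on a 6-class outcome, a gain of 3.6 over the 16.7% random baseline.

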