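# rechallenge

Decision support for re-administering a chemotherapeutic agent after a
serious adverse drug reaction (ADR).

When a cancer patient suffers a serious ADR, clinicians may still need to
*rechallenge* — give the same drug again — because alternative treatments
are limited. The rechallenge is **negative** if the ADR does not recur and
**positive** if it does, and no standard guideline exists for predicting
which will happen. `rechallenge` implements, end to end, a pipeline for
building and evaluating a probabilistic score for this decision, for
pharmacovigilance analysts and clinical-informatics researchers:

* **Attribute derivation** — a 53-attribute clinical schema (demographics,
  medical conditions, medications, laboratory parameters) with the
  constructed attributes: elderly flag (age ≥ 65), polypharmacy flag
  (> 5 concurrent medications), comorbidity count, and abnormal-lab flags
  against configurable reference intervals.
* **Mixed-type naive Bayes** — for attributes F₁…Fₙ assumed conditionally
  independent given the outcome class,

  P(NR | F) = P(NR) ∏ᵢ p(Fᵢ | NR) / [ P(NR) ∏ᵢ p(Fᵢ | NR) + P(PR) ∏ᵢ p(Fᵢ | PR) ],

  with per-class Gaussian densities for continuous attributes and smoothed
  frequency tables for categorical ones, computed stably in log space.
* **Evaluation** — trapezoidal ROC/AUC (equal to Mann–Whitney concordance
  with half credit for ties) plus sensitivity/specificity at
  clinician-chosen thresholds; negative rechallenge is always the
  detection target.
* **GA wrapper feature selection** — binary-mask chromosomes scored by
  testing-set AUC; roulette-wheel selection, single-point crossover (95%),
  per-bit mutation (5%), elitism, 100 generations × 80 subsets × 5
  restarts, fully seed-reproducible.
* **Synthetic cohorts** — `published_spec()` / `published_model()` encode
  the released model's class-conditional distribution table (17 negative /
  18 positive testing-set composition), so the whole pipeline is testable
  without patient data.

## Worked example

Simulate a testing-set-sized cohort from the published class-conditional
statistics, score it with the published 8-predictor model, and evaluate the
two clinically motivated thresholds:

```r
library(rechallenge)

cohort <- generate_cohort(published_spec(), seed = 1)
model  <- published_model()

predict(model, cohort[1:3, ], type = "prob")
#> # A tibble: 3 × 3
#>   posterior_negative posterior_positive degenerate
#>                <dbl>              <dbl> <lgl>
#> 1              0.809             0.191  FALSE
#> 2              1                 0      FALSE
#> 3              0.955             0.0445 FALSE

evaluate_model(cohort, model, thresholds = c(0.01, 0.8))
#> <performance_report>
#>   scores are P(negative rechallenge); a record is called negative
#>   when its score is strictly above the threshold
#>   n = 35 (17 negative / 18 positive rechallenge), AUC = 0.974
#>   threshold 0.01: sensitivity 100%, specificity 28% (TP 17 FP 13 TN 5 FN 0)
#>   threshold 0.8: sensitivity 65%, specificity 94% (TP 11 FP 1 TN 17 FN 6)
```

Each posterior is the probability that the ADR would *not* recur on
rechallenge. The low threshold (0.01) recovers every true
negative-rechallenge case — the operating point for curative intent, where
withholding a useful drug is the costlier error — while the high threshold
(0.8) trades sensitivity for 94% specificity, the palliative-intent
operating point. The second record's posterior of 1 is a zero-likelihood
elimination: its drug was never observed among positive-rechallenge cases
and the model is fitted with smoothing `alpha = 0` (see the methods
vignette for why, and when to prefer `alpha = 1`).

GA attribute selection and model fitting on your own cohort:

```r
split  <- split_cohort(cohort, n_train = 24, seed = 7)
result <- run_ga(split[split$is_train, ], split[split$is_test, ], seed = 7)
fit    <- nb_fit(cohort, subset = result$best_subset)
```

A command-line wrapper over the same functions (subcommands `derive`,
`simulate`, `select`, `train`, `predict`, `evaluate`, `fixture`) is
installed at `system.file("cli", "rechallenge.R", package = "rechallenge")`.

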