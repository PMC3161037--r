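---
title: "Methods: scoring chemotherapy rechallenge after a serious adverse drug reaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring chemotherapy rechallenge after a serious adverse drug reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rechallenge)
```

## The clinical problem

After a patient suffers a *serious* adverse drug reaction (ADR) to a
chemotherapeutic agent, clinicians must sometimes decide whether to
re-administer the same drug — a *rechallenge* — because effective
alternatives are scarce. A rechallenge is *negative* when the ADR does not
recur (the favourable outcome) and *positive* when it does. There are no
standard guidelines for this decision; it rests on individual clinical
judgement. This package implements a decision-support pipeline that scores
the posterior probability of negative rechallenge from routinely collected
clinical attributes, selects predictive attribute subsets with a
genetic-algorithm (GA) wrapper, and evaluates the resulting classifier at
clinician-chosen decision thresholds.

## The classifier

The model is a mixed-type naive Bayes classifier. Given attributes
$F = \{F_1, \dots, F_n\}$ assumed conditionally independent given the
outcome class $C \in \{\mathrm{NR}, \mathrm{PR}\}$ (negative / positive
rechallenge),

$$
P(\mathrm{NR} \mid F)
 = \frac{P(\mathrm{NR}) \prod_i p(F_i \mid \mathrm{NR})}
        {P(\mathrm{NR}) \prod_i p(F_i \mid \mathrm{NR})
         + P(\mathrm{PR}) \prod_i p(F_i \mid \mathrm{PR})}.
$$

* **Continuous attributes** (age, laboratory values, counts) use per-class
  Gaussian densities with sample mean and sample standard deviation
  ($n-1$ denominator). The Gaussian choice is the standard naive Bayes
  treatment and matches the mean ± SD form in which the released model's
  distribution table is published; a discretization-based variant would be
  an alternative reading but is not implemented.
* **Categorical and binary attributes** (drug, abnormal-lab flags, …) use
  per-class category frequencies with additive smoothing `alpha` over the
  schema's full category list.

Class priors are empirical class frequencies. Posteriors are evaluated in
log space with a log-sum-exp reduction; a property test confirms agreement
with the direct product formulation to 1e-9 wherever the direct product
does not underflow.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` (smoothing) | 0 | pseudocounts | reproduces exact zero class-conditional proportions as published (e.g. rituximab never observed among positive rechallenges); set `alpha = 1` (Laplace) for robust use on new data, where an unseen category should not be decisive |
| `sd_floor` | 1e-6 | native units | prevents degenerate zero-variance Gaussians (e.g. a constant attribute within a class) |
| `threshold` | per call | probability | a record is called negative exactly when its score *strictly exceeds* the threshold; 0.01 suits curative intent (maximise sensitivity: do not withhold a useful drug), 0.8 suits palliative intent (maximise specificity: avoid repeat serious ADRs) |
| reference intervals | conventional adult panel | per lab | the abnormal-lab flags need low/high bounds; sites should substitute their own laboratory's ranges via `read_reference_intervals()` |

Two deliberately conservative conventions are fixed rather than
configurable: a score exactly equal to the threshold is classified
*positive* (never recommend rechallenge on a boundary score), and the ROC
detection target is always negative rechallenge (the direction the model
scores), preventing silent axis flips between reports.

### Missing values

Missing attribute values skip the corresponding factor at both fit and
prediction time (a missing-at-random contract). A record missing *every*
model attribute — or whose likelihood vanishes under both classes, which
can happen with `alpha = 0` — carries no usable evidence: the prior is
returned and a warning raised.

## The attribute schema

Cohorts are plain tibbles validated against a schema (`default_schema()`)
declaring 53 attributes across demographics, medical conditions,
medications and laboratory parameters, including the constructed
attributes: the elderly flag (age ≥ 65), the polypharmacy flag (> 5
concurrent medications), the comorbidity count over seven listed
conditions, and abnormal-laboratory flags (value strictly outside its
reference interval). Age appears both continuously and as the elderly
binary; subset selection may keep either or both.

The full original attribute catalogue is not public, so the shipped schema
is a reconstruction: the published attribute groups plus the stated
derivations. To reach the documented total of 53, abnormal flags are
constructed for 12 of the 13 laboratory parameters (basophil, the least
commonly flagged differential count, is left without one). The schema is
data, not code — a site with the exact catalogue can supply it as JSON via
`read_schema()` and everything downstream follows it.

## Development protocol

`split_cohort()` replicates the original overlapping protocol: from the
eligible (non-validation-era) pool, `n_train` records are sampled without
replacement as the training set, while the *entire* eligible pool is the
testing set — training records are re-scored during selection. Records
from the held-out era are tagged validation and touched by neither. The
split is reproducible bit-for-bit under a fixed seed.

## GA attribute selection

Chromosomes are bit masks over the candidate attributes (at least one bit
set, enforced by repair). Fitness is the testing-set AUC of a naive Bayes
model fitted on the training set with the masked attributes. Search
settings default to population 80, 100 generations, crossover 95%,
mutation 5%, 5 restarts; the published work states these rates but not the
operators, so the canonical bit-string choices are used:

* **single-point crossover** at a uniform cut;
* **per-bit mutation** — the 5% rate is read per bit, giving ≈ 2.65
  expected flips on a 53-bit mask;
* **roulette-wheel** (fitness-proportional) parent selection with full
  generational replacement;
* **initial bit density 0.5**;
* **elitism 1** — added so the per-run best fitness is provably
  non-decreasing; set `elitism = 0` for a strictly generational scheme;
* restarts use seeds `seed, seed + 1, …`, holding the split fixed (the
  restarts differ only in their starting populations);
* ties between equally fit subsets break towards fewer attributes, then
  the earlier run — smaller models are preferred at equal discrimination.

A degenerate chromosome (e.g. an attribute entirely missing within a
class) scores fitness 0 with a logged message rather than aborting the
run. Fitness values are memoised per mask — fitness is deterministic given
the split — which speeds up converged populations without touching the
random stream, so results are bit-reproducible under a fixed seed. The
final published predictor set was refined from the GA output by expert
clinical assessment; that step is judgement, not computation, so the
package exposes it only as a user-supplied subset to `nb_fit()`.

## Evaluation

`roc_auc()` integrates the empirical ROC curve trapezoidally, giving tied
scores half credit; this equals the Mann–Whitney pair concordance, and a
property test verifies the equality to 1e-12 against an exhaustive
pair-enumeration oracle (and against an independent ROC implementation).
Sensitivity is the proportion of true negative-rechallenge cases called
negative; specificity the proportion of true positive-rechallenge cases
called positive. Percentages are displayed rounded but stored at full
precision. Whether the originally reported AUC used trapezoidal or step
integration is unverifiable without the original validation data; the
difference vanishes when scores are tie-free.

## The synthetic cohort generator

Because the original 46-patient cohort is not deposited, `cohortsim`
provides the test bed. `published_spec()` carries the released model's
class-conditional statistics: Gaussians for age, albumin, RBC and platelet
levels and proportions for the drug and abnormal-lab flags, with class
sizes 17 negative / 18 positive inferred from the unit fractions in the
proportion columns (0.059 = 1/17, 0.056 = 1/18, 0.278 = 5/18). Two
numerical details:

* the printed drug proportion columns sum to 1.001 and 1.002 (3-decimal
  rounding of counts over 17 and 18); the spec renormalises each vector so
  probability tables are exact, shifting each entry by at most 0.2% and
  leaving exact zeros untouched;
* continuous draws are resampled onto physiological support (age ≥ 18
  years, laboratory values > 0), because the printed Gaussians place
  non-trivial mass below zero for platelets. Resampling means the
  *sampled* population is the truncated Gaussian: its mean exceeds the
  printed parameter by about 0.8 years for age and 6 units for platelets.
  Parameter-recovery tests therefore check fitted moments against the
  closed-form truncated-normal mean implied by the printed parameters —
  the printed values remain the generating parameters, and the oracle
  accounts exactly for the support restriction.

What the generator deliberately does **not** emulate: correlations between
attributes (only marginals are published, and the classifier assumes
independence anyway), real missingness patterns, era effects between the
development and validation years, and the unknown composition of the
24-case training subset. Passing tests therefore demonstrate that the
machinery is correct under the published marginal structure — not that the
published external-validation performance (AUC 0.767 on 11 held-out cases)
is reproducible, which would require the undeposited patient data. Indeed
the published model scored on cohorts drawn from its own spec is
optimistic (resubstitution-style AUC ≈ 0.9–0.97 across seeds).

## Problem sizes used by the test suite

Chosen as the package's own verification scale: parameter recovery uses
10,000 records per class (standard errors small enough that a 3-SE band is
a sharp check); the AUC equivalence property runs 200 random instances up
to n = 200; the GA planted-signal check uses a 100-record cohort with one
perfectly separating binary attribute among 20 standard-normal noise
attributes, searched at the default settings from five independent seeds
(the planted attribute makes any containing subset score AUC 1 under
`alpha = 0`, so recovery isolates the search machinery from sampling
noise).

## Known limitations

* The development cohort behind the published parameters is tiny (35
  cases) and not public; the packaged model is a reconstruction from the
  published distribution table, labelled as such, not the original fitted
  object.
* `alpha = 0` makes unseen categories decisive at prediction time; for
  prospective use switch to `alpha = 1`.
* No confidence intervals on AUC are produced, and no probability
  calibration is applied to the posterior scores.
* Only two outcome classes are supported, and the comorbidity count is
  modelled as Gaussian when selected, which is a coarse approximation for
  a small count variable.
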