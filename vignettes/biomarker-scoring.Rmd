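---
title: "Scoring biomarker reporting completeness: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring biomarker reporting completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmtoolkit)
```

This vignette is the package's account of its science: what is being
modelled, which knobs exist and why their defaults are what they are,
which design decisions were genuinely open, and what the validation suite
does and does not demonstrate.

## The problem and the model

A biomarker's published evidence base can be audited against a checklist
of attributes associated with successful clinical translation. The
checklist is hierarchical: four categories — analytical validity (assay
performance and specimen handling), clinical validity (study design and
statistical evaluation), clinical utility (real-world value:
cost-effectiveness, feasibility, guideline approval) and rationale (the
unmet clinical need) — each split into sub-categories, each sub-category
holding one or more concrete attributes.

Scoring is deliberately binary: an attribute is either reported in a
publication (1) or it is not (0). Binary indicators keep the protocol
auditable by independent raters ([`dual_rater_check()`]) and avoid
graded judgements that invite assessor bias. The category score of a
publication is the *flat* mean over all attributes in the category, not
the mean of sub-category means: sub-categories differ in size, and the
flat mean weights every attribute equally, which is the stated intent of
equal-weight scoring. Sub-category means are still computed, but only to
drive gap reports.

Biomarker-level category scores are unweighted means over the biomarker's
publications. Two further steps produce the headline number:

1. **Clinical-utility amendment.** Clinical publications cannot show
   whether cost-effectiveness, feasibility, human-factor, implementation,
   decisional-analysis or clinical-usefulness studies exist for the
   biomarker; those live in separate literatures. The amendment pushes
   the biomarker-level mean CU score convexly towards 1:
   \(\mathrm{CU}^* = s + w\,(k/K)\,(1-s)\), where \(k\) of the \(K = 6\)
   amendable study types are present and \(w \in [0,1]\) (default 0.5).
   This form was chosen because it satisfies every property the
   procedure requires — it returns the unamended score when no
   additional study types exist, is monotone in \(k\), never exceeds 1,
   and never decreases the score — while remaining a single interpretable
   parameter. It is exposed through `amendment_weight` /
   `amendable_types` so that a different amendment rule can be dropped
   in without touching the rest of the pipeline.
2. **Total score.** \(100 \sum_c w_c s_c\) over the included categories.
   The default includes AV, CV and amended CU with equal weights and
   excludes rationale: when biomarkers of the same disease are compared,
   rationale attributes are near-constant and contribute no
   discriminating signal (they can be re-included with
   `include_rationale = TRUE`).

### Order of operations

Whether the CU amendment should happen per publication or once per
biomarker is genuinely open. The package amends **once, at biomarker
level**, after averaging the per-publication CU scores, because the
study-type inventory is a property of the biomarker's whole literature,
not of any single clinical paper. Amending per publication with a
biomarker-level inventory would simply apply the same affine map before
instead of after averaging — identical for fixed \(k\) — so the choice
only matters if inventories are ever publication-specific; the
biomarker-level reading is the coherent one for that case too.

### Missing indicators

The protocol is strictly binary, so the default `na_policy = "as_zero"`
treats an unrecorded attribute as not reported. `"exclude"` removes `NA`
attributes from the denominator instead; it exists for attributes that
are structurally inapplicable to a corpus (e.g. animal-experiment
details in a purely clinical literature), where counting them as zero
would penalise every publication identically and compress scores.

## The checklist fixtures

`initial_checklist()` carries the reference topology: 129 attributes in
48 sub-categories with category counts 51 / 49 / 25 / 4. The attribute
*labels* are synthetic placeholders (the full attribute wording is not
part of the package); the *topology* is exact, which is what every
numeric behaviour depends on. Shares are computed by exact arithmetic
with half-up rounding to 2 decimal places: 51/129 = 39.53%,
49/129 = 37.98%, 25/129 = 19.38%, 4/129 = 3.10%. (Note 51/129 rounds to
39.53, not 39.54 — the package reports the exact value.)

`toolkit_v1()` applies the consensus revision: three interview-derived
attributes added (reimbursement, family applicability, automated
assessment — under existing cost-effectiveness, human-factor and
feasibility sub-categories) and the six Delphi-failed attributes removed,
giving 126 attributes in 47 sub-categories. Which sub-category is emptied
by the removals is not determined by the arithmetic; the fixture
designates the single-attribute "Experimental Animal Details"
sub-category, and documents the choice as arbitrary.

## Delphi consensus

`run_round()` computes per-item agreement (agree votes / votes cast) and
partitions items at the consensus threshold (default 0.75). Three
conventions needed fixing:

- **The boundary is inclusive** (`agreement >= threshold`): an item with
  3 agreements out of 4 meets a 75% level. This is configurable via
  `threshold`.
- **Consensus rate is item-wise**: the share of items reaching the
  threshold. In the packaged two-round fixture, 43 of 51 items pass
  round 1 (84.31%), 8 are carried, 2 recover in round 2 and 6 are
  removed. Participant-level agreement summaries (e.g. the mean
  agreement across items) are a different quantity and will generally
  differ from the item-wise rate; the package reports the item-wise
  definition because it is the one the retention rule acts on.
- **Likert collapsing** happens before construction: by convention the
  top two boxes of a response scale count as agreement.

`rank_weights()` converts category rank responses into weights by the
linear inverse-rank map \(w_c \propto m + 1 - \tilde r_c\) on the
per-category median rank, with the **lower-median** convention for even
participant counts (medians stay attainable ranks rather than
half-integers). Linear inversion was chosen over alternatives (e.g.
Borda-style or reciprocal-rank weights) for monotonicity and
transparency. Weighted and equal-weight totals differ little in practice,
and weights add interpretive complexity, so the pipeline defaults to
unweighted scoring; the weights path exists for sensitivity analyses.

## Group comparison

Successful-vs-stalled score comparisons use the Mann-Whitney U test.
Score distributions are bounded, often skewed and frequently tied, so the
rank test is the sensible default and is applied outright (no
normality pre-test gates the choice). Contracts worth stating:

- **Exact mode** computes the permutation null of the rank sum,
  including under ties, via a generating-function count over doubled
  midranks (counts, not samples — the p-value is exact). `mode = "auto"`
  uses it for tie-free samples with \(n_1 + n_2 \le 20\); it accepts up
  to \(n_1 + n_2 = 30\), beyond which subset counts grow past what is
  worth enumerating and the approximation is amply accurate.
- **Approximate mode** uses the normal approximation with tie-corrected
  variance and a 0.5 continuity correction; when every pooled value is
  tied the variance is zero and the p-value is 1 by convention.
- The two-sided p-value is \(\min(1,\, 2\min(P(U \le u), P(U \ge u)))\),
  and the reported two-sided statistic is \(\min(U_1, U_2)\).
- Tests are two-sided at \(\alpha = 0.05\) by default. Across
  per-category or per-endpoint tests no multiplicity adjustment is
  applied by default; Benjamini–Hochberg is available via `adjust =
  "BH"`.

`logistic_association()` delegates the maximum-likelihood fit to
iteratively reweighted least squares and adds the contracts that matter
for score covariates: complete/quasi-complete separation is detected and
flagged (rather than surfacing a huge, meaningless slope), and
zero-variance covariates are reported with a zero coefficient instead of
being dropped silently. `cox_association()` fits the partial likelihood
with Breslow tie handling and reports hazard-ratio-scale intervals. The
time axis of the survival model is deliberately **not** chosen by the
package: the user supplies the duration (e.g. years from first
publication to adoption or censoring), because no single convention is
canonical and the choice changes the estimand.

## The synthetic corpus generator

`generate_corpus()` emulates the data the scorer consumes, with the
structure the analysis assumes: each indicator is an independent
Bernoulli draw with a category- and status-specific reporting
probability; each non-clinical study type is present independently with
a status-specific probability; publication years surge a few years after
discovery. Defaults (chosen once, as plausible stylised conditions):

| parameter | successful | stalled |
|---|---|---|
| reporting probability, AV / CV / rationale | 0.8 | 0.5 |
| reporting probability, CU | 0.8 | 0.2 |
| study-type presence (per type) | 0.7 | 0.1 |
| biomarkers per group | 30 | 30 |
| publications per biomarker | 5 (fixed; Poisson option) | 5 |
| year offset from discovery | Poisson, mean 5 | same |

The stalled CU probability is far below the others because the scarcity
of clinical-utility evidence is the characteristic signature of stalled
biomarkers; the study-type gap (0.7 vs 0.1) encodes the same pattern at
inventory level. These are *synthetic* effect sizes reflecting a
qualitative pattern, not estimates of any real corpus.

What the generator does **not** emulate: correlation between attributes
within a publication (an optional per-publication "diligence" random
effect, a mean-one Beta multiplier on the reporting probabilities, is
provided to probe robustness to this assumption); selective publication;
rater error; study-type-dependent attribute applicability; real
publication-count distributions (real corpora range from ~10 to ~250
publications per biomarker). Passing tests therefore show that the
pipeline is correct and well-calibrated *under independence*, not that
real corpora will separate as cleanly.

Determinism contract: a configuration with a seed produces an identical
corpus on every run and platform, and generation restores the caller's
RNG state.

## Numerical choices

- Percentages are rounded **half-up** to 2 decimal places (base R's
  banker's rounding would turn exact .005 ties downward half the time).
- Weights passed to aggregation are renormalised to sum exactly to 1;
  equal weights and omitted weights produce bit-identical totals.
- Gap reports order ties by category order then label, so output is
  deterministic.
- Oracle-style exactness: the exact Mann-Whitney path works in integer
  counts (doubled midranks), so its p-values are exact rationals
  evaluated in double precision.

## Validation scales

The test suite and `scripts/acceptance.R` run at these problem sizes,
chosen to make Monte-Carlo bands tight enough to be meaningful:
flat-mean oracle equivalence on 1000 random checklists; exhaustive
exact-vs-enumeration agreement for all \(n_1 + n_2 \le 12\) (ties and no
ties, all three alternatives); 10,000 null replicates for the exact
test's type-I error; 1000 replicates at \(n = 500\) for logistic and Cox
coverage; 200 replicates for discrimination power; 300 for null
calibration of the full pipeline.

## Known limitations

- Scores measure reporting completeness, not biomarker performance: a
  well-reported weak biomarker outscores a badly reported strong one.
- Corpus assembly (literature search and screening) is manual and out of
  scope; the tool consumes already-assembled sheets.
- The amendment weight \(w = 0.5\) is a modelling default, not an
  estimate; sensitivity to it should be reported alongside results.
- The reference fixtures carry synthetic attribute labels; analyses of
  real corpora should load a full checklist definition document.
- Rationale scoring is supported but excluded from totals by default;
  comparative use of rationale attributes across disease areas is
  untested territory.
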