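---
title: "Probability-based shift-work exposure assessment and weight-status analysis"
author: "shiftjem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based shift-work exposure assessment and weight-status analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftjem)
```

## The problem

Questionnaires in many epidemiologic studies never ask about shift work
directly. When occupation is recorded, a job-exposure matrix (JEM) can stand
in for the missing question: tabulate, in a large labour survey, the
proportion of workers in each sex x occupation-code cell who hold regular
evening, night, or rotating schedules for more than 20 hours per week, and
assign that proportion — the probability of shift work, `P` — to every study
participant with that occupation code. `shiftjem` implements this exposure
assessment end to end, together with the downstream analysis it was built
for: the association between shift-work probability and overweight/obesity
in working women, estimated by baseline-category (polytomous) logistic
regression.

Because the source microdata (the labour-survey extract and the two study
samples) are confidential, the package ships a synthetic-data generator that
emulates their statistical structure with known ground truth, so every stage
— tabulation, suppression, hierarchical linkage, BMI handling, confounder
selection, model fitting — is testable without any external data.

## The exposure model

**Shift-worker definition.** A survey respondent is a shift worker iff their
schedule is regular evening, regular night, or rotating *and* their usual
hours exceed 20 h/week. Both conditions are read literally: exactly 20 h
does not qualify.

**Tabulation and suppression.** Counts and proportions are tabulated per
sex at two hierarchy levels: specific 4-character occupation codes and broad
2-character codes (the leading two characters, which identify the major
group in hierarchical occupation classifications). To protect
confidentiality, a cell's `P` value is concealed when the cell has fewer
than 25 workers, or fewer than 5 shift workers with fewer than 100 workers.
All three comparisons are strict (`< 25`, `< 5`, `< 100`), so the retained
boundary cases are exactly (25 workers, 5 shift) and (100 workers, any
shift count). Tabulation is unweighted — one record, one count; the package
makes no claim about survey weights because the tool it emulates documents
none.

**Linkage with fallback.** A current worker links to the specific-level `P`
of their 4-character code when it is retained. When it is suppressed — or
absent from the table, which is indistinguishable from the consumer's side —
the default `fallback` strategy retries with the broad code; the
`four_digit_only` strategy (a sensitivity analysis) does not. Workers whose
reports were too vague for any code, or whose codes fail both lookups, form
a `missing_p` category; non-current workers form `not_working`. Both are
kept as separate regression dummies rather than pooled, so each retains its
own comparison against the reference.

**Categorization.** `P` is cut into near nil (`< 1.5%`), low (`1.5% to
< 10%`), medium (`10% to < 45%`) and high (`45%+`), each boundary belonging
to the upper category. The cut-points are compared on the proportion scale
(0.015, 0.10, 0.45) and every boundary is unit-tested from both sides at
±1e-9.

## Outcomes

BMI is weight (kg) / height (m)². Before classification the outermost 0.2%
of weight and of height are trimmed. The total fraction is split
symmetrically, 0.1% per tail — the standard reading of a single "outermost"
fraction — and the rule is an order-statistic one: with
`k = floor(n * fraction / 2)`, values strictly beyond the `(k+1)`-th order
statistic in either tail are flagged, so at most `k` values go per tail, a
constant sample is never trimmed, and the behaviour is exactly reproducible
across platforms. The per-tail split is a parameter, so the asymmetric
reading (0.2% per tail) can be explored. A participant trimmed on either
measurement is excluded from classification. WHO classes follow: normal /
underweight `BMI < 25`, overweight `25 <= BMI < 30`, obese `BMI >= 30`.

## The regression model

Weight class (reference = normal/underweight) is regressed on exposure
category (reference = near nil, dummies for low, medium, high, missing-P,
not-working) and covariates by the baseline-category multinomial logit.
The fitter is written in-package: full Newton iteration on the stacked
score with step-halving, run to a gradient max-norm of 1e-10 (capped at 100
iterations), with the covariance taken as the inverse observed information.
Model-based (not robust) covariance is used, matching the conventional Wald
intervals reported in this literature; CIs are `exp(coef ± 1.96·SE)` and
p-values two-tailed Wald at α = 0.05. A likelihood-ratio route (`lr_test`)
is available as a secondary statistic. Three oracles pin the fitter down in
the tests: on a two-group table it must reproduce the closed-form
cross-product ratios to 1e-6; with a two-level outcome it must match
`glm(family = binomial)` to 1e-8; and on three-level data it must agree
with an independent multinomial implementation.

Rows with any missing model variable are dropped (complete case). An
exposure level with an empty outcome cell is inestimable (its coefficient
diverges), so such levels are excluded from estimation with a message —
mirroring the low-cell-count removal practised in the original analyses —
rather than being allowed to destabilize the fit.

**Confounder selection.** Candidates from the descriptive-table variable
list (age, education, race, marital status, parity, smoking, calories,
alcohol, physical activity) enter by forward selection under the 10.0%
change-in-estimate criterion. Three design points were genuinely open and
are resolved as follows. (1) *Which parameter is "the parameter of
interest"?* The full set of informative exposure ORs — low, medium, high,
both outcome contrasts — aggregated by the maximum, so every reported
contrast is protected. (2) *Which scale?* The OR scale by default
(`|OR_with − OR_without| / OR_without`), the conventional epidemiologic
reading, and the one that avoids dividing by near-zero log-odds; the
log-odds scale is an option. (3) *Is age force-entered?* No: age is listed
among the assessed variables, so it competes like any candidate. Ties break
by candidate order; a candidate whose trial fit is singular or
non-convergent is skipped that round with a warning. The realized covariate
sets of the original analyses cannot be re-derived without the raw data, so
the package validates the *procedure* (a constructed confounder moving an
exposure OR by ≥ 10% is admitted; independent covariates never are), not
any particular selected set.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is validated under.

*Survey arm.* 12,500 female respondents (the size of the labour-survey
extract behind the original tool) across 13 occupation codes whose shift
propensities (0.005–0.72) span all four categories, weighted so the realized
cells resemble a clerical/teaching/retail/nursing workforce. Respondents
draw a shift schedule with probability equal to their code's propensity —
split uniformly across evening/night/rotating, which the downstream
definition never distinguishes — and hours from N(37.5, 7.5²) truncated at
0. Three codes are deliberately rare: one falls under the 25-worker
threshold but belongs to a retained broad group (exercising fallback), and
two are concealed at both levels (exercising missing-P). Because ~1% of
hours draws fall at or below 20 h, realized `P` values sit a hair below the
configured propensities; the category assignments derive from the realized
JEM, so all downstream ground truth stays internally consistent.

*Study arm.* 3,377 women, category mix proportional to the published
population-based sample including its non-working group
(182/660/434/112/223 current workers + 1,766 non-workers). Each current
worker in an exposure category receives an occupation code drawn from the
JEM codes whose post-fallback `P` lies in that category (weighted by cell
size); 8% of near-nil/low/medium workers report only their broad code (the
high group always carries specific codes, matching the observed pattern
that every high-probability participant linked at four digits); missing-P
participants split between unreported occupations, an unknown broad group,
and codes concealed at both levels. Weight class is drawn from the
baseline-category logit with intercepts giving the published near-nil class
split (50/33/17) and exposure log-odds defaulting to the published adjusted
estimates (e.g. obese OR 1.88, high vs near nil). Covariate marginals copy
the published descriptive table; all covariate effects default to zero, and
confounding is induced on demand by per-category tilts plus outcome
effects. Continuous covariate effects are per SD of the centred value, so
intercepts keep their interpretation.

*Anthropometry back-solving.* Height ~ N(1.63 m, 0.07 m), BMI uniform
within the drawn class interval (normal/underweight floored at 17.5,
obese capped at 45 kg/m²), weight = BMI × height². This guarantees that
reclassifying the emitted height/weight reproduces the drawn class for
every untrimmed record — a tested invariant — while producing realistic
marginals. Values are emitted at full precision; rounding them would break
the round-trip guarantee at class boundaries.

*Individual-exposure variant.* For the misclassification experiment, each
participant instead carries a Bernoulli true shift-work indicator with
probability equal to their code's `P` (0 for non-workers, 0.1 for
missing-P), and the outcome is driven by that indicator with a configured
individual-level OR. Analysing such data by category — the only analysis
the tool permits — attenuates the estimate toward the null; the experiment
measures by how much.

*What the generator does not emulate:* panel structure and survey weights
of the labour survey, free-text occupation reports and their manual coding,
self-report bias in height/weight, and any real occupation dictionary (the
code alphabet is arbitrary). Passing tests therefore demonstrate that the
pipeline's logic and estimators behave correctly under the stated
statistical structure — not that the original studies' data met that
structure.

## Numerical choices and problem sizes

Convergence: gradient max-norm ≤ 1e-10, ≤ 100 Newton iterations,
step-halving guaranteeing a monotone likelihood (a tested invariant).
Display rounding is half-up (1 decimal for descriptive percentages,
integers for regression-table row percentages, with the sum of non-missing
class counts as denominator); persisted CSVs keep full precision via
`%.17g`, so a pipeline stage re-run from its persisted inputs reproduces
downstream artifacts exactly, and a fixed seed makes runs byte-identical.

Simulation sizes are chosen to keep the whole suite fast while leaving the
Monte-Carlo error well inside the asserted tolerances: parameter recovery
uses 200 replicates at n = 5,000 (mean log-OR within ±0.05 of log 1.88,
coverage in [92%, 98%]); attenuation 100 replicates at n = 4,000 (the
spec-free sample size chosen to match the study scale); null-model and
selection properties use 3–120 replicates at n = 1,500–6,000.

## Known limitations

- The published *adjusted* ORs are not reproducible here: they required the
  confidential individual-level data. The package instead reproduces every
  quantity computable from the published counts (percentages; crude ORs,
  e.g. (28×90)/(48×31) ≈ 1.69 for obesity in the high group) and validates
  the estimation machinery by simulation.
- Exposure is a group-level probability; the attenuation experiment
  quantifies, but does not correct, the resulting bias toward the null.
- Single-sex (female) generation; the JEM API carries sex so the
  sex-specific tabulation contract is honoured, but no male fixtures exist.
- No survey-weighted estimation, ordinal/continuous-BMI models, or exact
  small-sample inference.
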