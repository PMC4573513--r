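# shiftjem

Probability-based shift-work exposure assessment and weight-status analysis
for occupational epidemiology.

Many questionnaires record occupation but never ask about shift work.
`shiftjem` implements the standard workaround end to end: a job-exposure
matrix (JEM) that tabulates, from labour-survey records, the proportion
*P*<sub>shift work</sub> of workers in each sex × occupation-code cell who
hold regular evening, night, or rotating schedules for more than 20 h/week
— with small-cell confidentiality suppression (*P* concealed when a cell
has < 25 workers, or < 5 shift workers with < 100 workers) and hierarchical
fallback from specific 4-character codes to broad 2-character codes when
the specific value is concealed. Participants are categorized as near nil
(*P* < 1.5%), low (1.5 to < 10%), medium (10 to < 45%) or high (45%+)
probability of shift work, plus missing-*P* and non-working comparison
groups.

Downstream, the package computes BMI (kg/m²) from height and weight, trims
the outermost 0.2% of each measurement, classifies weight status at the
WHO cut-offs (25, 30), selects confounders by forward selection under the
10.0% change-in-estimate criterion, and fits the baseline-category
(polytomous) logistic regression

> log [ P(class = *j*) / P(class = normal) ] = **x**′β<sub>*j*</sub>,  *j* ∈ {overweight, obese},

by full Newton iteration with step-halving, reporting odds ratios,
exp(β ± 1.96·SE) Wald intervals, and two-tailed p-values (α = 0.05).
A synthetic-data generator emulates the labour survey and the study samples
with known ground truth (configurable exposure ORs, confounder structure,
suppression-triggering small cells), so the whole pipeline — including an
exposure-misclassification attenuation experiment — is testable with no
external data. It is aimed at occupational epidemiologists who want a
tested, reproducible implementation of this exposure-assessment design.

## Worked example

The published per-category weight-class counts ship with the package; an
exposure-only fit on the near-nil and high cells of the population-based
sample is saturated, so its ORs equal the closed-form cross-product ratios:

```r
library(shiftjem)
f <- fit_crude_from_counts(reference_class_counts("population"),
                           groups = c("near_nil", "high"))
f
#> Weight-class model: n = 6, covariates: (none)
#>    contrast         term estimate    se    or ci_low ci_high p_value
#>  overweight categoryhigh    0.061 0.279 1.062  0.615   1.837  0.8280
#>       obese categoryhigh    0.527 0.316 1.694  0.911   3.147  0.0956
```

The crude obese OR 1.694 is exactly (28×90)/(48×31) from the printed
counts (the published *adjusted* OR for this contrast, 1.88, required the
confidential individual-level data and is not reproducible from counts).

A full synthetic run — simulate survey, build and suppress the JEM,
simulate the study, link exposure, compute outcomes, select confounders,
fit, and report:

```r
rb <- run_pipeline(run_config(survey = survey_config(n_respondents = 8000),
                              study = study_config(n_participants = 1500),
                              seed = 11))
rb$flow$n_current_workers
#> [1] 692
rb$fit
#> Weight-class model: n = 1496, covariates: (none)
#>    contrast                term estimate    se    or ci_low ci_high p_value
#>  overweight         categorylow   -0.279 0.266 0.757  0.449   1.274  0.2940
#>  ...
#>       obese        categoryhigh    0.099 0.542 1.104  0.381   3.196  0.8550
```

The high-group obese OR here is noisy because a 1,500-person sample holds
only ~50 high-probability workers; the parameter-recovery experiment
(`recovery_experiment()`, 200 replicates at n = 5,000) shows the estimator
is unbiased with ~95% CI coverage under the generating OR of 1.88.

The numbered drivers under `analysis/` run the same stages as a narrated
workflow (`01_simulate_survey.R` … `07_misclassification.R`), writing their
tables under `results/`.

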