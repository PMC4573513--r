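#!/usr/bin/env Rscript
# Simulate the labour survey the exposure tool is tabulated from:
# 12,500 female respondents across occupation codes whose shift propensities
# span the four exposure categories, including rare codes that will fall
# under the disclosure thresholds.
suppressPackageStartupMessages(library(shiftjem))

dir.create("results", showWarnings = FALSE)
cfg <- survey_config(seed = 20251)
survey <- generate_survey(cfg)
shiftjem:::write_precise_csv(survey, "results/survey.csv")

shift_sched <- survey$schedule %in% c("regular_evening", "regular_night", "rotating")
cat(sprintf("Simulated %d survey respondents over %d occupation codes.\n",
            nrow(survey), length(unique(survey$occupation_code))))
cat(sprintf("%.1f%% hold a shift schedule; %.1f%% meet the full shift-worker definition (>20 h/week).\n",
            100 * mean(shift_sched),
            100 * mean(classify_shift_worker(survey$schedule, survey$weekly_hours))))
jsonlite::write_json(list(seed = cfg$seed, n_respondents = cfg$n_respondents),
                     "results/survey_provenance.json", auto_unbox = TRUE)
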