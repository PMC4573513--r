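#!/usr/bin/env Rscript
# Compute BMI from height and weight, trim the outermost 0.2% of each
# measurement, and classify weight status by the WHO cut-offs.
suppressPackageStartupMessages(library(shiftjem))

study <- read.csv("results/study.csv",
                  colClasses = c(participant_id = "character",
                                 occupation_code = "character"))
bmi <- bmi_outcomes(study, trim_fraction = 0.002)
shiftjem:::write_precise_csv(
  transform(bmi, weight_class = as.character(weight_class)), "results/bmi.csv")

cat(sprintf("BMI computed for %d participants; %d trimmed as outliers.\n",
            sum(!is.na(bmi$bmi)), sum(bmi$trimmed)))
print(table(bmi$weight_class))
cat(sprintf("Mean BMI %.1f (SD %.1f).\n", mean(bmi$bmi, na.rm = TRUE),
            sd(bmi$bmi, na.rm = TRUE)))
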