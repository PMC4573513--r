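#!/usr/bin/env Rscript
# Build the probability-of-shift-work job-exposure matrix at the specific
# (4-character) and broad (2-character) code levels and apply the
# small-cell confidentiality suppression rule.
suppressPackageStartupMessages(library(shiftjem))

survey <- read.csv("results/survey.csv",
                   colClasses = c(occupation_code = "character"))
jem <- build_jem(survey)
write_jem_csv(jem$specific, "results/jem_specific.csv")
write_jem_csv(jem$broad, "results/jem_broad.csv")

for (lv in c("specific", "broad")) {
  cells <- jem[[lv]]$cells
  cat(sprintf("%s level: %d codes, %d suppressed (<25 workers, or <5 shift workers with <100).\n",
              lv, nrow(cells), sum(cells$suppressed)))
}
ret <- jem$specific$cells[!jem$specific$cells$suppressed, ]
cat("Retained specific-level P values span",
    sprintf("%.3f-%.3f", min(ret$p_shift), max(ret$p_shift)),
    "across categories:", paste(sort(unique(categorize_p(ret$p_shift))), collapse = ", "), "\n")
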