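# Shared fixtures, built in code. The default JEM pair is moderately sized
# and reused across files through a per-session cache.

local_jem_cache <- new.env(parent = emptyenv())

default_test_jem <- function() {
  if (is.null(local_jem_cache$jem)) {
    sv <- generate_survey(survey_config(n_respondents = 12500, seed = 101))
    local_jem_cache$jem <- build_jem(sv)
  }
  local_jem_cache$jem
}

# survey records built by hand: one row per (code, schedule, hours) spec
make_survey_records <- function(codes, schedules, hours, sex = "female") {
  n <- max(length(codes), length(schedules), length(hours))
  data.frame(person_id = sprintf("S%03d", seq_len(n)), sex = rep_len(sex, n),
             occupation_code = rep_len(codes, n),
             weekly_hours = rep_len(hours, n),
             schedule = rep_len(schedules, n),
             stringsAsFactors = FALSE)
}

# a jem_table straight from cell counts (for boundary tests)
make_jem_table <- function(codes, n_total, n_shift, level = "specific",
                           sex = "female") {
  structure(list(level = level, sex = sex,
                 cells = data.frame(code = codes, n_total = n_total,
                                    n_shift = n_shift,
                                    p_shift = n_shift / n_total,
                                    suppressed = FALSE,
                                    stringsAsFactors = FALSE)),
            class = "jem_table")
}

make_study_records <- function(ids, employment = "current", code = NA,
                               height = 1.63, weight = 65) {
  n <- length(ids)
  data.frame(participant_id = ids,
             employment_status = rep_len(employment, n),
             occupation_code = rep_len(code, n),
             height = rep_len(height, n), weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}

# exposure/outcome frame for model tests, bypassing anthropometry
model_frame_from_study <- function(st) {
  cats <- intersect(c("near_nil", "low", "medium", "high", "missing_p",
                      "not_working"), unique(st$true_exposure_category))
  data.frame(category = factor(st$true_exposure_category, levels = cats),
             weight_class = factor(st$drawn_class,
                                   levels = c("normal_under", "overweight", "obese")))
}

# random 2 x 3 contingency counts in the reference-counts shape
random_counts_frame <- function(groups = c("near_nil", "high"),
                                min_cell = 1, max_cell = 60) {
  data.frame(group = groups,
             n_normal = sample(min_cell:max_cell, length(groups), TRUE),
             n_overweight = sample(min_cell:max_cell, length(groups), TRUE),
             n_obese = sample(min_cell:max_cell, length(groups), TRUE),
             stringsAsFactors = FALSE)
}
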