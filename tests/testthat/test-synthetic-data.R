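test_that("config validation names the offending field", {
  expect_error(survey_config(n_respondents = 0), "n_respondents")
  expect_error(survey_config(code_profiles = data.frame(
    code = "A123", weight = 1, propensity = 1.2)), "propensity")
  expect_error(survey_config(code_profiles = data.frame(
    code = "A123", weight = -1, propensity = 0.5)), "weight")
  expect_error(survey_config(code_profiles = data.frame(
    code = "A12", weight = 1, propensity = 0.5)), "4-character")
  expect_error(study_config(category_mix = c(near_nil = 0.5, low = 0.4,
                                             medium = 0.2, high = 0, missing = 0,
                                             not_working = 0)), "sum to 1")
  expect_error(study_config(category_mix = c(near_nil = 1)), "category_mix")
})

test_that("a fixed seed reproduces the generated data exactly", {
  cfg <- survey_config(n_respondents = 2000, seed = 33)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  jem <- default_test_jem()
  scfg <- study_config(n_participants = 500, seed = 34)
  expect_identical(generate_study(scfg, jem), generate_study(scfg, jem))
  expect_identical(generate_true_exposure_variant(scfg, jem),
                   generate_true_exposure_variant(scfg, jem))
})

test_that("degenerate propensities produce no / only shift schedules", {
  cp0 <- data.frame(code = "A111", weight = 1, propensity = 0)
  sv0 <- generate_survey(survey_config(n_respondents = 500, code_profiles = cp0,
                                       seed = 1))
  expect_false(any(sv0$schedule %in% c("regular_evening", "regular_night",
                                       "rotating")))

  cp1 <- data.frame(code = "A111", weight = 1, propensity = 1)
  sv1 <- generate_survey(survey_config(n_respondents = 500, code_profiles = cp1,
                                       hours_mean = 40, hours_sd = 0, seed = 2))
  expect_true(all(sv1$schedule %in% c("regular_evening", "regular_night",
                                      "rotating")))
  # all downstream-classified shift workers at fixed 40 h/week
  expect_true(all(classify_shift_worker(sv1$schedule, sv1$weekly_hours)))
  tb <- apply_suppression(tabulate_jem(sv1))
  expect_equal(tb$cells$p_shift, 1)
})

test_that("per-code schedule proportions recover the configured propensities", {
  cp <- data.frame(code = c("A111", "B222", "C333", "D444"),
                   weight = c(1, 1, 1, 1),
                   propensity = c(0.005, 0.05, 0.25, 0.6))
  sv <- generate_survey(survey_config(n_respondents = 20000, code_profiles = cp,
                                      seed = 77))
  shift_sched <- sv$schedule %in% c("regular_evening", "regular_night", "rotating")
  prop <- tapply(shift_sched, sv$occupation_code, mean)
  expect_true(all(abs(prop[cp$code] - cp$propensity) < 0.02))
})

test_that("study category mix is recovered within Monte-Carlo error", {
  jem <- default_test_jem()
  cfg <- study_config(n_participants = 10000, seed = 55)
  st <- generate_study(cfg, jem)
  mix <- cfg$category_mix
  names(mix)[names(mix) == "missing"] <- "missing_p"
  obs <- table(st$true_exposure_category)[names(mix)] / nrow(st)
  se <- sqrt(mix * (1 - mix) / nrow(st))
  expect_true(all(abs(obs - mix) <= 3 * se))
})

test_that("missing-category participants have unlinkable occupation reports", {
  jem <- default_test_jem()
  mix <- c(near_nil = 0.2, low = 0.2, medium = 0.2, high = 0.2,
           missing = 0.1, not_working = 0.1)
  st <- generate_study(study_config(n_participants = 4000, category_mix = mix,
                                    seed = 56), jem)
  frac <- mean(st$true_exposure_category == "missing_p")
  expect_lt(abs(frac - 0.1), 0.02)
  a <- link_exposure(st, jem$specific, jem$broad)
  expect_true(all(a$category[st$true_exposure_category == "missing_p"] == "missing_p"))
  # and conversely every drawn category is reproduced by linkage
  expect_identical(as.character(a$category), st$true_exposure_category)
})

test_that("emitted height/weight reproduce the drawn class for all untrimmed records", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 5000, seed = 57), jem)
  res <- bmi_outcomes(st)
  untr <- !res$trimmed
  expect_identical(as.character(res$weight_class[untr]), st$drawn_class[untr])
})

test_that("null outcome effects give class proportions independent of category", {
  jem <- default_test_jem()
  null_lo <- list(
    overweight = c(low = 0, medium = 0, high = 0, missing_p = 0, not_working = 0),
    obese = c(low = 0, medium = 0, high = 0, missing_p = 0, not_working = 0))
  st <- generate_study(study_config(n_participants = 10000,
                                    true_log_odds = null_lo, seed = 58), jem)
  tab <- table(st$true_exposure_category, st$drawn_class)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("a configured obese effect appears in the crude cross-product OR", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 10000, seed = 59), jem)
  tab <- table(st$true_exposure_category, st$drawn_class)
  crude <- (tab["high", "obese"] * tab["near_nil", "normal_under"]) /
    (tab["high", "normal_under"] * tab["near_nil", "obese"])
  expect_lt(abs(crude - 1.88), 0.3)
})

test_that("individual-exposure variant honours degenerate code probabilities", {
  # propensity 0: nobody truly exposed; propensity 1 (fixed hours): everyone
  for (spec in list(list(p = 0, expect = 0), list(p = 1, expect = 1))) {
    cp <- data.frame(code = "A111", weight = 1, propensity = spec$p)
    sv <- generate_survey(survey_config(n_respondents = 500, code_profiles = cp,
                                        hours_mean = 40, hours_sd = 0, seed = 3))
    jem <- build_jem(sv)
    mix <- c(near_nil = 0, low = 0, medium = 0, high = 0, missing = 0,
             not_working = 0)
    mix[if (spec$p == 0) "near_nil" else "high"] <- 1
    st <- generate_true_exposure_variant(
      study_config(n_participants = 300, category_mix = mix, seed = 4), jem)
    expect_true(all(st$true_shift_indicator == spec$expect))
  }
})
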