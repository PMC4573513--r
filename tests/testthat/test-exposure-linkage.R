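test_that("category cut-points map each boundary to the upper category", {
  expect_identical(categorize_p(0.014), "near_nil")
  expect_identical(categorize_p(0.015), "low")
  expect_identical(categorize_p(0.0999), "low")
  expect_identical(categorize_p(0.10), "medium")
  expect_identical(categorize_p(0.4499), "medium")
  expect_identical(categorize_p(0.45), "high")
  expect_identical(categorize_p(0), "near_nil")
  expect_identical(categorize_p(1), "high")
  # both sides of every boundary at +/- 1e-9
  for (b in c(0.015, 0.10, 0.45)) {
    expect_true(categorize_p(b - 1e-9) != categorize_p(b))
    expect_identical(categorize_p(b + 1e-9), categorize_p(b))
  }
  expect_error(categorize_p(-0.01), "domain error")
  expect_error(categorize_p(1.01), "domain error")
})

test_that("categorization is monotone non-decreasing in p", {
  p <- seq(0, 1, by = 0.001)
  idx <- match(categorize_p(p), c("near_nil", "low", "medium", "high"))
  expect_true(all(diff(idx) >= 0))
})

fixture_tables <- function() {
  spec <- make_jem_table(c("D112", "D115", "Q911"),
                         n_total = c(500, 30, 10), n_shift = c(360, 2, 1))
  spec <- apply_suppression(spec)          # D115, Q911 suppressed
  spec$cells$p_shift[1] <- 0.72            # pin the worked-example value
  broad <- make_jem_table(c("D1", "Q9"), n_total = c(530, 10),
                          n_shift = c(42, 1), level = "broad")
  broad$cells$p_shift[1] <- 0.08
  broad <- apply_suppression(broad)        # Q9 suppressed
  list(spec = spec, broad = broad)
}

test_that("linkage uses the specific value first and falls back to broad", {
  jt <- fixture_tables()
  st <- make_study_records(c("P1", "P2", "P3", "P4", "P5", "P6"),
                           employment = c("current", "current", "current",
                                          "current", "former", "current"),
                           code = c("D112", "D115", NA, "D1", "D112", "Q911"))
  a <- link_exposure(st, jt$spec, jt$broad, strategy = "fallback")
  # direct four-digit hit
  expect_equal(a$p_value[1], 0.72)
  expect_identical(a$source_level[1], "four_digit")
  expect_identical(as.character(a$category[1]), "high")
  # suppressed specific -> broad value
  expect_equal(a$p_value[2], 0.08)
  expect_identical(a$source_level[2], "two_digit")
  expect_identical(as.character(a$category[2]), "low")
  expect_true(a$specific_suppressed[2])
  # absent code -> missing
  expect_identical(as.character(a$category[3]), "missing_p")
  # two-character report links at broad level
  expect_identical(a$source_level[4], "two_digit")
  expect_identical(as.character(a$category[4]), "low")
  # former worker: not_working regardless of code
  expect_identical(as.character(a$category[5]), "not_working")
  expect_true(is.na(a$p_value[5]))
  # suppressed at both levels -> missing
  expect_identical(as.character(a$category[6]), "missing_p")

  # categories present iff a probability is present
  has_p <- !is.na(a$p_value)
  expect_true(all(a$category[has_p] %in% c("near_nil", "low", "medium", "high")))
  expect_true(all(a$category[!has_p] %in% c("missing_p", "not_working")))
})

test_that("four-digit-only strategy never consults the broad table", {
  jt <- fixture_tables()
  st <- make_study_records(c("P1", "P2", "P3"),
                           code = c("D112", "D115", "D1"))
  a <- link_exposure(st, jt$spec, jt$broad, strategy = "four_digit_only")
  expect_identical(a$source_level, c("four_digit", "none", "none"))
  expect_identical(as.character(a$category), c("high", "missing_p", "missing_p"))
})

test_that("four-digit-only assignments are the four-digit subset of fallback", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 800, seed = 21), jem)
  fb <- link_exposure(st, jem$specific, jem$broad, strategy = "fallback")
  fo <- link_exposure(st, jem$specific, jem$broad, strategy = "four_digit_only")
  fd <- fb$source_level == "four_digit"
  expect_identical(fo$source_level[fd], fb$source_level[fd])
  expect_identical(fo$p_value[fd], fb$p_value[fd])
  expect_identical(fo$category[fd], fb$category[fd])
  # everything else is unassigned under the restricted strategy
  expect_true(all(fo$category[!fd] %in% c("missing_p", "not_working")))
  # under fallback, a retained broad code always yields a category
  two <- fb$source_level == "two_digit"
  expect_true(all(fb$category[two] %in% c("near_nil", "low", "medium", "high")))
})

test_that("sex-mismatched JEM tables are refused", {
  jt <- fixture_tables()
  st <- make_study_records("P1", code = "D112")
  expect_error(link_exposure(st, jt$spec, jt$broad, sex = "male"),
               "linkage error")
})

test_that("flow accounting partitions current workers with hand-counted truth", {
  jt <- fixture_tables()
  # 10 four-digit hits, 5 broad fallbacks, 3 missing, plus 2 non-workers
  st <- make_study_records(
    sprintf("P%02d", 1:20),
    employment = c(rep("current", 18), "former", "never"),
    code = c(rep("D112", 10), rep("D115", 5), NA, "Q911", "Q9", "D112", NA))
  a <- link_exposure(st, jt$spec, jt$broad)
  fl <- flow_accounting(a, st)
  expect_equal(fl$n_current_workers, 18)
  expect_equal(fl$n_linked_four_digit, 10)
  expect_equal(fl$n_linked_two_digit, 5)
  expect_equal(fl$n_missing_p, 3)
  expect_equal(fl$n_vague_two_digit, 1)       # the absent report
  expect_equal(fl$n_vague_four_digit, 1)      # the "Q9" broad-only report
  expect_equal(fl$n_suppressed_four_digit, 6) # 5 x D115 + 1 x Q911
  expect_equal(fl$n_linked_four_digit + fl$n_linked_two_digit + fl$n_missing_p,
               fl$n_current_workers)
})

test_that("flow accounting rejects duplicate participant ids", {
  jt <- fixture_tables()
  st <- make_study_records(c("P1", "P1"), code = "D112")
  a <- link_exposure(st, jt$spec, jt$broad)
  expect_error(flow_accounting(a, st), "duplicate")
})
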