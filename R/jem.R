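#' Classify survey respondents as shift workers
#'
#' A respondent is a shift worker when they hold a regular evening, regular
#' night, or rotating schedule for more than 20 hours per week. The hours
#' threshold is strict: exactly 20 h/week does not qualify.
#'
#' @param schedule Character vector of work schedules; one of
#'   `"regular_day"`, `"regular_evening"`, `"regular_night"`, `"rotating"`,
#'   `"other"`.
#' @param weekly_hours Numeric vector of usual weekly hours (h/week, >= 0).
#' @return Logical vector, `TRUE` for shift workers.
#' @export
classify_shift_worker <- function(schedule, weekly_hours) {
  stopifnot(length(schedule) == length(weekly_hours))
  bad <- !schedule %in% SCHEDULE_LEVELS
  if (any(bad)) {
    stop("unknown schedule value(s): ", paste(unique(schedule[bad]), collapse = ", "))
  }
  if (any(!is.finite(weekly_hours)) || any(weekly_hours < 0)) {
    stop("weekly_hours must be finite and >= 0")
  }
  schedule %in% SHIFT_SCHEDULES & weekly_hours > 20
}

SCHEDULE_LEVELS <- c("regular_day", "regular_evening", "regular_night",
                     "rotating", "other")
SHIFT_SCHEDULES <- c("regular_evening", "regular_night", "rotating")

#' Map a specific occupation code to its broad code
#'
#' Occupation codes are hierarchical: the leading two characters of a
#' 4-character specific code identify the broad major group.
#'
#' @param code Character vector of occupation codes (length >= 2 each).
#' @return Character vector of 2-character broad codes.
#' @export
broad_code <- function(code) {
  if (any(is.na(code)) || any(nchar(code) < 2)) {
    stop("linkage error: occupation code shorter than 2 characters")
  }
  substr(code, 1L, 2L)
}

#' Tabulate a job-exposure matrix from survey records
#'
#' Counts total workers and shift workers per occupation code, within one
#' sex, at the specific (4-character) or broad (2-character) level, and
#' computes the proportion of shift workers `p_shift = n_shift / n_total`
#' (the P_shift-work value). Suppression is not applied here; see
#' [apply_suppression()].
#'
#' @param records Data frame of survey records with columns
#'   `sex`, `occupation_code`, `weekly_hours`, `schedule`.
#' @param level `"specific"` (codes as given) or `"broad"` (codes mapped to
#'   their 2-character prefix before counting).
#' @return A `jem_table` object: list with `level`, `sex`, and a `cells`
#'   data frame (`code`, `n_total`, `n_shift`, `p_shift`, `suppressed`).
#' @export
tabulate_jem <- function(records, level = c("specific", "broad")) {
  level <- match.arg(level)
  sex <- unique(records$sex)
  if (length(sex) > 1) {
    stop("all records in one tabulation must share the same sex; got: ",
         paste(sex, collapse = ", "))
  }
  if (nrow(records) == 0) {
    warning("tabulate_jem: empty record collection; returning empty table")
    cells <- data.frame(code = character(), n_total = integer(),
                        n_shift = integer(), p_shift = numeric(),
                        suppressed = logical(), stringsAsFactors = FALSE)
    return(structure(list(level = level, sex = if (length(sex)) sex else NA_character_,
                          cells = cells), class = "jem_table"))
  }
  code <- records$occupation_code
  if (level == "broad") code <- broad_code(code)
  shift <- classify_shift_worker(records$schedule, records$weekly_hours)
  n_total <- as.integer(table(code))
  n_shift <- as.integer(tapply(shift, code, sum))
  codes <- sort(unique(code))
  cells <- data.frame(
    code = codes,
    n_total = n_total,
    n_shift = n_shift,
    p_shift = n_shift / n_total,
    suppressed = FALSE,
    stringsAsFactors = FALSE
  )
  structure(list(level = level, sex = sex, cells = cells), class = "jem_table")
}

#' Apply confidentiality suppression to a JEM table
#'
#' A cell's P_shift-work value is concealed when there are fewer than 25
#' total workers in the occupation code, or fewer than five shift workers in
#' a code with less than 100 total workers. All comparisons are strict, per
#' the disclosure rule's wording; a cell with exactly 25 workers and 5 shift
#' workers is retained, as is one with 100 workers and any shift count.
#'
#' @param table A `jem_table` from [tabulate_jem()].
#' @return The table with `suppressed` set and `p_shift` of suppressed cells
#'   replaced by `NA` so consumers cannot read concealed values.
#' @export
apply_suppression <- function(table) {
  stopifnot(inherits(table, "jem_table"))
  cells <- table$cells
  supp <- cells$n_total < 25 | (cells$n_shift < 5 & cells$n_total < 100)
  cells$suppressed <- supp
  cells$p_shift[supp] <- NA_real_
  table$cells <- cells
  table
}

#' Build the specific/broad JEM pair from survey records
#'
#' Convenience wrapper: tabulates at both hierarchy levels and applies
#' suppression to each.
#'
#' @inheritParams tabulate_jem
#' @return List with elements `specific` and `broad`, each a suppressed
#'   `jem_table`.
#' @export
build_jem <- function(records) {
  list(
    specific = apply_suppression(tabulate_jem(records, "specific")),
    broad    = apply_suppression(tabulate_jem(records, "broad"))
  )
}

#' Look up a code in a JEM table
#'
#' @param table A `jem_table`.
#' @param code Single occupation code at the table's level.
#' @return List with `status` (`"linked"`, `"suppressed"`, or `"absent"`)
#'   and `p` (the P_shift-work value when linked, otherwise `NA`).
#' @export
jem_lookup <- function(table, code) {
  stopifnot(inherits(table, "jem_table"), length(code) == 1)
  i <- match(code, table$cells$code)
  if (is.na(i)) return(list(status = "absent", p = NA_real_))
  if (table$cells$suppressed[i]) return(list(status = "suppressed", p = NA_real_))
  list(status = "linked", p = table$cells$p_shift[i])
}

#' @export
print.jem_table <- function(x, ...) {
  cat(sprintf("Job-exposure matrix (%s level, sex = %s): %d codes, %d suppressed\n",
              x$level, x$sex, nrow(x$cells), sum(x$cells$suppressed)))
  invisible(x)
}

#' Write / read a JEM table as CSV
#'
#' Suppressed rows carry an empty `p_shift` field, emulating the concealment
#' applied to the published tabulations.
#'
#' @param table A `jem_table`.
#' @param path File path.
#' @return `write_jem_csv` returns `path` invisibly; `read_jem_csv` returns
#'   a `jem_table`.
#' @export
write_jem_csv <- function(table, path) {
  cells <- table$cells
  out <- data.frame(code = cells$code, level = table$level, sex = table$sex,
                    n_total = cells$n_total, n_shift = cells$n_shift,
                    p_shift = ifelse(cells$suppressed, "",
                                     format(cells$p_shift, digits = 17)),
                    suppressed = cells$suppressed,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_jem_csv
#' @export
read_jem_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(code = "character", p_shift = "character"))
  p <- suppressWarnings(as.numeric(raw$p_shift))
  cells <- data.frame(code = raw$code, n_total = raw$n_total,
                      n_shift = raw$n_shift, p_shift = p,
                      suppressed = raw$suppressed, stringsAsFactors = FALSE)
  structure(list(level = raw$level[1], sex = raw$sex[1], cells = cells),
            class = "jem_table")
}
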