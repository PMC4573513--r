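EXPOSURE_CATEGORIES <- c("near_nil", "low", "medium", "high",
                         "missing_p", "not_working")

#' Categorize a probability of shift work
#'
#' Cut-points on the proportion scale: near nil (p < 0.015), low
#' (0.015 <= p < 0.10), medium (0.10 <= p < 0.45), high (p >= 0.45).
#' Each boundary belongs to the upper category.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Character vector of categories.
#' @export
categorize_p <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("domain error: p must lie in [0, 1]")
  }
  ifelse(p < 0.015, "near_nil",
         ifelse(p < 0.10, "low",
                ifelse(p < 0.45, "medium", "high")))
}

#' Link study participants to P_shift-work values
#'
#' Assigns each participant a probability of shift work from the JEM pair.
#' Current workers with a 4-character code retained in the specific table
#' link there (`source_level = "four_digit"`). When the specific value is
#' suppressed or the code is absent (indistinguishable from the consumer
#' side), the `"fallback"` strategy tries the 2-character broad code
#' (`source_level = "two_digit"`); the `"four_digit_only"` strategy does not.
#' Participants reporting only a 2-character code can link at the broad
#' level under fallback. Anyone failing all lookups gets `missing_p`;
#' non-current workers get `not_working` regardless of code.
#'
#' @param study Data frame of study records with at least `participant_id`,
#'   `employment_status`, `occupation_code` (NA allowed).
#' @param jem_specific,jem_broad Suppressed `jem_table`s built for the
#'   participants' sex.
#' @param strategy `"fallback"` (specific first, broad on failure) or
#'   `"four_digit_only"`.
#' @param sex Sex the study sample was drawn from; must match both tables.
#' @return Data frame with `participant_id`, `p_value`, `source_level`
#'   (`four_digit` / `two_digit` / `none`), `category`, and
#'   `specific_suppressed` (the 4-digit code existed but was concealed --
#'   used for flow accounting).
#' @export
link_exposure <- function(study, jem_specific, jem_broad,
                          strategy = c("fallback", "four_digit_only"),
                          sex = "female") {
  strategy <- match.arg(strategy)
  stopifnot(inherits(jem_specific, "jem_table"), inherits(jem_broad, "jem_table"))
  if (!identical(jem_specific$sex, sex) || !identical(jem_broad$sex, sex)) {
    stop("linkage error: JEM table sex does not match the study sample sex")
  }
  if (jem_specific$level != "specific" || jem_broad$level != "broad") {
    stop("linkage error: tables must be a (specific, broad) pair")
  }
  n <- nrow(study)
  p_value <- rep(NA_real_, n)
  source_level <- rep("none", n)
  category <- rep(NA_character_, n)
  specific_suppressed <- rep(FALSE, n)

  for (i in seq_len(n)) {
    if (study$employment_status[i] != "current") {
      category[i] <- "not_working"
      next
    }
    code <- study$occupation_code[i]
    if (is.na(code) || nchar(code) < 2) {
      category[i] <- "missing_p"
      next
    }
    hit <- NULL
    if (nchar(code) >= 4) {
      res <- jem_lookup(jem_specific, code)
      if (res$status == "linked") {
        hit <- list(p = res$p, src = "four_digit")
      } else if (res$status == "suppressed") {
        specific_suppressed[i] <- TRUE
      }
    }
    if (is.null(hit) && strategy == "fallback") {
      res <- jem_lookup(jem_broad, broad_code(code))
      if (res$status == "linked") hit <- list(p = res$p, src = "two_digit")
    }
    if (is.null(hit)) {
      category[i] <- "missing_p"
    } else {
      p_value[i] <- hit$p
      source_level[i] <- hit$src
      category[i] <- categorize_p(hit$p)
    }
  }
  data.frame(participant_id = study$participant_id, p_value = p_value,
             source_level = source_level,
             category = factor(category, levels = EXPOSURE_CATEGORIES),
             specific_suppressed = specific_suppressed,
             stringsAsFactors = FALSE)
}

#' Flow accounting for exposure assignment
#'
#' Partitions current workers by linkage outcome, mirroring the sample-size
#' flow from reported occupation to the shift-work variable: vague reports
#' uncodable even at the broad level, reports codable only at the broad
#' level, specific codes concealed by suppression, and the linked /
#' missing-P totals. Conservation:
#' `n_linked_four_digit + n_linked_two_digit + n_missing_p = n_current_workers`.
#'
#' @param assignments Output of [link_exposure()].
#' @param study The study records the assignments were made from.
#' @return Named list of counts.
#' @export
flow_accounting <- function(assignments, study) {
  if (anyDuplicated(study$participant_id) || anyDuplicated(assignments$participant_id)) {
    stop("data-integrity error: duplicate participant ids")
  }
  if (nrow(assignments) != nrow(study)) {
    stop("data-integrity error: one assignment per record required")
  }
  m <- match(study$participant_id, assignments$participant_id)
  a <- assignments[m, ]
  cur <- study$employment_status == "current"
  code <- study$occupation_code
  counts <- list(
    n_current_workers = sum(cur),
    n_vague_two_digit = sum(cur & (is.na(code) | nchar(code) < 2)),
    n_vague_four_digit = sum(cur & !is.na(code) & nchar(code) >= 2 & nchar(code) < 4),
    n_suppressed_four_digit = sum(cur & a$specific_suppressed),
    n_linked_four_digit = sum(cur & a$source_level == "four_digit"),
    n_linked_two_digit = sum(cur & a$source_level == "two_digit"),
    n_missing_p = sum(cur & a$category == "missing_p")
  )
  stopifnot(counts$n_linked_four_digit + counts$n_linked_two_digit +
              counts$n_missing_p == counts$n_current_workers)
  counts
}
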