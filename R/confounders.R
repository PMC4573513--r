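#' Forward change-in-estimate confounder selection
#'
#' Starting from the exposure-only model, each candidate covariate is
#' tentatively added and the relative change it induces in the exposure
#' effect estimates is measured; the candidate producing the largest change
#' of at least `threshold` percent is admitted, and the process repeats on
#' the enlarged model until no remaining candidate qualifies.
#'
#' The "parameter of interest" is the set of exposure odds ratios for the
#' low/medium/high contrasts (both outcome contrasts); the change is
#' aggregated by the maximum, so a covariate is admitted when it moves any
#' reported exposure contrast by the threshold. Change is measured on the
#' OR scale by default (`|OR_with - OR_without| / OR_without * 100`), the
#' conventional reading of the 10% change-in-estimate rule; `scale = "log"`
#' measures relative change of the log-odds instead. Ties are broken by
#' candidate list order. Candidates whose trial fit is rank-deficient or
#' non-convergent are skipped that round with a warning.
#'
#' @param data Analysis table (outcome, exposure, candidate columns).
#' @param candidates Character vector of candidate covariate names, in
#'   assessment order.
#' @param threshold Minimum percent change for admission (default 10.0).
#' @param scale `"or"` or `"log"`: scale on which change is measured.
#' @param exposure,outcome,exposure_ref,outcome_ref Passed to
#'   [fit_weight_model()].
#' @param exposure_levels Exposure dummies protected by the criterion.
#' @param ... Passed to [fit_weight_model()].
#' @return Object of class `selection_trace`: `steps` data frame (round,
#'   candidate, max_relative_change, admitted), `final_covariates` in
#'   admission order, `base_ors`, `final_ors`, and the final `fit`.
#' @export
select_confounders <- function(data, candidates, threshold = 10.0,
                               scale = c("or", "log"),
                               exposure = "category", outcome = "weight_class",
                               exposure_ref = "near_nil",
                               outcome_ref = "normal_under",
                               exposure_levels = c("low", "medium", "high"),
                               ...) {
  scale <- match.arg(scale)
  est_of <- function(fit) {
    ors <- exposure_ors(fit, levels = exposure_levels)
    if (scale == "log") log(ors) else ors
  }
  rel_change <- function(new, ref) {
    ch <- abs(new - ref) / abs(ref) * 100
    max(ch, na.rm = TRUE)
  }
  refit <- function(covs) {
    fit_weight_model(data, exposure = exposure, covariates = covs,
                     outcome = outcome, exposure_ref = exposure_ref,
                     outcome_ref = outcome_ref, ...)
  }

  base_fit <- refit(character())
  cur_fit <- base_fit
  cur_est <- est_of(cur_fit)
  admitted <- character()
  remaining <- candidates
  steps <- data.frame(round = integer(), candidate = character(),
                      max_relative_change = numeric(), admitted = logical(),
                      stringsAsFactors = FALSE)
  round_i <- 0L
  while (length(remaining)) {
    round_i <- round_i + 1L
    changes <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cand <- remaining[i]
      f <- tryCatch(refit(c(admitted, cand)), error = function(e) e)
      if (inherits(f, "error")) {
        warning("candidate '", cand, "' skipped this round: ",
                conditionMessage(f))
        next
      }
      if (!f$converged) {
        warning("candidate '", cand, "' skipped this round: fit did not converge")
        next
      }
      fits[[i]] <- f
      changes[i] <- rel_change(est_of(f), cur_est)
    }
    if (all(is.na(changes))) break
    best <- which.max(ifelse(is.na(changes), -Inf, changes))
    qualifies <- changes[best] >= threshold
    steps <- rbind(steps, data.frame(
      round = round_i, candidate = remaining[best],
      max_relative_change = changes[best], admitted = qualifies,
      stringsAsFactors = FALSE))
    if (!qualifies) break
    admitted <- c(admitted, remaining[best])
    cur_fit <- fits[[best]]
    cur_est <- est_of(cur_fit)
    remaining <- remaining[-best]
  }

  structure(list(steps = steps, final_covariates = admitted,
                 base_ors = est_of(base_fit), final_ors = est_of(cur_fit),
                 threshold = threshold, scale = scale, fit = cur_fit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Change-in-estimate forward selection (threshold %.1f%%, %s scale)\n",
              x$threshold, x$scale))
  if (nrow(x$steps)) {
    s <- x$steps
    s$max_relative_change <- round(s$max_relative_change, 2)
    print(s, row.names = FALSE)
  }
  cat("Admitted: ", if (length(x$final_covariates))
    paste(x$final_covariates, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
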