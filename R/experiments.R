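#' Parameter-recovery experiment
#'
#' Repeatedly generates study samples under the configured exposure effects
#' (by default the published adjusted estimates, e.g. obese log-OR
#' log(1.88) for high vs near nil), fits the exposure-only weight-class
#' model to each replicate, and records the estimate and 95% Wald interval
#' for a chosen exposure term. With no confounding in the generator (the
#' default), the crude fit estimates the generating log-odds directly, so
#' the experiment measures bias and interval coverage of the estimator.
#'
#' @param jem JEM pair from [build_jem()].
#' @param n_participants Sample size per replicate.
#' @param reps Number of replicates.
#' @param seed Seed for the replicate stream.
#' @param level,contrast Exposure term monitored (default high / obese).
#' @param config Base [study_config()]; its seed is overridden per
#'   replicate.
#' @return Data frame with one row per converged replicate: `est`, `se`,
#'   `ci_low`, `ci_high` (log-odds scale), `covered` (true value inside the
#'   CI), plus attribute `truth` (the generating log-odds).
#' @export
recovery_experiment <- function(jem, n_participants = 5000, reps = 200,
                                seed = 1, level = "high", contrast = "obese",
                                config = study_config(n_participants = n_participants)) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  truth <- config$true_log_odds[[contrast]][[level]]
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    st <- generate_study(cfg, jem)
    at <- data.frame(
      category = factor(st$true_exposure_category,
                        levels = intersect(EXPOSURE_CATEGORIES,
                                           unique(st$true_exposure_category))),
      weight_class = factor(st$drawn_class, levels = WEIGHT_CLASSES))
    f <- fit_weight_model(at)
    if (!f$converged) next
    row <- f$table[f$table$contrast == contrast &
                     f$table$term == paste0("category", level), ]
    rows[[r]] <- data.frame(est = row$estimate, se = row$se,
                            ci_low = row$estimate - 1.96 * row$se,
                            ci_high = row$estimate + 1.96 * row$se)
  }
  out <- do.call(rbind, rows)
  out$covered <- out$ci_low <= truth & truth <= out$ci_high
  attr(out, "truth") <- truth
  out
}

#' Exposure-misclassification attenuation experiment
#'
#' Generates study samples in which an individual true shift-work indicator
#' (Bernoulli with the occupation's P value) drives the outcome with a
#' configured individual-level odds ratio, then analyses the data the only
#' way the exposure tool allows: by probability category. Because category
#' membership only partially predicts individual exposure, the
#' category-level OR is attenuated toward the null relative to the
#' individual-level OR.
#'
#' @inheritParams recovery_experiment
#' @param individual_or Individual-level true odds ratio (obese contrast).
#' @return Numeric vector of category-level OR estimates (high vs near
#'   nil, obese contrast), one per converged replicate; attribute
#'   `individual_or` carries the generating value.
#' @export
attenuation_experiment <- function(jem, n_participants = 4000, reps = 100,
                                   seed = 1, individual_or = 3.0,
                                   config = study_config(n_participants = n_participants)) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  config$individual_log_odds <- c(overweight = 0, obese = log(individual_or))
  ors <- numeric(0)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    st <- generate_true_exposure_variant(cfg, jem)
    at <- data.frame(
      category = factor(st$true_exposure_category,
                        levels = intersect(EXPOSURE_CATEGORIES,
                                           unique(st$true_exposure_category))),
      weight_class = factor(st$drawn_class, levels = WEIGHT_CLASSES))
    f <- fit_weight_model(at)
    if (!f$converged) next
    row <- f$table[f$table$contrast == "obese" &
                     f$table$term == "categoryhigh", ]
    ors <- c(ors, row$or)
  }
  attr(ors, "individual_or") <- individual_or
  ors
}
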