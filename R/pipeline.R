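#' Round half-up
#'
#' Display rounding for report tables: exact halves round away from zero
#' (0.05 -> 0.1 at one decimal), unlike banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentages of class counts
#'
#' @param counts Numeric vector of counts.
#' @param digits Decimal places (half-up).
#' @return Percentages summing to ~100, computed over `sum(counts)`.
#' @export
class_percentages <- function(counts, digits = 1) {
  round_half_up(100 * counts / sum(counts), digits)
}

# full-precision CSV writer so persisted intermediates round-trip exactly
write_precise_csv <- function(df, path) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.17g", df[[nm]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Merge study records, exposure assignments, and BMI results
#'
#' @param study,assignments,bmi Outputs of [generate_study()] (or real
#'   records), [link_exposure()], and [bmi_outcomes()].
#' @return One analysis table keyed by `participant_id`.
#' @export
build_analysis_table <- function(study, assignments, bmi) {
  at <- merge(study, assignments, by = "participant_id", sort = FALSE)
  merge(at, bmi, by = "participant_id", sort = FALSE)
}

#' Descriptive distribution table
#'
#' Counts, percentages, and means (+/- SD) of selected variables amongst
#' current workers. Weight-class percentages use the sum of the three class
#' counts as denominator; exposure-category percentages use all current
#' workers, including the unattainable (missing-P) group.
#'
#' @param analysis Analysis table from [build_analysis_table()].
#' @param covariates Covariate column names to summarize.
#' @return Data frame with `variable`, `level`, `n`, `pct`, `mean`, `sd`.
#' @export
descriptive_table <- function(analysis,
                              covariates = c("age", "education", "race",
                                             "marital", "parity", "smoking",
                                             "calories", "alcohol",
                                             "physical_activity")) {
  cur <- analysis[analysis$employment_status == "current", , drop = FALSE]
  rows <- list()
  add <- function(variable, level, n = NA, pct = NA, mean = NA, sd = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, n = n, pct = pct,
      mean = mean, sd = sd, stringsAsFactors = FALSE)
  }
  add("sample_size", "current_workers", n = nrow(cur))
  add("bmi", "all", mean = round_half_up(mean(cur$bmi, na.rm = TRUE), 1),
      sd = round_half_up(stats::sd(cur$bmi, na.rm = TRUE), 1))
  wc <- table(factor(cur$weight_class, levels = WEIGHT_CLASSES))
  pw <- class_percentages(as.numeric(wc))
  for (i in seq_along(wc)) add("weight_class", names(wc)[i], n = as.numeric(wc[i]),
                               pct = pw[i])
  ec <- table(factor(as.character(cur$category),
                     levels = c("near_nil", "low", "medium", "high", "missing_p")))
  pe <- round_half_up(100 * as.numeric(ec) / nrow(cur), 1)
  for (i in seq_along(ec)) add("exposure_category", names(ec)[i],
                               n = as.numeric(ec[i]), pct = pe[i])
  for (v in intersect(covariates, names(cur))) {
    if (is.numeric(cur[[v]])) {
      add(v, "all", mean = round_half_up(mean(cur[[v]], na.rm = TRUE), 1),
          sd = round_half_up(stats::sd(cur[[v]], na.rm = TRUE), 1))
    } else {
      tb <- table(cur[[v]])
      pc <- class_percentages(as.numeric(tb))
      for (i in seq_along(tb)) add(v, names(tb)[i], n = as.numeric(tb[i]),
                                   pct = pc[i])
    }
  }
  do.call(rbind, rows)
}

#' Most frequent occupations per exposure category
#'
#' @param analysis Analysis table.
#' @param k Number of occupations to report per category.
#' @return Data frame `category`, `rank`, `code`, `n`, `pct` (within
#'   category, of linked current workers); ties broken by code order.
#' @export
top_occupations <- function(analysis, k = 3) {
  out <- list()
  for (cc in c("near_nil", "low", "medium", "high")) {
    sub <- analysis[!is.na(analysis$category) & analysis$category == cc &
                      !is.na(analysis$occupation_code), , drop = FALSE]
    if (!nrow(sub)) next
    tb <- table(sub$occupation_code)
    tb <- tb[order(-as.numeric(tb), names(tb))]
    top <- utils::head(tb, k)
    out[[cc]] <- data.frame(category = cc, rank = seq_along(top),
                            code = names(top), n = as.numeric(top),
                            pct = round_half_up(100 * as.numeric(top) / sum(tb)),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(category = character(), rank = integer(),
                      code = character(), n = numeric(), pct = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Regression report table
#'
#' Per exposure group: sample size, mean BMI, weight-class counts with row
#' percentages (denominator = sum of the non-missing class counts, rounded
#' half-up to integers), and the fitted ORs, 95% CIs, and p-values for both
#' outcome contrasts. The reference group carries OR 1.0.
#'
#' @param analysis Analysis table.
#' @param fit A `weight_fit` on the same data.
#' @return Data frame, one row per exposure group.
#' @export
regression_table <- function(analysis, fit) {
  groups <- c("near_nil", "low", "medium", "high", "missing_p", "not_working")
  tt <- fit$table
  rows <- lapply(groups, function(g) {
    sub <- analysis[!is.na(analysis$category) & analysis$category == g, , drop = FALSE]
    wc <- table(factor(sub$weight_class, levels = WEIGHT_CLASSES))
    pc <- if (sum(wc) > 0) round_half_up(100 * as.numeric(wc) / sum(wc)) else rep(NA, 3)
    term <- paste0(fit$exposure, g)
    pull <- function(cn, col) {
      s <- tt[tt$contrast == cn & tt$term == term, col]
      if (length(s)) s else NA_real_
    }
    data.frame(group = g, n = nrow(sub),
               mean_bmi = round_half_up(mean(sub$bmi, na.rm = TRUE), 1),
               n_normal = as.numeric(wc[1]), pct_normal = pc[1],
               n_overweight = as.numeric(wc[2]), pct_overweight = pc[2],
               n_obese = as.numeric(wc[3]), pct_obese = pc[3],
               or_overweight = if (g == "near_nil") 1 else pull("overweight", "or"),
               ci_low_overweight = pull("overweight", "ci_low"),
               ci_high_overweight = pull("overweight", "ci_high"),
               p_overweight = pull("overweight", "p_value"),
               or_obese = if (g == "near_nil") 1 else pull("obese", "or"),
               ci_low_obese = pull("obese", "ci_low"),
               ci_high_obese = pull("obese", "ci_high"),
               p_obese = pull("obese", "p_value"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subgroup analysis within an exposure category
#'
#' Refits the (optionally adjusted) model on a stratum of an exposure
#' category -- e.g. nurses alone, or the non-nursing remainder of the
#' high-probability group -- versus the reference category.
#'
#' @param analysis Analysis table.
#' @param codes Occupation codes defining the stratum.
#' @param category Exposure category the stratum lives in.
#' @param covariates Adjustment covariates.
#' @param exposure_ref Reference category.
#' @param ... Passed to [fit_weight_model()].
#' @return A `weight_fit` for the stratum-vs-reference contrast.
#' @export
subgroup_analysis <- function(analysis, codes, category = "high",
                              covariates = character(),
                              exposure_ref = "near_nil", ...) {
  in_stratum <- !is.na(analysis$category) & analysis$category == category &
    analysis$occupation_code %in% codes
  in_ref <- !is.na(analysis$category) & analysis$category == exposure_ref
  if (!any(in_stratum)) stop("data error: empty stratum (no participants match)")
  d <- analysis[in_stratum | in_ref, , drop = FALSE]
  d$category <- factor(ifelse(in_stratum[in_stratum | in_ref], category,
                              exposure_ref),
                       levels = c(exposure_ref, category))
  fit_weight_model(d, exposure = "category", covariates = covariates,
                   exposure_ref = exposure_ref, ...)
}

#' Pipeline run configuration
#'
#' @param survey A [survey_config()].
#' @param study A [study_config()].
#' @param strategy Linkage strategy (see [link_exposure()]).
#' @param trim_fraction BMI outlier-trimming fraction.
#' @param candidates Covariates assessed for confounding.
#' @param threshold Change-in-estimate threshold (%).
#' @param out_dir Output directory for persisted artifacts.
#' @param seed Master seed; sets the survey and study seeds.
#' @return A `run_config` list.
#' @export
run_config <- function(survey = survey_config(), study = study_config(),
                       strategy = c("fallback", "four_digit_only"),
                       trim_fraction = 0.002,
                       candidates = c("age", "education", "race", "marital",
                                      "parity", "smoking", "calories",
                                      "alcohol", "physical_activity"),
                       threshold = 10.0, out_dir = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) {
    survey$seed <- seed
    study$seed <- seed + 1L
  }
  structure(list(survey = survey, study = study, strategy = strategy,
                 trim_fraction = trim_fraction, candidates = candidates,
                 threshold = threshold, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) survey and study data, build and suppress the JEM,
#' link exposure with flow accounting, compute/trim/classify BMI, select
#' confounders by change in estimate, fit the adjusted weight-class model,
#' and assemble report tables. Each intermediate artifact is persisted
#' under `out_dir` (when set) as CSV/JSON; the run is deterministic given
#' the seed.
#'
#' @param config A [run_config()].
#' @return A `report_bundle` list: `survey`, `jem`, `study`, `assignments`,
#'   `flow`, `bmi`, `analysis`, `selection`, `fit`, `descriptives`,
#'   `top_occupations`, `regression`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit_csv <- function(df, name) if (!is.null(out))
    write_precise_csv(df, file.path(out, name))
  emit_json <- function(x, name) if (!is.null(out))
    jsonlite::write_json(x, file.path(out, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  survey <- stage("simulate_survey", generate_survey(config$survey))
  emit_csv(survey, "survey.csv")
  message("stage simulate_survey: ", nrow(survey), " records")

  jem <- stage("build_jem", build_jem(survey))
  if (!is.null(out)) {
    write_jem_csv(jem$specific, file.path(out, "jem_specific.csv"))
    write_jem_csv(jem$broad, file.path(out, "jem_broad.csv"))
  }
  message("stage build_jem: ", nrow(jem$specific$cells), " specific / ",
          nrow(jem$broad$cells), " broad cells")

  study <- stage("simulate_study", generate_study(config$study, jem))
  emit_csv(study, "study.csv")
  message("stage simulate_study: ", nrow(study), " participants")

  assignments <- stage("link_exposure",
                       link_exposure(study, jem$specific, jem$broad,
                                     strategy = config$strategy,
                                     sex = config$survey$sex))
  flow <- stage("flow_accounting", flow_accounting(assignments, study))
  emit_csv(transform(assignments, category = as.character(category)),
           "assignments.csv")
  emit_json(flow, "flow.json")
  message("stage link_exposure: ", flow$n_linked_four_digit, " four-digit, ",
          flow$n_linked_two_digit, " two-digit, ", flow$n_missing_p,
          " missing of ", flow$n_current_workers, " current workers")

  bmi <- stage("outcomes", bmi_outcomes(study, config$trim_fraction))
  emit_csv(bmi, "bmi.csv")
  message("stage outcomes: ", sum(bmi$trimmed), " trimmed of ", nrow(bmi))

  analysis <- stage("assemble", build_analysis_table(study, assignments, bmi))

  selection <- stage("select_confounders",
                     select_confounders(analysis, config$candidates,
                                        threshold = config$threshold))
  emit_json(list(steps = selection$steps,
                 final_covariates = selection$final_covariates),
            "selection.json")
  message("stage select_confounders: admitted ",
          if (length(selection$final_covariates))
            paste(selection$final_covariates, collapse = ", ") else "(none)")

  fit <- stage("fit", fit_weight_model(analysis,
                                       covariates = selection$final_covariates))
  emit_json(list(converged = fit$converged, n_used = fit$n_used,
                 logLik = fit$logLik, table = fit$table), "fit.json")
  message("stage fit: n = ", fit$n_used, ", converged = ", fit$converged)

  descriptives <- stage("report", descriptive_table(analysis))
  topocc <- stage("report", top_occupations(analysis))
  regtab <- stage("report", regression_table(analysis, fit))
  provenance <- list(package = "shiftjem",
                     version = as.character(utils::packageVersion("shiftjem")),
                     seed = config$seed, strategy = config$strategy,
                     trim_fraction = config$trim_fraction,
                     threshold = config$threshold,
                     n_respondents = config$survey$n_respondents,
                     n_participants = config$study$n_participants)
  if (!is.null(out)) {
    utils::write.csv(descriptives, file.path(out, "descriptives.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(topocc, file.path(out, "top_occupations.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(regtab, file.path(out, "regression_table.csv"),
                     row.names = FALSE, na = "")
    emit_json(provenance, "provenance.json")
  }

  structure(list(survey = survey, jem = jem, study = study,
                 assignments = assignments, flow = flow, bmi = bmi,
                 analysis = analysis, selection = selection, fit = fit,
                 descriptives = descriptives, top_occupations = topocc,
                 regression = regtab, provenance = provenance),
            class = "report_bundle")
}
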