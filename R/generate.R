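#' Survey generator configuration
#'
#' Describes a synthetic labour survey: occupation codes with relative
#' sizes and shift-work propensities, hours distribution, and sex. Defaults
#' emulate the national labour-survey extract the exposure tool is built
#' from: 12,500 respondents, female, full-time hours (mean 37.5 h/week),
#' and occupation codes whose propensities span all four exposure
#' categories plus small codes that trigger confidentiality suppression.
#'
#' @param n_respondents Number of respondents (>= 1).
#' @param code_profiles Data frame with columns `code` (4-character),
#'   `weight` (relative size, > 0), `propensity` (probability a
#'   respondent's schedule is a shift schedule, in `[0, 1]`).
#' @param sex Sex label for the tabulation.
#' @param hours_mean,hours_sd Weekly-hours normal distribution (h/week;
#'   draws truncated at 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `survey_config` list.
#' @export
survey_config <- function(n_respondents = 12500,
                          code_profiles = default_code_profiles(),
                          sex = "female",
                          hours_mean = 37.5, hours_sd = 7.5,
                          seed = NULL) {
  cfg <- list(n_respondents = n_respondents, code_profiles = code_profiles,
              sex = sex, hours_mean = hours_mean, hours_sd = hours_sd,
              seed = seed)
  validate_survey_config(cfg)
  structure(cfg, class = "survey_config")
}

validate_survey_config <- function(cfg) {
  if (!is.numeric(cfg$n_respondents) || cfg$n_respondents < 1) {
    stop("configuration error: n_respondents must be >= 1")
  }
  cp <- cfg$code_profiles
  if (!is.data.frame(cp) || !all(c("code", "weight", "propensity") %in% names(cp))) {
    stop("configuration error: code_profiles needs columns code, weight, propensity")
  }
  if (any(nchar(cp$code) != 4)) {
    stop("configuration error: code_profiles$code must be 4-character codes")
  }
  if (any(cp$weight <= 0)) stop("configuration error: code_profiles$weight must be positive")
  if (any(cp$propensity < 0 | cp$propensity > 1)) {
    stop("configuration error: code_profiles$propensity must lie in [0, 1]")
  }
  if (!is.numeric(cfg$hours_sd) || cfg$hours_sd < 0) {
    stop("configuration error: hours_sd must be >= 0")
  }
  invisible(cfg)
}

#' Default occupation-code profiles for the synthetic labour survey
#'
#' Thirteen codes spanning the four exposure categories (shift propensities
#' from 0.005 to 0.72, the top being the nursing-type code), two of them
#' deliberately rare so their cells fall under the disclosure thresholds:
#' one specific code suppressed but recoverable through its broad group
#' (fallback), and two suppressed at both hierarchy levels.
#'
#' @return Data frame with `code`, `weight`, `propensity`.
#' @export
default_code_profiles <- function() {
  data.frame(
    code = c("C011", "C032",           # near nil: clerical/secretarial
             "B511", "B522", "E211",   # low: finance, teaching
             "G211", "D235", "G973",   # medium: retail, health technicians
             "D112", "D233", "G981",   # high: nursing, aides, cleaners
             "D236",                   # rare: suppressed at 4-digit, broad D2 retained
             "H821", "F154"),          # rare: suppressed at both levels
    weight = c(0.160, 0.060,
               0.140, 0.100, 0.080,
               0.090, 0.070, 0.050,
               0.100, 0.040, 0.030,
               0.0015,
               0.0015, 0.0045),
    propensity = c(0.005, 0.010,
                   0.030, 0.050, 0.080,
                   0.150, 0.250, 0.400,
                   0.550, 0.650, 0.720,
                   0.600,
                   0.300, 0.030),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic labour-survey records
#'
#' Each respondent is assigned an occupation code (multinomial over the
#' profile weights) and a schedule: with probability equal to the code's
#' shift propensity, one of regular evening / regular night / rotating
#' (split uniformly -- the downstream definition never distinguishes them),
#' otherwise regular day (90%) or other (10%). Weekly hours are normal,
#' truncated at zero.
#'
#' @param config A [survey_config()].
#' @return Data frame of survey records: `person_id`, `sex`,
#'   `occupation_code`, `weekly_hours`, `schedule`.
#' @export
generate_survey <- function(config) {
  validate_survey_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_respondents)
  cp <- config$code_profiles
  idx <- sample.int(nrow(cp), n, replace = TRUE, prob = cp$weight)
  code <- cp$code[idx]
  is_shift <- stats::runif(n) < cp$propensity[idx]
  schedule <- character(n)
  schedule[is_shift] <- sample(SHIFT_SCHEDULES, sum(is_shift), replace = TRUE)
  schedule[!is_shift] <- sample(c("regular_day", "other"), sum(!is_shift),
                                replace = TRUE, prob = c(0.9, 0.1))
  hours <- pmax(0, stats::rnorm(n, config$hours_mean, config$hours_sd))
  data.frame(person_id = sprintf("S%06d", seq_len(n)),
             sex = config$sex,
             occupation_code = code,
             weekly_hours = hours,
             schedule = schedule,
             stringsAsFactors = FALSE)
}

# --- study sample ----------------------------------------------------------

#' Covariate specification helpers
#'
#' Build entries of a study config's `confounder_spec`. Categorical
#' covariates are sampled from `probs` (normalized); continuous ones from a
#' normal distribution. Per-contrast effects are log-odds: a vector over
#' levels (reference first, conventionally 0) for categorical covariates, a
#' per-standard-deviation slope (applied to the centred, scaled value) for
#' continuous ones. `tilt` optionally makes the covariate depend on the
#' true exposure category -- a named vector over categories that
#' exponentially tilts the level probabilities (categorical) or shifts the
#' mean (continuous), which is how confounding structure is induced.
#'
#' @param name Covariate name.
#' @param levels,probs Levels and marginal probabilities (categorical).
#' @param mean,sd Normal parameters (continuous).
#' @param beta_overweight,beta_obese Log-odds effects per contrast.
#' @param tilt Optional named numeric over exposure categories.
#' @return A covariate spec list.
#' @export
cov_cat <- function(name, levels, probs, beta_overweight = 0, beta_obese = 0,
                    tilt = NULL) {
  stopifnot(length(levels) == length(probs), all(probs >= 0))
  list(name = name, type = "categorical", levels = levels,
       probs = probs / sum(probs),
       beta_overweight = rep(beta_overweight, length.out = length(levels)),
       beta_obese = rep(beta_obese, length.out = length(levels)),
       tilt = tilt)
}

#' @rdname cov_cat
#' @export
cov_num <- function(name, mean, sd, beta_overweight = 0, beta_obese = 0,
                    tilt = NULL) {
  list(name = name, type = "continuous", mean = mean, sd = sd,
       beta_overweight = beta_overweight, beta_obese = beta_obese,
       tilt = tilt)
}

#' Default covariate specification
#'
#' Marginal distributions taken from the population-based sample's
#' descriptive table (age 46.4 +/- 8.5 y; education 33/57/10%; 90% white;
#' etc.); all outcome effects zero unless overridden, so the default study
#' conditions carry no confounding.
#'
#' @return List of covariate specs.
#' @export
default_confounder_spec <- function() {
  list(
    cov_num("age", 46.4, 8.5),
    cov_cat("education", c("secondary_or_less", "post_secondary", "graduate"),
            c(525, 919, 165)),
    cov_cat("race", c("white", "non_white"), c(1456, 155)),
    cov_cat("marital", c("never_married", "married", "divorced_separated", "widowed"),
            c(101, 1242, 220, 48)),
    cov_cat("parity", c("0", "1", "2_3", "4plus"), c(236, 900, 342, 128)),
    cov_cat("smoking", c("never", "lt15", "ge15"), c(786, 490, 314)),
    cov_num("calories", 1767.1, 646.2),
    cov_cat("alcohol", c("never", "1_6", "7plus"), c(742, 549, 309)),
    cov_cat("physical_activity", c("lt1", "ge1"), c(450, 1142))
  )
}

#' Study generator configuration
#'
#' Defaults emulate the population-based sample: 3,377 women of whom about
#' 48% are current workers, category mix proportional to the published
#' distribution (182 near nil / 660 low / 434 medium / 112 high / 223
#' missing current workers + 1,766 non-workers), outcome effects equal to
#' the published adjusted estimates (e.g. obese log-OR log(1.88) for high
#' vs near nil), and near-nil baseline class proportions 50/33/17.
#'
#' @param n_participants Number of participants.
#' @param category_mix Named probabilities over `near_nil, low, medium,
#'   high, missing, not_working`; must sum to 1 (tolerance 1e-9).
#' @param true_log_odds List with `overweight` and `obese` named vectors of
#'   log-odds for the exposure dummies (`low, medium, high, missing_p,
#'   not_working`; near nil is the reference).
#' @param baseline_intercepts Named vector: per-contrast intercepts.
#' @param confounder_spec List of [cov_cat()]/[cov_num()] entries.
#' @param anthropometry List: `height_mean`, `height_sd` (m), `bmi_ranges`
#'   (per-class BMI intervals; obese capped at 45).
#' @param individual_log_odds Per-contrast log-odds of an individual true
#'   shift-work indicator, used by [generate_true_exposure_variant()].
#' @param vague_four_digit_rate Probability that a current worker in the
#'   near-nil/low/medium categories reports an occupation codable only at
#'   the broad level (code truncated to its 2-character prefix when the
#'   broad category agrees); high-category workers always carry specific
#'   codes, matching the observed linkage pattern.
#' @param seed Integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 3377,
                         category_mix = c(near_nil = 182, low = 660,
                                          medium = 434, high = 112,
                                          missing = 223, not_working = 1766) / 3377,
                         true_log_odds = list(
                           overweight = log(c(low = 0.94, medium = 0.87,
                                              high = 1.15, missing_p = 0.75,
                                              not_working = 0.90)),
                           obese = log(c(low = 1.16, medium = 1.27,
                                         high = 1.88, missing_p = 0.71,
                                         not_working = 1.30))),
                         baseline_intercepts = c(overweight = log(33 / 50),
                                                 obese = log(17 / 50)),
                         confounder_spec = default_confounder_spec(),
                         anthropometry = list(height_mean = 1.63,
                                              height_sd = 0.07,
                                              bmi_ranges = list(
                                                normal_under = c(17.5, 25),
                                                overweight = c(25, 30),
                                                obese = c(30, 45))),
                         individual_log_odds = c(overweight = 0, obese = log(3)),
                         vague_four_digit_rate = 0.08,
                         seed = NULL) {
  cfg <- list(n_participants = n_participants, category_mix = category_mix,
              true_log_odds = true_log_odds,
              baseline_intercepts = baseline_intercepts,
              confounder_spec = confounder_spec,
              anthropometry = anthropometry,
              individual_log_odds = individual_log_odds,
              vague_four_digit_rate = vague_four_digit_rate,
              seed = seed)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

MIX_CATEGORIES <- c("near_nil", "low", "medium", "high", "missing", "not_working")

validate_study_config <- function(cfg) {
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1) {
    stop("configuration error: n_participants must be >= 1")
  }
  mix <- cfg$category_mix
  if (!all(MIX_CATEGORIES %in% names(mix))) {
    stop("configuration error: category_mix must name ",
         paste(MIX_CATEGORIES, collapse = ", "))
  }
  if (any(mix < 0 | mix > 1)) {
    stop("configuration error: category_mix probabilities must lie in [0, 1]")
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("configuration error: category_mix must sum to 1 (tolerance 1e-9)")
  }
  for (cn in c("overweight", "obese")) {
    if (!all(c("low", "medium", "high", "missing_p", "not_working") %in%
             names(cfg$true_log_odds[[cn]]))) {
      stop("configuration error: true_log_odds$", cn,
           " must name low, medium, high, missing_p, not_working")
    }
  }
  invisible(cfg)
}

# Effective (post-fallback) P value and category of every specific code.
# Returns the code pools the generator draws from.
jem_code_pools <- function(jem) {
  sp <- jem$specific$cells
  eff <- numeric(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!sp$suppressed[i]) {
      eff[i] <- sp$p_shift[i]
    } else {
      b <- jem_lookup(jem$broad, broad_code(sp$code[i]))
      eff[i] <- if (b$status == "linked") b$p else NA_real_
    }
  }
  cat <- rep(NA_character_, length(eff))
  cat[!is.na(eff)] <- categorize_p(eff[!is.na(eff)])
  list(codes = sp$code, n_total = sp$n_total, eff_p = eff, category = cat)
}

draw_covariates <- function(spec, cat_draw) {
  n <- length(cat_draw)
  out <- list()
  effects <- list(overweight = numeric(n), obese = numeric(n))
  for (cv in spec) {
    if (cv$type == "continuous") {
      mu <- rep(cv$mean, n)
      if (!is.null(cv$tilt)) {
        shift <- cv$tilt[cat_draw]
        shift[is.na(shift)] <- 0
        mu <- mu + shift
      }
      x <- stats::rnorm(n, mu, cv$sd)
      z <- (x - cv$mean) / cv$sd
      effects$overweight <- effects$overweight + cv$beta_overweight * z
      effects$obese <- effects$obese + cv$beta_obese * z
      out[[cv$name]] <- x
    } else {
      L <- length(cv$levels)
      lev_idx <- integer(n)
      if (is.null(cv$tilt)) {
        lev_idx <- sample.int(L, n, replace = TRUE, prob = cv$probs)
      } else {
        for (cc in unique(cat_draw)) {
          sel <- cat_draw == cc
          t <- if (cc %in% names(cv$tilt)) cv$tilt[[cc]] else 0
          pr <- cv$probs * exp(t * (seq_len(L) - 1))
          lev_idx[sel] <- sample.int(L, sum(sel), replace = TRUE, prob = pr / sum(pr))
        }
      }
      effects$overweight <- effects$overweight + cv$beta_overweight[lev_idx]
      effects$obese <- effects$obese + cv$beta_obese[lev_idx]
      out[[cv$name]] <- factor(cv$levels[lev_idx], levels = cv$levels)
    }
  }
  list(columns = out, effects = effects)
}

# Shared scaffolding for the two study generators: draws categories,
# employment, occupation codes and covariates; outcome assignment differs.
generate_study_frame <- function(config, jem) {
  validate_study_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_participants)
  mix <- config$category_mix[MIX_CATEGORIES]
  cat_draw <- sample(MIX_CATEGORIES, n, replace = TRUE, prob = mix)

  pools <- jem_code_pools(jem)
  unlinkable <- pools$codes[is.na(pools$category)]

  employment <- rep("current", n)
  nw <- cat_draw == "not_working"
  employment[nw] <- sample(c("former", "never"), sum(nw), replace = TRUE,
                           prob = c(0.85, 0.15))

  code <- rep(NA_character_, n)
  for (cc in c("near_nil", "low", "medium", "high")) {
    sel <- cat_draw == cc
    if (!any(sel)) next
    pool <- which(pools$category == cc & !is.na(pools$category))
    if (!length(pool)) {
      stop("configuration error: JEM provides no linkable code for category ", cc)
    }
    code[sel] <- sample(pools$codes[pool], sum(sel), replace = TRUE,
                        prob = pools$n_total[pool])
  }
  # missing-P mechanisms: unreported, uncodable broad group, or a code
  # concealed at both hierarchy levels
  mi <- which(cat_draw == "missing")
  if (length(mi)) {
    mech <- sample(c("absent", "vague", "suppressed"), length(mi),
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
    code[mi[mech == "vague"]] <- "ZZ"
    sup <- mi[mech == "suppressed"]
    if (length(sup)) {
      code[sup] <- if (length(unlinkable)) {
        sample(unlinkable, length(sup), replace = TRUE)
      } else "ZZ"
    }
  }
  # former workers: half report an old occupation, half none
  if (any(nw)) {
    old <- nw & stats::runif(n) < 0.5 & employment == "former"
    linkable <- pools$codes[!is.na(pools$category)]
    code[old] <- sample(linkable, sum(old), replace = TRUE)
  }
  # vague specific reports: truncate to the broad code where the broad
  # category agrees (never in the high group)
  vag <- cat_draw %in% c("near_nil", "low", "medium") &
    stats::runif(n) < config$vague_four_digit_rate
  for (i in which(vag)) {
    bc <- broad_code(code[i])
    b <- jem_lookup(jem$broad, bc)
    if (b$status == "linked" && categorize_p(b$p) == cat_draw[i]) code[i] <- bc
  }

  cov <- draw_covariates(config$confounder_spec, cat_draw)

  base <- data.frame(participant_id = sprintf("P%06d", seq_len(n)),
                     employment_status = employment,
                     occupation_code = code,
                     stringsAsFactors = FALSE)
  for (nm in names(cov$columns)) base[[nm]] <- cov$columns[[nm]]
  list(base = base, cat_draw = cat_draw, cov_effects = cov$effects,
       pools = pools, n = n)
}

draw_anthropometry <- function(config, class_draw) {
  n <- length(class_draw)
  anth <- config$anthropometry
  height <- stats::rnorm(n, anth$height_mean, anth$height_sd)
  height <- pmax(height, 1.2)
  bmi <- numeric(n)
  for (cls in names(anth$bmi_ranges)) {
    sel <- class_draw == cls
    rg <- anth$bmi_ranges[[cls]]
    bmi[sel] <- stats::runif(sum(sel), rg[1], rg[2])
  }
  list(height = height, weight = bmi * height^2, drawn_class = class_draw)
}

draw_class <- function(eta_ow, eta_ob) {
  n <- length(eta_ow)
  e1 <- exp(eta_ow); e2 <- exp(eta_ob)
  p0 <- 1 / (1 + e1 + e2)
  u <- stats::runif(n)
  ifelse(u < p0, "normal_under",
         ifelse(u < p0 + e1 * p0, "overweight", "obese"))
}

#' Generate a synthetic study sample
#'
#' Draws each participant's true exposure category, employment status,
#' occupation code (from the JEM codes whose post-fallback P value lies in
#' the category), and covariates; draws the weight class from the
#' baseline-category multinomial logit implied by the configured log-odds;
#' and back-solves height/weight so the BMI class reproduces the drawn
#' class exactly (height normal, BMI uniform within the class interval,
#' weight = BMI x height^2).
#'
#' @param config A [study_config()].
#' @param jem A `list(specific, broad)` JEM pair from [build_jem()].
#' @return Data frame of study records including hidden bookkeeping column
#'   `true_exposure_category`.
#' @export
generate_study <- function(config, jem) {
  g <- generate_study_frame(config, jem)
  cat6 <- ifelse(g$cat_draw == "missing", "missing_p", g$cat_draw)
  eta_ow <- rep(config$baseline_intercepts[["overweight"]], g$n)
  eta_ob <- rep(config$baseline_intercepts[["obese"]], g$n)
  dum <- cat6 != "near_nil"
  eta_ow[dum] <- eta_ow[dum] + config$true_log_odds$overweight[cat6[dum]]
  eta_ob[dum] <- eta_ob[dum] + config$true_log_odds$obese[cat6[dum]]
  eta_ow <- eta_ow + g$cov_effects$overweight
  eta_ob <- eta_ob + g$cov_effects$obese
  cls <- draw_class(eta_ow, eta_ob)
  an <- draw_anthropometry(config, cls)
  out <- g$base
  out$height <- an$height
  out$weight <- an$weight
  out$true_exposure_category <- cat6
  out$drawn_class <- cls
  out
}

#' Generate a study sample with individual-level true exposure
#'
#' Variant for the misclassification (attenuation) experiment: each
#' participant carries an individual true shift-work indicator drawn
#' Bernoulli with probability equal to their code's post-fallback P value
#' (0 for non-workers, 0.1 for missing-P participants), and the outcome is
#' driven by that indicator through `individual_log_odds` -- not by the
#' category. Analysing these data at the category level shows the
#' attenuation that group-level probabilities induce.
#'
#' @inheritParams generate_study
#' @return Study records with additional column `true_shift_indicator`.
#' @export
generate_true_exposure_variant <- function(config, jem) {
  g <- generate_study_frame(config, jem)
  p_ind <- rep(0, g$n)
  eff <- g$pools$eff_p[match(g$base$occupation_code, g$pools$codes)]
  cur <- g$base$employment_status == "current"
  p_ind[cur] <- ifelse(is.na(eff[cur]), 0.1, eff[cur])
  # two-character vague reports: use the broad P value
  two <- cur & !is.na(g$base$occupation_code) & nchar(g$base$occupation_code) == 2
  for (i in which(two)) {
    b <- jem_lookup(jem$broad, g$base$occupation_code[i])
    p_ind[i] <- if (b$status == "linked") b$p else 0.1
  }
  s <- as.numeric(stats::runif(g$n) < p_ind)
  eta_ow <- config$baseline_intercepts[["overweight"]] +
    config$individual_log_odds[["overweight"]] * s + g$cov_effects$overweight
  eta_ob <- config$baseline_intercepts[["obese"]] +
    config$individual_log_odds[["obese"]] * s + g$cov_effects$obese
  cls <- draw_class(eta_ow, eta_ob)
  an <- draw_anthropometry(config, cls)
  out <- g$base
  out$height <- an$height
  out$weight <- an$weight
  out$true_exposure_category <- ifelse(g$cat_draw == "missing", "missing_p", g$cat_draw)
  out$true_shift_indicator <- s
  out$drawn_class <- cls
  out
}
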