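WEIGHT_CLASSES <- c("normal_under", "overweight", "obese")

#' Body mass index
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.na(weight) & weight <= 0) || any(!is.na(height) & height <= 0)) {
    stop("domain error: weight and height must be positive")
  }
  weight / height^2
}

#' WHO weight classification
#'
#' Normal/underweight: BMI < 25; overweight: 25 <= BMI < 30; obese:
#' BMI >= 30. Boundaries belong to the upper class.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2, > 0).
#' @return Factor with levels `normal_under`, `overweight`, `obese`.
#' @export
classify_weight <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("domain error: BMI must be positive")
  cls <- ifelse(bmi < 25, "normal_under", ifelse(bmi < 30, "overweight", "obese"))
  factor(cls, levels = WEIGHT_CLASSES)
}

#' Flag outlying measurements for trimming
#'
#' Flags the outermost `fraction` of a measurement's distribution,
#' symmetrically: `fraction / 2` per tail. The rule is an order-statistic
#' one: with `k = floor(n * fraction / 2)`, values strictly below the
#' `(k+1)`-th smallest or strictly above the `(k+1)`-th largest observation
#' are flagged, so at most `k` values are removed per tail and a degenerate
#' (all-equal) sample is never trimmed.
#'
#' @param values Numeric vector of measurements; `NA`s are never flagged.
#' @param fraction Total fraction to trim, split over the two tails
#'   (default 0.002, i.e. the outermost 0.2%). Must lie in `[0, 0.5)`.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
trim_outliers <- function(values, fraction = 0.002) {
  stopifnot(fraction >= 0, fraction < 0.5)
  ok <- !is.na(values)
  out <- rep(FALSE, length(values))
  x <- values[ok]
  n <- length(x)
  if (n == 0) return(out)
  k <- floor(n * fraction / 2)
  s <- sort(x)
  lo <- s[k + 1L]
  hi <- s[n - k]
  out[ok] <- x < lo | x > hi
  out
}

#' Compute, trim, and classify BMI for a study sample
#'
#' Trimming is applied separately to weight and to height; a participant
#' flagged on either variable is excluded from classification. Records with
#' missing height or weight carry `NA` BMI and class.
#'
#' @param study Data frame with `participant_id`, `height` (m), `weight` (kg).
#' @param trim_fraction Total outlier fraction per variable (see
#'   [trim_outliers()]).
#' @return Data frame with `participant_id`, `bmi`, `weight_class`,
#'   `trimmed`.
#' @export
bmi_outcomes <- function(study, trim_fraction = 0.002) {
  trimmed <- trim_outliers(study$weight, trim_fraction) |
    trim_outliers(study$height, trim_fraction)
  bmi <- compute_bmi(study$weight, study$height)
  cls <- classify_weight(bmi)
  cls[trimmed] <- NA
  data.frame(participant_id = study$participant_id,
             bmi = ifelse(trimmed, NA_real_, bmi),
             weight_class = cls,
             trimmed = trimmed,
             stringsAsFactors = FALSE)
}
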