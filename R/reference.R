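#' Published weight-class counts by shift-work probability category
#'
#' The reported per-category weight-class counts (normal/underweight,
#' overweight, obese) and group mean BMI for the two study samples: the
#' population-based sample of currently working women and the university
#' alumni cohort subset, including the missing-P and non-working comparison
#' groups. These printed counts are inputs for worked examples: category
#' percentages and crude (exposure-only) odds ratios are recomputable from
#' them, while the published adjusted estimates are not, since they
#' required the individual-level data.
#'
#' @param sample `"population"`, `"alumni"`, or `"both"`.
#' @return Data frame: `sample`, `group`, `n_group`, `mean_bmi`,
#'   `n_normal`, `n_overweight`, `n_obese`.
#' @export
reference_class_counts <- function(sample = c("both", "population", "alumni")) {
  sample <- match.arg(sample)
  path <- system.file("extdata", "reference_class_counts.csv",
                      package = "shiftjem", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (sample != "both") x <- x[x$sample == sample, , drop = FALSE]
  x
}

#' Crude multinomial fit from aggregated class counts
#'
#' Expands a per-group weight-class contingency table into weighted
#' observations and fits the exposure-only baseline-category model. On a
#' two-group table the fitted ORs equal the closed-form cross-product
#' ratios of the cells (saturated model).
#'
#' @param counts Data frame in the shape of [reference_class_counts()].
#' @param groups Exposure groups to include; the first is the reference.
#' @return A `weight_fit`.
#' @export
fit_crude_from_counts <- function(counts, groups = c("near_nil", "high")) {
  counts <- counts[counts$group %in% groups, , drop = FALSE]
  if (!nrow(counts)) stop("data error: no matching groups in counts")
  long <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(category = counts$group[i],
               weight_class = WEIGHT_CLASSES,
               w = as.numeric(counts[i, c("n_normal", "n_overweight", "n_obese")]),
               stringsAsFactors = FALSE)
  }))
  long <- long[long$w > 0, , drop = FALSE]
  long$category <- factor(long$category, levels = groups)
  long$weight_class <- factor(long$weight_class, levels = WEIGHT_CLASSES)
  fit_weight_model(long, exposure = "category", outcome = "weight_class",
                   exposure_ref = groups[1], weights = long$w)
}
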