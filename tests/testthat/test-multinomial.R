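test_that("saturated two-group fits reproduce closed-form cross-product ratios", {
  set.seed(314)
  for (i in 1:10) {
    cnt <- random_counts_frame()
    f <- fit_crude_from_counts(cnt)
    for (cls in c("n_overweight", "n_obese")) {
      cp_or <- (cnt[2, cls] * cnt[1, "n_normal"]) /
        (cnt[2, "n_normal"] * cnt[1, cls])
      contrast <- if (cls == "n_obese") "obese" else "overweight"
      got <- f$table$or[f$table$contrast == contrast &
                          f$table$term == "categoryhigh"]
      expect_lt(abs(got - cp_or), 1e-6)
    }
  }
})

test_that("collapsing to two outcome levels equals ordinary logistic regression", {
  set.seed(271)
  for (i in 1:5) {
    n <- 300
    d <- data.frame(x = rnorm(n),
                    g = factor(sample(c("a", "b", "c"), n, TRUE)))
    eta <- -0.2 + 0.6 * d$x + 0.4 * (d$g == "b") - 0.3 * (d$g == "c")
    d$y <- factor(ifelse(runif(n) < plogis(eta), "case", "ctrl"),
                  levels = c("ctrl", "case"))
    X <- model.matrix(~ x + g, d)
    m <- multinom_bcl(d$y, X)
    g <- glm(y ~ x + g, data = d, family = binomial(),
             control = glm.control(epsilon = 1e-12))
    expect_lt(max(abs(m$coefficients[, 1] - coef(g))), 1e-8)
    # model-based standard errors agree too
    expect_lt(max(abs(m$se[, 1] - summary(g)$coefficients[, 2])), 1e-6)
  }
})

test_that("three-level fits agree with an independent multinomial implementation", {
  skip_if_not_installed("nnet")
  set.seed(99)
  n <- 600
  d <- data.frame(x = rnorm(n), g = factor(sample(c("a", "b"), n, TRUE)))
  lp1 <- -0.5 + 0.4 * d$x; lp2 <- -1 + 0.8 * d$x + 0.5 * (d$g == "b")
  p0 <- 1 / (1 + exp(lp1) + exp(lp2))
  u <- runif(n)
  d$y <- factor(ifelse(u < p0, "ref", ifelse(u < p0 * (1 + exp(lp1)), "m", "h")),
                levels = c("ref", "m", "h"))
  m <- multinom_bcl(d$y, model.matrix(~ x + g, d))
  nn <- nnet::multinom(y ~ x + g, d, trace = FALSE, reltol = 1e-14)
  expect_lt(max(abs(t(coef(nn)) - m$coefficients)), 1e-6)
  expect_true(m$converged)
})

test_that("the log-likelihood never decreases across Newton iterations", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 2000, seed = 61), jem)
  f <- fit_weight_model(model_frame_from_study(st))
  expect_true(all(diff(f$fit$loglik_trace) >= -1e-9))
  expect_true(f$converged)
  expect_lte(f$fit$grad_norm, 1e-8)
})

test_that("recoding the exposure reference shifts coefficients by beta_ref", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 3000, seed = 62), jem)
  at <- model_frame_from_study(st)
  f1 <- fit_weight_model(at, exposure_ref = "near_nil")
  f2 <- fit_weight_model(at, exposure_ref = "low")
  for (cn in c("overweight", "obese")) {
    b1 <- f1$table[f1$table$contrast == cn, ]
    b2 <- f2$table[f2$table$contrast == cn, ]
    bhigh1 <- b1$estimate[b1$term == "categoryhigh"]
    blow1 <- b1$estimate[b1$term == "categorylow"]
    bhigh2 <- b2$estimate[b2$term == "categoryhigh"]
    expect_lt(abs(bhigh2 - (bhigh1 - blow1)), 1e-6)
    # the recoded model has a near_nil dummy equal to -beta_low
    bnn2 <- b2$estimate[b2$term == "categorynear_nil"]
    expect_lt(abs(bnn2 + blow1), 1e-6)
  }
})

test_that("under null effects the estimates centre on zero with uniform p-values", {
  jem <- default_test_jem()
  null_lo <- list(
    overweight = c(low = 0, medium = 0, high = 0, missing_p = 0, not_working = 0),
    obese = c(low = 0, medium = 0, high = 0, missing_p = 0, not_working = 0))
  reps <- 120
  est <- pv <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- generate_study(study_config(n_participants = 1500,
                                      true_log_odds = null_lo,
                                      seed = 7000 + r), jem)
    f <- fit_weight_model(model_frame_from_study(st))
    row <- f$table[f$table$contrast == "obese" & f$table$term == "categoryhigh", ]
    est[r] <- row$estimate; pv[r] <- row$p_value
  }
  se_mean <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est)), 3.5 * se_mean + 0.02)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("degenerate designs are refused with informative errors", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 1000, seed = 63), jem)
  at <- model_frame_from_study(st)
  at$dup <- as.numeric(at$category == "high")   # collinear with the high dummy
  at$cat2 <- at$category
  expect_error(fit_weight_model(at, covariates = c("dup", "cat2")),
               "singular design")
  expect_error(fit_weight_model(at, exposure = "nope"), "missing column")
  at1 <- at[at$weight_class != "obese", ]
  at1$weight_class <- droplevels(at1$weight_class)
  f2 <- fit_weight_model(at1)      # two observed levels: valid binary fit
  expect_equal(ncol(f2$fit$coefficients), 1)
})

test_that("exposure levels with an empty outcome cell are excluded, not forced", {
  d <- data.frame(
    category = factor(rep(c("near_nil", "high", "missing_p"), c(120, 90, 30)),
                      levels = c("near_nil", "high", "missing_p")),
    weight_class = factor(c(rep(c("normal_under", "overweight", "obese"), 40),
                            rep(c("normal_under", "overweight", "obese"), 30),
                            rep(c("normal_under", "overweight"), 15)),
                          levels = c("normal_under", "overweight", "obese")))
  expect_message(f <- fit_weight_model(d), "missing_p")
  expect_identical(f$dropped_levels, "missing_p")
  expect_false("categorymissing_p" %in% f$table$term)
  expect_true(f$converged)
})

test_that("Wald summaries flag significance consistently with the CIs", {
  # closed-form check: estimate 0 with SE 1 has p = 1
  cnt <- data.frame(group = c("near_nil", "high"),
                    n_normal = c(50, 50), n_overweight = c(30, 30),
                    n_obese = c(20, 20))
  f <- fit_crude_from_counts(cnt)
  ws <- wald_summary(f)
  eff <- ws[ws$term != "(Intercept)", ]
  expect_true(all(abs(eff$estimate) < 1e-8))
  expect_true(all(eff$p_value > 0.999))
  expect_false(any(eff$significant))
  # lower CI bound above 1 on the OR scale iff p < 0.05
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 4000, seed = 64), jem)
  f2 <- fit_weight_model(model_frame_from_study(st))
  ws2 <- wald_summary(f2, alpha = 0.05)
  eff2 <- ws2[ws2$term != "(Intercept)", ]
  expect_identical(eff2$ci_low > 1 | eff2$ci_high < 1, eff2$significant)
  # a non-converged fit refuses to summarize
  f2$converged <- FALSE
  expect_error(wald_summary(f2), "converge")
})

test_that("the likelihood-ratio route agrees in direction with the Wald route", {
  jem <- default_test_jem()
  st <- generate_study(study_config(n_participants = 3000, seed = 65), jem)
  at <- model_frame_from_study(st)
  full <- fit_weight_model(at)
  d0 <- at; d0$one <- factor(ifelse(d0$category == "near_nil", "near_nil", "rest"))
  # reduced model: collapse all non-reference categories
  red <- fit_weight_model(d0, exposure = "one", exposure_ref = "near_nil")
  lr <- lr_test(full, red)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 8)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
})
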