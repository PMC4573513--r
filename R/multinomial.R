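#' Baseline-category multinomial logistic regression
#'
#' Maximum-likelihood fit of the baseline-category (polytomous) logit model:
#' for outcome levels `1..K` with level 1 the reference,
#' `log(P(Y = j) / P(Y = 1)) = x' beta_j` for `j = 2..K`. The likelihood is
#' maximized by full Newton iteration with step-halving; the covariance is
#' the inverse observed information. With `K = 2` the model is ordinary
#' logistic regression.
#'
#' @param y Factor (or coercible) outcome; the first level is the reference.
#' @param X Numeric design matrix (including an intercept column if wanted).
#' @param weights Optional non-negative case weights (e.g. cell counts when
#'   fitting from an aggregated contingency table).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `multinom_fit`: `coefficients` (p x (K-1) matrix,
#'   one column per non-reference level), `se`, `vcov` (stacked
#'   contrast-major), `logLik`, `loglik_trace`, `converged`, `n`,
#'   `outcome_levels`.
#' @export
multinom_bcl <- function(y, X, weights = NULL, tol = 1e-10, max_iter = 100L) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("data error: outcome must have at least 2 observed levels")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular design: collinear term(s): ", paste(bad, collapse = ", "))
  }

  m <- K - 1L
  # indicator matrix for non-reference levels
  Z <- matrix(0, n, m)
  for (j in seq_len(m)) Z[, j] <- as.numeric(y == levels(y)[j + 1L])

  loglik_at <- function(B) {
    eta <- X %*% B
    # log(1 + sum_j exp(eta_j)) computed stably
    M <- pmax(0, apply(eta, 1, max))
    lse <- M + log(exp(-M) + rowSums(exp(eta - M)))
    sum(weights * (rowSums(Z * eta) - lse))
  }
  probs_at <- function(B) {
    eta <- X %*% B
    M <- pmax(0, apply(eta, 1, max))
    denom <- exp(-M) + rowSums(exp(eta - M))
    exp(eta - M) / denom
  }

  B <- matrix(0, p, m)
  ll <- loglik_at(B)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  grad_norm <- Inf

  while (iter < max_iter) {
    iter <- iter + 1L
    P <- probs_at(B)
    # stacked gradient (contrast-major)
    G <- crossprod(X, weights * (Z - P))
    grad_norm <- max(abs(G))
    if (grad_norm <= tol) { converged <- TRUE; break }
    # observed information, (m*p) x (m*p)
    info <- matrix(0, m * p, m * p)
    for (j in seq_len(m)) {
      for (k in j:m) {
        wjk <- weights * (P[, j] * ((j == k) - P[, k]))
        blk <- crossprod(X, X * wjk)
        ri <- (j - 1L) * p + seq_len(p)
        ci <- (k - 1L) * p + seq_len(p)
        info[ri, ci] <- blk
        if (j != k) info[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(info, as.vector(G)),
                     error = function(e) stop("singular design: information matrix not invertible"))
    # step-halving: the likelihood never decreases across iterations
    lambda <- 1
    repeat {
      Bnew <- B + matrix(lambda * step, p, m)
      llnew <- loglik_at(Bnew)
      if (llnew >= ll - 1e-12 || lambda < 2^-30) break
      lambda <- lambda / 2
    }
    B <- Bnew
    ll <- llnew
    trace <- c(trace, ll)
  }

  P <- probs_at(B)
  info <- matrix(0, m * p, m * p)
  for (j in seq_len(m)) {
    for (k in j:m) {
      wjk <- weights * (P[, j] * ((j == k) - P[, k]))
      blk <- crossprod(X, X * wjk)
      ri <- (j - 1L) * p + seq_len(p)
      ci <- (k - 1L) * p + seq_len(p)
      info[ri, ci] <- blk
      if (j != k) info[ci, ri] <- t(blk)
    }
  }
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, m * p, m * p))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, m)
  dimnames(B) <- dimnames(se) <- list(colnames(X), levels(y)[-1])

  structure(list(coefficients = B, se = se, vcov = V, logLik = ll,
                 loglik_trace = trace, converged = converged,
                 iterations = iter, grad_norm = grad_norm,
                 n = sum(weights > 0), nobs = n,
                 outcome_levels = levels(y), terms = colnames(X)),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("Baseline-category multinomial fit: %d obs, %d contrasts, logLik %.3f, %s\n",
              x$nobs, ncol(x$coefficients), x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the weight-class regression on exposure and covariates
#'
#' Fits the baseline-category multinomial logit of weight class
#' (reference = normal/underweight) on shift-work exposure category
#' (reference = near nil) plus covariates, reporting odds ratios with 95%
#' Wald intervals (`exp(coef +/- 1.96 * SE)`) and two-tailed p-values.
#' Rows with any missing model variable are dropped (complete case).
#' Exposure levels with an empty outcome cell cannot be estimated and are
#' excluded with a message, mirroring low-cell-count removal.
#'
#' @param data Data frame holding outcome, exposure, and covariates.
#' @param exposure Name of the exposure column (factor-like).
#' @param covariates Character vector of covariate column names (factors or
#'   numeric).
#' @param outcome Name of the outcome column (3-level weight class, or
#'   2-level after a collapse).
#' @param exposure_ref,outcome_ref Reference levels.
#' @param weights Optional case weights column values.
#' @param ... Passed to [multinom_bcl()] (`tol`, `max_iter`).
#' @return Object of class `weight_fit`: the underlying `multinom_fit`, a
#'   tidy `table` (contrast, term, estimate, se, or, ci_low, ci_high,
#'   p_value), `n_used`, `dropped_levels`, and bookkeeping fields.
#' @export
fit_weight_model <- function(data, exposure = "category",
                             covariates = character(), outcome = "weight_class",
                             exposure_ref = "near_nil",
                             outcome_ref = "normal_under",
                             weights = NULL, ...) {
  vars <- c(outcome, exposure, covariates)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) stop("data error: missing column(s): ",
                                 paste(missing_vars, collapse = ", "))
  d <- data[, vars, drop = FALSE]
  if (!is.null(weights)) d$.w <- weights
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]

  d[[outcome]] <- stats::relevel(droplevels(as.factor(d[[outcome]])), ref = outcome_ref)
  d[[exposure]] <- stats::relevel(droplevels(as.factor(d[[exposure]])), ref = exposure_ref)
  if (nlevels(d[[outcome]]) < 2) stop("data error: outcome level(s) empty after filtering")

  # exposure levels with an empty outcome cell are inestimable: drop them
  tab <- table(d[[exposure]], d[[outcome]])
  bad_levels <- rownames(tab)[apply(tab == 0, 1, any)]
  if (exposure_ref %in% bad_levels) {
    stop("data error: reference exposure level has an empty outcome cell")
  }
  if (length(bad_levels)) {
    message("excluding exposure level(s) with an empty outcome cell: ",
            paste(bad_levels, collapse = ", "))
    d <- d[!d[[exposure]] %in% bad_levels, , drop = FALSE]
    d[[exposure]] <- droplevels(d[[exposure]])
  }
  if (nlevels(d[[exposure]]) < 2) {
    stop("data error: no estimable exposure contrast remains ",
         "(every non-reference level has an empty outcome cell)")
  }

  for (v in covariates) if (!is.numeric(d[[v]])) d[[v]] <- droplevels(as.factor(d[[v]]))

  fml <- stats::reformulate(c(exposure, covariates))
  X <- stats::model.matrix(fml, data = d)
  w <- if (is.null(weights)) NULL else d$.w
  fit <- multinom_bcl(d[[outcome]], X, weights = w, ...)

  contrasts <- colnames(fit$coefficients)
  tabl <- do.call(rbind, lapply(contrasts, function(cn) {
    est <- fit$coefficients[, cn]
    se <- fit$se[, cn]
    data.frame(contrast = cn, term = rownames(fit$coefficients),
               estimate = est, se = se,
               or = exp(est),
               ci_low = exp(est - 1.96 * se),
               ci_high = exp(est + 1.96 * se),
               p_value = 2 * stats::pnorm(-abs(est / se)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  structure(list(fit = fit, table = tabl, n_used = nrow(d),
                 dropped_levels = bad_levels,
                 exposure = exposure, covariates = covariates,
                 outcome = outcome,
                 exposure_levels = levels(d[[exposure]]),
                 converged = fit$converged, logLik = fit$logLik),
            class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("Weight-class model: n = %d, covariates: %s\n", x$n_used,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)"))
  tt <- x$table[x$table$term != "(Intercept)", ]
  tt[, c("estimate", "se", "or", "ci_low", "ci_high")] <-
    round(tt[, c("estimate", "se", "or", "ci_low", "ci_high")], 3)
  tt$p_value <- signif(tt$p_value, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Exposure odds ratios from a fitted weight model
#'
#' @param fit A `weight_fit`.
#' @param levels Exposure dummy levels of interest (default the three
#'   informative contrasts low/medium/high).
#' @return Matrix of ORs, contrasts in rows, exposure levels in columns;
#'   `NA` where a level was dropped.
#' @export
exposure_ors <- function(fit, levels = c("low", "medium", "high")) {
  terms <- paste0(fit$exposure, levels)
  contrasts <- unique(fit$table$contrast)
  out <- matrix(NA_real_, length(contrasts), length(levels),
                dimnames = list(contrasts, levels))
  for (cn in contrasts) {
    sub <- fit$table[fit$table$contrast == cn, ]
    out[cn, ] <- sub$or[match(terms, sub$term)]
  }
  out
}

#' Significance-annotated Wald summary
#'
#' @param fit A converged `weight_fit`.
#' @param alpha Two-tailed significance level (CI level `1 - alpha`).
#' @return The fit's coefficient table with `ci_low`/`ci_high` at the
#'   requested level and a logical `significant` column (`p < alpha`).
#' @export
wald_summary <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "weight_fit"))
  if (!fit$converged) {
    stop("fit did not converge (gradient max-norm ", format(fit$fit$grad_norm),
         "); refusing to summarize")
  }
  z <- if (alpha == 0.05) 1.96 else stats::qnorm(1 - alpha / 2)
  tt <- fit$table
  tt$ci_low <- exp(tt$estimate - z * tt$se)
  tt$ci_high <- exp(tt$estimate + z * tt$se)
  tt$significant <- tt$p_value < alpha
  tt
}

#' Likelihood-ratio statistic between nested weight-model fits
#'
#' Secondary inference route alongside the Wald tests.
#'
#' @param fit_full,fit_reduced Nested `weight_fit` objects on the same data.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  stat <- 2 * (fit_full$logLik - fit_reduced$logLik)
  df <- length(fit_full$fit$coefficients) - length(fit_reduced$fit$coefficients)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
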