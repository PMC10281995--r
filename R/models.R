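## Exposure -> neuropathology association battery.
##
## Separate age-adjusted regressions per exposure measure (logistic for
## CTE status and severity, linear for NFT burden), with effects reported
## per scaled unit: per concussion, non-speed vs speed, per year of play,
## per 1,000 hits, per 10,000 g, per 1,000,000 rad/s^2.  Model comparison
## uses BIC evidence categories, paired bootstrap ROC tests and 10-fold
## cross-validated Brier scores.

exposure_units <- function() {
  c(concussion_count = "per concussion",
    speed_flag = "non-speed vs speed",
    duration = "per year of play",
    chii = "per 1,000 hits",
    chii_g = "per 10,000 g",
    chii_r = "per 1,000,000 rad/s^2")
}

## scaled exposure column for model fitting
exposure_vector <- function(data, exposure) {
  switch(exposure,
    concussion_count = data$concussion_count,
    speed_flag = as.numeric(data$speed_flag == "non_speed"),
    duration = data$duration,
    chii = data$chii / 1000,
    chii_g = data$chii_g / 10000,
    chii_r = data$chii_r / 1e6,
    abort_invalid(paste0("unknown exposure measure: '", exposure, "'"))
  )
}

#' Specify one exposure-outcome model
#'
#' @param outcome \code{"cte_status"} (absent vs present),
#'   \code{"cte_severity"} (low vs high stage, fitted on the CTE-positive
#'   subset) or \code{"nft_burden"} (0--33 sum, fitted on donors with the
#'   complete 11-region panel).
#' @param exposure One of \code{"concussion_count"}, \code{"speed_flag"},
#'   \code{"duration"}, \code{"chii"}, \code{"chii_g"}, \code{"chii_r"}.
#'   The index exposures are scaled before fitting so estimates are per
#'   1,000 hits, per 10,000 g and per 1,000,000 rad/s^2 respectively.
#' @param adjust_age Include age at death as a covariate (default TRUE).
#' @return A list of class \code{"model_spec"}.
#' @export
model_spec <- function(outcome = c("cte_status", "cte_severity", "nft_burden"),
                       exposure = c("duration", "chii", "chii_g", "chii_r",
                                    "concussion_count", "speed_flag"),
                       adjust_age = TRUE) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  structure(list(outcome = outcome, exposure = exposure,
                 adjust_age = isTRUE(adjust_age),
                 unit = exposure_units()[[exposure]]),
            class = "model_spec")
}

## apply the model specification's subset rule and return (y, x, age)
model_frame <- function(data, spec) {
  if (spec$outcome == "cte_severity") {
    data <- data[data$cte_status == "present", , drop = FALSE]
  }
  if (spec$outcome == "nft_burden") {
    data <- data[!is.na(data$nft_burden), , drop = FALSE]
  }
  y <- switch(spec$outcome,
    cte_status = as.numeric(data$cte_status == "present"),
    cte_severity = as.numeric(data$cte_stage == "high"),
    nft_burden = as.numeric(data$nft_burden)
  )
  x <- exposure_vector(data, spec$exposure)
  keep <- !is.na(y) & !is.na(x) & !is.na(data$age_at_death)
  list(y = y[keep], x = x[keep], age = data$age_at_death[keep])
}

fit_result <- function(model, spec, n, family) {
  co <- summary(model)$coefficients
  est <- co["x", 1]
  se <- co["x", 2]
  p <- co["x", 4]
  ll <- as.numeric(stats::logLik(model))
  df_params <- attr(stats::logLik(model), "df")
  bic <- df_params * log(n) - 2 * ll
  ci_lo <- est - stats::qnorm(0.975) * se
  ci_hi <- est + stats::qnorm(0.975) * se
  out <- list(
    spec = spec,
    estimate = est,
    or_or_beta = if (family == "binomial") exp(est) else est,
    ci95 = if (family == "binomial") exp(c(ci_lo, ci_hi)) else c(ci_lo, ci_hi),
    p_value = p,
    log_likelihood = ll,
    df = df_params,
    bic = bic,
    r_squared = if (family == "gaussian") summary(model)$r.squared else NULL,
    n = n,
    model = model
  )
  class(out) <- "rhipem_fit"
  out
}

#' @export
print.rhipem_fit <- function(x, ...) {
  lab <- if (inherits(x$model, "glm")) "OR" else "beta"
  cat(sprintf("%s ~ %s (%s), n = %d\n  %s = %.3f (95%% CI %.3f-%.3f), p = %.3g, BIC = %.1f\n",
              x$spec$outcome, x$spec$exposure, x$spec$unit, x$n, lab,
              x$or_or_beta, x$ci95[1], x$ci95[2], x$p_value, x$bic))
  invisible(x)
}

#' Age-adjusted logistic regression of a binary CTE outcome on one exposure
#'
#' Maximum-likelihood logistic fit of the outcome (CTE status, or
#' severity on the CTE-positive subset) on the scaled exposure, plus age
#' at death when \code{spec$adjust_age}.  The Wald 95% interval on the
#' log-odds is exponentiated for reporting.  BIC is
#' \eqn{k \ln n - 2 \ell}.
#'
#' @param data Donor table (see [simulate_cohort()] for the columns).
#' @param spec A [model_spec()] with a binary outcome.
#' @return A \code{"rhipem_fit"} object.
#' @export
fit_binary <- function(data, spec) {
  if (spec$outcome == "nft_burden") abort_invalid("use fit_linear() for nft_burden")
  mf <- model_frame(data, spec)
  n <- length(mf$y)
  if (n == 0 || length(unique(mf$y)) < 2) {
    abort_model("outcome has a single class after subsetting",
                class = "rhipem_degenerate_design")
  }
  if (stats::var(mf$x) == 0) {
    abort_model("exposure is constant: degenerate design",
                class = "rhipem_degenerate_design")
  }
  n_events <- sum(mf$y)
  if (min(n_events, n - n_events) < 10) {
    warning("fewer than 10 events in one outcome arm; estimates may be unstable")
  }
  fml <- if (spec$adjust_age) y ~ x + age else y ~ x
  fit <- stats::glm(fml, family = stats::binomial(),
                    data = data.frame(y = mf$y, x = mf$x, age = mf$age),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort_model("logistic fit did not converge within the iteration cap",
                class = "rhipem_nonconvergence")
  }
  eta <- abs(stats::predict(fit, type = "link"))
  if (max(eta) > 25 && all(abs(stats::fitted(fit) - mf$y) < 1e-6)) {
    abort_model("complete or quasi-complete separation detected",
                class = "rhipem_separation")
  }
  fit_result(fit, spec, n, "binomial")
}

#' Age-adjusted linear regression of NFT burden on one exposure
#'
#' Ordinary least squares on the complete-case subset (donors with all 11
#' NFT regions scored).  Reports the mean difference in burden per scaled
#' exposure unit, Wald 95% CI, p-value, R-squared and Gaussian BIC.
#'
#' @inheritParams fit_binary
#' @param spec A [model_spec()] with outcome \code{"nft_burden"}.
#' @return A \code{"rhipem_fit"} object.
#' @export
fit_linear <- function(data, spec) {
  if (spec$outcome != "nft_burden") abort_invalid("fit_linear() expects outcome 'nft_burden'")
  mf <- model_frame(data, spec)
  n <- length(mf$y)
  n_par <- 2 + spec$adjust_age
  if (n <= n_par) abort_model("more parameters than observations")
  if (stats::var(mf$x) == 0) {
    abort_model("exposure is constant: degenerate design",
                class = "rhipem_degenerate_design")
  }
  fml <- if (spec$adjust_age) y ~ x + age else y ~ x
  fit <- stats::lm(fml, data = data.frame(y = mf$y, x = mf$x, age = mf$age))
  fit_result(fit, spec, n, "gaussian")
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' The AUC is computed as the Mann-Whitney concordance: the probability
#' that a random case outscores a random control, counting ties as one
#' half.  The confidence interval is a seeded percentile bootstrap over
#' donors.
#'
#' @param scores Numeric predictor (fitted probability or linear
#'   predictor) per donor.
#' @param labels Binary outcome per donor (0/1 or logical).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class \code{"auc_result"}: \code{auc}, \code{ci95},
#'   \code{n_boot}, \code{seed}, \code{n}.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 200, seed = 1)$auc # 0.75
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) abort_invalid("scores and labels differ in length")
  if (length(unique(labels)) < 2) abort_invalid("both outcome classes must be present")
  auc <- auc_stat(scores, labels)
  boots <- with_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(labels), replace = TRUE)
      if (length(unique(labels[i])) < 2) return(NA_real_)
      auc_stat(scores[i], labels[i])
    }, 0)
  })
  structure(list(auc = auc,
                 ci95 = stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                                        names = FALSE),
                 n_boot = n_boot, seed = seed, n = length(labels)),
            class = "auc_result")
}

## Mann-Whitney AUC via ranks (ties count half)
auc_stat <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired bootstrap test for an AUC difference
#'
#' Compares the discriminative power of two models scored on the same
#' donors: donors are resampled with replacement \code{n_boot} times,
#' both AUCs recomputed per replicate, and a two-sided percentile
#' p-value taken from the replicate distribution of the difference
#' against zero.
#'
#' @param scores_a,scores_b Predictors from the two models, paired on the
#'   same donors.
#' @param labels Binary outcome per donor.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return A list: \code{auc_a}, \code{auc_b}, \code{delta},
#'   \code{p_value}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_auc_diff <- function(scores_a, scores_b, labels, n_boot = 2000, seed = 1) {
  labels <- as.numeric(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort_invalid("scores_a, scores_b and labels must be paired (equal length)")
  }
  if (length(unique(labels)) < 2) abort_invalid("both outcome classes must be present")
  deltas <- with_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(labels), replace = TRUE)
      if (length(unique(labels[i])) < 2) return(NA_real_)
      auc_stat(scores_a[i], labels[i]) - auc_stat(scores_b[i], labels[i])
    }, 0)
  })
  deltas <- deltas[!is.na(deltas)]
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(auc_a = auc_stat(scores_a, labels),
       auc_b = auc_stat(scores_b, labels),
       delta = auc_stat(scores_a, labels) - auc_stat(scores_b, labels),
       p_value = min(1, p), n_boot = n_boot, seed = seed)
}

#' 10-fold cross-validated prediction error
#'
#' Randomly partitions the donors into \code{k} folds (sizes within one
#' of each other), refits the model on each training set and predicts
#' probabilities on the held-out fold.  The mean error is the Brier
#' score: the mean squared difference between predicted probability and
#' the 0/1 outcome, pooled over all donors.
#'
#' @param data Donor table.
#' @param spec A [model_spec()] with a binary outcome.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the partition.
#' @return A list of class \code{"cv_result"}: \code{k},
#'   \code{per_fold_errors}, \code{mean_error}, \code{fold_sizes},
#'   \code{seed}.
#' @export
kfold_cv <- function(data, spec, k = 10, seed = 1) {
  mf <- model_frame(data, spec)
  n <- length(mf$y)
  if (n < k) abort_invalid("need at least k donors for k-fold cross-validation")
  folds <- with_seed(derive_seed(seed, "folds"), {
    sample(rep(seq_len(k), length.out = n))
  })
  df <- data.frame(y = mf$y, x = mf$x, age = mf$age)
  fml <- if (spec$adjust_age) y ~ x + age else y ~ x
  sq_err <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    train <- df[!test, , drop = FALSE]
    if (length(unique(train$y)) < 2) {
      abort_model(paste0("training fold ", f, " has a single outcome class"),
                  class = "rhipem_fold_error")
    }
    fit <- stats::glm(fml, family = stats::binomial(), data = train)
    p <- stats::predict(fit, newdata = df[test, , drop = FALSE],
                        type = "response")
    sq_err[test] <- (p - df$y[test])^2
    per_fold[f] <- mean(sq_err[test])
  }
  structure(list(k = k, per_fold_errors = per_fold,
                 mean_error = mean(sq_err),
                 fold_sizes = as.integer(table(folds)), seed = seed),
            class = "cv_result")
}

#' BIC evidence category for a model-fit difference
#'
#' Conventional evidence bands on the absolute BIC difference: below 2,
#' no evidence; 2--6, positive; 6--10, strong; above 10, very strong.
#'
#' @param delta_bic Numeric BIC difference.
#' @return One of \code{"none"}, \code{"positive"}, \code{"strong"},
#'   \code{"very_strong"}.
#' @export
bic_evidence_category <- function(delta_bic) {
  d <- abs(delta_bic)
  if (d < 2) "none" else if (d <= 6) "positive" else if (d <= 10) "strong" else "very_strong"
}

#' Compare two fitted exposure models
#'
#' Computes the BIC difference (model b minus model a, so a positive
#' value favours model a), its evidence category, and carries through a
#' bootstrap AUC-difference p-value when supplied.  Significance is
#' flagged at the Bonferroni-adjusted level 0.0083.
#'
#' @param fit_a,fit_b \code{"rhipem_fit"} objects on the same donors and
#'   outcome.
#' @param auc_p Optional p-value from [bootstrap_auc_diff()].
#' @param alpha Bonferroni-adjusted significance level (default 0.0083).
#' @return A list of class \code{"model_comparison"}: \code{delta_bic},
#'   \code{evidence_category}, \code{auc_diff_p},
#'   \code{auc_diff_significant}.
#' @export
compare_models <- function(fit_a, fit_b, auc_p = NA_real_, alpha = 0.0083) {
  stopifnot(inherits(fit_a, "rhipem_fit"), inherits(fit_b, "rhipem_fit"))
  if (fit_a$n != fit_b$n) {
    abort_invalid("fits were made on different numbers of donors; comparison undefined")
  }
  delta <- fit_b$bic - fit_a$bic
  structure(list(delta_bic = delta,
                 evidence_category = bic_evidence_category(delta),
                 auc_diff_p = auc_p,
                 auc_diff_significant = !is.na(auc_p) && auc_p < alpha,
                 alpha = alpha),
            class = "model_comparison")
}

#' Fit the full exposure-outcome model grid
#'
#' Runs the six exposure measures against the three outcomes (logistic
#' for CTE status and severity, linear for NFT burden), each adjusted
#' for age at death, and flags Bonferroni significance at
#' \code{alpha = 0.0083}.  For significant exposures in the binary
#' outcomes it also reports the ROC AUC and the 10-fold cross-validated
#' Brier score, following the convention of reporting model-performance
#' companions only where the exposure passes screening.
#'
#' @param donors Donor table (as produced by [simulate_cohort()]).
#' @param exposures Character vector of exposure measures to fit.
#' @param outcomes Character vector of outcomes to fit.
#' @param alpha Bonferroni-adjusted significance level.
#' @param screen_alpha Screening level for computing AUC/CV companions
#'   (default 0.05).
#' @param n_boot,k,seed Companion-analysis settings.
#' @return A list with \code{results} (one row per outcome-exposure pair
#'   attempted: estimate, CI, p, BIC, AUC, CV error, n) and \code{fits}
#'   (the underlying \code{"rhipem_fit"} objects, named
#'   \code{outcome.exposure}).  Severity models whose subset is too small
#'   are skipped with a logged reason in the \code{skipped} element.
#' @export
fit_exposure_grid <- function(donors,
                              exposures = c("concussion_count", "speed_flag",
                                            "duration", "chii", "chii_g", "chii_r"),
                              outcomes = c("cte_status", "cte_severity", "nft_burden"),
                              alpha = 0.0083, screen_alpha = 0.05,
                              n_boot = 2000, k = 10, seed = 1) {
  rows <- list()
  fits <- list()
  skipped <- character(0)
  for (outcome in outcomes) {
    for (exposure in exposures) {
      spec <- model_spec(outcome, exposure)
      tag <- paste(outcome, exposure, sep = ".")
      fit <- tryCatch(
        if (outcome == "nft_burden") fit_linear(donors, spec)
        else suppressWarnings(fit_binary(donors, spec)),
        rhipem_error = function(e) conditionMessage(e)
      )
      if (is.character(fit)) {
        skipped <- c(skipped, stats::setNames(fit, tag))
        next
      }
      fits[[tag]] <- fit
      auc <- NA_real_; auc_lo <- NA_real_; auc_hi <- NA_real_; cv <- NA_real_
      if (outcome != "nft_burden" && fit$p_value < screen_alpha) {
        mf <- model_frame(donors, spec)
        scores <- stats::predict(fit$model, type = "response")
        a <- roc_auc(scores, mf$y, n_boot = n_boot, seed = seed)
        auc <- a$auc; auc_lo <- a$ci95[1]; auc_hi <- a$ci95[2]
        cv <- kfold_cv(donors, spec, k = k, seed = seed)$mean_error
      }
      rows[[tag]] <- data.frame(
        outcome = outcome, exposure = exposure, unit = spec$unit,
        estimate = fit$estimate, or_or_beta = fit$or_or_beta,
        ci_low = fit$ci95[1], ci_high = fit$ci95[2],
        p = fit$p_value,
        r_squared = if (is.null(fit$r_squared)) NA_real_ else fit$r_squared,
        bic = fit$bic, auc = auc, auc_ci_low = auc_lo, auc_ci_high = auc_hi,
        cv_mean_error = cv, n = fit$n,
        significant = fit$p_value < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, fits = fits, skipped = skipped,
       alpha = alpha, seed = seed)
}

#' Pairwise comparison of significant exposure models
#'
#' For every pair of fitted exposure models for one binary outcome,
#' computes the BIC difference with its evidence category and the paired
#' bootstrap AUC-difference p-value.
#'
#' @param donors Donor table.
#' @param grid Output of [fit_exposure_grid()].
#' @param outcome Which binary outcome's fits to compare.
#' @param n_boot,seed Bootstrap settings.
#' @return Data frame with one row per ordered pair:
#'   \code{model_a}, \code{model_b}, \code{delta_bic}, \code{category},
#'   \code{auc_diff_p}.
#' @export
compare_exposure_models <- function(donors, grid, outcome = "cte_status",
                                    n_boot = 2000, seed = 1) {
  tags <- names(grid$fits)
  tags <- tags[startsWith(tags, paste0(outcome, "."))]
  keep <- vapply(tags, function(t) grid$fits[[t]]$p_value < 0.05, FALSE)
  tags <- tags[keep]
  if (length(tags) < 2) {
    return(data.frame(model_a = character(0), model_b = character(0),
                      delta_bic = numeric(0), category = character(0),
                      auc_diff_p = numeric(0)))
  }
  score_of <- function(tag) stats::predict(grid$fits[[tag]]$model, type = "response")
  spec1 <- grid$fits[[tags[1]]]$spec
  y <- model_frame(donors, spec1)$y
  out <- list()
  for (i in seq_along(tags)) {
    for (j in seq_along(tags)) {
      if (i >= j) next
      a <- tags[i]; b <- tags[j]
      bd <- bootstrap_auc_diff(score_of(a), score_of(b), y,
                               n_boot = n_boot, seed = seed)
      cmpr <- compare_models(grid$fits[[a]], grid$fits[[b]], bd$p_value)
      out[[paste(a, b)]] <- data.frame(
        model_a = sub(paste0(outcome, "."), "", a, fixed = TRUE),
        model_b = sub(paste0(outcome, "."), "", b, fixed = TRUE),
        delta_bic = cmpr$delta_bic, category = cmpr$evidence_category,
        auc_diff_p = bd$p_value, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
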