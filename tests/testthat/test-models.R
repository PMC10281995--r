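# Age-adjusted association battery: logistic and linear fits, ROC/AUC,
# bootstrap comparison, cross-validation and BIC evidence categories.

pem <- football_pem()

test_that("a 2x2 logistic fit reproduces the cross-product odds ratio", {
  d <- donors_2x2(a = 10, b = 5, c = 5, d = 10)
  fit <- suppressWarnings(
    fit_binary(d, model_spec("cte_status", "duration", adjust_age = FALSE)))
  expect_equal(fit$or_or_beta, 4.0, tolerance = 1e-6)  # ad/bc
  # random 2x2 designs, against the closed form
  set.seed(1)
  for (i in 1:10) {
    cnt <- sample(5:40, 4, replace = TRUE)
    d <- donors_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    fit <- suppressWarnings(
      fit_binary(d, model_spec("cte_status", "duration", adjust_age = FALSE)))
    expect_equal(fit$or_or_beta, (cnt[1] * cnt[4]) / (cnt[2] * cnt[3]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and separated designs raise explicit errors", {
  d <- donors_2x2(10, 5, 5, 10)
  d$duration <- 3  # constant exposure
  expect_error(fit_binary(d, model_spec("cte_status", "duration")),
               class = "rhipem_degenerate_design")
  sep <- data.frame(
    cte_status = rep(c("present", "absent"), each = 30),
    duration = c(rnorm(30, 20, 1), rnorm(30, 2, 1)),
    age_at_death = 60
  )
  expect_error(
    suppressWarnings(
      fit_binary(sep, model_spec("cte_status", "duration", adjust_age = FALSE))),
    class = "rhipem_separation")
})

test_that("a null exposure fits an odds ratio near one", {
  set.seed(33)
  d <- data.frame(
    cte_status = ifelse(runif(10000) < 0.5, "present", "absent"),
    duration = rnorm(10000, 12, 5),
    age_at_death = rnorm(10000, 60, 15)
  )
  fit <- fit_binary(d, model_spec("cte_status", "duration"))
  se <- (log(fit$ci95[2]) - log(fit$ci95[1])) / (2 * qnorm(0.975))
  expect_lt(abs(fit$estimate), 3 * se)
})

test_that("linear NFT models recover exact and noisy effects", {
  d <- data.frame(nft_burden = 0.5 * (1:40), duration = 1:40,
                  age_at_death = 60, cte_status = "present")
  # a noiseless design triggers lm's perfect-fit warning by construction
  fit <- suppressWarnings(
    fit_linear(d, model_spec("nft_burden", "duration", adjust_age = FALSE)))
  expect_equal(fit$or_or_beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(7)
  n <- 5000
  dur <- rnorm(n, 12, 5); age <- rnorm(n, 60, 15)
  d2 <- data.frame(nft_burden = 0.47 * dur + 0.1 * age + rnorm(n, 0, 4),
                   duration = dur, age_at_death = age, cte_status = "present")
  fit2 <- fit_linear(d2, model_spec("nft_burden", "duration"))
  expect_true(fit2$ci95[1] <= 0.47 && 0.47 <= fit2$ci95[2])

  d3 <- data.frame(nft_burden = rnorm(n), duration = dur,
                   age_at_death = age, cte_status = "present")
  fit3 <- fit_linear(d3, model_spec("nft_burden", "duration"))
  expect_lt(abs(fit3$estimate), 0.05)
  expect_lt(fit3$r_squared, 0.01)
  expect_error(fit_linear(d3[1:3, ], model_spec("nft_burden", "duration")),
               class = "rhipem_model_error")
})

test_that("the complete-case rule drops donors with partial NFT panels", {
  d <- data.frame(nft_burden = c(1:20, NA, NA), duration = c(1:20, 50, 60),
                  age_at_death = 60, cte_status = "present")
  fit <- suppressWarnings(
    fit_linear(d, model_spec("nft_burden", "duration", adjust_age = FALSE)))
  expect_equal(fit$n, 20)
})

test_that("AUC equals the all-pairs concordance and is rank-invariant", {
  a <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 100, seed = 1)
  expect_equal(a$auc, 0.75)  # 3 of 4 case-control pairs concordant
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1), n_boot = 10)$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5), n_boot = 10)$auc, 0.5)

  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    got <- roc_auc(scores, labels, n_boot = 10, seed = i)$auc
    expect_identical(got, oracle_auc(scores, labels))
    # strictly increasing transforms leave the AUC unchanged
    expect_identical(roc_auc(exp(2 * scores), labels, n_boot = 10)$auc, got)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1), n_boot = 10),
               class = "rhipem_invalid_input")
})

test_that("our AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  ours <- roc_auc(scores, labels, n_boot = 10)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("bootstrap AUC comparison separates models and passes the null", {
  set.seed(2)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  perfect <- y + runif(n, 0, 0.1)
  noise <- runif(n)
  self <- bootstrap_auc_diff(perfect, perfect, y, n_boot = 500, seed = 1)
  expect_gte(self$p_value, 0.99)
  strong <- bootstrap_auc_diff(perfect, noise, y, n_boot = 500, seed = 1)
  expect_lt(strong$p_value, 0.01)
  expect_error(bootstrap_auc_diff(perfect[-1], noise, y),
               class = "rhipem_invalid_input")
})

test_that("cross-validation partitions donors and scores honest errors", {
  set.seed(12)
  n <- 237
  d <- data.frame(
    cte_status = ifelse(rbinom(n, 1, 0.4) == 1, "present", "absent"),
    duration = rnorm(n, 12, 5),
    age_at_death = rnorm(n, 60, 15)
  )
  cv <- kfold_cv(d, model_spec("cte_status", "duration"), k = 10, seed = 3)
  expect_equal(sum(cv$fold_sizes), n)
  expect_lte(max(cv$fold_sizes) - min(cv$fold_sizes), 1)
  expect_equal(length(cv$per_fold_errors), 10)

  # perfectly predictable outcome: near-zero Brier score
  sep <- data.frame(
    cte_status = rep(c("present", "absent"), each = 50),
    duration = rep(c(20, 2), each = 50),
    age_at_death = 60
  )
  cv2 <- suppressWarnings(
    kfold_cv(sep, model_spec("cte_status", "duration", adjust_age = FALSE),
             k = 10, seed = 1))
  expect_lt(cv2$mean_error, 1e-4)

  # an uninformative predictor approaches the constant-predictor Brier
  # score pi*(1-pi)
  set.seed(9)
  n2 <- 2000; pi0 <- 0.3
  d3 <- data.frame(
    cte_status = ifelse(rbinom(n2, 1, pi0) == 1, "present", "absent"),
    duration = rnorm(n2),
    age_at_death = rnorm(n2, 60, 15)
  )
  cv3 <- kfold_cv(d3, model_spec("cte_status", "duration", adjust_age = FALSE),
                  k = 10, seed = 2)
  expect_lt(abs(cv3$mean_error - pi0 * (1 - pi0)), 0.02)

  tiny <- d[1:5, ]
  expect_error(kfold_cv(tiny, model_spec("cte_status", "duration"), k = 10),
               class = "rhipem_invalid_input")
})

test_that("BIC matches its definition and comparisons map to categories", {
  co <- simulate_cohort(cohort_params(400, seed = 14), pem)
  for (expo in c("duration", "chii_g")) {
    fit <- fit_binary(co$donors, model_spec("cte_status", expo))
    expect_equal(fit$bic, fit$df * log(fit$n) - 2 * fit$log_likelihood,
                 tolerance = 1e-12)
    expect_equal(fit$bic, BIC(fit$model), tolerance = 1e-8)
    expect_true(fit$ci95[1] <= fit$or_or_beta && fit$or_or_beta <= fit$ci95[2])
  }
  lin <- fit_linear(co$donors, model_spec("nft_burden", "duration"))
  expect_equal(lin$bic, lin$df * log(lin$n) - 2 * lin$log_likelihood,
               tolerance = 1e-12)

  fa <- fit_binary(co$donors, model_spec("cte_status", "duration"))
  fb <- fit_binary(co$donors, model_spec("cte_status", "chii_g"))
  cmp <- compare_models(fa, fb, auc_p = 0.5)
  expect_equal(cmp$delta_bic, fb$bic - fa$bic, tolerance = 1e-12)
  self <- compare_models(fa, fa)
  expect_equal(self$delta_bic, 0)
  expect_equal(self$evidence_category, "none")
  expect_equal(bic_evidence_category(11.3), "very_strong")
  expect_equal(bic_evidence_category(-11.3), "very_strong")
  expect_equal(bic_evidence_category(4), "positive")
  expect_equal(bic_evidence_category(8), "strong")
  expect_equal(bic_evidence_category(1.2), "none")

  short <- fit_binary(co$donors[1:300, ], model_spec("cte_status", "duration"))
  expect_error(compare_models(fa, short), class = "rhipem_invalid_input")
})

test_that("dropping the age covariate does not flip a strong exposure effect", {
  co <- simulate_cohort(cohort_params(2000, seed = 19), pem)
  with_age <- fit_binary(co$donors, model_spec("cte_status", "duration"))
  without <- fit_binary(co$donors,
                        model_spec("cte_status", "duration", adjust_age = FALSE))
  expect_true(with_age$estimate > 0 && without$estimate > 0)
  expect_lt(abs(with_age$estimate - without$estimate), 0.1)
})

test_that("the model grid covers every attempted outcome-exposure pair", {
  co <- simulate_cohort(cohort_params(800, seed = 23), pem)
  grid <- fit_exposure_grid(co$donors, n_boot = 100, seed = 2)
  res <- grid$results
  expect_equal(nrow(res), 18)  # 6 exposures x 3 outcomes
  expect_setequal(unique(res$outcome),
                  c("cte_status", "cte_severity", "nft_burden"))
  # the duration-driven generator makes all cumulative measures significant
  strong <- res[res$outcome == "cte_status" &
                  res$exposure %in% c("duration", "chii", "chii_g", "chii_r"), ]
  expect_true(all(strong$significant))
  expect_true(all(is.finite(strong$auc)) && all(strong$auc > 0.5))
  expect_true(all(is.finite(strong$cv_mean_error)))
  # concussions and position are null exposures in the generator
  null_rows <- res[res$exposure %in% c("concussion_count", "speed_flag"), ]
  expect_true(all(is.na(null_rows$auc)) || all(null_rows$p > 0.0083))

  cmp <- compare_exposure_models(co$donors, grid, "cte_status",
                                 n_boot = 100, seed = 2)
  expect_true(nrow(cmp) >= 6)
  expect_true(all(cmp$category %in%
                    c("none", "positive", "strong", "very_strong")))
})
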