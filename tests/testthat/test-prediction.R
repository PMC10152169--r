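test_that("logistic coefficients match closed forms on contingency toys", {
  # 2x2 table: exposure x with success prob p0 = 0.25, p1 = 0.75
  df <- data.frame(x = rep(c(0, 1), each = 8))
  y <- c(rep(c(1, 0, 0, 0), 2), rep(c(1, 1, 1, 0), 2))
  fit <- fit_logistic(df, y)
  or_closed <- (6 * 6) / (2 * 2)     # ad/bc
  expect_equal(unname(exp(coef(fit)["x"])), or_closed, tolerance = 1e-6)
  # intercept-only model reproduces the prevalence logit
  fit0 <- fit_logistic(data.frame(z = rep(0, 16))[0], y)
  expect_equal(unname(coef(fit0)[1]), qlogis(mean(y)), tolerance = 1e-8)
})

test_that("separation raises an error that the ridge fallback resolves", {
  df <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(df, y), "ridge")
  rfit <- fit_logistic(df, y, ridge = TRUE)
  p <- predict(rfit, df, type = "response")
  expect_true(all((p > 0.5) == (y == 1)))
})

test_that("cross-validated AUC behaves at the extremes and matches the O(n^2) oracle", {
  set.seed(20)
  # perfectly separable feature -> AUC 1 in every fold
  df <- data.frame(x = c(rnorm(50, -5), rnorm(50, 5)))
  y <- rep(c(0, 1), each = 50)
  suppressMessages(cv <- cv_auc(df, y, k = 5, seed = 1))
  expect_equal(cv$mean_auc, 1)
  # shuffled labels -> AUC near 1/2
  df2 <- data.frame(x = rnorm(2000), w = rnorm(2000))
  y2 <- sample(rep(c(0, 1), each = 1000))
  cv2 <- cv_auc(df2, y2, k = 5, seed = 2)
  expect_lt(abs(cv2$mean_auc - 0.5), 0.05)
  # Mann-Whitney identity equals brute-force pairwise counting
  s <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.9, 0.2, 0.65, 0.4, 0.5,
         0.15, 0.85, 0.3, 0.7, 0.55, 0.45, 0.25, 0.75, 0.6, 0.95)
  lab <- rep(c(FALSE, TRUE), 10)
  pairs <- expand.grid(i = which(lab), j = which(!lab))
  brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                       ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(facetraits:::auc_mw(s, lab), brute, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(facetraits:::auc_mw(s, lab),
               as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratified folds are deterministic and class-balanced", {
  y <- rep(c(0, 1), times = c(70, 30))
  f1 <- facetraits:::stratified_folds(y, 5, seed = 3)
  f2 <- facetraits:::stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_gte(sum(y == 1 & f1 == k), 5)
    expect_gte(sum(y == 0 & f1 == k), 13)
  }
})

test_that("model comparison reports both AUCs, ORs and F-tests", {
  set.seed(21)
  n <- 400
  cov <- sample_covariates(n, seed = 22)
  Z <- matrix(rnorm(n * 10), n, 10)
  label <- rbinom(n, 1, 0.5)
  Z[, 3] <- Z[, 3] + 0.9 * label
  rep <- compare_models(cov, Z, label, k = 5, seed = 23)
  expect_s3_class(rep, "prediction_report")
  expect_length(rep$fold_auc_a, 5)
  expect_equal(nrow(rep$odds_ratios), 10)
  expect_true(all(rep$odds_ratios$odds_ratio > 0))
  expect_gt(rep$auc_model_b, rep$auc_model_a)
  # the informative trait dominates the F-tests of Model B
  fb <- rep$f_tests_b
  expect_equal(fb$variable[which.max(fb$f_statistic)], "trait_002")
  g <- glance(rep)
  expect_named(g, c("auc_model_a", "auc_model_b", "n_exposed", "n_control"))
  expect_equal(g$n_exposed, sum(label == 1))
  # a zero-coefficient trait has an odds ratio of exp(0) = 1
  expect_equal(exp(0), 1)
  dir <- withr::local_tempdir()
  write_prediction_report(rep, dir)
  expect_true(file.exists(file.path(dir, "prediction.json")))
})

test_that("F-test p-values are uniform for null features", {
  set.seed(24)
  pv <- replicate(200, {
    x <- data.frame(a = rnorm(60))
    y <- rbinom(60, 1, 0.5)
    facetraits:::anova_f_tests(x, y)$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
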