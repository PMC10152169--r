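fake_covariates <- function(n, seed = 1) {
  with_seed <- facetraits:::with_seed
  with_seed(seed, tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    ethnicity = factor(sample(c("Dutch", "non-Dutch-Western", "Turkish",
                                "Moroccan"), n, TRUE),
                       levels = c("Dutch", "non-Dutch-Western", "Turkish",
                                  "Moroccan")),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 levels = c("female", "male")),
    child_age = rnorm(n, 9.8, 0.3),
    child_bmi = rnorm(n, 17.5, 2),
    maternal_age = rnorm(n, 30, 4),
    maternal_smoking = runif(n) < 0.4))
}

test_that("trait regression matches lm and the normal-equations oracle", {
  set.seed(10)
  n <- 80
  cov <- fake_covariates(n)
  expos <- rbinom(n, 1, 0.5)
  Z <- matrix(rnorm(n * 3), n, 3)
  Z[, 2] <- Z[, 2] + 0.8 * expos
  res <- fit_trait_regressions(Z, expos, cov)
  for (j in 1:3) {
    ref <- lm(Z[, j] ~ expos + ethnicity + sex + child_age + child_bmi +
                maternal_age + maternal_smoking, data = cov)
    s <- summary(ref)$coefficients["expos", ]
    expect_equal(res$beta[j], unname(s["Estimate"]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(s["Std. Error"]), tolerance = 1e-10)
    expect_equal(res$p_value[j], unname(s["Pr(>|t|)"]), tolerance = 1e-10)
  }
  # normal-equations oracle on a hand-solvable single-covariate toy
  x <- c(0, 1, 0, 1); y <- c(1, 3, 2, 5); zc <- c(1, 2, 3, 4)
  X <- cbind(1, x, zc)
  beta_ne <- solve(t(X) %*% X, t(X) %*% y)
  toy <- fit_trait_regressions(
    matrix(y, 4), x, tibble::tibble(child_age = zc))
  expect_equal(toy$beta, beta_ne[2], tolerance = 1e-10)
})

test_that("a trait orthogonal to the whole design gives a zero coefficient", {
  expos <- c(0, 1, 0, 1)
  age <- c(1, 2, 3, 4)
  X <- cbind(1, expos, age)
  z <- c(qr.Q(qr(X), complete = TRUE)[, 4])   # spans the null space of X'
  res <- fit_trait_regressions(matrix(z, 4), expos,
                               tibble::tibble(child_age = age))
  expect_equal(res$beta[1], 0, tolerance = 1e-12)
})

test_that("permutation-null p-values are uniform", {
  set.seed(11)
  n <- 400
  Z <- matrix(rnorm(n * 100), n)
  cov <- fake_covariates(n, seed = 4)
  expos <- sample(rep(c(0, 1), each = n / 2))
  res <- fit_trait_regressions(Z, expos, cov)
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
  expect_true(all(res$fdr_p >= res$p_value))
})

test_that("rank-deficient designs fail loudly and NAs are dropped with a message", {
  n <- 30
  cov <- fake_covariates(n, seed = 5)
  cov$maternal_age <- cov$child_age        # exact collinearity
  expect_error(
    fit_trait_regressions(matrix(rnorm(n), n), rbinom(n, 1, 0.5), cov),
    "collinear")
  cov2 <- fake_covariates(n, seed = 6)
  cov2$child_bmi[3] <- NA
  expect_message(
    res <- fit_trait_regressions(matrix(rnorm(n), n), rbinom(n, 1, 0.5),
                                 cov2),
    "listwise")
  expect_equal(attr(res, "n_exposed") + attr(res, "n_control"), n - 1L)
})

test_that("BH adjustment matches the definitional step-up procedure", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$significant))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  set.seed(12)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$adjusted, bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, NA)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "finite|\\[0, 1\\]")
})

test_that("growth traits are exact elementwise differences on paired ids", {
  Z9 <- matrix(1:8, 4, 2, dimnames = list(paste0("S", 1:4), NULL))
  Z13 <- matrix(c(2, 4, 6, 8, 1, 1, 1, 1), 4, 2,
                dimnames = list(paste0("S", c(2, 3, 4, 9)), NULL))
  expect_message(G <- growth_traits(Z9, Z13, paste0("S", c(2, 3, 4, 9))),
                 "unpaired")
  expect_equal(rownames(G), paste0("S", 2:4))
  expect_identical(G, Z13[1:3, ] - Z9[2:4, ])
  expect_true(all(growth_traits(Z9, Z9) == 0))
  expect_lte(nrow(G), min(nrow(Z9), nrow(Z13)))
})

test_that("stratum selection respects tier, level band and ethnicity", {
  cov <- sample_covariates(500, seed = 30)
  grp <- facetraits:::stratum_groups(cov, stratum_spec(tier = "2b",
                                                       level_band = ">1",
                                                       ethnicity = "dutch"))
  sel <- cov[cov$subject_id %in% grp$exposed, ]
  expect_true(all(sel$ethnicity == "Dutch"))
  expect_true(all(sel$pae_level > 1))
  expect_true(all(sel$drank_trimester1))
  ctrl <- cov[cov$subject_id %in% grp$control, ]
  expect_true(all(ctrl$pae_level == 0))
  expect_true(all(ctrl$ethnicity == "Dutch"))
  grp2a <- facetraits:::stratum_groups(cov, stratum_spec(tier = "2a",
                                                         level_band = ">0"))
  sel2a <- cov[cov$subject_id %in% grp2a$exposed, ]
  expect_true(all(!sel2a$drank_trimester2 & !sel2a$drank_trimester3))
  band <- facetraits:::stratum_groups(cov, stratum_spec(level_band = c(2, 3)))
  expect_true(all(cov$pae_level[cov$subject_id %in% band$exposed] %in% 2:3))
})

test_that("stratified analysis and the sex check share one output schema", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 4, seed = 60)
  co <- simulate_cohort(60, population = pop, seed = 61, slope = 1)
  model <- pca_baseline(co$faces_9y, 5)
  a <- run_stratified_analysis(co, model, stratum_spec())
  expect_s3_class(a, "trait_assoc")
  expect_named(a, c("trait_index", "beta", "se", "p_value", "fdr_p",
                    "significant", "trait_mean", "trait_sd", "f_z"))
  s <- sex_phenotype_check(co, model)
  expect_identical(names(s), names(a))
  g <- glance(a)
  expect_equal(g$n_traits, 5L)
  td <- tidy(a)
  expect_true("stratum_tier" %in% names(td))
  # growth analysis consistent with the arithmetic definition
  ag <- run_stratified_analysis(co, model, stratum_spec(age_group = "growth"))
  expect_s3_class(ag, "trait_assoc")
  expect_error(run_stratified_analysis(co, model,
                                       stratum_spec(level_band = c(99))),
               "empty")
})
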