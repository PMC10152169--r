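test_that("weekly drinks map to the six printed consumption levels", {
  expect_equal(assign_levels(0.5), 1L)    # <1 per week
  expect_equal(assign_levels(2), 2L)      # 1-3 per week
  expect_equal(assign_levels(5), 3L)      # 4-6 per week
  expect_equal(assign_levels(7), 4L)      # 1 per day
  expect_equal(assign_levels(17), 5L)     # 2-3 per day
  expect_equal(assign_levels(25), 6L)     # >3 per day
  expect_error(assign_levels(0), "positive")
  expect_error(assign_levels(-1), "positive")
})

test_that("tier membership follows the timing definitions", {
  rec <- tibble::tibble(
    drank_before_pregnancy = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    drank_trimester1 = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    drank_trimester2 = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    drank_trimester3 = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  t <- assign_tiers(rec)
  expect_equal(t$control, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(t$tier1_exposed, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(t$tier2a_exposed, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # continued drinkers are tier 2b but not 2a
  expect_equal(t$tier2b_exposed, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # later-trimester-only drinking fits no stratum
  expect_equal(t$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("sampled covariates are reproducible and hit their marginals", {
  c1 <- sample_covariates(50, seed = 3)
  expect_identical(c1, sample_covariates(50, seed = 3))
  expect_equal(nrow(sample_covariates(1, seed = 1)), 1L)
  m <- default_covariate_marginals()
  m$ethnicity <- c(Dutch = 0.86, `non-Dutch-Western` = 0.06,
                   Turkish = 0.05, Moroccan = 0.03)
  big <- sample_covariates(10000, seed = 9, marginals = m)
  expect_equal(mean(big$ethnicity == "Dutch"), 0.86, tolerance = 0.012)
  expect_equal(mean(big$maternal_smoking), m$p_smoking, tolerance = 0.02)
  # abstinence iff no drinking flags
  flags <- big$drank_before_pregnancy | big$drank_trimester1 |
    big$drank_trimester2 | big$drank_trimester3
  expect_identical(big$pae_level == 0L, !flags)
  bad <- m; bad$ethnicity[1] <- 0.5
  expect_error(sample_covariates(10, marginals = bad), "sum to 1")
})

test_that("face synthesis is a linear construction in exposure level", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 4, seed = 21)
  eff <- effect_spec(tm, "nose_tip", slope = 1)
  cov0 <- sample_covariates(6, seed = 5)
  cov3 <- cov0
  cov0$pae_level <- 0L
  cov3$pae_level <- 3L
  f0 <- synthesize_faces(pop, cov0, eff, noise_sd_mm = 0, seed = 31)$faces_9y
  f3 <- synthesize_faces(pop, cov3, eff, noise_sd_mm = 0, seed = 31)$faces_9y
  d <- f3$coords[, , 1] - f0$coords[, , 1]
  mask <- attr(tm, "region_masks")$nose_tip
  expect_equal(sqrt(rowSums(d[mask, , drop = FALSE]^2)),
               rep(3, length(mask)), tolerance = 1e-10)
  off <- setdiff(seq_len(nrow(tm$vertices)), mask)
  expect_equal(max(abs(d[off, ])), 0)
})

test_that("the mean of many unexposed faces converges to the template", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 4, seed = 22)
  cov <- sample_covariates(600, seed = 13)
  cov$pae_level <- 0L
  fs <- synthesize_faces(pop, cov, effect = NULL, noise_sd_mm = 0.1,
                         seed = 14)$faces_9y
  mean_face <- apply(fs$coords, c(1, 2), mean)
  # population modes have mean zero; CLT bound with 3 SE headroom
  mode_sd <- sqrt(sum((2 * 0.9^(0:3))^2) / 3 + 0.1^2)
  expect_lt(max(abs(mean_face - tm$vertices)), 5 * mode_sd / sqrt(600))
})

test_that("generator is deterministic for fixed seeds", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 3, seed = 40)
  a <- simulate_cohort(30, population = pop, seed = 8)
  b <- simulate_cohort(30, population = pop, seed = 8)
  expect_identical(a$faces_9y$coords, b$faces_9y$coords)
  expect_identical(a$faces_13y$coords, b$faces_13y$coords)
  expect_identical(a$covariates, b$covariates)
})

test_that("longitudinal wave pairs a subset and applies growth/attenuation", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 3, seed = 41)
  co <- simulate_cohort(40, population = pop, seed = 9, slope = 1,
                        attenuation_13y = 0.4)
  expect_true(all(co$paired_ids %in% co$faces_9y$subject_ids))
  expect_lt(length(co$paired_ids), 40)
  # no growth, full effect carry-over, no noise -> 13y equals 9y
  base <- synthesize_faces(pop, sample_covariates(12, seed = 2),
                           effect_spec(tm, slope = 1), noise_sd_mm = 0,
                           seed = 3)
  same <- synthesize_longitudinal(base, growth_mm = 0, attenuation_13y = 1,
                                  seed = 4)
  keep <- match(same$paired_ids, base$faces_9y$subject_ids)
  expect_equal(same$faces_13y$coords, base$faces_9y$coords[, , keep],
               tolerance = 1e-12)
  # attenuation 0 removes the exposure displacement entirely
  gone <- synthesize_longitudinal(base, growth_mm = 0, attenuation_13y = 0,
                                  seed = 4)
  mask <- attr(tm, "region_masks")$nose_tip
  lv <- base$covariates$pae_level[match(gone$paired_ids,
                                        base$covariates$subject_id)]
  i <- which(lv > 0)[1]
  skip_if(is.na(i))
  d9 <- base$faces_9y$coords[mask, , match(gone$paired_ids[i],
                                           base$faces_9y$subject_ids)]
  d13 <- gone$faces_13y$coords[mask, , i]
  expect_equal(sqrt(mean((d13 - d9)^2)) * sqrt(3), lv[i], tolerance = 0.1)
})

test_that("dose monotonicity holds in the noiseless generator", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 3, seed = 42)
  eff <- effect_spec(tm, "nose_tip", slope = 0.5)
  cov <- sample_covariates(7, seed = 6)
  cov$pae_level <- 0:6
  zero <- cov; zero$pae_level <- 0L
  f <- synthesize_faces(pop, cov, eff, noise_sd_mm = 0, seed = 7)$faces_9y
  f0 <- synthesize_faces(pop, zero, eff, noise_sd_mm = 0, seed = 7)$faces_9y
  mask <- attr(tm, "region_masks")$nose_tip
  disp <- sapply(1:7, function(i)
    mean(sqrt(rowSums((f$coords[mask, , i] - f0$coords[mask, , i])^2))))
  expect_true(all(diff(disp) >= 0))
})

test_that("cohort files round-trip through disk", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 2, seed = 50)
  co <- simulate_cohort(3, population = pop, seed = 12)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "covariates.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  ply <- file.path(dir, "cohort", "9y", paste0(co$faces_9y$subject_ids[1], ".ply"))
  expect_true(file.exists(ply))
  back <- read_mesh(ply)
  expect_equal(back$vertices, co$faces_9y$coords[, , 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})
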