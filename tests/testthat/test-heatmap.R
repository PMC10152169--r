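test_that("trait displacement fields follow the linear-decoder oracle", {
  model <- tiny_pca()
  f0 <- trait_displacement_field(model, 2, 0)
  expect_equal(max(abs(f0)), 0)
  f <- trait_displacement_field(model, 3, 1.7)
  oracle <- 1.7 * matrix(model$components[, 3], 150, 3)
  expect_equal(f, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(trait_displacement_field(model, 99, 1), "range")
  # field norm summed over vertices equals the trait's f(z) at that delta
  expect_equal(sum(sqrt(rowSums(f^2))), effect_size_f(model, 3, 1.7),
               tolerance = 1e-9)
})

test_that("combining fields is linear, cancels opposites, and is sign-flip invariant", {
  set.seed(30)
  fields <- list(matrix(rnorm(30), 10), matrix(rnorm(30), 10))
  one <- combine_significant_traits(fields[1], betas = 1, trait_sds = 1)
  expect_equal(one, fields[[1]])
  cancel <- combine_significant_traits(list(fields[[1]], fields[[1]]),
                                       betas = c(1, -1), trait_sds = c(1, 1))
  expect_equal(max(abs(cancel)), 0)
  b <- c(0.4, -1.2); s <- c(0.5, 2)
  base <- combine_significant_traits(fields, b, s)
  expect_equal(combine_significant_traits(fields, 2 * b, s), 2 * base,
               tolerance = 1e-12)
  flipped <- combine_significant_traits(
    list(-fields[[1]], fields[[2]]), c(-b[1], b[2]), s)
  expect_equal(flipped, base, tolerance = 1e-12)
  expect_error(combine_significant_traits(list(), numeric(), numeric()),
               "no significant")
})

test_that("radial signing projects onto the outward direction", {
  tm <- tiny_template()
  ctr <- geometric_center(tm)
  u <- sweep(tm$vertices, 2, ctr)
  u <- u / sqrt(rowSums(u^2))
  out_field <- 2 * u
  expect_true(all(radial_sign(out_field, tm) > 0))
  expect_equal(radial_sign(out_field, tm), rep(2, 150), tolerance = 1e-10)
  # a tangential field has no radial component
  tang <- cbind(-u[, 2], u[, 1], 0)
  tang <- tang - u * rowSums(tang * u)
  expect_lt(max(abs(radial_sign(tang, tm))), 1e-10)
  set.seed(31)
  f <- matrix(rnorm(450), 150)
  expect_equal(radial_sign(f, tm), rowSums(f * u), tolerance = 1e-12)
})

test_that("localization score counts top vertices inside the mask", {
  hm <- numeric(100)
  mask <- 11:20
  hm[mask] <- c(5, -6, 7, -8, 9, 10, -11, 12, 13, 14)
  expect_equal(localization_score(hm, mask, top_fraction = 0.1), 1)
  set.seed(32)
  rand_scores <- replicate(300, localization_score(rnorm(100), mask, 0.1))
  expect_lt(abs(mean(rand_scores) - 0.1), 0.02)
  expect_error(localization_score(hm, integer()), "non-empty")
  expect_error(localization_score(hm, mask, top_fraction = 0), "top_fraction")
})

test_that("heatmap export writes colored PLY plus an exact CSV", {
  tm <- tiny_template()
  set.seed(33)
  hm <- rnorm(150)
  ply <- withr::local_tempfile(fileext = ".ply")
  paths <- export_heatmap(tm, hm, ply)
  back <- read_mesh(paths["ply"])
  expect_equal(attr(back, "scalar"), hm, tolerance = 1e-6)
  expect_false(is.null(attr(back, "color")))
  csv <- read.csv(paths["csv"])
  expect_equal(csv$scalar, hm, tolerance = 1e-13)
  # zero heatmap renders uniform white
  p2 <- export_heatmap(tm, rep(0, 150), withr::local_tempfile(fileext = ".ply"))
  col <- attr(read_mesh(p2["ply"]), "color")
  expect_true(all(col == 255))
})

test_that("assoc_heatmap localizes a strong injected region on a linear model", {
  tm <- tiny_template()
  pop <- make_population(tm, n_modes = 4, seed = 70)
  co <- simulate_cohort(250, population = pop, seed = 71, slope = 1.5,
                        noise_sd_mm = 0.1)
  model <- pca_baseline(co$faces_9y, 12)
  a <- run_stratified_analysis(co, model, stratum_spec())
  hm <- assoc_heatmap(model, a, use = "fdr")
  expect_false(is.null(hm))
  mask <- attr(tm, "region_masks")$nose_tip
  expect_gt(localization_score(hm$scalar, mask),
            3 * length(mask) / nrow(tm$vertices))
  p <- plot_heatmap(tm, hm$scalar)
  expect_s3_class(p, "ggplot")
})
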