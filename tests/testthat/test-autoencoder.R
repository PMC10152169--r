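test_that("training memorises a single repeated face", {
  tm <- tiny_template()
  V <- nrow(tm$vertices)
  set.seed(1)
  face <- tm$vertices + matrix(rnorm(V * 3), V)
  coords <- array(rep(face, 12), c(V, 3, 12))
  coords <- coords + array(rnorm(length(coords), sd = 1e-3), dim(coords))
  fs <- face_set(sprintf("S%02d", 1:12), coords, tm)
  model <- train_face_model(fs, tiny_config(epochs = 30L),
                            hierarchy = tiny_hierarchy())
  # the model decodes essentially the memorised mean face, so the error is
  # on the scale of the added jitter, far below face-scale variation
  expect_lt(reconstruction_error(model, fs), 0.05)
})

test_that("training loss decreases and is seed-reproducible", {
  fs <- tiny_faces(16)
  m1 <- train_face_model(fs, tiny_config(epochs = 6L),
                         hierarchy = tiny_hierarchy())
  expect_lt(m1$history$train_mae[6], m1$history$train_mae[1])
  m2 <- train_face_model(fs, tiny_config(epochs = 6L),
                         hierarchy = tiny_hierarchy())
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("encode/decode respect the model contract", {
  fs <- tiny_faces(10)
  model <- train_face_model(fs, tiny_config(), hierarchy = tiny_hierarchy())
  Z <- encode_faces(model, fs)
  expect_equal(dim(Z), c(10L, 4L))
  expect_true(all(is.finite(Z)))
  expect_identical(rownames(Z), fs$subject_ids)
  expect_identical(Z, encode_faces(model, fs))       # deterministic
  # traits stay finite under 10 mm perturbations of the template
  pert <- fs$coords[, , 1] + matrix(runif(450, -10, 10), 150)
  expect_true(all(is.finite(encode_faces(model, pert))))
  dec <- decode_traits(model, Z[1:3, , drop = FALSE])
  expect_equal(dim(dec), c(150L, 3L, 3L))
  m <- decode_mesh(model, Z[1, ])
  expect_identical(m$faces, fs$template$faces)
  expect_error(decode_traits(model, matrix(0, 1, 7)), "columns")
  expect_error(encode_faces(model, fs$coords[1:10, , ]), "topology")
  # decode is continuous in z
  z <- model$latent_mean
  d0 <- decode_traits(model, z)
  steps <- sapply(c(1e-1, 1e-3), function(e) {
    zp <- z; zp[2] <- zp[2] + e
    max(abs(decode_traits(model, zp) - d0))
  })
  expect_lt(steps[2], steps[1])
  expect_lt(steps[2], 1e-1)
})

test_that("reconstruction error equals the brute-force double loop", {
  model <- tiny_pca()
  fs <- tiny_faces(3, seed = 21)
  err <- reconstruction_error(model, fs)
  rec <- decode_traits(model, encode_faces(model, fs))
  acc <- 0
  for (i in 1:3) {
    per_vertex <- numeric(150)
    for (v in 1:150)
      per_vertex[v] <- sqrt(sum((rec[v, , i] - fs$coords[v, , i])^2))
    acc <- acc + mean(per_vertex)
  }
  expect_equal(err, acc / 3, tolerance = 1e-12)
})

test_that("PCA baseline reconstructs perfectly at full rank and improves with N", {
  fs <- tiny_faces(12, seed = 31)
  full <- pca_baseline(fs, 3 * 150)
  expect_lt(reconstruction_error(full, fs), 1e-8)
  errs <- sapply(c(1, 3, 6, 11), function(N)
    reconstruction_error(pca_baseline(fs, N), fs))
  expect_true(all(diff(errs) <= 1e-10))
  # projection matches the direct SVD oracle
  X <- t(matrix(fs$coords, 450, 12))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  Z <- encode_faces(pca_baseline(fs, 4), fs)
  oracle <- Xc %*% sv$v[, 1:4]
  for (j in 1:4)  # components defined up to sign
    expect_equal(abs(Z[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("generalization is zero when held-out faces lie in the model span", {
  fs <- tiny_faces(12, seed = 41)
  full <- pca_baseline(fs, 11)
  held <- face_set(fs$subject_ids[1:4], fs$coords[, , 1:4], fs$template)
  gs <- generalization_specificity(full, held, n_samples = 5, seed = 2)
  expect_lt(gs["generalization"], 1e-8)
  expect_gte(gs["specificity"], 0)
  expect_error(generalization_specificity(full, held, n_samples = 0), "n_samples")
})

test_that("trait correlations match the textbook formula and flag degeneracy", {
  set.seed(6)
  Z <- matrix(rnorm(20), 5, 4)
  tc <- trait_correlations(Z)
  manual <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- Z[, i] - mean(Z[, i]); xj <- Z[, j] - mean(Z[, j])
    manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(tc$correlations, manual, tolerance = 1e-12)
  Zdup <- cbind(Z, Z[, 1])
  expect_equal(trait_correlations(Zdup)$correlations[1, 5], 1)
  Zzero <- cbind(Z, 0)
  expect_warning(tcz <- trait_correlations(Zzero), "zero-variance")
  expect_equal(tcz$correlations[5, 1:4], rep(0, 4))
  # independent columns at large n concentrate near zero
  big <- trait_correlations(matrix(rnorm(4000), 1000, 4))
  expect_lt(abs(big$summary$off_diag_mean), 0.1)
})

test_that("effect size f(z) matches its definition on a linear model", {
  model <- tiny_pca()
  expect_equal(effect_size_f(model, 2, 0), 0)
  sds <- c(0.5, 1, 2, 0.3, 1.5)
  f <- sapply(1:5, function(j) effect_size_f(model, j, sds[j]))
  # linear decoder: displacement field is sd * component j
  oracle <- sapply(1:5, function(j) {
    comp <- matrix(model$components[, j], 150, 3)
    sds[j] * sum(sqrt(rowSums(comp^2)))
  })
  expect_equal(f, oracle, tolerance = 1e-9)
  expect_equal(facetraits:::effect_sizes_all(model, sds), f, tolerance = 1e-9)
  expect_error(effect_size_f(model, 9, 1), "range")
})
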