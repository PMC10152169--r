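test_that("decimation to the same size is the identity", {
  tm <- tiny_template()
  r <- decimate_qem(tm, nrow(tm$vertices))
  expect_identical(r$mesh, tm)
  expect_identical(r$kept, seq_len(nrow(tm$vertices)))
})

test_that("decimating an icosahedron to 6 vertices keeps a valid mesh", {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  ico <- triangle_mesh(v, f)
  r <- decimate_qem(ico, 6)
  expect_equal(nrow(r$mesh$vertices), 6L)
  expect_mesh_valid(r$mesh)
  expect_true(all(r$kept %in% 1:12))
  # kept vertices retain their original coordinates (subset selection)
  expect_equal(r$mesh$vertices, v[r$kept, ], ignore_attr = TRUE)
})

test_that("hierarchy level sizes follow the ceiling-by-factor law", {
  tm <- make_template(1024)
  h <- build_hierarchy(tm)
  expect_equal(level_sizes(h), c(1024, 256, 64, 16, 4))
  sizes <- level_sizes(h)
  expect_equal(sizes[-1], ceiling(sizes[-5] / 4))
  expect_error(build_hierarchy(tiny_template(), factors = c(4, 4, 4, 4)),
               "exhausts")
})

test_that("down-transforms are selectors and up-transforms are barycentric", {
  h <- tiny_hierarchy()
  for (l in seq_along(h$down_transforms)) {
    D <- h$down_transforms[[l]]
    expect_true(all(Matrix::rowSums(D) == 1))
    expect_true(all(Matrix::rowSums(D != 0) == 1))
    U <- h$up_transforms[[l]]
    expect_equal(max(abs(Matrix::rowSums(U) - 1)), 0, tolerance = 1e-6)
    expect_true(all(Matrix::rowSums(U != 0) <= 3))
  }
})

test_that("up-sampling a down-sampled smooth template is accurate", {
  tm <- tiny_template()
  h <- tiny_hierarchy()
  rec <- apply_transform(h$up_transforms[[1]],
                         apply_transform(h$down_transforms[[1]], tm$vertices))
  err <- mean(sqrt(rowSums((rec - tm$vertices)^2)))
  expect_lt(err, 1.5)   # mm, coarse-to-fine interpolation of a smooth surface
})

test_that("apply_transform matches dense multiplication and checks shapes", {
  h <- tiny_hierarchy()
  D <- h$down_transforms[[1]]
  set.seed(2)
  X <- matrix(rnorm(ncol(D) * 5), ncol(D))
  expect_equal(apply_transform(D, X), as.matrix(D) %*% X, tolerance = 1e-12)
  expect_equal(apply_transform(Matrix::Diagonal(ncol(D)), X), X,
               ignore_attr = TRUE)
  # constant signals survive down-then-up exactly
  cons <- matrix(1, ncol(D), 2)
  expect_equal(apply_transform(h$up_transforms[[1]],
                               apply_transform(D, cons)), cons,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(apply_transform(D, X[1:3, ]), "expects")
})

test_that("hierarchy construction is deterministic and serialisable", {
  h1 <- build_hierarchy(tiny_template(), factors = c(2, 2))
  h2 <- build_hierarchy(tiny_template(), factors = c(2, 2))
  expect_identical(h1$levels, h2$levels)
  expect_identical(h1$down_transforms, h2$down_transforms)
  dir <- withr::local_tempdir()
  write_hierarchy(h1, dir)
  back <- read_hierarchy(dir)
  expect_equal(level_sizes(back), level_sizes(h1))
  expect_equal(back$levels[[2]]$vertices, h1$levels[[2]]$vertices,
               tolerance = 1e-6)
  expect_equal(as.matrix(back$up_transforms[[1]]),
               as.matrix(h1$up_transforms[[1]]), tolerance = 1e-12)
})
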