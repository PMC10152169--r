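# Shared small fixtures, built lazily and memoised for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_template <- function() fixture("tiny_template", function() make_template(150))

tiny_hierarchy <- function() fixture("tiny_hierarchy", function()
  build_hierarchy(tiny_template(), factors = c(2, 2)))

# a handful of smooth random faces on the tiny template
tiny_faces <- function(n = 8, seed = 7, sd = 1) {
  tm <- tiny_template()
  V <- nrow(tm$vertices)
  pop <- fixture("tiny_population", function()
    make_population(tiny_template(), n_modes = 5, seed = 99))
  cov <- sample_covariates(n, seed = seed)
  synthesize_faces(pop, cov, effect = NULL, noise_sd_mm = 0.1 * sd,
                   seed = seed + 1)$faces_9y
}

tiny_config <- function(...) {
  defaults <- list(latent_dim = 4L, channels = c(4L, 6L), K = 3L,
                   factors = c(2, 2), epochs = 4L, batch_size = 4L,
                   lr = 5e-3, seed = 11L)
  do.call(encoder_config, utils::modifyList(defaults, list(...)))
}

# a quick linear "model" with the encode/decode contract: PCA on tiny faces
tiny_pca <- function() fixture("tiny_pca", function()
  pca_baseline(tiny_faces(10), 5))

expect_mesh_valid <- function(mesh) {
  expect_s3_class(mesh, "triangle_mesh")
  expect_true(all(is.finite(mesh$vertices)))
  if (nrow(mesh$faces) > 0) {
    expect_gte(min(mesh$faces), 1L)
    expect_lte(max(mesh$faces), nrow(mesh$vertices))
  }
}
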