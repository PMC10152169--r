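#' Linear (PCA) face model baseline
#'
#' Mean-centred principal-component projection with `N` components and the
#' same encode/decode contract as the auto-encoder, for generalisation /
#' specificity comparisons.
#'
#' @param faces a [face_set()] (training cohort).
#' @param N number of components (truncated to the available rank).
#' @return An object of class `pca_face_model`.
#' @export
pca_baseline <- function(faces, N) {
  coords <- faces$coords
  V <- dim(coords)[1]; n <- dim(coords)[3]
  X <- t(matrix(coords, V * 3L, n))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(N, n - 1L, ncol(Xc)))
  comps <- sv$v
  scores <- Xc %*% comps
  structure(list(mean = mu, components = comps,
                 mean_face = matrix(mu, V, 3L),
                 config = list(latent_dim = ncol(comps)),
                 template = faces$template,
                 latent_mean = colMeans(scores),
                 latent_sd = apply(scores, 2, sd)),
            class = "pca_face_model")
}

#' @export
print.pca_face_model <- function(x, ...) {
  cat(sprintf("<pca_face_model: V = %d, %d components>\n",
              nrow(x$mean_face), ncol(x$components)))
  invisible(x)
}

#' @export
encode_faces.pca_face_model <- function(model, faces, batch_size = 64L) {
  coords <- coords_of(faces, model)
  V <- dim(coords)[1]; n <- dim(coords)[3]
  X <- t(matrix(coords, V * 3L, n))
  Z <- sweep(X, 2, model$mean) %*% model$components
  rownames(Z) <- if (inherits(faces, "face_set")) faces$subject_ids else NULL
  Z
}

#' @export
decode_traits.pca_face_model <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  X <- sweep(tcrossprod(Z, model$components), 2, model$mean, `+`)
  V <- nrow(model$mean_face)
  array(t(X), c(V, 3L, nrow(Z)))
}

#' Generalisation and specificity of a face model
#'
#' Generalisation is the mean per-vertex reconstruction error on held-out
#' faces. Specificity decodes `n_samples` latent vectors drawn from the
#' model's fitted (diagonal) latent Gaussian and reports their mean
#' per-vertex distance to the nearest held-out face: low values mean random
#' model samples look like real faces.
#'
#' @param model a trained face model (auto-encoder or PCA).
#' @param heldout_faces a [face_set()] disjoint from training.
#' @param n_samples number of random latent samples.
#' @param seed integer seed.
#' @return Named numeric vector `c(generalization, specificity)` in mm.
#' @export
generalization_specificity <- function(model, heldout_faces, n_samples = 50L,
                                       seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be at least 1")
  gen <- reconstruction_error(model, heldout_faces)
  N <- length(model$latent_mean)
  Z <- with_seed(seed,
    sweep(matrix(rnorm(n_samples * N), n_samples, N) %*%
            diag(model$latent_sd, N), 2, model$latent_mean, `+`))
  dec <- decode_traits(model, Z)
  coords <- heldout_faces$coords
  nh <- dim(coords)[3]
  spec <- vapply(seq_len(n_samples), function(s) {
    d <- coords - array(dec[, , s], dim(coords))
    pv <- sqrt(d[, 1, , drop = FALSE]^2 + d[, 2, , drop = FALSE]^2 +
                 d[, 3, , drop = FALSE]^2)
    min(colMeans(matrix(pv, dim(coords)[1], nh)))
  }, numeric(1))
  c(generalization = gen, specificity = mean(spec))
}

#' Pairwise correlations between latent traits
#'
#' Pearson correlation matrix of the trait columns, with an off-diagonal
#' mean/SD summary. Zero-variance traits are flagged with a warning and
#' their correlations set to 0.
#'
#' @param Z `n x N` trait matrix, `n >= 3`.
#' @return A list with `correlations` (N x N), and `summary` (tibble with
#'   off-diagonal mean and SD).
#' @export
trait_correlations <- function(Z) {
  stopifnot(nrow(Z) >= 3)
  sds <- apply(Z, 2, sd)
  zero <- sds == 0
  if (any(zero)) warning(sum(zero), " zero-variance trait(s); correlations set to 0")
  C <- diag(ncol(Z))
  ok <- which(!zero)
  if (length(ok) >= 2) C[ok, ok] <- cor(Z[, ok, drop = FALSE])
  off <- C[upper.tri(C)]
  list(correlations = C,
       summary = tibble::tibble(off_diag_mean = mean(off),
                                off_diag_sd = sd(off)))
}

#' Effect size f(z) of a trait on facial shape
#'
#' Total decoded vertex displacement for a one-SD perturbation of one trait:
#' the sum over all template vertices of the Euclidean distance between the
#' face decoded at the latent mean and at the mean plus `trait_sd` on trait
#' `j`. Zero when `trait_sd` is 0.
#'
#' @param model a trained face model.
#' @param trait_index 1-based trait index.
#' @param trait_sd the trait's standard deviation in the analysis sample.
#' @param center latent vector to perturb around; default the model's
#'   latent mean.
#' @return Scalar f(z) (mm summed over vertices).
#' @export
effect_size_f <- function(model, trait_index, trait_sd, center = NULL) {
  if (is.null(center)) center <- model$latent_mean
  N <- length(center)
  if (trait_index < 1 || trait_index > N) stop("trait_index out of range")
  if (trait_sd == 0) return(0)
  zp <- center
  zp[trait_index] <- zp[trait_index] + trait_sd
  d <- decode_traits(model, rbind(center, zp))
  sum(sqrt(rowSums((d[, , 2] - d[, , 1])^2)))
}

# f(z) for all traits in one batched decode
effect_sizes_all <- function(model, trait_sds, center = NULL) {
  if (is.null(center)) center <- model$latent_mean
  N <- length(center)
  Z <- matrix(center, N + 1L, N, byrow = TRUE)
  Z[cbind(seq_len(N) + 1L, seq_len(N))] <-
    Z[cbind(seq_len(N) + 1L, seq_len(N))] + trait_sds
  d <- decode_traits(model, Z)
  base <- d[, , 1]
  vapply(seq_len(N), function(j)
    sum(sqrt(rowSums((d[, , j + 1L] - base)^2))), numeric(1))
}
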