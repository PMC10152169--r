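# Graph-convolutional mesh auto-encoder. Four Chebyshev-convolution +
# pooling blocks compress a corresponded face (V x 3) through the sampling
# hierarchy to the coarsest level, a dense layer maps it to N latent traits,
# and the decoder mirrors the path back. Trained by mini-batch gradient
# descent with adaptive step sizes (Adam by default, RMSprop optional) on a
# mean-absolute-error reconstruction loss; everything is plain linear
# algebra, so a fixed seed gives bitwise-reproducible training.
#
# Batch signals use the stacked layout of chebconv.R throughout: a batch of
# B C-channel signals is a (V*B) x C matrix with vertex index fastest.

#' Auto-encoder configuration
#'
#' @param latent_dim number of latent facial traits N; default 200.
#' @param channels feature channels of the four encoder blocks.
#' @param K Chebyshev polynomial order.
#' @param factors per-level down-sampling factors of the hierarchy.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr learning rate, decayed by `lr_decay` per epoch.
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param optimizer `"adam"` (default) or `"rmsprop"`.
#' @param val_fraction held-out fraction for the best-checkpoint criterion.
#' @param seed integer seed controlling initialisation, split and batching.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(latent_dim = 200L, channels = c(32L, 32L, 32L, 64L),
                           K = 6L, factors = c(4, 4, 4, 4), epochs = 300L,
                           batch_size = 16L, lr = 1e-3, lr_decay = 0.99,
                           optimizer = c("adam", "rmsprop"),
                           val_fraction = 0.1, seed = 1L) {
  stopifnot(latent_dim >= 1, K >= 1, length(channels) == length(factors))
  structure(list(latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels), K = as.integer(K),
                 factors = factors, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, optimizer = match.arg(optimizer),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

init_params <- function(cfg, hier) {
  nl <- length(cfg$channels)
  V_coarse <- nrow(hier$levels[[nl + 1L]]$vertices)
  flat <- V_coarse * cfg$channels[nl]
  cin <- c(3L, cfg$channels[-nl])
  enc <- lapply(seq_len(nl), function(l)
    list(W = glorot(c(cfg$K, cin[l], cfg$channels[l]),
                    cfg$K * cin[l], cfg$channels[l]),
         b = numeric(cfg$channels[l])))
  dec_cout <- c(3L, cfg$channels[-nl])   # output channels of decoder conv at level l
  dec <- lapply(seq_len(nl), function(l) {
    c_in <- cfg$channels[l]
    list(W = glorot(c(cfg$K, c_in, dec_cout[l]), cfg$K * c_in, dec_cout[l]),
         b = numeric(dec_cout[l]))
  })
  list(enc = enc,
       fc_enc = list(W = glorot(c(cfg$latent_dim, flat), flat, cfg$latent_dim),
                     b = numeric(cfg$latent_dim)),
       fc_dec = list(W = glorot(c(flat, cfg$latent_dim), cfg$latent_dim, flat),
                     b = numeric(flat)),
       dec = dec)
}

# coords (V, 3, B) array <-> stacked (V*B) x 3 matrix (vertex fastest)
to_layout <- function(coords) {
  d <- dim(coords)
  m <- aperm(coords, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], 3L)
  m
}

from_layout <- function(m, B) {
  V <- nrow(m) / B
  dim(m) <- c(V, B, 3L)
  aperm(m, c(1, 3, 2))
}

# decoder half; z is N x B, returns stacked (V*B) x 3 output plus caches
dec_forward <- function(params, hier, cfg, fast, z, keep_cache = FALSE) {
  nl <- length(cfg$channels)
  B <- ncol(z)
  h <- params$fc_dec$W %*% z + params$fc_dec$b
  V5 <- nrow(hier$levels[[nl + 1L]]$vertices)
  C <- cfg$channels[nl]
  G <- aperm(array(h, c(V5, C, B)), c(1, 3, 2))
  dim(G) <- c(V5 * B, C)
  caches <- vector("list", nl)
  for (l in nl:1) {
    up <- sp_mult(fast$U[[l]], G, B)
    cv <- cheb_conv_fast(fast$L[[l]], up, B, cfg$channels[l],
                         params$dec[[l]]$W, params$dec[[l]]$b)
    out <- if (l > 1) elu(cv$out) else cv$out
    if (keep_cache) caches[[l]] <- list(conv = cv, out = out)
    G <- out
  }
  list(out = G, caches = caches)
}

net_forward <- function(params, hier, cfg, fast, Xmat, B,
                        keep_cache = FALSE, encode_only = FALSE) {
  nl <- length(cfg$channels)
  H <- Xmat
  Cin <- 3L
  enc_caches <- vector("list", nl)
  shapes <- vector("list", nl)
  for (l in seq_len(nl)) {
    cv <- cheb_conv_fast(fast$L[[l]], H, B, Cin, params$enc[[l]]$W,
                         params$enc[[l]]$b)
    act <- elu(cv$out)
    pooled <- sp_mult(fast$D[[l]], act, B)
    if (keep_cache) enc_caches[[l]] <- list(conv = cv, act = act)
    H <- pooled
    Cin <- cfg$channels[l]
    shapes[[l]] <- c(nrow(pooled) / B, Cin)
  }
  V5 <- nrow(H) / B; C <- cfg$channels[nl]
  dim(H) <- c(V5, B, C)
  flatH <- aperm(H, c(1, 3, 2))
  dim(flatH) <- c(V5 * C, B)
  z <- params$fc_enc$W %*% flatH + params$fc_enc$b
  if (encode_only)
    return(list(z = z, B = B, shapes = shapes))
  dec <- dec_forward(params, hier, cfg, fast, z, keep_cache)
  list(z = z, out = dec$out, flatH = flatH, B = B,
       enc_caches = enc_caches, dec_caches = dec$caches, shapes = shapes)
}

net_backward <- function(params, hier, cfg, fast, fwd, dOut) {
  nl <- length(cfg$channels)
  B <- fwd$B
  grads <- list(enc = vector("list", nl), dec = vector("list", nl))
  G <- dOut
  for (l in seq_len(nl)) {
    cache <- fwd$dec_caches[[l]]
    dconv <- if (l > 1) elu_backward(G, cache$out) else G
    bk <- cheb_conv_fast_backward(fast$L[[l]], cache$conv, params$dec[[l]]$W,
                                  dconv)
    grads$dec[[l]] <- list(W = bk$dW, b = bk$db)
    G <- sp_mult(fast$Ut[[l]], bk$dX, B)
  }
  V5 <- nrow(G) / B; C <- cfg$channels[nl]
  dim(G) <- c(V5, B, C)
  dh <- aperm(G, c(1, 3, 2))
  dim(dh) <- c(V5 * C, B)
  grads$fc_dec <- list(W = tcrossprod(dh, fwd$z), b = rowSums(dh))
  dz <- crossprod(params$fc_dec$W, dh)
  grads$fc_enc <- list(W = tcrossprod(dz, fwd$flatH), b = rowSums(dz))
  dflat <- crossprod(params$fc_enc$W, dz)
  dim(dflat) <- c(V5, C, B)
  dH <- aperm(dflat, c(1, 3, 2))
  dim(dH) <- c(V5 * B, C)
  for (l in nl:1) {
    cache <- fwd$enc_caches[[l]]
    dact <- sp_mult(fast$Dt[[l]], dH, B)
    dconv <- elu_backward(dact, cache$act)
    bk <- cheb_conv_fast_backward(fast$L[[l]], cache$conv, params$enc[[l]]$W,
                                  dconv)
    grads$enc[[l]] <- list(W = bk$dW, b = bk$db)
    dH <- bk$dX
  }
  grads
}

# one optimiser step over the whole parameter tree; state holds first and
# second moment accumulators (rmsprop leaves m unused)
optim_update <- function(params, grads, state, lr, method, step,
                         rho = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- if (method == "rmsprop") {
    function(p, g, st) {
      st$v <- rho * st$v + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(st$v) + eps), st = st)
    }
  } else {
    bc1 <- 1 - beta1^step
    bc2 <- 1 - beta2^step
    function(p, g, st) {
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      list(p = p - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps), st = st)
    }
  }
  for (grp in c("enc", "dec")) {
    for (l in seq_along(params[[grp]])) {
      for (w in c("W", "b")) {
        r <- upd(params[[grp]][[l]][[w]], grads[[grp]][[l]][[w]],
                 state[[grp]][[l]][[w]])
        params[[grp]][[l]][[w]] <- r$p
        state[[grp]][[l]][[w]] <- r$st
      }
    }
  }
  for (grp in c("fc_enc", "fc_dec")) {
    for (w in c("W", "b")) {
      r <- upd(params[[grp]][[w]], grads[[grp]][[w]], state[[grp]][[w]])
      params[[grp]][[w]] <- r$p
      state[[grp]][[w]] <- r$st
    }
  }
  list(params = params, state = state)
}

zero_like <- function(p)
  rapply(p, function(x) list(m = x * 0, v = x * 0), how = "replace")

normalise_batch <- function(coords, mean_face, scale) {
  sweep(coords, c(1, 2), mean_face) / scale
}

#' Train the mesh auto-encoder
#'
#' Minimises the mean absolute vertex-coordinate reconstruction error on
#' mean-face-centred, globally scaled inputs, with a 90/10 subject split
#' and the best-validation-checkpoint rule. Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param faces a [face_set()] (the training cohort).
#' @param config an [encoder_config()].
#' @param hierarchy optional pre-built [build_hierarchy()]; built from the
#'   face-set template when `NULL`.
#' @param verbose print per-epoch losses?
#' @return An object of class `face_model`: trained parameters, hierarchy,
#'   normalisation constants, loss history and latent summary statistics of
#'   the training cohort.
#' @export
train_face_model <- function(faces, config = encoder_config(),
                             hierarchy = NULL, verbose = FALSE) {
  n <- length(faces$subject_ids)
  stopifnot(n >= 2)
  if (is.null(hierarchy))
    hierarchy <- build_hierarchy(faces$template, config$factors)
  fast <- fast_ops(hierarchy)
  with_seed(config$seed, {
    params <- init_params(config, hierarchy)
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sort(sample.int(n, n_val))
    tr_idx <- setdiff(seq_len(n), val_idx)
    mean_face <- apply(faces$coords[, , tr_idx, drop = FALSE], c(1, 2), mean)
    centred <- sweep(faces$coords[, , tr_idx, drop = FALSE], c(1, 2), mean_face)
    scale <- sqrt(mean(centred^2))
    if (scale == 0) scale <- 1
    Xtr <- centred / scale
    Xval <- to_layout(normalise_batch(faces$coords[, , val_idx, drop = FALSE],
                                      mean_face, scale))
    nval <- length(val_idx)
    state <- zero_like(params)
    lr <- config$lr
    best <- list(loss = Inf, params = params)
    history <- data.frame(epoch = integer(), train_mae = numeric(),
                          val_mae = numeric())
    ntr <- length(tr_idx)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        step <- step + 1L
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        Xb <- to_layout(Xtr[, , idx, drop = FALSE])
        fwd <- net_forward(params, hierarchy, config, fast, Xb, length(idx),
                           keep_cache = TRUE)
        resid <- fwd$out - Xb
        loss <- mean(abs(resid))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        ep_loss <- ep_loss + loss * length(idx)
        dOut <- sign(resid) / length(resid)
        grads <- net_backward(params, hierarchy, config, fast, fwd, dOut)
        r <- optim_update(params, grads, state, lr, config$optimizer, step)
        params <- r$params; state <- r$state
      }
      val_out <- net_forward(params, hierarchy, config, fast, Xval, nval)$out
      val_loss <- mean(abs(val_out - Xval))
      if (val_loss < best$loss) best <- list(loss = val_loss, params = params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_mae = ep_loss / ntr,
                                           val_mae = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        ep_loss / ntr, val_loss))
      lr <- lr * config$lr_decay
    }
    model <- structure(list(params = best$params, config = config,
                            hierarchy = hierarchy, fast = fast,
                            mean_face = mean_face,
                            scale = scale, template = faces$template,
                            history = tibble::as_tibble(history),
                            best_val_mae = best$loss),
                       class = "face_model")
    Z <- encode_faces(model, faces)
    model$latent_mean <- colMeans(Z)
    model$latent_sd <- apply(Z, 2, sd)
    model
  })
}

#' @export
print.face_model <- function(x, ...) {
  cat(sprintf(
    "<face_model: V = %d, N = %d traits, best validation MAE %.4f (normalised)>\n",
    nrow(x$mean_face), x$config$latent_dim, x$best_val_mae))
  invisible(x)
}

#' Encode corresponded faces into latent traits
#'
#' @param model a [train_face_model()] or [pca_baseline()] model.
#' @param faces a [face_set()] (or a `V x 3 x n` coordinate array) with the
#'   model's template topology.
#' @param batch_size faces encoded per forward pass.
#' @return `n x N` trait matrix with subject ids as row names.
#' @export
encode_faces <- function(model, faces, batch_size = 64L) {
  UseMethod("encode_faces")
}

coords_of <- function(faces, model) {
  coords <- if (inherits(faces, "face_set")) faces$coords else faces
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1] != nrow(model$mean_face))
    stop("face topology does not match the model template")
  coords
}

model_fast <- function(model) {
  if (!is.null(model$fast)) model$fast else fast_ops(model$hierarchy)
}

#' @export
encode_faces.face_model <- function(model, faces, batch_size = 64L) {
  coords <- coords_of(faces, model)
  fast <- model_fast(model)
  n <- dim(coords)[3]
  Z <- matrix(NA_real_, n, model$config$latent_dim)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    Xb <- to_layout(normalise_batch(coords[, , idx, drop = FALSE],
                                    model$mean_face, model$scale))
    Z[idx, ] <- t(net_forward(model$params, model$hierarchy, model$config,
                              fast, Xb, length(idx), encode_only = TRUE)$z)
  }
  rownames(Z) <- if (inherits(faces, "face_set")) faces$subject_ids else NULL
  Z
}

#' Decode latent traits back to faces
#'
#' @param model a trained model.
#' @param Z `n x N` trait matrix (or a length-N vector).
#' @return `V x 3 x n` array of decoded vertex coordinates (mm).
#' @export
decode_traits <- function(model, Z) UseMethod("decode_traits")

#' @export
decode_traits.face_model <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  if (ncol(Z) != model$config$latent_dim)
    stop("Z must have ", model$config$latent_dim, " columns")
  out <- dec_forward(model$params, model$hierarchy, model$config,
                     model_fast(model), t(Z))$out
  sweep(from_layout(out, nrow(Z)) * model$scale, c(1, 2), model$mean_face, `+`)
}

#' Decode a single trait vector to a mesh
#'
#' @param model a trained model.
#' @param z length-N latent vector; defaults to the model's latent mean.
#' @return A [triangle_mesh()].
#' @export
decode_mesh <- function(model, z = NULL) {
  if (is.null(z)) z <- model$latent_mean
  triangle_mesh(decode_traits(model, z)[, , 1], model$template$faces)
}

#' Intermediate signal shapes of the encoder
#'
#' Runs a shape probe through the encoding path and returns the
#' (vertices x channels) dimensions after each convolution + pooling block
#' plus the latent length.
#'
#' @param model a trained `face_model`.
#' @return List with `blocks` (list of c(V, C)) and `latent`.
#' @export
encoder_shapes <- function(model) {
  V <- nrow(model$mean_face)
  Xb <- to_layout(array(0, c(V, 3, 1)))
  fwd <- net_forward(model$params, model$hierarchy, model$config,
                     model_fast(model), Xb, 1L)
  list(blocks = fwd$shapes, latent = nrow(fwd$z))
}

#' Mean per-vertex reconstruction error
#'
#' Mean over faces of the mean over vertices of the Euclidean distance (mm)
#' between input and reconstructed coordinates.
#'
#' @param model a trained model.
#' @param faces a [face_set()].
#' @return Scalar error in mm.
#' @export
reconstruction_error <- function(model, faces) {
  coords <- coords_of(faces, model)
  rec <- decode_traits(model, encode_faces(model, faces))
  d <- rec - coords
  pv <- sqrt(d[, 1, , drop = FALSE]^2 + d[, 2, , drop = FALSE]^2 +
               d[, 3, , drop = FALSE]^2)
  mean(pv)
}
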