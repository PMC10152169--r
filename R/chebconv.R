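# Chebyshev spectral graph convolution. A filter of order K applies
# Y = sum_k T_k(L) X W_k with T_0 = I, T_1 = L, T_k = 2 L T_{k-1} - T_{k-2},
# where L is the rescaled graph operator (spectrum in [-1, 1]).
#
# Training-loop internals carry a batch of B C-channel signals as one
# stacked (V*B) x C matrix with vertex index fastest; its memory order
# equals that of a V x (B*C) matrix, so the sparse kernel can apply a V x V
# operator per face without any reshaping copy, and the per-layer weight
# multiply is a plain GEMM per Chebyshev order.

csc_parts <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  list(p = M@p, i = M@i, x = M@x, nrow = nrow(M), ncol = ncol(M))
}

# apply a sparse V' x V operator to a stacked (V*B) x C batch;
# optionally fused as alpha * op %*% X + beta * init
sp_mult <- function(parts, X, B = 1L, alpha = 1, init = NULL, beta = 1) {
  C <- ncol(X)
  y <- .spmm_cpp(parts$p, parts$i, parts$x, parts$nrow, X,
                 as.integer(B * C), alpha, init, beta)
  dim(y) <- c(parts$nrow * B, C)
  y
}

# fast-apply structures for every level of a hierarchy
fast_ops <- function(hier) {
  list(L = lapply(hier$operators, function(o) csc_parts(o$laplacian)),
       D = lapply(hier$down_transforms, csc_parts),
       Dt = lapply(hier$down_transforms, function(m) csc_parts(Matrix::t(m))),
       U = lapply(hier$up_transforms, csc_parts),
       Ut = lapply(hier$up_transforms, function(m) csc_parts(Matrix::t(m))))
}

cheb_basis_fast <- function(Lp, Xmat, K, B) {
  basis <- vector("list", K)
  basis[[1]] <- Xmat
  if (K >= 2) basis[[2]] <- sp_mult(Lp, Xmat, B)
  if (K >= 3) for (k in 3:K)    # T_k = 2 L T_{k-1} - T_{k-2}, fused
    basis[[k]] <- sp_mult(Lp, basis[[k - 1]], B, alpha = 2,
                          init = basis[[k - 2]], beta = -1)
  basis
}

# Xmat: stacked (V*B) x Cin. W: K x Cin x Cout array.
cheb_conv_fast <- function(Lp, Xmat, B, Cin, W, bias) {
  K <- dim(W)[1]; Cout <- dim(W)[3]
  basis <- cheb_basis_fast(Lp, Xmat, K, B)
  Y <- basis[[1]] %*% matrix(W[1, , ], Cin, Cout)
  if (K >= 2) for (k in 2:K)
    Y <- Y + basis[[k]] %*% matrix(W[k, , ], Cin, Cout)
  Y <- .add_bias_cpp(Y, bias)
  list(out = Y, basis = basis, B = B, Cin = Cin, K = K, Cout = Cout)
}

cheb_conv_fast_backward <- function(Lp, cache, W, dY) {
  B <- cache$B; Cin <- cache$Cin; K <- cache$K; Cout <- cache$Cout
  dW <- array(0, dim(W))
  for (k in seq_len(K)) dW[k, , ] <- crossprod(cache$basis[[k]], dY)
  db <- colSums(dY)
  bars <- lapply(seq_len(K), function(k)
    tcrossprod(dY, matrix(W[k, , ], Cin, Cout)))
  # reverse-mode accumulation through the Chebyshev recursion
  if (K >= 3) for (k in K:3) {
    bars[[k - 1]] <- sp_mult(Lp, bars[[k]], B, alpha = 2,
                             init = bars[[k - 1]], beta = 1)
    bars[[k - 2]] <- bars[[k - 2]] - bars[[k]]
  }
  dX <- if (K >= 2) sp_mult(Lp, bars[[2]], B, init = bars[[1]], beta = 1)
        else bars[[1]]
  list(dX = dX, dW = dW, db = db)
}

#' Chebyshev graph convolution of a vertex signal
#'
#' Applies the order-`K` spectral filter
#' `sum_k T_k(L) %*% signal %*% W_k` with the Chebyshev recursion
#' `T_0 = I`, `T_1 = L`, `T_k = 2 L T_{k-1} - T_{k-2}` on the rescaled
#' graph operator.
#'
#' @param signal `V x Cin` numeric matrix.
#' @param graph_operator a [build_graph_operator()] result.
#' @param weights numeric array `K x Cin x Cout`.
#' @param bias optional length-`Cout` bias.
#' @return `V x Cout` matrix.
#' @export
cheb_conv <- function(signal, graph_operator, weights, bias = NULL) {
  signal <- as.matrix(signal)
  if (length(dim(weights)) != 3L) stop("weights must be a K x Cin x Cout array")
  if (dim(weights)[2] != ncol(signal))
    stop("weights expect ", dim(weights)[2], " input channels, signal has ",
         ncol(signal))
  if (nrow(signal) != nrow(graph_operator$laplacian))
    stop("signal rows must match graph operator size")
  if (is.null(bias)) bias <- numeric(dim(weights)[3])
  res <- cheb_conv_fast(csc_parts(graph_operator$laplacian), signal,
                        B = 1L, Cin = ncol(signal), weights, bias)
  res$out
}

elu <- function(x) {
  y <- .elu_cpp(x)
  dim(y) <- dim(x)
  y
}

# dY * elu'(x), with the derivative recovered from the activation output
elu_backward <- function(dy, y) {
  g <- .elu_backward_cpp(dy, y)
  dim(g) <- dim(dy)
  g
}
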