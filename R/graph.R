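#' Unique undirected edges of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return Integer matrix with two columns (a < b), one row per edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Spectral graph operator of a mesh
#'
#' Builds the binary vertex adjacency from shared face edges and the
#' symmetric-normalised graph Laplacian rescaled for Chebyshev filtering.
#' With the normalised Laplacian's spectrum contained in `[0, 2]`, the
#' rescaled operator `L - I` has spectrum in `[-1, 1]`, the domain of the
#' Chebyshev recursion. Isolated vertices are allowed (zero rows) with a
#' warning.
#'
#' @param mesh a [triangle_mesh()].
#' @return An object of class `graph_operator` with sparse `adjacency` and
#'   `laplacian` (the rescaled operator) fields plus `degree`.
#' @export
build_graph_operator <- function(mesh) {
  V <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(V, V))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0))
    warning("mesh has ", sum(deg == 0), " isolated vertex/vertices")
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dinv <- Matrix::Diagonal(V, dinv)
  # normalised Laplacian L = I - D^-1/2 A D^-1/2, rescaled to L - I
  # (lambda_max bound 2), i.e. -D^-1/2 A D^-1/2 on non-isolated vertices.
  Lr <- Matrix::Diagonal(V, ifelse(deg > 0, 0, -1)) - Dinv %*% A %*% Dinv
  structure(list(adjacency = A, laplacian = methods::as(Lr, "generalMatrix"),
                 degree = deg),
            class = "graph_operator")
}

#' @export
print.graph_operator <- function(x, ...) {
  cat(sprintf("<graph_operator: %d vertices, %d edges>\n",
              nrow(x$adjacency), sum(x$adjacency@x > 0) / 2))
  invisible(x)
}
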