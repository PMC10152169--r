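#' Quadric-error-metric mesh decimation
#'
#' Repeated minimum-cost edge contraction with Garland-Heckbert per-vertex
#' plane quadrics and a boundary-edge penalty, until the requested vertex
#' count is reached. Contractions collapse onto an existing endpoint (the one
#' with the smaller combined quadric error; ties keep the lower vertex
#' index), so coarse vertices are a subset of fine vertices and the
#' down-transform is a row selector. Deterministic for a given mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param target target vertex count, in `[4, V)`; `target = V` returns the
#'   mesh unchanged with an identity map.
#' @param boundary_weight penalty weight for boundary-preserving constraint
#'   planes.
#' @return A list with `mesh` (the coarse [triangle_mesh()]), `kept`
#'   (indices of surviving fine vertices, ascending) and `vertex_map`
#'   (length-V map from each fine vertex to the coarse vertex it collapsed
#'   into).
#' @export
decimate_qem <- function(mesh, target, boundary_weight = 1000) {
  V <- nrow(mesh$vertices)
  if (target == V)
    return(list(mesh = mesh, kept = seq_len(V), vertex_map = seq_len(V)))
  if (target < 4 || target > V) stop("target must be in [4, V]")
  res <- .qem_decimate_cpp(mesh$vertices, mesh$faces, as.integer(target),
                           boundary_weight)
  list(mesh = triangle_mesh(res$vertices, res$faces),
       kept = res$kept, vertex_map = res$vertex_map)
}

#' Multi-resolution mesh sampling hierarchy
#'
#' Coarsens the template by quadric-error decimation with the given factor
#' per level (`V_{l+1} = ceiling(V_l / factor)`), and builds the transform
#' matrices used for pooling in mesh convolutions: each down-transform `D_l`
#' selects the kept vertices (one unit entry per row); each up-transform
#' `U_l` carries a coarse signal back to the fine level by barycentric
#' coordinates of each fine vertex's projection onto its nearest coarse
#' triangle (weights sum to 1; negativity allowed when the projection falls
#' outside the triangle). With the default factors a 5023-vertex template
#' yields level sizes 1256, 314, 79 and 20.
#'
#' @param template a [triangle_mesh()].
#' @param factors down-sampling factor per level; default `c(4, 4, 4, 4)`.
#' @return An object of class `sampling_hierarchy`: `levels` (list of
#'   meshes, finest first), `down_transforms`, `up_transforms`, `operators`
#'   (a [build_graph_operator()] per level).
#' @export
build_hierarchy <- function(template, factors = c(4, 4, 4, 4)) {
  stopifnot(all(factors > 0))
  levels <- list(template)
  down <- list(); up <- list()
  cur <- template
  for (l in seq_along(factors)) {
    target <- ceiling(nrow(cur$vertices) / factors[l])
    if (target < 4)
      stop("factor chain exhausts the mesh at level ", l,
           " (target ", target, " vertices)")
    dec <- decimate_qem(cur, target)
    Vf <- nrow(cur$vertices)
    D <- Matrix::sparseMatrix(i = seq_along(dec$kept), j = dec$kept, x = 1,
                              dims = c(length(dec$kept), Vf))
    nb <- .nearest_barycentric_cpp(cur$vertices, dec$mesh$vertices,
                                   dec$mesh$faces)
    tri <- dec$mesh$faces[nb$face, , drop = FALSE]
    U <- Matrix::sparseMatrix(i = rep(seq_len(Vf), 3L),
                              j = as.vector(tri),
                              x = as.vector(nb$bary),
                              dims = c(Vf, nrow(dec$mesh$vertices)))
    down[[l]] <- D
    up[[l]] <- U
    cur <- dec$mesh
    levels[[l + 1L]] <- cur
  }
  structure(list(levels = levels, down_transforms = down, up_transforms = up,
                 operators = lapply(levels, build_graph_operator),
                 factors = factors),
            class = "sampling_hierarchy")
}

#' @export
print.sampling_hierarchy <- function(x, ...) {
  cat("<sampling_hierarchy: level sizes ",
      paste(vapply(x$levels, function(m) nrow(m$vertices), 1L),
            collapse = " -> "), ">\n", sep = "")
  invisible(x)
}

#' Vertex counts per hierarchy level
#'
#' @param hierarchy a [build_hierarchy()] result.
#' @return Integer vector, finest level first.
#' @export
level_sizes <- function(hierarchy) {
  vapply(hierarchy$levels, function(m) nrow(m$vertices), 1L)
}

#' Apply a sampling transform to a vertex signal
#'
#' Sparse matrix times dense per-vertex signal.
#'
#' @param transform a down- or up-transform matrix from the hierarchy.
#' @param signal numeric matrix with one row per vertex.
#' @return The transformed signal.
#' @export
apply_transform <- function(transform, signal) {
  signal <- as.matrix(signal)
  if (ncol(transform) != nrow(signal))
    stop("transform expects ", ncol(transform), " vertices, signal has ",
         nrow(signal))
  as.matrix(transform %*% signal)
}

#' Serialise / restore a sampling hierarchy as plain-text files
#'
#' Meshes are written as ASCII PLY and transforms in MatrixMarket
#' coordinate format under one directory.
#'
#' @param hierarchy a [build_hierarchy()] result.
#' @param dir directory to create/read.
#' @return `dir` (write) or the restored hierarchy (read).
#' @export
write_hierarchy <- function(hierarchy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(hierarchy$levels))
    write_mesh(hierarchy$levels[[l]], file.path(dir, sprintf("level_%d.ply", l - 1L)))
  for (l in seq_along(hierarchy$down_transforms)) {
    Matrix::writeMM(methods::as(hierarchy$down_transforms[[l]], "CsparseMatrix"),
                    file.path(dir, sprintf("down_%d.mtx", l)))
    Matrix::writeMM(methods::as(hierarchy$up_transforms[[l]], "CsparseMatrix"),
                    file.path(dir, sprintf("up_%d.mtx", l)))
  }
  writeLines(as.character(hierarchy$factors), file.path(dir, "factors.txt"))
  invisible(dir)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(dir) {
  factors <- as.numeric(readLines(file.path(dir, "factors.txt")))
  levels <- lapply(seq_len(length(factors) + 1L) - 1L, function(l)
    read_mesh(file.path(dir, sprintf("level_%d.ply", l))))
  down <- lapply(seq_along(factors), function(l)
    methods::as(Matrix::readMM(file.path(dir, sprintf("down_%d.mtx", l))), "CsparseMatrix"))
  up <- lapply(seq_along(factors), function(l)
    methods::as(Matrix::readMM(file.path(dir, sprintf("up_%d.mtx", l))), "CsparseMatrix"))
  structure(list(levels = levels, down_transforms = down, up_transforms = up,
                 operators = lapply(levels, build_graph_operator),
                 factors = factors),
            class = "sampling_hierarchy")
}
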