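#' Triangle mesh
#'
#' A minimal shared-topology surface: a `V x 3` matrix of vertex coordinates
#' (millimetres) and an `F x 3` integer matrix of 1-based vertex indices.
#' All corresponded faces in a study share one face array; only the vertex
#' coordinates differ between subjects.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  v <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > v)
      stop("face indices out of range [1, V]")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("faces with repeated vertices are not allowed")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Geometric center of a mesh
#'
#' Arithmetic mean of the vertex coordinates. Used as the reference point for
#' the inward/outward sign convention of displacement heatmaps.
#'
#' @param mesh a [triangle_mesh()].
#' @return Numeric length-3 vector.
#' @export
geometric_center <- function(mesh) {
  if (nrow(mesh$vertices) < 1L) stop("mesh has no vertices")
  colMeans(mesh$vertices)
}

#' Rigid (Kabsch) alignment onto a corresponded template
#'
#' Finds the rigid transform (optionally with a uniform scale) minimising the
#' summed squared distance between corresponding vertices, and returns the
#' transformed mesh. Correspondence is assumed: vertex i of `mesh` matches
#' vertex i of `template`. Scaling is off by default, appropriate for scans
#' acquired with fixed camera geometry.
#'
#' @param mesh,template corresponded [triangle_mesh()] objects.
#' @param with_scaling allow a uniform scale factor? Default `FALSE`.
#' @return The aligned `triangle_mesh` with attributes `rotation`,
#'   `translation`, `scale` and `rmsd`.
#' @export
procrustes_align <- function(mesh, template, with_scaling = FALSE) {
  X <- mesh$vertices
  Y <- template$vertices
  if (nrow(X) != nrow(Y)) stop("vertex counts differ; meshes must be corresponded")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(crossprod(X0, Y0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)   # maps X0 rows onto Y0 rows: Y0 ~ X0 %*% t(R)
  scale <- if (with_scaling) {
    sum(diag(D) * s$d) / sum(X0^2)
  } else 1
  aligned <- scale * X0 %*% t(R)
  aligned <- sweep(aligned, 2, cy, `+`)
  out <- triangle_mesh(aligned, mesh$faces)
  attr(out, "rotation") <- R
  attr(out, "translation") <- cy - scale * as.numeric(R %*% cx)
  attr(out, "scale") <- scale
  attr(out, "rmsd") <- sqrt(mean(rowSums((aligned - Y)^2)))
  out
}

#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals, unit-normalised. Vertices
#' with no incident faces get a zero normal.
#'
#' @param mesh a [triangle_mesh()].
#' @return `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  p1 <- mesh$vertices[f[, 1], , drop = FALSE]
  p2 <- mesh$vertices[f[, 2], , drop = FALSE]
  p3 <- mesh$vertices[f[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- matrix(0, V, 3)
  for (j in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], f[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, c] <- n[idx, c] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n
}

#' Corresponded face set
#'
#' A cohort of meshes sharing the template's topology. Coordinates are held
#' in a single `V x 3 x n` array for efficient vectorised generation,
#' encoding and statistics.
#'
#' @param subject_ids character vector of length n.
#' @param coords numeric array `V x 3 x n`.
#' @param template the shared-topology [triangle_mesh()].
#' @return An object of class `face_set`.
#' @export
face_set <- function(subject_ids, coords, template) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(template$vertices))
    stop("coords vertex count differs from template")
  if (length(subject_ids) != dim(coords)[3])
    stop("subject_ids length differs from number of faces")
  structure(list(subject_ids = as.character(subject_ids), coords = coords,
                 template = template),
            class = "face_set")
}

#' @export
print.face_set <- function(x, ...) {
  cat(sprintf("<face_set: %d subjects, %d vertices>\n",
              length(x$subject_ids), dim(x$coords)[1]))
  invisible(x)
}

#' Extract one subject's mesh from a face set
#'
#' @param faces a [face_set()].
#' @param i subject position or subject id.
#' @return A [triangle_mesh()].
#' @export
face_mesh <- function(faces, i) {
  if (is.character(i)) i <- match(i, faces$subject_ids)
  triangle_mesh(faces$coords[, , i], faces$template$faces)
}
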