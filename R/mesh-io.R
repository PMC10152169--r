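ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  switch(type,
    char = , int8 = readBin(con, integer(), n, size = 1L, signed = TRUE, endian = "little"),
    uchar = , uint8 = readBin(con, integer(), n, size = 1L, signed = FALSE, endian = "little"),
    short = , int16 = readBin(con, integer(), n, size = 2L, signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(con, integer(), n, size = 2L, signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 = readBin(con, integer(), n, size = 4L, endian = "little"),
    float = , float32 = readBin(con, numeric(), n, size = 4L, endian = "little"),
    double = , float64 = readBin(con, numeric(), n, size = 8L, endian = "little"),
    stop("unsupported PLY type: ", type))
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary-little-endian PLY and plain OBJ. Extra
#' per-vertex PLY properties are kept: a `quality` property is returned as
#' the `scalar` attribute, `red`/`green`/`blue` as the `color` attribute.
#' Only triangular faces are accepted.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `NULL` to infer from the extension.
#' @return A [triangle_mesh()], possibly with `scalar`/`color` attributes.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj"))
  if (format == "ply") read_ply(path) else read_obj(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file (line 1): ", path)
  fmt <- NULL
  elements <- list()  # list of list(name, count, props = list(name,type,list_count_type))
  cur <- NULL
  lineno <- 1L
  repeat {
    line <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(line) == 0L) stop("unexpected end of PLY header at line ", lineno)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element at line ", lineno)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3], is_list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], is_list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("malformed PLY header at line ", lineno, ": ", line)
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  if (is.null(ve)) stop("PLY file has no vertex element")
  vprop_names <- vapply(ve$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% vprop_names))
    stop("PLY vertex element lacks x/y/z properties")

  if (fmt == "ascii") {
    body <- readLines(con)
    if (length(body) < ve$count + if (is.null(fe)) 0L else fe$count)
      stop("PLY body truncated")
    vlines <- body[seq_len(ve$count)]
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                   nrow = ve$count, byrow = TRUE)
    if (ncol(vdat) != length(ve$props))
      stop("PLY vertex rows have wrong field count")
    colnames(vdat) <- vprop_names
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      flines <- body[ve$count + seq_len(fe$count)]
      ftok <- strsplit(trimws(flines), "\\s+")
      sizes <- vapply(ftok, function(t) as.integer(t[1]), 1L)
      if (any(sizes != 3L)) {
        bad <- which(sizes != 3L)[1]
        stop("non-triangular face at face line ", bad, " (size ", sizes[bad], ")")
      }
      faces <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
    }
  } else {
    nv <- ve$count
    scalar_types <- vapply(ve$props, `[[`, "", "type")
    if (any(vapply(ve$props, `[[`, TRUE, "is_list")))
      stop("list-valued vertex properties are not supported")
    sizes <- ply_type_size[scalar_types]
    rowsize <- sum(sizes)
    raw <- readBin(con, "raw", n = nv * rowsize)
    if (length(raw) < nv * rowsize) stop("PLY binary vertex block truncated")
    vdat <- matrix(NA_real_, nv, length(ve$props))
    off <- 0L
    # column-wise decode via per-row offsets
    rcon <- rawConnection(raw)
    for (i in seq_len(nv)) {
      for (j in seq_along(ve$props))
        vdat[i, j] <- ply_read_scalar(rcon, scalar_types[j], 1L)
    }
    close(rcon)
    colnames(vdat) <- vprop_names
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      fl <- fe$props[[1]]
      if (!fl$is_list) stop("PLY face element lacks a list property")
      faces <- matrix(0L, fe$count, 3L)
      for (i in seq_len(fe$count)) {
        cnt <- ply_read_scalar(con, fl$count_type, 1L)
        if (cnt != 3L) stop("non-triangular face at face ", i, " (size ", cnt, ")")
        faces[i, ] <- ply_read_scalar(con, fl$type, 3L) + 1L
      }
    }
  }
  mesh <- triangle_mesh(vdat[, c("x", "y", "z"), drop = FALSE],
                        if (is.null(faces)) matrix(integer(), 0, 3) else faces)
  if ("quality" %in% colnames(vdat)) attr(mesh, "scalar") <- vdat[, "quality"]
  if (all(c("red", "green", "blue") %in% colnames(vdat)))
    attr(mesh, "color") <- vdat[, c("red", "green", "blue"), drop = FALSE]
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path)
  vsel <- startsWith(lines, "v ")
  fsel <- startsWith(lines, "f ")
  if (!any(vsel)) stop("OBJ file has no vertices: ", path)
  vtok <- strsplit(trimws(sub("^v", "", lines[vsel])), "\\s+")
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  faces <- matrix(integer(), 0, 3)
  if (any(fsel)) {
    ftok <- strsplit(trimws(sub("^f", "", lines[fsel])), "\\s+")
    sizes <- lengths(ftok)
    if (any(sizes != 3L)) {
      bad <- which(fsel)[which(sizes != 3L)[1]]
      stop("non-triangular face at line ", bad, " (", sizes[sizes != 3L][1],
           " vertices); triangles only")
    }
    # strip texture/normal refs ("i/j/k" -> "i")
    faces <- t(vapply(ftok, function(t) as.integer(sub("/.*$", "", t)), integer(3)))
  }
  if (any(is.na(verts)) || any(is.na(faces))) stop("malformed OBJ file: ", path)
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' ASCII output. An optional per-vertex scalar is stored as the PLY
#' `quality` property and, when `color = TRUE`, also mapped through a
#' diverging red-white-blue colormap (symmetric about zero) to `uchar` RGB
#' vertex colors. OBJ stores plain geometry only.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `NULL` to infer from the extension.
#' @param per_vertex_scalar optional numeric vector of length V.
#' @param color also store colormap RGB (PLY only)? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, per_vertex_scalar = NULL,
                       color = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj"))
  if (!is.null(per_vertex_scalar) &&
        length(per_vertex_scalar) != nrow(mesh$vertices))
    stop("per_vertex_scalar length differs from vertex count")
  if (format == "obj") {
    if (!is.null(per_vertex_scalar))
      stop("OBJ cannot store per-vertex scalars; use PLY")
    lines <- c(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               if (nrow(mesh$faces) > 0L)
                 sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                         mesh$faces[, 3]))
    writeLines(lines, path)
    return(invisible(path))
  }
  v <- nrow(mesh$vertices); f <- nrow(mesh$faces)
  props <- c("property float x", "property float y", "property float z")
  cols <- NULL
  if (!is.null(per_vertex_scalar)) {
    props <- c(props, "property float quality")
    if (isTRUE(color)) {
      cols <- diverging_rgb(per_vertex_scalar)
      props <- c(props, "property uchar red", "property uchar green",
                 "property uchar blue")
    }
  }
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", v), props,
              paste("element face", f),
              "property list uchar int vertex_indices", "end_header")
  vcols <- mesh$vertices
  fmt_parts <- "%.9g %.9g %.9g"
  if (!is.null(per_vertex_scalar)) {
    vcols <- cbind(vcols, per_vertex_scalar)
    fmt_parts <- paste(fmt_parts, "%.9g")
    if (!is.null(cols)) {
      vcols <- cbind(vcols, cols)
      fmt_parts <- paste(fmt_parts, "%d %d %d")
    }
  }
  vlines <- do.call(sprintf, c(list(fmt_parts),
                               lapply(seq_len(ncol(vcols)), function(j) vcols[, j])))
  flines <- if (f > 0L)
    sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
            mesh$faces[, 3] - 1L) else character()
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

# Diverging red-white-blue map, symmetric about 0; limits at the 99th
# percentile of |x| so single extreme vertices do not saturate the scale.
# Negative (inward) -> red, positive (outward) -> blue.
diverging_rgb <- function(x, limit = NULL) {
  if (is.null(limit)) limit <- quantile(abs(x), 0.99, names = FALSE)
  if (!is.finite(limit) || limit <= 0) limit <- 1
  t <- pmax(-1, pmin(1, x / limit))
  r <- ifelse(t < 0, 255, round(255 * (1 - t)))
  b <- ifelse(t > 0, 255, round(255 * (1 + t)))
  g <- round(255 * (1 - abs(t)))
  cbind(red = as.integer(r), green = as.integer(g), blue = as.integer(b))
}
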