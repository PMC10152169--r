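# Deterministic synthetic face template: a triangulated half-ellipsoid patch
# ("face" side of a head) with protruding nose and chin lobes, scaled to a
# ~180 mm head height so displacements read in millimetres. Row-based
# parameterisation over azimuth (theta, left-right) and polar angle (phi,
# top-down); adjacent rows with different vertex counts are bridged by a
# shortest-diagonal triangulation, which is fully deterministic.

bridge_rows <- function(idx_a, idx_b, t_a, t_b) {
  na <- length(idx_a); nb <- length(idx_b)
  out <- matrix(0L, 0L, 3L)
  i <- 1L; j <- 1L
  while (i < na || j < nb) {
    adv_a <- if (i < na && j < nb) {
      t_a[i + 1L] <= t_b[j + 1L]
    } else i < na
    if (adv_a) {
      out <- rbind(out, c(idx_a[i], idx_a[i + 1L], idx_b[j]))
      i <- i + 1L
    } else {
      out <- rbind(out, c(idx_a[i], idx_b[j + 1L], idx_b[j]))
      j <- j + 1L
    }
  }
  out
}

#' Synthetic face template mesh
#'
#' Builds a deterministic face-like surface with a given exact vertex count:
#' a half-ellipsoid patch (semi-axes 70 x 90 x 80 mm) with Gaussian nose and
#' chin lobes. Five named, non-empty, pairwise-disjoint region masks are
#' attached (`nose_tip`, `nose_bridge`, `chin`, `lower_eyelids`,
#' `forehead`), defined in the surface parameterisation, along with the
#' `(theta, phi)` coordinates of every vertex.
#'
#' @param n_vertices total vertex count; default 5023.
#' @return A [triangle_mesh()] with attributes `region_masks` (named list of
#'   vertex index vectors) and `uv` (`V x 2` matrix of angles in degrees).
#' @export
make_template <- function(n_vertices = 5023) {
  if (n_vertices < 100) stop("n_vertices must be at least 100")
  theta_rng <- c(-80, 80)    # azimuth, degrees
  phi_rng <- c(15, 165)      # polar angle from the top, degrees

  # row layout: counts proportional to sin(phi), adjusted to the exact total
  n_rows <- max(8L, round(sqrt(n_vertices * 1.15)))
  phi <- seq(phi_rng[1], phi_rng[2], length.out = n_rows)
  w <- sin(phi * pi / 180)
  counts <- pmax(3L, round(w / sum(w) * n_vertices))
  diff <- n_vertices - sum(counts)
  # distribute the remainder deterministically over the largest rows
  ord <- order(counts, decreasing = TRUE)
  k <- 1L
  while (diff != 0L) {
    r <- ord[(k - 1L) %% n_rows + 1L]
    step <- sign(diff)
    if (counts[r] + step >= 3L) {
      counts[r] <- counts[r] + step
      diff <- diff - step
    }
    k <- k + 1L
  }

  a <- 70; b <- 90; cc <- 80   # mm semi-axes (width, height, depth)
  verts <- matrix(0, n_vertices, 3)
  uv <- matrix(0, n_vertices, 2)
  row_idx <- vector("list", n_rows)
  row_t <- vector("list", n_rows)
  pos <- 0L
  for (r in seq_len(n_rows)) {
    m <- counts[r]
    th <- seq(theta_rng[1], theta_rng[2], length.out = m)
    idx <- pos + seq_len(m)
    sp <- sin(phi[r] * pi / 180); cp <- cos(phi[r] * pi / 180)
    verts[idx, 1] <- a * sp * sin(th * pi / 180)
    verts[idx, 2] <- b * cp
    verts[idx, 3] <- cc * sp * cos(th * pi / 180)
    uv[idx, 1] <- th
    uv[idx, 2] <- phi[r]
    row_idx[[r]] <- idx
    row_t[[r]] <- (th - theta_rng[1]) / diff(theta_rng)
    pos <- pos + m
  }

  faces <- do.call(rbind, lapply(seq_len(n_rows - 1L), function(r)
    bridge_rows(row_idx[[r]], row_idx[[r + 1L]], row_t[[r]], row_t[[r + 1L]])))

  # nose and chin lobes: radial Gaussian bumps in (theta, phi)
  bump <- function(th0, ph0, sth, sph, height) {
    g <- exp(-0.5 * (((uv[, 1] - th0) / sth)^2 + ((uv[, 2] - ph0) / sph)^2))
    height * g
  }
  radial <- verts / sqrt(rowSums(verts^2))
  h <- bump(0, 96, 14, 11, 14) +    # nose
       bump(0, 150, 16, 9, 8) +     # chin
       bump(0, 38, 40, 14, 3)       # brow/forehead fullness
  verts <- verts + radial * h

  mesh <- triangle_mesh(verts, faces)
  # consistent outward orientation
  nrm <- vertex_normals(mesh)
  if (mean(rowSums(nrm * radial)) < 0)
    mesh <- triangle_mesh(verts, faces[, c(1, 3, 2)])

  th <- uv[, 1]; ph <- uv[, 2]
  masks <- list(
    nose_tip = which(abs(th) <= 28 & ph >= 84 & ph <= 112),
    nose_bridge = which(abs(th) <= 12 & ph >= 60 & ph < 84),
    chin = which(abs(th) <= 30 & ph >= 138 & ph <= 160),
    lower_eyelids = which(abs(th) >= 18 & abs(th) <= 48 & ph >= 67 & ph <= 82),
    forehead = which(abs(th) <= 45 & ph >= 25 & ph <= 50)
  )
  if (any(lengths(masks) == 0L))
    stop("n_vertices too small to allocate all named regions")
  attr(mesh, "region_masks") <- masks
  attr(mesh, "uv") <- uv
  mesh
}
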