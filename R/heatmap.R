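# Decoder-based facial heatmaps: significant traits are mapped back to the
# face as per-vertex displacement fields, combined with their regression
# coefficients as weights, and signed radially (inward negative / red,
# outward positive / blue) with respect to the head's geometric center.

#' Displacement field of one latent trait
#'
#' Decodes the latent mean and the mean perturbed by `delta` on trait `j`,
#' and returns the per-vertex difference: the facial phenotype this trait
#' represents, at `delta` trait units.
#'
#' @param model a trained face model.
#' @param trait_index 1-based trait index.
#' @param delta perturbation in trait units; conventionally one trait SD.
#' @param center latent vector to perturb; default the model latent mean.
#' @return `V x 3` displacement matrix (mm) with attribute `trait_index`.
#' @export
trait_displacement_field <- function(model, trait_index, delta,
                                     center = NULL) {
  if (is.null(center)) center <- model$latent_mean
  N <- length(center)
  if (trait_index < 1 || trait_index > N) stop("trait_index out of range")
  zp <- center
  zp[trait_index] <- zp[trait_index] + delta
  d <- decode_traits(model, rbind(center, zp))
  field <- d[, , 2] - d[, , 1]
  attr(field, "trait_index") <- trait_index
  field
}

#' Combine significant traits into one displacement field
#'
#' Weighted sum of per-trait displacement fields using the regression
#' coefficients as weights. Each field is expected at a +1-SD perturbation
#' and each weight is `beta / sd`, so traits of different latent scales
#' contribute comparably and the result is invariant to flipping any
#' trait's sign (which flips both its beta and its field).
#'
#' @param fields list of `V x 3` fields (one per significant trait, at +1
#'   trait SD).
#' @param betas regression coefficients of the same traits.
#' @param trait_sds the traits' SDs; weights are `betas / trait_sds`.
#'   Use `rep(1, length(betas))` for raw-beta weighting.
#' @return `V x 3` combined displacement field.
#' @export
combine_significant_traits <- function(fields, betas, trait_sds) {
  if (length(fields) == 0) stop("no significant traits to combine")
  stopifnot(length(betas) == length(fields),
            length(trait_sds) == length(fields))
  w <- betas / trait_sds
  out <- matrix(0, nrow(fields[[1]]), 3)
  for (i in seq_along(fields)) out <- out + w[i] * fields[[i]]
  out
}

#' Radially signed heatmap scalar
#'
#' Projects a displacement field onto the outward radial direction from the
#' head's geometric center: positive = outward (rendered blue), negative =
#' inward (rendered red). Vertices coinciding with the center get 0 with a
#' warning.
#'
#' @param field `V x 3` displacement field (mm).
#' @param template the template mesh.
#' @param center reference point; default [geometric_center()] of the
#'   template.
#' @return Numeric vector of signed per-vertex scalars (mm).
#' @export
radial_sign <- function(field, template, center = geometric_center(template)) {
  r <- sweep(template$vertices, 2, center)
  len <- sqrt(rowSums(r^2))
  if (any(len == 0)) warning("vertex coincides with the center; scalar set to 0")
  u <- r
  u[len > 0, ] <- r[len > 0, , drop = FALSE] / len[len > 0]
  u[len == 0, ] <- 0
  rowSums(field * u)
}

#' Localisation of a heatmap against a ground-truth region
#'
#' Fraction of the highest-|scalar| vertices (the top `top_fraction` of V)
#' that fall inside the given region mask. Under a spatially random heatmap
#' the expected score is the mask's share of vertices.
#'
#' @param heatmap signed per-vertex scalar.
#' @param mask integer vertex indices of the true region (non-empty).
#' @param top_fraction fraction of vertices counted as "top"; in `(0, 1]`.
#' @return Overlap score in `[0, 1]`.
#' @export
localization_score <- function(heatmap, mask, top_fraction = 0.1) {
  if (length(mask) == 0) stop("mask must be non-empty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  k <- max(1L, round(top_fraction * length(heatmap)))
  top <- order(abs(heatmap), decreasing = TRUE)[seq_len(k)]
  mean(top %in% mask)
}

#' Heatmap for the significant traits of an association analysis
#'
#' Convenience wrapper: builds the per-trait fields at +1 SD, combines them
#' with coefficient weights, and signs them radially.
#'
#' @param model a trained face model.
#' @param assoc a `trait_assoc` tibble.
#' @param use `"fdr"` (FDR-significant traits) or `"nominal"` (p < 0.05).
#' @return List with `field` (V x 3), `scalar` (signed heatmap) and
#'   `traits` (indices used), or `NULL` when no trait qualifies.
#' @export
assoc_heatmap <- function(model, assoc, use = c("fdr", "nominal")) {
  use <- match.arg(use)
  sel <- if (use == "fdr") assoc$significant else assoc$p_value < 0.05
  idx <- assoc$trait_index[sel]
  if (length(idx) == 0) return(NULL)
  sds <- assoc$trait_sd[sel]
  fields <- lapply(seq_along(idx), function(i)
    trait_displacement_field(model, idx[i], sds[i]))
  field <- combine_significant_traits(fields, assoc$beta[sel], sds)
  list(field = field,
       scalar = radial_sign(field, model$template),
       traits = idx)
}

#' Export a heatmap as colored PLY plus CSV
#'
#' Writes the template with the scalar stored as the PLY `quality` property
#' and a diverging red-white-blue vertex coloring (symmetric about zero,
#' clipped at the 99th percentile of |scalar|), plus a `vertex_id,scalar`
#' CSV next to it.
#'
#' @param template the template mesh.
#' @param heatmap signed per-vertex scalar.
#' @param path output PLY path; the CSV swaps the extension.
#' @return Named vector of the two paths, invisibly.
#' @export
export_heatmap <- function(template, heatmap, path) {
  stopifnot(length(heatmap) == nrow(template$vertices))
  write_mesh(template, path, format = "ply", per_vertex_scalar = heatmap,
             color = TRUE)
  csv <- sub("\\.[^.]*$", ".csv", path)
  utils::write.table(
    data.frame(vertex_id = seq_along(heatmap), scalar = heatmap),
    csv, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(ply = path, csv = csv))
}

#' Frontal-view heatmap plot
#'
#' Orthographic frontal projection of the template colored by the signed
#' heatmap (red inward, blue outward).
#'
#' @param template the template mesh.
#' @param heatmap signed per-vertex scalar.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(template, heatmap) {
  df <- tibble::tibble(x = template$vertices[, 1], y = template$vertices[, 2],
                       scalar = heatmap)
  lim <- quantile(abs(heatmap), 0.99, names = FALSE)
  if (!is.finite(lim) || lim <= 0) lim <- 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$scalar)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_gradient2(low = "red", mid = "white", high = "blue",
                                   limits = c(-lim, lim),
                                   oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "mm", x = NULL, y = NULL,
                  title = "Signed facial displacement (red inward, blue outward)") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
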