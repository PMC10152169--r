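# Synthetic cohort generator: corresponded faces plus covariates and a
# graded prenatal-alcohol exposure with known injected shape effects. The
# generator emulates the statistical structure the analysis assumes --
# smooth population shape variation, covariate-linked displacement fields,
# a dose-linear exposure effect on named regions, and longitudinal pairing
# with an attenuated effect at the older age -- not photorealistic faces.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Default covariate marginals for the synthetic cohort
#'
#' Category probabilities and continuous means/SDs loosely matching a large
#' population birth cohort at child age 9: four ethnicity categories with a
#' Dutch majority, roughly balanced sex, child BMI ~17.5, maternal age ~30,
#' ~40% maternal smoking, a third of mothers abstinent, lognormal weekly
#' drinks among drinkers, and drinking-timing shares that put most exposed
#' mothers in the any-first-trimester group. Among mothers who drank during
#' pregnancy, 99% also drank before pregnancy.
#'
#' @return A named list understood by [sample_covariates()].
#' @export
default_covariate_marginals <- function() {
  list(
    ethnicity = c(Dutch = 0.74, `non-Dutch-Western` = 0.09,
                  Turkish = 0.09, Moroccan = 0.08),
    p_male = 0.48,
    child_age = c(mean = 9.8, sd = 0.35),
    child_bmi = c(mean = 17.5, sd = 2.4),
    maternal_age = c(mean = 30.5, sd = 4.5),
    p_smoking = 0.40,
    p_abstinent = 0.33,
    drinks_meanlog = log(1.2),
    drinks_sdlog = 1.1,
    timing = c(before_only = 0.30, trimester1_only = 0.42, continued = 0.28),
    p_before_given_during = 0.99
  )
}

#' Consumption level from average weekly drinks
#'
#' Maps a continuous average consumption (standard drinks per week, one
#' drink ~12 g alcohol) to the six-level scale: <1 per week; 1-3 per week;
#' 4-6 per week; 1 per day; 2-3 per day; >3 per day. Daily categories are
#' converted at 7 days/week and adjacent integer bands split at their
#' midpoints. Abstinence (level 0) is handled upstream; non-positive input
#' is an error.
#'
#' @param weekly_drinks positive numeric vector.
#' @return Integer levels in 1..6.
#' @export
assign_levels <- function(weekly_drinks) {
  if (any(weekly_drinks <= 0)) stop("weekly_drinks must be positive")
  cuts <- c(1, 3.5, 6.5, 10.5, 24.5)   # 1/day = 7, 2-3/day = 14-21, >3/day > 21
  findInterval(weekly_drinks, cuts) + 1L
}

#' Exposure-timing tier membership
#'
#' Classifies each record into the timing strata: abstinent mothers form the
#' control group of every tier; drinking only before pregnancy defines the
#' tier-1 exposed group; first-trimester drinking with abstinence afterwards
#' defines tier 2a (and is also in tier 2b); any first-trimester drinking,
#' including mothers who continued, defines tier 2b. Records fitting none of
#' these (e.g. drinking only in later trimesters) are flagged excluded.
#'
#' @param covariates tibble with `drank_before_pregnancy` and
#'   `drank_trimester1/2/3` logical columns.
#' @return The input with logical columns `control`, `tier1_exposed`,
#'   `tier2a_exposed`, `tier2b_exposed`, `excluded` appended.
#' @export
assign_tiers <- function(covariates) {
  b <- covariates$drank_before_pregnancy
  t1 <- covariates$drank_trimester1
  t2 <- covariates$drank_trimester2
  t3 <- covariates$drank_trimester3
  control <- !b & !t1 & !t2 & !t3
  tier1 <- b & !t1 & !t2 & !t3
  tier2a <- t1 & !t2 & !t3
  tier2b <- t1
  excluded <- !control & !tier1 & !tier2b
  dplyr::mutate(covariates, control = control, tier1_exposed = tier1,
                tier2a_exposed = tier2a, tier2b_exposed = tier2b,
                excluded = excluded)
}

#' Sample a synthetic covariate/exposure table
#'
#' Draws `n` subjects with ethnicity, sex, ages, BMI, maternal smoking and a
#' graded alcohol exposure: abstinent with probability
#' `marginals$p_abstinent`, otherwise a lognormal average weekly consumption
#' discretised by [assign_levels()], with drinking timing (before only /
#' first trimester only / continued) drawn from `marginals$timing`.
#' Reproducible for a fixed seed.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param marginals see [default_covariate_marginals()].
#' @return A tibble, one row per subject.
#' @export
sample_covariates <- function(n, seed = 1L,
                              marginals = default_covariate_marginals()) {
  stopifnot(n >= 1)
  m <- marginals
  if (abs(sum(m$ethnicity) - 1) > 1e-9)
    stop("ethnicity probabilities must sum to 1")
  if (abs(sum(m$timing) - 1) > 1e-9)
    stop("timing probabilities must sum to 1")
  with_seed(seed, {
    eth <- sample(names(m$ethnicity), n, replace = TRUE, prob = m$ethnicity)
    sex <- ifelse(runif(n) < m$p_male, "male", "female")
    age <- rnorm(n, m$child_age["mean"], m$child_age["sd"])
    bmi <- pmax(11, rnorm(n, m$child_bmi["mean"], m$child_bmi["sd"]))
    mage <- rnorm(n, m$maternal_age["mean"], m$maternal_age["sd"])
    smoke <- runif(n) < m$p_smoking
    drinker <- runif(n) >= m$p_abstinent
    weekly <- ifelse(drinker, rlnorm(n, m$drinks_meanlog, m$drinks_sdlog), 0)
    level <- integer(n)
    level[drinker] <- assign_levels(weekly[drinker])
    timing <- sample(names(m$timing), n, replace = TRUE, prob = m$timing)
    before_if_during <- runif(n) < m$p_before_given_during
    tr1 <- drinker & timing != "before_only"
    tr2 <- drinker & timing == "continued"
    tr3 <- tr2
    before <- drinker & (timing == "before_only" | before_if_during)
    tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      ethnicity = factor(eth, levels = names(m$ethnicity)),
      sex = factor(sex, levels = c("female", "male")),
      child_age = age,
      child_bmi = bmi,
      maternal_age = mage,
      maternal_smoking = smoke,
      weekly_drinks = weekly,
      pae_level = level,
      drank_before_pregnancy = before,
      drank_trimester1 = tr1,
      drank_trimester2 = tr2,
      drank_trimester3 = tr3
    )
  })
}

#' Ground-truth exposure effect specification
#'
#' Defines where and how exposure displaces the face in the generator:
#' per-region vertex masks on the template, a unit direction per masked
#' vertex, a dose slope in mm per consumption level, and a multiplier for
#' the attenuated effect at age 13. Default directions follow the
#' fetal-alcohol facial pattern: nose tip turned up-and-out, nose bridge
#' drawn inward (shortened nose), chin turned out, lower-eyelid region
#' turned in.
#'
#' @param template a [make_template()] mesh with region masks.
#' @param regions which named regions carry the effect; default `"nose_tip"`.
#' @param slope mm of displacement per exposure level.
#' @param attenuation_13y effect multiplier in `[0, 1]` at age 13.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(template, regions = "nose_tip", slope = 1.0,
                        attenuation_13y = 0.3) {
  masks <- attr(template, "region_masks")
  stopifnot(!is.null(masks), all(regions %in% names(masks)),
            attenuation_13y >= 0, attenuation_13y <= 1)
  nrm <- vertex_normals(template)
  unit_rows <- function(x) x / sqrt(rowSums(x^2))
  dir_for <- function(region) {
    idx <- masks[[region]]
    switch(region,
      nose_tip = unit_rows(nrm[idx, , drop = FALSE] +
                             matrix(c(0, 0.8, 0), length(idx), 3, byrow = TRUE)),
      nose_bridge = -nrm[idx, , drop = FALSE],
      chin = nrm[idx, , drop = FALSE],
      lower_eyelids = -nrm[idx, , drop = FALSE],
      forehead = nrm[idx, , drop = FALSE])
  }
  structure(list(region_masks = masks[regions],
                 direction_fields = setNames(lapply(regions, dir_for), regions),
                 slope = slope, attenuation_13y = attenuation_13y),
            class = "effect_spec")
}

# Laplacian-smoothed Gaussian random fields: white noise per vertex smoothed
# by repeated neighbour averaging, rescaled to unit RMS vertex displacement.
smooth_random_fields <- function(template, n_fields, smoothing_steps = 15) {
  V <- nrow(template$vertices)
  op <- build_graph_operator(template)
  deg <- pmax(op$degree, 1)
  S <- Matrix::Diagonal(V, 1 / (deg + 1)) %*%
    (op$adjacency + Matrix::Diagonal(V))
  lapply(seq_len(n_fields), function(k) {
    f <- matrix(rnorm(V * 3), V, 3)
    for (s in seq_len(smoothing_steps)) f <- as.matrix(S %*% f)
    f / sqrt(mean(rowSums(f^2)))
  })
}

#' Fixed shape population for the synthetic cohort
#'
#' Defines the population that cohorts are sampled from: smooth random
#' shape-mode fields with geometrically decaying scales, plus the fixed
#' covariate displacement fields (sex on the chin, BMI as a smooth fullness
#' field, age as radial growth). Cohorts drawn from the same population
#' share these fields and differ only in subjects (mode coefficients,
#' covariates, exposure, noise), so a model trained on one cohort transfers
#' to replicate cohorts. With `mode_model = "quadratic"` the population
#' lies on a curved manifold: faces are a quadratic function (linear plus
#' pairwise-product fields) of a low-dimensional latent vector, which a
#' linear shape model cannot span.
#'
#' @param template a [make_template()] mesh.
#' @param n_modes number of linear population modes.
#' @param mode_scale RMS mm of the largest population mode.
#' @param mode_model `"linear"` (default) or `"quadratic"`.
#' @param latent_dim latent dimension of the quadratic model.
#' @param seed integer seed fixing the population fields.
#' @return An object of class `shape_population`.
#' @export
make_population <- function(template, n_modes = 24, mode_scale = 2.0,
                            mode_model = c("linear", "quadratic"),
                            latent_dim = 8, seed = 1000L) {
  mode_model <- match.arg(mode_model)
  stopifnot(n_modes >= 1)
  V <- nrow(template$vertices)
  masks <- attr(template, "region_masks")
  with_seed(seed, {
    if (mode_model == "linear") {
      fields <- smooth_random_fields(template, n_modes)
      sds <- mode_scale * 0.9^(seq_len(n_modes) - 1)
      M <- vapply(seq_len(n_modes),
                  function(k) as.vector(fields[[k]]) * sds[k],
                  numeric(3 * V))                  # 3V x n_modes
      quad <- NULL
    } else {
      nq <- latent_dim * (latent_dim + 1) / 2
      lin <- smooth_random_fields(template, latent_dim)
      qua <- smooth_random_fields(template, nq)
      lin_sds <- mode_scale * 0.9^(seq_len(latent_dim) - 1)
      M <- vapply(seq_len(latent_dim),
                  function(k) as.vector(lin[[k]]) * lin_sds[k], numeric(3 * V))
      quad <- vapply(seq_len(nq), function(m) as.vector(qua[[m]]) * 0.7,
                     numeric(3 * V))
    }
    nrm <- vertex_normals(template)
    sex_field <- matrix(0, V, 3)
    sex_field[masks$chin, ] <- 0.8 * nrm[masks$chin, , drop = FALSE]
    bmi_field <- smooth_random_fields(template, 1)[[1]] * 0.12
    ctr <- geometric_center(template)
    radial <- sweep(template$vertices, 2, ctr)
    radial <- radial / sqrt(rowSums(radial^2))
    structure(list(template = template, mode_model = mode_model,
                   modes = M, quad_modes = quad, latent_dim = latent_dim,
                   sex_field = as.vector(sex_field),
                   bmi_field = as.vector(bmi_field),
                   age_field = as.vector(radial * 0.8),
                   seed = seed),
              class = "shape_population")
  })
}

#' @export
print.shape_population <- function(x, ...) {
  cat(sprintf("<shape_population: %s, %d mode field(s), V = %d>\n",
              x$mode_model, ncol(x$modes), nrow(x$template$vertices)))
  invisible(x)
}

#' Synthesise corresponded faces for a covariate table (age-9 wave)
#'
#' Each face is the template plus (i) the population's shape modes with
#' per-subject standard-normal coefficients, (ii) covariate displacements,
#' (iii) the injected exposure effect `slope * pae_level` along the effect
#' direction fields, and (iv) iid Gaussian vertex noise.
#'
#' @param population a [make_population()] object.
#' @param covariates a [sample_covariates()] tibble.
#' @param effect an [effect_spec()]; `NULL` injects no exposure effect.
#' @param noise_sd_mm iid vertex noise SD in mm.
#' @param seed integer seed for subject coefficients and noise.
#' @return An object of class `synthetic_cohort` with fields `faces_9y`
#'   (a [face_set()]), `covariates`, and `truth` (effect spec, coefficients,
#'   seeds).
#' @export
synthesize_faces <- function(population, covariates, effect = NULL,
                             noise_sd_mm = 0.25, seed = 1L) {
  stopifnot(inherits(population, "shape_population"), noise_sd_mm >= 0)
  template <- population$template
  V <- nrow(template$vertices)
  n <- nrow(covariates)
  with_seed(seed, {
    base <- as.vector(template$vertices)          # length 3V, column-major
    if (population$mode_model == "linear") {
      m <- ncol(population$modes)
      coef <- matrix(rnorm(n * m), n, m)
      X <- tcrossprod(coef, population$modes)      # n x 3V
      truth_modes <- list(coefficients = coef)
    } else {
      d <- population$latent_dim
      C <- matrix(rnorm(n * d), n, d)
      pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
      Qfeat <- vapply(seq_len(nrow(pairs)), function(m) {
        j <- pairs[m, 1]; k <- pairs[m, 2]
        if (j == k) (C[, j]^2 - 1) / sqrt(2) else C[, j] * C[, k]
      }, numeric(n))
      X <- tcrossprod(C, population$modes) +
        tcrossprod(Qfeat, population$quad_modes)
      truth_modes <- list(latent = C)
    }

    X <- X +
      outer(as.numeric(covariates$sex == "male"), population$sex_field) +
      outer(covariates$child_bmi - mean(covariates$child_bmi),
            population$bmi_field) +
      outer(covariates$child_age - mean(covariates$child_age),
            population$age_field)

    # injected exposure effect, linear in consumption level
    if (!is.null(effect)) {
      eff_vec <- numeric(3 * V)
      for (rg in names(effect$region_masks)) {
        idx <- effect$region_masks[[rg]]
        d <- effect$direction_fields[[rg]]
        for (c in 1:3) eff_vec[idx + (c - 1) * V] <- eff_vec[idx + (c - 1) * V] + d[, c]
      }
      X <- X + outer(covariates$pae_level * effect$slope, eff_vec)
    }

    if (noise_sd_mm > 0)
      X <- X + matrix(rnorm(n * 3 * V, sd = noise_sd_mm), n, 3 * V)

    coords <- array(t(X) + base, dim = c(V, 3, n))
    faces <- face_set(covariates$subject_id, coords, template)
    structure(list(faces_9y = faces, faces_13y = NULL,
                   covariates = covariates, paired_ids = NULL,
                   population = population,
                   truth = list(effect = effect, modes = truth_modes,
                                noise_sd_mm = noise_sd_mm, seed = seed,
                                mode_model = population$mode_model)),
              class = "synthetic_cohort")
  })
}

#' Add the age-13 wave to a synthetic cohort
#'
#' A reproducible subset of subjects is re-measured at 13: the 9-year face
#' plus a deterministic radial growth field, the exposure effect rescaled by
#' `attenuation_13y - 1` (so the residual effect is `attenuation_13y` times
#' the 9-year one), and fresh vertex noise. Every 13-year subject also
#' appears at 9 (longitudinal pairing).
#'
#' @param cohort a [synthesize_faces()] result.
#' @param growth_mm radial growth in mm between ages.
#' @param attenuation_13y effect multiplier in `[0, 1]` at 13.
#' @param seed integer seed.
#' @param pair_fraction fraction of subjects re-measured.
#' @return The cohort with `faces_13y`, `covariates_13y` and `paired_ids`
#'   filled in.
#' @export
synthesize_longitudinal <- function(cohort, growth_mm = 4,
                                    attenuation_13y = 0.3, seed = 2L,
                                    pair_fraction = 0.75) {
  stopifnot(attenuation_13y >= 0, attenuation_13y <= 1)
  faces <- cohort$faces_9y
  template <- faces$template
  V <- nrow(template$vertices)
  n <- length(faces$subject_ids)
  with_seed(seed, {
    keep <- sort(sample.int(n, round(pair_fraction * n)))
    ctr <- geometric_center(template)
    radial <- sweep(template$vertices, 2, ctr)
    radial <- radial / sqrt(rowSums(radial^2))
    growth <- radial * growth_mm
    coords <- faces$coords[, , keep, drop = FALSE]
    coords <- coords + array(growth, dim = c(V, 3, length(keep)))
    effect <- cohort$truth$effect
    if (!is.null(effect)) {
      eff <- matrix(0, V, 3)
      for (rg in names(effect$region_masks)) {
        idx <- effect$region_masks[[rg]]
        eff[idx, ] <- eff[idx, ] + effect$direction_fields[[rg]]
      }
      lv <- cohort$covariates$pae_level[keep]
      scale <- (attenuation_13y - 1) * effect$slope * lv
      coords <- coords + outer(eff, rep(1, length(keep))) *
        rep(scale, each = V * 3)
    }
    if (cohort$truth$noise_sd_mm > 0)
      coords <- coords + array(rnorm(length(coords), sd = cohort$truth$noise_sd_mm),
                               dim = dim(coords))
    ids <- faces$subject_ids[keep]
    cohort$faces_13y <- face_set(ids, coords, template)
    cohort$covariates_13y <- dplyr::mutate(
      cohort$covariates[keep, ],
      child_age = .data$child_age + 3.8,
      child_bmi = .data$child_bmi + 1.6)
    cohort$paired_ids <- ids
    cohort$truth$attenuation_13y <- attenuation_13y
    cohort$truth$growth_mm <- growth_mm
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects at 9y%s, V = %d>\n",
              length(x$faces_9y$subject_ids),
              if (!is.null(x$faces_13y))
                sprintf(", %d at 13y", length(x$faces_13y$subject_ids)) else "",
              dim(x$faces_9y$coords)[1]))
  invisible(x)
}

#' One-call synthetic study cohort
#'
#' Convenience wrapper: template, covariates, 9-year faces with the injected
#' effect, and the 13-year wave.
#'
#' @param n subjects at age 9.
#' @param n_vertices template size (ignored when `population` is given).
#' @param regions effect regions, see [effect_spec()].
#' @param slope effect slope, mm per level (0 disables the effect).
#' @param attenuation_13y,growth_mm see [synthesize_longitudinal()].
#' @param noise_sd_mm,n_modes see [synthesize_faces()] / [make_population()].
#' @param seed integer seed for the subjects; sub-seeds for covariates,
#'   faces and the 13-year wave are derived from it. The population fields
#'   are controlled separately by `pop_seed`, so different `seed`s give
#'   replicate cohorts from the same population.
#' @param pop_seed seed of the population fields.
#' @param marginals see [sample_covariates()].
#' @param population optional pre-built [make_population()] (saves
#'   rebuilding and fixes the shape basis across calls).
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(n, n_vertices = 1024, regions = "nose_tip",
                            slope = 1.0, attenuation_13y = 0.3,
                            growth_mm = 4, noise_sd_mm = 0.25, n_modes = 24,
                            seed = 1L, pop_seed = 1000L,
                            marginals = default_covariate_marginals(),
                            population = NULL) {
  if (is.null(population))
    population <- make_population(make_template(n_vertices), n_modes = n_modes,
                                  seed = pop_seed)
  template <- population$template
  cov <- sample_covariates(n, seed = seed, marginals = marginals)
  eff <- if (slope > 0) effect_spec(template, regions, slope, attenuation_13y)
         else NULL
  cohort <- synthesize_faces(population, cov, effect = eff,
                             noise_sd_mm = noise_sd_mm, seed = seed + 1L)
  synthesize_longitudinal(cohort, growth_mm = growth_mm,
                          attenuation_13y = attenuation_13y, seed = seed + 2L)
}

#' Write a synthetic cohort to disk
#'
#' One ASCII PLY per subject per age under `dir/cohort/<age>/`, the
#' covariate table as `covariates.csv`, and the ground truth (regions,
#' slope, seeds) as `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (age in c("9y", "13y")) {
    fs <- if (age == "9y") cohort$faces_9y else cohort$faces_13y
    if (is.null(fs)) next
    sub <- file.path(dir, "cohort", age)
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(fs$subject_ids))
      write_mesh(face_mesh(fs, i), file.path(sub, paste0(fs$subject_ids[i], ".ply")))
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(regions = names(truth$effect$region_masks),
         slope = truth$effect$slope,
         attenuation_13y = truth$attenuation_13y,
         noise_sd_mm = truth$noise_sd_mm, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}
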