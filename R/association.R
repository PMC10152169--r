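# Trait-wise association testing. Each latent trait is regressed on an
# exposure indicator plus covariates by ordinary least squares; the exposure
# betas are tested against the t distribution and corrected across the N
# traits of one analysis by the Benjamini-Hochberg step-up rule.

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with monotone enforcement and significance
#' flags at level `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level; default 0.05.
#' @return List with `adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= alpha)
}

# Build the adjustment design matrix from a covariate tibble. Reference
# categories: Dutch ethnicity, female sex, non-smoking.
covariate_design <- function(covariates,
                             vars = c("ethnicity", "sex", "child_age",
                                      "child_bmi", "maternal_age",
                                      "maternal_smoking")) {
  df <- as.data.frame(covariates[, intersect(vars, names(covariates))])
  if ("ethnicity" %in% names(df)) {
    df$ethnicity <- droplevels(factor(df$ethnicity))
    if ("Dutch" %in% levels(df$ethnicity))
      df$ethnicity <- stats::relevel(df$ethnicity, "Dutch")
    if (nlevels(df$ethnicity) < 2) df$ethnicity <- NULL
  }
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("maternal_smoking" %in% names(df))
    df$maternal_smoking <- as.numeric(df$maternal_smoking)
  model.matrix(~ ., data = df)[, -1, drop = FALSE]
}

#' Trait-wise OLS association with an exposure indicator
#'
#' Fits, for every trait column, the linear model
#' `trait ~ exposure + covariates` and returns the exposure term's
#' coefficient, standard error and two-sided t-test p-value, with
#' Benjamini-Hochberg adjustment across traits. Rows with missing values
#' are dropped listwise (with a message).
#'
#' @param Z `n x N` trait matrix.
#' @param exposure numeric or logical vector of length n (1/TRUE = exposed).
#' @param covariates tibble of adjustment covariates (ethnicity, sex, ages,
#'   BMI, maternal smoking); extra columns are ignored.
#' @param alpha FDR level.
#' @param term name of the predictor of interest in the output; cosmetic.
#' @return A tibble of class `trait_assoc`, one row per trait: `trait_index`
#'   (1-based), `beta`, `se`, `p_value`, `fdr_p`, `significant`,
#'   `trait_mean`, `trait_sd`, with `n_exposed`/`n_control` attributes.
#' @export
fit_trait_regressions <- function(Z, exposure, covariates, alpha = 0.05,
                                  term = "exposure") {
  Z <- as.matrix(Z)
  exposure <- as.numeric(exposure)
  stopifnot(length(exposure) == nrow(Z), nrow(covariates) == nrow(Z))
  vars <- intersect(c("ethnicity", "sex", "child_age", "child_bmi",
                      "maternal_age", "maternal_smoking"), names(covariates))
  keep <- complete.cases(Z) & is.finite(exposure) &
    complete.cases(as.data.frame(covariates[, vars]))
  if (!all(keep))
    message("dropping ", sum(!keep), " incomplete record(s) (listwise deletion)")
  Z <- Z[keep, , drop = FALSE]
  C <- covariate_design(covariates[keep, ])
  X <- cbind(`(Intercept)` = 1, exposure = exposure[keep], C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, Z)                      # p x N
  res <- Z - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  j <- match("exposure", colnames(X))
  beta <- coefs[j, ]
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- ifelse(se > 0, beta / se, 0)
  p <- 2 * pt(-abs(tval), df)
  fdr <- bh_fdr(p, alpha)
  out <- tibble::tibble(
    trait_index = seq_len(ncol(Z)),
    beta = unname(beta), se = unname(se), p_value = unname(p),
    fdr_p = fdr$adjusted, significant = fdr$significant,
    trait_mean = colMeans(Z), trait_sd = apply(Z, 2, sd))
  attr(out, "n_exposed") <- sum(exposure[keep] == 1)
  attr(out, "n_control") <- sum(exposure[keep] == 0)
  attr(out, "df") <- df
  attr(out, "term") <- term
  class(out) <- c("trait_assoc", class(out))
  out
}

#' Growth traits between the two study ages
#'
#' Elementwise per-subject trait difference, age 13 minus age 9, restricted
#' to subjects present at both ages. Traits must come from the same trained
#' model. Unpaired subjects are dropped with a message.
#'
#' @param Z9,Z13 trait matrices with subject ids as row names.
#' @param paired_ids optional id vector; defaults to the intersection.
#' @return Trait matrix of differences with paired ids as row names.
#' @export
growth_traits <- function(Z9, Z13, paired_ids = NULL) {
  if (is.null(rownames(Z9)) || is.null(rownames(Z13)))
    stop("trait matrices need subject ids as row names")
  common <- intersect(rownames(Z13), rownames(Z9))
  if (is.null(paired_ids)) paired_ids <- common
  miss <- setdiff(paired_ids, common)
  if (length(miss) > 0) {
    message("excluding ", length(miss), " unpaired subject(s)")
    paired_ids <- intersect(paired_ids, common)
  }
  Z13[paired_ids, , drop = FALSE] - Z9[paired_ids, , drop = FALSE]
}

#' Stratum specification for a stratified analysis
#'
#' @param tier exposure-timing tier: `"1"`, `"2a"` or `"2b"`.
#' @param level_band consumption levels defining the exposed group: a vector
#'   of levels (e.g. `c(2, 3)`) or the string `">1"`.
#' @param ethnicity `"multi-ethnic"`, `"western"` or `"dutch"`.
#' @param age_group `"9y"`, `"13y"` or `"growth"`.
#' @return A list of class `stratum_spec`.
#' @export
stratum_spec <- function(tier = "2b", level_band = ">0",
                         ethnicity = "multi-ethnic", age_group = "9y") {
  tier <- match.arg(as.character(tier), c("1", "2a", "2b"))
  ethnicity <- match.arg(ethnicity, c("multi-ethnic", "western", "dutch"))
  age_group <- match.arg(age_group, c("9y", "13y", "growth"))
  structure(list(tier = tier, level_band = level_band, ethnicity = ethnicity,
                 age_group = age_group),
            class = "stratum_spec")
}

level_in_band <- function(level, band) {
  if (is.character(band) && length(band) == 1L && grepl("^>", band)) {
    level > as.numeric(sub(">", "", band))
  } else {
    level %in% as.numeric(band)
  }
}

# exposed/control subject ids for a stratum
stratum_groups <- function(covariates, spec) {
  tiers <- assign_tiers(covariates)
  exposed_flag <- switch(spec$tier, "1" = tiers$tier1_exposed,
                         "2a" = tiers$tier2a_exposed,
                         "2b" = tiers$tier2b_exposed)
  eth <- switch(spec$ethnicity,
                "multi-ethnic" = rep(TRUE, nrow(covariates)),
                "western" = covariates$ethnicity %in% c("Dutch", "non-Dutch-Western"),
                "dutch" = covariates$ethnicity == "Dutch")
  exposed <- exposed_flag & eth & level_in_band(covariates$pae_level, spec$level_band)
  control <- tiers$control & eth
  list(exposed = covariates$subject_id[exposed],
       control = covariates$subject_id[control])
}

#' Stratified exposure association analysis
#'
#' Runs one stratum of the study design: selects the abstinent controls and
#' the exposed group defined by tier, consumption-level band and ethnicity
#' subset; computes traits for the requested age group (encoding faces with
#' the trained model, or trait growth for the longitudinal subset); fits the
#' trait-wise adjusted regressions; applies FDR across the traits; and
#' attaches each trait's effect size f(z).
#'
#' @param cohort a `synthetic_cohort` (or any list with `faces_9y`,
#'   `faces_13y`, `covariates`, `covariates_13y`).
#' @param model a trained face model.
#' @param spec a [stratum_spec()].
#' @param alpha FDR level.
#' @return A `trait_assoc` tibble with an added `f_z` column and the
#'   stratum stored in the `stratum` attribute.
#' @export
run_stratified_analysis <- function(cohort, model, spec = stratum_spec(),
                                    alpha = 0.05) {
  grp <- stratum_groups(cohort$covariates, spec)
  if (length(grp$exposed) == 0) stop("empty exposed group for this stratum")
  if (length(grp$control) == 0) stop("empty control group for this stratum")
  if (spec$age_group == "9y") {
    Z <- encode_faces(model, cohort$faces_9y)
    cov <- cohort$covariates
  } else {
    if (is.null(cohort$faces_13y)) stop("cohort has no 13-year wave")
    Z13 <- encode_faces(model, cohort$faces_13y)
    if (spec$age_group == "13y") {
      Z <- Z13; cov <- cohort$covariates_13y
    } else {
      Z9 <- encode_faces(model, cohort$faces_9y)
      Z <- growth_traits(Z9, Z13)
      cov <- cohort$covariates_13y[match(rownames(Z),
                                         cohort$covariates_13y$subject_id), ]
    }
  }
  ids <- intersect(c(grp$control, grp$exposed), rownames(Z))
  exposed <- ids %in% grp$exposed
  if (sum(exposed) == 0 || sum(!exposed) == 0)
    stop("stratum has an empty group after age-group selection")
  Zs <- Z[ids, , drop = FALSE]
  covs <- cov[match(ids, cov$subject_id), ]
  out <- fit_trait_regressions(Zs, exposed, covs, alpha = alpha)
  sds <- apply(Zs, 2, sd)
  out$f_z <- effect_sizes_all(model, sds)
  attr(out, "stratum") <- spec
  out
}

#' Sex-difference sanity analysis
#'
#' Runs the same trait-wise machinery with sex as the predictor of interest
#' (male vs female) and the remaining covariates adjusted, as a positive
#' control: the combined heatmap of significant traits should reproduce
#' known sex differences in facial shape.
#'
#' @param cohort a `synthetic_cohort`.
#' @param model a trained face model.
#' @param age_group `"9y"` or `"13y"`.
#' @param alpha FDR level.
#' @return A `trait_assoc` tibble with `f_z`.
#' @export
sex_phenotype_check <- function(cohort, model, age_group = "9y",
                                alpha = 0.05) {
  faces <- if (age_group == "9y") cohort$faces_9y else cohort$faces_13y
  cov <- if (age_group == "9y") cohort$covariates else cohort$covariates_13y
  Z <- encode_faces(model, faces)
  cov <- cov[match(rownames(Z), cov$subject_id), ]
  male <- cov$sex == "male"
  out <- fit_trait_regressions(
    Z, male, cov[, c("ethnicity", "child_age", "child_bmi", "maternal_age",
                     "maternal_smoking")],
    alpha = alpha, term = "sex")
  out$f_z <- effect_sizes_all(model, apply(Z, 2, sd))
  attr(out, "stratum") <- list(predictor = "sex", age_group = age_group)
  out
}

#' Write an association table as TSV
#'
#' Columns mirror the study's reporting format (index, p, FDR p,
#' coefficient, SE, mean, SD, f(z)) plus stratum metadata rows as comments.
#'
#' @param assoc a `trait_assoc` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  spec <- attr(assoc, "stratum")
  hdr <- c(sprintf("# n_exposed=%s n_control=%s",
                   attr(assoc, "n_exposed"), attr(assoc, "n_control")),
           if (!is.null(spec))
             paste0("# stratum: ", paste(names(spec), unlist(spec),
                                         sep = "=", collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(assoc), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
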