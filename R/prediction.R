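# Exposure recognition: logistic regression of exposed vs control from
# covariates alone (Model A) and covariates plus all latent traits
# (Model B), scored by stratified 5-fold cross-validated AUC, with per-trait
# odds ratios and per-variable one-way ANOVA F-tests.

#' Maximum-likelihood logistic regression
#'
#' Unpenalised fit via [stats::glm()]. Complete or quasi-complete
#' separation (non-convergence with diverging coefficients) is detected and
#' raised as an error advising the ridge fallback, which refits with a
#' small L2 penalty by iteratively reweighted least squares.
#'
#' @param features data frame of predictors.
#' @param label binary outcome (0/1 or logical).
#' @param ridge use the ridge fallback? Default `FALSE`.
#' @param lambda ridge penalty when `ridge = TRUE`.
#' @return The fitted model (class `glm`, or `ridge_logistic`).
#' @export
fit_logistic <- function(features, label, ridge = FALSE, lambda = 1e-3) {
  df <- as.data.frame(features)
  y <- as.numeric(label)
  stopifnot(all(y %in% c(0, 1)))
  if (ridge) return(ridge_logistic(df, y, lambda))
  fml <- if (ncol(df) == 0) y ~ 1 else y ~ .
  fit <- suppressWarnings(glm(fml, data = cbind(data.frame(y = y), df),
                              family = binomial()))
  eta <- fit$linear.predictors
  if (!fit$converged || max(abs(eta)) > 25)
    stop("separation detected (diverging coefficients); ",
         "refit with ridge = TRUE")
  fit
}

# small-penalty logistic fit by IRLS; predicts like glm via predict()
ridge_logistic <- function(df, y, lambda) {
  X <- model.matrix(~ ., df)
  beta <- numeric(ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 terms = colnames(X)),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newdata, type = "response", ...) {
  X <- model.matrix(~ ., as.data.frame(newdata))
  eta <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients)
  if (type == "response") 1 / (1 + exp(-eta)) else eta
}

# AUC by the Mann-Whitney identity with midpoint (average-rank) tie handling
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment, reproducible
stratified_folds <- function(label, k, seed) {
  label <- as.logical(label)
  fold <- integer(length(label))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(label == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated AUC of a logistic model
#'
#' Stratified k-fold split; a model is fitted on each training fold and its
#' out-of-fold predicted probabilities are scored by the Mann-Whitney AUC.
#'
#' @param features data frame of predictors.
#' @param label binary outcome.
#' @param k number of folds; default 5.
#' @param seed integer seed for the fold split.
#' @param ridge passed to [fit_logistic()].
#' @return List with `mean_auc` and per-fold `fold_auc`.
#' @export
cv_auc <- function(features, label, k = 5L, seed = 1L, ridge = FALSE) {
  df <- as.data.frame(features)
  y <- as.numeric(label)
  fold <- stratified_folds(y, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2)
      stop("a class is absent from fold ", f)
    fit <- tryCatch(
      fit_logistic(df[tr, , drop = FALSE], y[tr], ridge = ridge),
      error = function(e) {
        if (!grepl("separation", conditionMessage(e))) stop(e)
        message("fold ", f, ": separation detected; using ridge fallback")
        fit_logistic(df[tr, , drop = FALSE], y[tr], ridge = TRUE)
      })
    p <- predict(fit, df[!tr, , drop = FALSE], type = "response")
    auc_mw(p, y[!tr])
  }, numeric(1))
  list(mean_auc = mean(aucs), fold_auc = aucs)
}

# one-way ANOVA F-test of each feature across the two label groups
anova_f_tests <- function(features, label) {
  df <- as.data.frame(features)
  y <- factor(label)
  purrr::map_dfr(names(df), function(v) {
    x <- df[[v]]
    if (is.factor(x) || is.character(x) || is.logical(x))
      x <- as.numeric(factor(x))
    a <- anova(lm(x ~ y))
    tibble::tibble(variable = v, f_statistic = a$`F value`[1],
                   p_value = a$`Pr(>F)`[1])
  })
}

#' Compare covariate-only and covariate-plus-trait exposure models
#'
#' Model A uses maternal age, maternal smoking, child BMI, child age and
#' sex; Model B adds all latent traits. Both are scored with the same
#' stratified folds; per-trait odds ratios (with Wald p-values) come from
#' the full-data Model B fit, and one-way ANOVA F-tests are reported per
#' independent variable for both models.
#'
#' @param covariates covariate tibble (rows aligned with `traits`).
#' @param traits `n x N` trait matrix.
#' @param label binary exposure outcome.
#' @param k folds; default 5.
#' @param seed fold seed.
#' @param ridge use the ridge fallback in all fits.
#' @return An object of class `prediction_report`: AUCs, fold AUCs, odds
#'   ratios, F-tests and group sizes.
#' @export
compare_models <- function(covariates, traits, label, k = 5L, seed = 1L,
                           ridge = FALSE) {
  stopifnot(nrow(covariates) == nrow(traits),
            nrow(traits) == length(label))
  y <- as.numeric(label)
  feats_a <- data.frame(
    maternal_age = covariates$maternal_age,
    maternal_smoking = as.numeric(covariates$maternal_smoking),
    child_bmi = covariates$child_bmi,
    child_age = covariates$child_age,
    sex = factor(covariates$sex, levels = c("female", "male")))
  traits <- as.matrix(traits)
  colnames(traits) <- sprintf("trait_%03d", seq_len(ncol(traits)) - 1L)
  feats_b <- cbind(feats_a, as.data.frame(traits))
  cv_a <- cv_auc(feats_a, y, k = k, seed = seed, ridge = ridge)
  cv_b <- cv_auc(feats_b, y, k = k, seed = seed, ridge = ridge)
  full_b <- tryCatch(fit_logistic(feats_b, y, ridge = ridge),
                     error = function(e) {
                       if (!grepl("separation", conditionMessage(e))) stop(e)
                       message("full Model B: separation detected; ridge fallback")
                       fit_logistic(feats_b, y, ridge = TRUE)
                     })
  cf <- if (inherits(full_b, "glm")) summary(full_b)$coefficients else
    cbind(Estimate = full_b$coefficients, `Pr(>|z|)` = NA_real_)
  tr_rows <- grepl("^trait_", rownames(cf))
  or_tbl <- tibble::tibble(
    trait = rownames(cf)[tr_rows],
    odds_ratio = exp(cf[tr_rows, "Estimate"]),
    p_value = if ("Pr(>|z|)" %in% colnames(cf)) cf[tr_rows, "Pr(>|z|)"]
              else NA_real_)
  structure(list(
    auc_model_a = cv_a$mean_auc, auc_model_b = cv_b$mean_auc,
    fold_auc_a = cv_a$fold_auc, fold_auc_b = cv_b$fold_auc,
    odds_ratios = or_tbl,
    f_tests_a = anova_f_tests(feats_a, y),
    f_tests_b = anova_f_tests(feats_b, y),
    n_exposed = sum(y == 1), n_control = sum(y == 0)),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report: AUC A = %.3f, AUC B = %.3f (Ne = %d, Nc = %d)>\n",
    x$auc_model_a, x$auc_model_b, x$n_exposed, x$n_control))
  invisible(x)
}

#' Write a prediction report as JSON and TSV
#'
#' @param report a [compare_models()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_prediction_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(auc_model_a = report$auc_model_a, auc_model_b = report$auc_model_b,
         fold_auc_a = report$fold_auc_a, fold_auc_b = report$fold_auc_b,
         n_exposed = report$n_exposed, n_control = report$n_control),
    file.path(dir, "prediction.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$odds_ratios, file.path(dir, "odds_ratios.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(rbind(cbind(model = "A", report$f_tests_a),
                           cbind(model = "B", report$f_tests_b)),
                     file.path(dir, "f_tests.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
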