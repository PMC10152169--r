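# broom-style accessors and default plots for fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trait association table
#'
#' The table is already tidy (one row per trait); this returns it as a
#' plain tibble with the stratum metadata attached as columns.
#'
#' @param x a `trait_assoc` result.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.trait_assoc <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  spec <- attr(x, "stratum")
  if (!is.null(spec))
    for (nm in names(spec))
      out[[paste0("stratum_", nm)]] <- as.character(spec[[nm]])
  out
}

#' One-row summary of a trait association analysis
#'
#' @param x a `trait_assoc` result.
#' @param ... unused.
#' @return A tibble with trait counts, group sizes and the smallest
#'   adjusted p-value.
#' @export
glance.trait_assoc <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x),
    n_significant = sum(x$significant),
    n_nominal = sum(x$p_value < 0.05),
    min_fdr_p = min(x$fdr_p),
    n_exposed = attr(x, "n_exposed"),
    n_control = attr(x, "n_control"))
}

#' Tidy a prediction report
#'
#' @param x a `prediction_report`.
#' @param ... unused.
#' @return A tibble of per-trait odds ratios with p-values.
#' @export
tidy.prediction_report <- function(x, ...) x$odds_ratios

#' One-row summary of a prediction report
#'
#' @param x a `prediction_report`.
#' @param ... unused.
#' @return A tibble with both cross-validated AUCs and group sizes.
#' @export
glance.prediction_report <- function(x, ...) {
  tibble::tibble(auc_model_a = x$auc_model_a, auc_model_b = x$auc_model_b,
                 n_exposed = x$n_exposed, n_control = x$n_control)
}

#' Manhattan-style plot of trait associations
#'
#' @param object a `trait_assoc` result.
#' @param ... unused.
#' @return A ggplot object: -log10 p per trait, FDR-significant traits
#'   highlighted.
#' @export
autoplot.trait_assoc <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait_index,
                                   y = -log10(.data$p_value),
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "trait index", y = expression(-log[10](p)),
                  color = "FDR-significant") +
    ggplot2::theme_minimal()
}

#' Per-fold AUC plot for the two prediction models
#'
#' @param object a `prediction_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_report <- function(object, ...) {
  df <- tibble::tibble(
    model = rep(c("A: covariates", "B: covariates + traits"),
                times = c(length(object$fold_auc_a), length(object$fold_auc_b))),
    fold = c(seq_along(object$fold_auc_a), seq_along(object$fold_auc_b)),
    auc = c(object$fold_auc_a, object$fold_auc_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$fold))) +
    ggplot2::labs(y = "fold AUC", x = NULL, color = "fold") +
    ggplot2::theme_minimal()
}

#' Training-loss plot for a face model
#'
#' @param object a `face_model`.
#' @param ... unused.
#' @return A ggplot object of train/validation MAE per epoch.
#' @export
autoplot.face_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_mae", "val_mae"),
                            names_to = "set", values_to = "mae")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mae,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean absolute error (normalised)") +
    ggplot2::theme_minimal()
}
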