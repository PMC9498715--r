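#' Plot per-repeat cross-validation accuracy for one model
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot: per-fold r-squared points by repeat with the
#'   per-repeat mean overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.holo_cv <- function(object, ...) {
  pf <- object$per_fold
  pr <- object$per_repeat
  ggplot2::ggplot(pf, ggplot2::aes(x = factor(.data$repeat_index),
                                   y = .data$r2)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = pr, colour = "firebrick", size = 2.5) +
    ggplot2::labs(x = "CV repeat", y = expression(r^2),
                  title = sprintf("Model '%s': mean r² = %.3f",
                                  object$label, object$mean_r2)) +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of model accuracies
#'
#' Mean cross-validated r-squared per model with error bars (SD over
#' repeats by default, standard error with `se = TRUE`), the usual way
#' prediction accuracies of competing holo-omic models are displayed.
#'
#' @param results List of [cross_validate()] results.
#' @param se Use the standard error of the per-repeat values instead of
#'   their SD.
#' @return A ggplot.
#' @export
plot_model_comparison <- function(results, se = FALSE) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "holo_cv")))
  df <- purrr::map_dfr(results, glance)
  df$err <- if (se) df$se_r2 else df$sd_r2
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean_r2,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r2 - .data$err,
                                        ymax = .data$mean_r2 + .data$err),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(paste("prediction accuracy ", r^2))) +
    ggplot2::theme_minimal()
}
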