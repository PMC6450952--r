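#' Forest plot of per-organ enrichment odds ratios
#'
#' Odds ratios with Woolf 95% intervals on a log scale, one row per organ
#' system, with the no-effect line at 1.
#'
#' @param object An `enrichment_tbl` (per-SOC or pooled).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$soc <- factor(df$soc, levels = rev(unique(df$soc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$soc)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (side effect | genetic support)", y = NULL,
      title = "Side-effect enrichment by organ system"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a permutation null with the observed statistic
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "Null statistic", y = "Permutations",
      title = sprintf(
        "Permutation null (%s): observed = %.3f, empirical P = %.3g",
        object$mode, object$observed, object$empirical_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of pooled out-of-fold predictions
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  p <- object$predictions[order(-object$predictions$score), ]
  df <- tibble(
    fpr = c(0, cumsum(p$label == 0) / sum(p$label == 0)),
    tpr = c(0, cumsum(p$label == 1) / sum(p$label == 1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf(
        "Leave-one-target-set-out ROC (%s, %s): AUC = %.3f",
        object$soc, object$variant, object$auc
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
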