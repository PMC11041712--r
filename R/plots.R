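#' Plot phenotype calls against the classification threshold
#'
#' Novel-object exploration time per subject versus its subject-specific
#' threshold (familiar mean + k SD); points above the identity line are
#' Unimpaired.
#'
#' @param calls Phenotype-call tibble from [classify_subjects()].
#' @return A ggplot object.
#' @export
plot_phenotypes <- function(calls) {
  ggplot2::ggplot(
    calls,
    ggplot2::aes(.data$threshold, .data$new_time, colour = .data$label)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "familiar mean + k · SD (s)",
      y = "novel-object exploration (s)",
      colour = NULL,
      title = "Novel-object recognition criterion"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-miRNA expression calls
#'
#' Replicate-mean log2 fold change per miRNA, ordered by fold change and
#' coloured by category, with the +/- calling threshold marked.
#'
#' @param calls Call tibble from [array_pipeline()] / [call_expression()].
#' @param call_thresh Threshold drawn as guide lines (default 0.7).
#' @return A ggplot object.
#' @export
plot_expression_calls <- function(calls, call_thresh = 0.7) {
  calls |>
    arrange(.data$mean_log2_fc) |>
    mutate(idx = row_number()) |>
    ggplot2::ggplot(
      ggplot2::aes(.data$idx, .data$mean_log2_fc, colour = .data$category)
    ) +
    ggplot2::geom_hline(
      yintercept = c(-call_thresh, call_thresh),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "miRNA (ranked)",
      y = expression(log[2] ~ "fold change (IM / UM)"),
      colour = NULL,
      title = "Microarray expression calls"
    ) +
    ggplot2::theme_minimal()
}

#' Plot qPCR fold changes with asymmetric error bars
#'
#' @param estimates Fold-change tibble from [fold_changes()].
#' @return A ggplot object (bars per assay x pool, error bars
#'   `fold_change - lower_error` to `fold_change + upper_error`).
#' @export
plot_fold_changes <- function(estimates) {
  ggplot2::ggplot(
    estimates,
    ggplot2::aes(.data$assay, .data$fold_change, fill = .data$sample_id)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$fold_change - .data$lower_error,
        ymax = .data$fold_change + .data$upper_error
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = NULL,
      y = expression(2^{
        -Delta * Delta * Ct
      }),
      fill = "pool",
      title = "Relative quantification by qPCR"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Autoplot a cross-platform correlation
#'
#' Scatter of qPCR versus microarray log2 fold changes with the least-squares
#' line and the Pearson r in the subtitle.
#'
#' @param object A `platform_cor` object from [platform_pearson()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.platform_cor <- function(object, ...) {
  ggplot2::ggplot(
    object$pairs,
    ggplot2::aes(.data$log2fc_array, .data$log2fc_qpcr)
  ) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression("microarray" ~ log[2] ~ "FC"),
      y = expression("qPCR" ~ log[2] ~ "FC"),
      title = "Cross-platform agreement",
      subtitle = sprintf("Pearson r = %.2f, p = %.4f, n = %d", object$r, object$p, object$n)
    ) +
    ggplot2::theme_minimal()
}
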