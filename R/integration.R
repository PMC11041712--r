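#' Pair microarray and qPCR log2 fold changes per miRNA
#'
#' Joins the per-miRNA array calls to the qPCR estimates by miRNA name and
#' keeps one complete pair per miRNA. miRNAs missing a value on either
#' platform are dropped with a warning, never imputed.
#'
#' @param array_calls Per-miRNA tibble with `mirna` and `mean_log2_fc`
#'   (e.g. from [array_pipeline()]).
#' @param qpcr_estimates Fold-change tibble from [fold_changes()] (the
#'   calibrator's own rows, fold change 1, are ignored); alternatively any
#'   tibble with `assay`/`mirna` and `log2_fc` columns.
#'
#' @return A tibble with columns `mirna`, `log2fc_array`, `log2fc_qpcr`.
#' @export
platform_pairs <- function(array_calls, qpcr_estimates) {
  if ("assay" %in% names(qpcr_estimates) && !"mirna" %in% names(qpcr_estimates)) {
    qpcr_estimates <- rename(qpcr_estimates, mirna = "assay")
  }
  if ("calibrator_id" %in% names(qpcr_estimates)) {
    qpcr_estimates <- filter(
      qpcr_estimates,
      .data$sample_id != .data$calibrator_id
    )
  }
  q <- qpcr_estimates |>
    select("mirna", log2fc_qpcr = "log2_fc")
  a <- array_calls |>
    select("mirna", log2fc_array = "mean_log2_fc")
  pairs <- inner_join(a, q, by = "mirna") |>
    filter(is.finite(.data$log2fc_array), is.finite(.data$log2fc_qpcr))
  n_dropped <- length(union(a$mirna, q$mirna)) - nrow(pairs)
  if (n_dropped > 0) {
    warn(paste0(
      "platform_pairs: dropped ", n_dropped,
      " miRNA(s) missing a value on one platform"
    ))
  }
  pairs
}

#' Pearson agreement between platforms
#'
#' Pearson correlation of the paired log2 fold changes, with the two-sided
#' p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param pairs Paired tibble from [platform_pairs()] (columns
#'   `log2fc_array`, `log2fc_qpcr`).
#'
#' @return An object of class `platform_cor`; `tidy()`/`glance()` give a
#'   one-row tibble with `r`, `p`, `n`, `df`.
#' @export
platform_pearson <- function(pairs) {
  x <- pairs$log2fc_array
  y <- pairs$log2fc_qpcr
  if (length(x) < 3) abort("need at least 3 paired miRNAs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance on one platform: correlation undefined")
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(
      r = unname(fit$estimate),
      p = fit$p.value,
      n = length(x),
      df = unname(fit$parameter),
      pairs = pairs
    ),
    class = "platform_cor"
  )
}

#' @export
print.platform_cor <- function(x, ...) {
  cat(sprintf(
    "Pearson cross-platform agreement: r = %.2f, p = %.4f (n = %d)\n",
    x$r, x$p, x$n
  ))
  invisible(x)
}

#' @rdname platform_pearson
#' @param x A `platform_cor` object.
#' @param ... Unused.
#' @export
tidy.platform_cor <- function(x, ...) {
  tibble(r = x$r, p = x$p, n = x$n, df = x$df)
}

#' @rdname platform_pearson
#' @export
glance.platform_cor <- function(x, ...) tidy(x)

#' Select candidate miRNAs above a fold-change threshold
#'
#' Retains miRNAs whose replicate-mean log2 fold change strictly exceeds
#' `threshold` and ranks them in descending order of fold change; ties are
#' broken lexicographically by miRNA name so the output is deterministic.
#'
#' @param calls Per-miRNA tibble with `mirna` and `mean_log2_fc`.
#' @param threshold Lower bound on `mean_log2_fc` (default +0.5).
#'
#' @return The retained subset with a `rank` column (1 = largest fold
#'   change), sorted by rank.
#' @export
select_candidates <- function(calls, threshold = 0.5) {
  calls |>
    filter(.data$mean_log2_fc > threshold) |>
    arrange(desc(.data$mean_log2_fc), .data$mirna) |>
    mutate(rank = row_number())
}
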