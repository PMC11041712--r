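#' Per-sample delta-Ct against an internal reference assay
#'
#' For every sample x assay cell, averages the technical-replicate Ct values
#' and subtracts the same sample's reference-assay mean Ct
#' (`dct_mean = mean(Ct_target) - mean(Ct_reference)`). The replicate SDs are
#' propagated in quadrature: `dct_sd = sqrt(sd_target^2 + sd_ref^2)`.
#'
#' @param ct_data Long Ct tibble with columns `sample_id`, `assay`,
#'   `replicate`, `ct` (cycles), as read by [read_ct_table()] or generated by
#'   [simulate_qpcr()].
#' @param reference_assay Name of the internal-reference assay
#'   (default `"U6"`, the usual small-nuclear-RNA control).
#'
#' @return A tibble with one row per sample x non-reference assay:
#'   `sample_id`, `assay`, `dct_mean`, `dct_sd`, `n_replicates`.
#' @export
delta_ct <- function(ct_data, reference_assay = "U6") {
  needed <- c("sample_id", "assay", "ct")
  missing <- setdiff(needed, names(ct_data))
  if (length(missing) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(ct_data$ct))) abort("all Ct values must be finite")
  if (!reference_assay %in% ct_data$assay) {
    abort(paste0("reference assay `", reference_assay, "` not present"))
  }
  per_cell <- ct_data |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(
      ct_mean = mean(.data$ct),
      ct_sd = if (n() > 1) sd(.data$ct) else 0,
      n_replicates = n(),
      .groups = "drop"
    )
  ref <- per_cell |>
    filter(.data$assay == reference_assay) |>
    select("sample_id", ref_mean = "ct_mean", ref_sd = "ct_sd")
  targets <- filter(per_cell, .data$assay != reference_assay)
  no_ref <- setdiff(targets$sample_id, ref$sample_id)
  if (length(no_ref) > 0) {
    abort(paste0(
      "sample(s) without reference-assay replicates: ",
      paste(no_ref, collapse = ", ")
    ))
  }
  targets |>
    inner_join(ref, by = "sample_id") |>
    mutate(
      dct_mean = .data$ct_mean - .data$ref_mean,
      dct_sd = sqrt(.data$ct_sd^2 + .data$ref_sd^2)
    ) |>
    select("sample_id", "assay", "dct_mean", "dct_sd", "n_replicates")
}

#' Relative quantification by the 2^-ddCt method
#'
#' Expresses each sample's delta-Ct relative to a calibrator sample:
#' `ddct = dct_mean - dct_mean(calibrator)` within each assay, fold change
#' `2^-ddct`. Error bars propagate the delta-Ct SD through the exponential
#' asymmetrically: `upper = 2^-(ddct - sd) - fc`, `lower = fc - 2^-(ddct + sd)`,
#' so the upper bar always meets or exceeds the lower one. The calibrator
#' sample's own fold change is exactly 1 for every assay.
#'
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @param calibrator Sample id used as the calibrator (default `"UM"`,
#'   the Unimpaired pool).
#'
#' @return A tibble with one row per assay x sample: `assay`, `sample_id`,
#'   `calibrator_id`, `ddct`, `fold_change`, `upper_error`, `lower_error`,
#'   `sd_dct`, `log2_fc` (= `-ddct`).
#' @export
fold_changes <- function(dct, calibrator = "UM") {
  if (!calibrator %in% dct$sample_id) {
    abort(paste0("calibrator sample `", calibrator, "` not present"))
  }
  cal <- dct |>
    filter(.data$sample_id == calibrator) |>
    select("assay", cal_dct = "dct_mean")
  no_cal <- setdiff(dct$assay, cal$assay)
  if (length(no_cal) > 0) {
    abort(paste0(
      "assay(s) without calibrator measurements: ",
      paste(no_cal, collapse = ", ")
    ))
  }
  dct |>
    inner_join(cal, by = "assay") |>
    mutate(
      ddct = .data$dct_mean - .data$cal_dct,
      fold_change = 2^(-.data$ddct),
      upper_error = 2^(-(.data$ddct - .data$dct_sd)) - .data$fold_change,
      lower_error = .data$fold_change - 2^(-(.data$ddct + .data$dct_sd)),
      calibrator_id = calibrator,
      sd_dct = .data$dct_sd,
      log2_fc = -.data$ddct
    ) |>
    select(
      "assay", "sample_id", "calibrator_id", "ddct", "fold_change",
      "upper_error", "lower_error", "sd_dct", "log2_fc"
    ) |>
    arrange(.data$assay, .data$sample_id != calibrator, .data$sample_id)
}

#' Log2 of a 2^-ddCt fold change
#'
#' @param fold_change Positive fold-change value(s).
#' @return `log2(fold_change)`; exactly `-ddct` for estimates produced by
#'   [fold_changes()].
#' @export
log2_fold_change <- function(fold_change) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0)) {
    abort("fold changes must be positive and finite")
  }
  log2(fold_change)
}

#' Warn about wide technical-replicate spreads
#'
#' Optional Ct-table validator: flags sample x assay cells whose replicate
#' range exceeds `max_range` cycles, a common symptom of pipetting error.
#' Nothing is removed.
#'
#' @inheritParams delta_ct
#' @param max_range Largest acceptable within-cell Ct range (default 1 cycle).
#' @return `ct_data`, invisibly; warns when wide cells exist.
#' @export
validate_ct_replicates <- function(ct_data, max_range = 1) {
  wide <- ct_data |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(range = diff(range(.data$ct)), .groups = "drop") |>
    filter(.data$range > max_range)
  if (nrow(wide) > 0) {
    warn(paste0(
      "Ct replicate range exceeds ", max_range, " cycle(s) for ",
      nrow(wide), " sample x assay cell(s)"
    ))
  }
  invisible(ct_data)
}
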