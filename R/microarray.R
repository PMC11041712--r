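#' Remove flagged array spots
#'
#' Keeps only spots whose scanner quality flag is `"ok"`, dropping marginal
#' and absent spots. The number removed is reported via a message.
#'
#' @param probes A probe-level tibble with at least a `flag` column
#'   (`"ok"`, `"marginal"` or `"absent"`), as returned by
#'   [read_probe_table()] or [simulate_array()].
#'
#' @return The subset of `probes` with `flag == "ok"`.
#' @export
filter_flags <- function(probes) {
  bad <- setdiff(unique(probes$flag), c("ok", "marginal", "absent"))
  if (length(bad) > 0) {
    abort(paste0("unknown flag value(s): ", paste(bad, collapse = ", ")))
  }
  kept <- filter(probes, .data$flag == "ok")
  n_removed <- nrow(probes) - nrow(kept)
  if (n_removed > 0) {
    inform(paste0("filter_flags: removed ", n_removed, " flagged spot(s)"))
  }
  if (nrow(kept) == 0) warn("filter_flags: no spots survived flag filtering")
  kept
}

#' Normalize two-channel log2 ratios against endogenous controls
#'
#' For each slide, forms per-probe raw log2 ratios `log2(hy3 / hy5)`
#' (Impaired pool over Unimpaired pool under the default channel assignment)
#' and centres them by subtracting the median raw ratio of the slide's
#' endogenous-control probes. The mean log intensity
#' `(log2 hy3 + log2 hy5) / 2` is carried for intensity filtering. Probes
#' with a non-positive intensity in either channel are dropped with a
#' warning. Control probes stay in the output, marked, so the centring is
#' auditable, but downstream calling excludes them.
#'
#' @param probes Probe tibble with columns `mirna`, `hy3`, `hy5`,
#'   `is_control`, `slide_id`.
#' @param method `"controls"` (median over control probes per slide;
#'   falls back to the slide's global median with a message when a slide has
#'   no usable control) or `"global"` (always the slide's global median).
#' @param normalize Set `FALSE` to skip centring and return raw log2 ratios.
#'
#' @return A tibble with columns `mirna`, `slide_id`, `log2_ratio`,
#'   `mean_log_intensity`, `is_control`. Positive `log2_ratio` means higher
#'   in the Impaired pool.
#' @export
normalize_slides <- function(probes, method = c("controls", "global"),
                             normalize = TRUE) {
  method <- match.arg(method)
  needed <- c("mirna", "hy3", "hy5", "is_control", "slide_id")
  missing <- setdiff(needed, names(probes))
  if (length(missing) > 0) {
    abort(paste0("probe table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  n_bad <- sum(probes$hy3 <= 0 | probes$hy5 <= 0)
  if (n_bad > 0) {
    warn(paste0(
      "normalize_slides: dropped ", n_bad,
      " probe(s) with non-positive intensity before log transform"
    ))
    probes <- filter(probes, .data$hy3 > 0, .data$hy5 > 0)
  }
  ratios <- probes |>
    mutate(
      raw = log2(.data$hy3 / .data$hy5),
      mean_log_intensity = (log2(.data$hy3) + log2(.data$hy5)) / 2
    )
  if (!normalize) {
    return(ratios |>
      select(
        "mirna", "slide_id",
        log2_ratio = "raw", "mean_log_intensity", "is_control"
      ))
  }
  ratios |>
    group_by(.data$slide_id) |>
    mutate(log2_ratio = .data$raw - slide_center(
      .data$raw, .data$is_control, .data$slide_id[1], method
    )) |>
    ungroup() |>
    select("mirna", "slide_id", "log2_ratio", "mean_log_intensity", "is_control")
}

slide_center <- function(raw, is_control, slide_id, method) {
  if (method == "controls") {
    if (any(is_control)) {
      return(median(raw[is_control]))
    }
    inform(paste0(
      "normalize_slides: slide ", slide_id,
      " has no control probes; falling back to the global median"
    ))
  }
  median(raw)
}

#' Intensity-window filter
#'
#' Retains probes whose mean log intensity lies strictly inside
#' `(lo, hi)`, excluding spots near the noise floor or the scanner's
#' saturation ceiling.
#'
#' @param ratios Normalized-ratio tibble from [normalize_slides()].
#' @param lo,hi Open-interval bounds on the log2 mean intensity
#'   (defaults 8 and 14).
#'
#' @return The subset of `ratios` with `lo < mean_log_intensity < hi`.
#' @export
intensity_filter <- function(ratios, lo = 8, hi = 14) {
  if (lo >= hi) abort("`lo` must be strictly below `hi`")
  filter(ratios, .data$mean_log_intensity > lo, .data$mean_log_intensity < hi)
}

#' Average technical-replicate log2 ratios per miRNA
#'
#' Collapses replicate slides to one row per miRNA: arithmetic mean and
#' sample SD (denominator n-1; 0 for a single replicate) of the normalized
#' log2 ratios, with the replicate count. Control probes are excluded.
#'
#' @param ratios Normalized-ratio tibble ([normalize_slides()], optionally
#'   filtered by [intensity_filter()]).
#'
#' @return A tibble with columns `mirna`, `mean_log2_fc`, `sd_log2_fc`,
#'   `n_replicates`.
#' @export
average_replicates <- function(ratios) {
  ratios |>
    filter(!.data$is_control) |>
    group_by(.data$mirna) |>
    summarise(
      mean_log2_fc = mean(.data$log2_ratio),
      sd_log2_fc = if (n() > 1) sd(.data$log2_ratio) else 0,
      n_replicates = n(),
      .groups = "drop"
    ) |>
    arrange(.data$mirna)
}

#' Fold-change / SD retention rule
#'
#' Flags (or subsets to) miRNAs considered by the retention rule: absolute
#' mean log2 fold change strictly above `fc_thresh` and replicate SD on the
#' side of `sd_thresh` given by `sd_mode`. `"as_printed"` requires
#' `SD > sd_thresh`; `"reproducibility"` is the conventional
#' replicate-agreement reading and requires `SD < sd_thresh`.
#'
#' @param calls Per-miRNA tibble from [average_replicates()].
#' @param fc_thresh Fold-change arm threshold on `|mean_log2_fc|`
#'   (default 0.5).
#' @param sd_thresh SD arm threshold (default 0.4).
#' @param sd_mode `"as_printed"` or `"reproducibility"`.
#' @param keep_all If `TRUE` return all rows with a logical
#'   `passed_retention` column; if `FALSE` (default) return the retained
#'   subset.
#'
#' @return A tibble; see `keep_all`.
#' @export
retention_filter <- function(calls, fc_thresh = 0.5, sd_thresh = 0.4,
                             sd_mode = c("as_printed", "reproducibility"),
                             keep_all = FALSE) {
  sd_mode <- match.arg(sd_mode)
  sd_ok <- if (sd_mode == "as_printed") {
    calls$sd_log2_fc > sd_thresh
  } else {
    calls$sd_log2_fc < sd_thresh
  }
  out <- mutate(calls, passed_retention = abs(.data$mean_log2_fc) > fc_thresh & sd_ok)
  if (keep_all) out else filter(out, .data$passed_retention)
}

#' Call expression categories from mean log2 fold changes
#'
#' Categorizes each miRNA by the strict +/-`call_thresh` rule on its
#' replicate-mean log2 ratio: `"up"` above `+call_thresh`, `"down"` below
#' `-call_thresh`, `"unchanged"` otherwise.
#'
#' @param calls Per-miRNA tibble with a `mean_log2_fc` column
#'   ([average_replicates()]).
#' @param call_thresh Significance threshold on the log2 scale (default 0.7).
#'
#' @return `calls` with a `category` column added
#'   (factor levels `up`, `down`, `unchanged`).
#' @export
call_expression <- function(calls, call_thresh = 0.7) {
  if (any(!is.finite(calls$mean_log2_fc))) {
    abort("mean_log2_fc must be finite for every miRNA")
  }
  mutate(calls, category = factor(
    dplyr::case_when(
      .data$mean_log2_fc > call_thresh ~ "up",
      .data$mean_log2_fc < -call_thresh ~ "down",
      TRUE ~ "unchanged"
    ),
    levels = c("up", "down", "unchanged")
  ))
}

#' Tally expression calls
#'
#' @param calls Tibble with a `category` column from [call_expression()].
#'
#' @return A one-row tibble `n_total`, `n_up`, `n_down`, `n_unchanged`;
#'   the three category counts always partition `n_total`.
#' @export
summarize_calls <- function(calls) {
  cat <- factor(calls$category, levels = c("up", "down", "unchanged"))
  if (anyNA(cat) && nrow(calls) > 0) abort("unknown expression category")
  counts <- table(cat)
  tibble(
    n_total = nrow(calls),
    n_up = unname(counts["up"]),
    n_down = unname(counts["down"]),
    n_unchanged = unname(counts["unchanged"])
  )
}

#' Run the full microarray pipeline
#'
#' Chains the stages from probe-level intensities to expression calls:
#' flag filtering, per-slide control normalization, intensity windowing,
#' replicate averaging, retention flagging and +/-`call_thresh`
#' categorization. Each stage only ever drops rows, never adds them.
#'
#' @inheritParams filter_flags
#' @inheritParams normalize_slides
#' @inheritParams intensity_filter
#' @inheritParams retention_filter
#' @inheritParams call_expression
#'
#' @return A per-miRNA tibble with `mean_log2_fc`, `sd_log2_fc`,
#'   `n_replicates`, `passed_retention` and `category`; the call summary is
#'   available via [summarize_calls()].
#' @export
array_pipeline <- function(probes, lo = 8, hi = 14, fc_thresh = 0.5,
                           sd_thresh = 0.4,
                           sd_mode = c("as_printed", "reproducibility"),
                           call_thresh = 0.7, normalize = TRUE,
                           method = c("controls", "global")) {
  sd_mode <- match.arg(sd_mode)
  method <- match.arg(method)
  probes |>
    filter_flags() |>
    normalize_slides(method = method, normalize = normalize) |>
    intensity_filter(lo = lo, hi = hi) |>
    average_replicates() |>
    retention_filter(
      fc_thresh = fc_thresh, sd_thresh = sd_thresh,
      sd_mode = sd_mode, keep_all = TRUE
    ) |>
    call_expression(call_thresh = call_thresh)
}
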