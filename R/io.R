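# GenePix-style flag codes: 0/100 good, -50 not found (marginal),
# -75 empty and -100 bad (absent)
gpr_flag_map <- function(flags) {
  dplyr::case_when(
    flags >= 0 ~ "ok",
    flags %in% c(-25, -50) ~ "marginal",
    flags %in% c(-75, -100) ~ "absent",
    TRUE ~ NA_character_
  )
}

#' Read a behavior exploration CSV
#'
#' Strictly-validated reader for per-subject exploration tables: required
#' columns `subject_id`, `phase`, `t_obj1`..`t_obj6`, `novel_index`
#' (1-based, empty for non-test rows); an optional `group` column is kept.
#'
#' @param file Path to the CSV.
#' @return A tibble of exploration records.
#' @export
read_behavior_table <- function(file) {
  data <- readr::read_csv(file, show_col_types = FALSE)
  needed <- c("subject_id", "phase", object_cols(), "novel_index")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "behavior table lacks column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  bad_phase <- setdiff(unique(data$phase), c("habituation", "study", "test"))
  if (length(bad_phase) > 0) {
    abort(paste0("unknown phase(s): ", paste(bad_phase, collapse = ", ")))
  }
  data$novel_index <- as.integer(data$novel_index)
  check_object_columns(data)
  test_rows <- data[data$phase == "test", ]
  if (nrow(test_rows) > 0) check_novel_index(test_rows)
  if (any(data$phase != "test" & !is.na(data$novel_index))) {
    abort("novel_index must be empty outside the test phase")
  }
  data
}

#' Write a behavior exploration CSV
#'
#' @param data Exploration tibble (see [read_behavior_table()] for columns).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_behavior_table <- function(data, file) {
  readr::write_csv(data, file)
  invisible(file)
}

#' Validate study-phase totals against the task's exploration cap
#'
#' Warns (does not truncate) when any study-phase row's total exploration
#' exceeds the cap; user data are never silently modified.
#'
#' @param data Exploration tibble.
#' @param study_cap Cap in seconds (default 210 = 35 s x 6 objects).
#' @return `data`, invisibly.
#' @export
validate_study_cap <- function(data, study_cap = 210) {
  study <- data[data$phase == "study", ]
  if (nrow(study) > 0) {
    totals <- rowSums(as.matrix(study[object_cols()]))
    over <- totals > study_cap + sqrt(.Machine$double.eps)
    if (any(over)) {
      warn(paste0(
        sum(over), " study-phase record(s) exceed the ", study_cap,
        " s exploration cap"
      ))
    }
  }
  invisible(data)
}

#' Read a probe-level two-channel intensity table
#'
#' Parses either a GPR-like tab-delimited scanner export (columns `Block`,
#' `Row`, `Column`, `Name`, a 635 nm column for Hy5/red, a 532 nm column for
#' Hy3/green, and `Flags`; GenePix flag codes mapped to
#' ok/marginal/absent) or the package's simplified CSV dialect (columns
#' `probe_id`, `mirna`, `hy3`, `hy5`, `flag`, `is_control`, `slide_id`).
#'
#' @param file Path to the table.
#' @param dialect `"auto"` (sniff from the header), `"gpr"` or `"simple"`.
#' @param slide_id Slide identifier to assign (GPR dialect only; defaults to
#'   the file name without extension).
#' @param control_pattern Regular expression on probe names marking
#'   endogenous-control spots (GPR dialect; default matches names containing
#'   "ctrl" or "control", case-insensitively).
#'
#' @return A probe tibble: `probe_id`, `mirna`, `hy3`, `hy5`, `flag`,
#'   `is_control`, `slide_id`.
#' @export
read_probe_table <- function(file, dialect = c("auto", "gpr", "simple"),
                             slide_id = NULL,
                             control_pattern = "(?i)ctrl|control") {
  dialect <- match.arg(dialect)
  header <- readLines(file, n = 50, warn = FALSE)
  header <- header[nzchar(header)]
  if (length(header) == 0) {
    warn("read_probe_table: empty file, returning no probes")
    return(tibble(
      probe_id = character(0), mirna = character(0), hy3 = numeric(0),
      hy5 = numeric(0), flag = character(0), is_control = logical(0),
      slide_id = character(0)
    ))
  }
  if (dialect == "auto") {
    dialect <- if (any(grepl("\tName\t|^Block\t", header))) "gpr" else "simple"
  }
  if (dialect == "gpr") {
    read_probe_gpr(file, slide_id %||%
      sub("\\.[^.]*$", "", basename(file)), control_pattern)
  } else {
    read_probe_simple(file)
  }
}

read_probe_gpr <- function(file, slide_id, control_pattern) {
  lines <- readLines(file, warn = FALSE)
  hdr_idx <- grep("^\"?Block\\b", lines)[1]
  if (is.na(hdr_idx)) abort("GPR dialect: no header row starting with `Block`")
  data <- readr::read_tsv(file, skip = hdr_idx - 1, show_col_types = FALSE)
  f635 <- grep("^F635", names(data), value = TRUE)[1]
  f532 <- grep("^F532", names(data), value = TRUE)[1]
  if (is.na(f635) || is.na(f532) || !all(c("Name", "Flags") %in% names(data))) {
    abort("GPR dialect requires Name, F635*, F532* and Flags columns")
  }
  if (nrow(data) == 0) {
    warn("read_probe_table: empty data section")
  }
  coord <- paste(data$Block, data$Row, data$Column)
  if (anyDuplicated(coord)) abort("duplicate probe coordinates in GPR file")
  if (any(data[[f635]] < 0) || any(data[[f532]] < 0)) {
    abort("negative intensities in GPR file")
  }
  flag <- gpr_flag_map(data$Flags)
  if (anyNA(flag) && nrow(data) > 0) abort("unknown GenePix flag code")
  tibble(
    probe_id = paste0("b", data$Block, "r", data$Row, "c", data$Column),
    mirna = data$Name,
    hy3 = data[[f532]], # 532 nm = green = Hy3 (Impaired pool)
    hy5 = data[[f635]], # 635 nm = red = Hy5 (Unimpaired pool)
    flag = flag,
    is_control = grepl(control_pattern, data$Name, perl = TRUE),
    slide_id = slide_id
  )
}

read_probe_simple <- function(file) {
  data <- readr::read_csv(file, show_col_types = FALSE)
  needed <- c("probe_id", "mirna", "hy3", "hy5", "flag", "is_control", "slide_id")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "simple probe dialect lacks column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(data$hy3 < 0) || any(data$hy5 < 0)) {
    abort("negative intensities in probe table")
  }
  bad <- setdiff(unique(data$flag), c("ok", "marginal", "absent"))
  if (length(bad) > 0) {
    abort(paste0("unknown flag value(s): ", paste(bad, collapse = ", ")))
  }
  data$is_control <- as.logical(data$is_control)
  data
}

#' Write a probe table in the simplified dialect
#'
#' @param probes Probe tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_probe_table <- function(probes, file) {
  readr::write_csv(probes, file)
  invisible(file)
}

#' Write per-miRNA expression calls and their JSON summary
#'
#' @param calls Call tibble from [array_pipeline()] / [call_expression()].
#' @param file Output CSV path.
#' @param summary_file Optional JSON path for the [summarize_calls()] tally.
#' @return `file`, invisibly.
#' @export
write_expression_calls <- function(calls, file, summary_file = NULL) {
  readr::write_csv(calls, file)
  if (!is.null(summary_file)) {
    jsonlite::write_json(
      as.list(summarize_calls(calls)),
      summary_file,
      auto_unbox = TRUE
    )
  }
  invisible(file)
}

#' Read a long-format qPCR Ct table
#'
#' Columns `sample_id`, `assay`, `replicate`, `ct`.
#'
#' @param file Path to the CSV.
#' @return A Ct tibble.
#' @export
read_ct_table <- function(file) {
  data <- readr::read_csv(file, show_col_types = FALSE)
  needed <- c("sample_id", "assay", "replicate", "ct")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(data$ct))) abort("non-finite Ct values")
  data
}

#' Write a qPCR Ct table
#'
#' @param ct_data Ct tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ct_table <- function(ct_data, file) {
  readr::write_csv(ct_data, file)
  invisible(file)
}

#' Write fold-change estimates in a results-table layout
#'
#' One row per assay x pool with the 2^-ddCt point estimate and its
#' asymmetric errors.
#'
#' @param estimates Tibble from [fold_changes()].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_fold_changes <- function(estimates, file) {
  estimates |>
    select(
      "assay", "sample_id", "fold_change", "upper_error", "lower_error"
    ) |>
    readr::write_csv(file)
  invisible(file)
}

#' Read a target-prediction table
#'
#' Columns `gene_symbol`, logical `tapmir`, `targetscan`, `mirdb`,
#' `validated`, optional numeric `tapmir_probability`.
#'
#' @param file Path to the CSV.
#' @return A prediction tibble suitable for [consensus_targets()].
#' @export
read_target_table <- function(file) {
  data <- readr::read_csv(file, show_col_types = FALSE)
  needed <- c("gene_symbol", "tapmir", "targetscan", "mirdb", "validated")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "target table lacks column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  for (col in c("tapmir", "targetscan", "mirdb", "validated")) {
    data[[col]] <- as.logical(data[[col]])
  }
  data
}
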