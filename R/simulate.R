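# run code under a locally-set seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a novel-object-recognition cohort with a latent impaired fraction
#'
#' Generates study- and test-phase exploration records for the six-object
#' task. Per-object exploration times are log-normal (non-negative,
#' right-skewed, as exploratory-behavior durations are). Latent-unimpaired
#' subjects explore the novel object `novelty_boost` times longer on average;
#' latent-impaired subjects treat it like any familiar object (boost 1).
#' Study-phase totals exceeding `study_cap` are proportionally rescaled to
#' the cap, mimicking the timed cutoff, so the cohort size stays fixed.
#'
#' @param n_subjects Cohort size (default 29).
#' @param impaired_fraction Latent impaired share of the cohort
#'   (default 13/29). The first `round(n * fraction)` subjects are impaired;
#'   ordering is randomized only through the subject draws themselves.
#' @param base_object_time Median per-object exploration time, seconds
#'   (default 20).
#' @param dispersion Log-scale SD of per-object times (default 0.25).
#' @param novelty_boost Multiplicative novel-object preference of
#'   unimpaired subjects (default 2.5; must be >= 1).
#' @param study_cap Maximum total study-phase exploration, seconds
#'   (default 210 = 35 s per object).
#' @param seed Optional integer seed; identical seeds give identical output.
#'
#' @return A list with `records` (tibble: `subject_id`, `phase`
#'   (`"study"`/`"test"`), `t_obj1`..`t_obj6`, `novel_index` (`NA` for
#'   study rows)) and `truth` (tibble: `subject_id`, `latent_label`).
#' @export
simulate_cohort <- function(n_subjects = 29, impaired_fraction = 13 / 29,
                            base_object_time = 20, dispersion = 0.25,
                            novelty_boost = 2.5, study_cap = 210,
                            seed = NULL) {
  if (n_subjects < 1) abort("need at least one subject")
  if (impaired_fraction < 0 || impaired_fraction > 1) {
    abort("`impaired_fraction` must be in [0, 1]")
  }
  if (novelty_boost < 1) abort("`novelty_boost` must be >= 1")
  if (study_cap <= 0) abort("`study_cap` must be positive")
  local_seed(seed, {
    n_imp <- round(n_subjects * impaired_fraction)
    latent <- c(
      rep("Impaired", n_imp),
      rep("Unimpaired", n_subjects - n_imp)
    )
    ids <- sprintf("subj_%02d", seq_len(n_subjects))
    draw_times <- function(n) rlnorm(n, log(base_object_time), dispersion)
    records <- purrr::map(seq_len(n_subjects), function(i) {
      study <- draw_times(6)
      if (sum(study) > study_cap) study <- study * study_cap / sum(study)
      novel_index <- sample.int(6, 1)
      test <- draw_times(6)
      boost <- if (latent[i] == "Unimpaired") novelty_boost else 1
      test[novel_index] <- boost * test[novel_index]
      bind_rows(
        tibble(
          subject_id = ids[i], phase = "study",
          !!!setNames(as.list(study), object_cols()),
          novel_index = NA_integer_
        ),
        tibble(
          subject_id = ids[i], phase = "test",
          !!!setNames(as.list(test), object_cols()),
          novel_index = novel_index
        )
      )
    }) |> purrr::list_rbind()
    list(
      records = records,
      truth = tibble(subject_id = ids, latent_label = latent)
    )
  })
}

#' Simulate two-channel miRNA array slides with planted fold changes
#'
#' Builds probe-level two-channel intensity tables for `n_replicates`
#' technical-replicate slides. Each miRNA gets a log2 baseline abundance
#' drawn uniformly from `intensity_range`; channel log2 intensities are
#' baseline +/- half the planted log2 fold change (Impaired pool in the Hy3
#' channel, Unimpaired in Hy5) plus Gaussian noise, and the Hy5 channel is
#' multiplied by `dye_bias` to emulate dye-labelling imbalance (absorbed by
#' control normalization downstream). Endogenous-control probes carry zero
#' fold change; a small fraction of spots is flagged like a scanner would.
#'
#' @param n_mirnas Number of non-control miRNA probes (default 179).
#' @param n_controls Number of endogenous-control probes (default 10).
#' @param n_replicates Technical-replicate slides (default 2).
#' @param upregulated Named numeric vector of planted log2 fold changes;
#'   `NULL` (default) plants 38 miRNAs at +1.2.
#' @param noise_sd Per-channel log2 intensity noise SD (default 0.1).
#' @param intensity_range Log2 baseline abundance interval
#'   (default `c(9, 13)`).
#' @param dye_bias Multiplicative bias applied to the Hy5 channel
#'   (default 1 = unbiased).
#' @param flag_rate Fraction of spots flagged marginal/absent (default 0.02).
#' @param seed Optional integer seed.
#'
#' @return A list with `probes` (tibble: `probe_id`, `mirna`, `hy3`, `hy5`,
#'   `flag`, `is_control`, `slide_id`) and `truth` (tibble: `mirna`,
#'   `true_log2_fc`, `true_category`).
#' @export
simulate_array <- function(n_mirnas = 179, n_controls = 10, n_replicates = 2,
                           upregulated = NULL, noise_sd = 0.1,
                           intensity_range = c(9, 13), dye_bias = 1,
                           flag_rate = 0.02, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (dye_bias <= 0) abort("`dye_bias` must be positive")
  if (length(intensity_range) != 2 || intensity_range[1] >= intensity_range[2]) {
    abort("`intensity_range` must be an increasing length-2 interval")
  }
  mirnas <- sprintf("mir-%03d", seq_len(n_mirnas))
  if (is.null(upregulated)) {
    n_up <- min(38, n_mirnas)
    upregulated <- setNames(rep(1.2, n_up), mirnas[seq_len(n_up)])
  }
  unknown <- setdiff(names(upregulated), mirnas)
  if (length(unknown) > 0) {
    abort(paste0(
      "planted miRNAs not in the simulated set: ",
      paste(unknown, collapse = ", ")
    ))
  }
  local_seed(seed, {
    fc <- setNames(rep(0, n_mirnas), mirnas)
    fc[names(upregulated)] <- upregulated
    controls <- sprintf("ctrl_%02d", seq_len(n_controls))
    all_names <- c(mirnas, controls)
    all_fc <- c(fc, setNames(rep(0, n_controls), controls))
    baseline <- runif(
      length(all_names),
      intensity_range[1], intensity_range[2]
    )
    probes <- purrr::map(seq_len(n_replicates), function(r) {
      k <- length(all_names)
      hy3 <- 2^(baseline + all_fc / 2 + rnorm(k, 0, noise_sd))
      hy5 <- 2^(baseline - all_fc / 2 + rnorm(k, 0, noise_sd)) * dye_bias
      flag <- sample(
        c("ok", "marginal", "absent"),
        k,
        replace = TRUE,
        prob = c(1 - flag_rate, flag_rate / 2, flag_rate / 2)
      )
      tibble(
        probe_id = sprintf("p_%s_r%d", all_names, r),
        mirna = all_names,
        hy3 = hy3,
        hy5 = hy5,
        flag = flag,
        is_control = all_names %in% controls,
        slide_id = sprintf("slide_%d", r)
      )
    }) |> purrr::list_rbind()
    truth <- tibble(
      mirna = mirnas,
      true_log2_fc = unname(fc),
      true_category = factor(
        dplyr::case_when(
          fc > 0 ~ "up",
          fc < 0 ~ "down",
          TRUE ~ "unchanged"
        ),
        levels = c("up", "down", "unchanged")
      )
    )
    list(probes = probes, truth = truth)
  })
}

#' Simulate a qPCR Ct table from latent expression differences
#'
#' Generates technical-replicate Ct values for two pooled samples, a
#' calibrator (`"UM"`) and a comparison pool (`"IM"`), from
#' `Ct = base_ct - expression + noise`: each assay has its own baseline
#' cycle threshold; the comparison pool's latent log2 expression is shifted
#' by the assay's planted difference, and the reference assay's difference
#' is fixed at zero.
#'
#' @param assays Named numeric vector of latent log2 expression differences
#'   (IM relative to UM). The default plants the five validated assays at
#'   differences matching fold changes 13.16, 1.22, 6.04, 8.01 and 2.49.
#' @param reference_assay Name of the zero-difference internal reference
#'   (default `"U6"`).
#' @param ct_noise_sd Replicate Ct noise SD in cycles (default 0.2).
#' @param n_replicates Technical replicates per sample x assay (default 3).
#' @param base_ct_range Uniform interval for per-assay baseline Ct
#'   (default `c(18, 30)`).
#' @param seed Optional integer seed.
#'
#' @return A list with `ct` (tibble: `sample_id`, `assay`, `replicate`,
#'   `ct`) and `truth` (tibble: `assay`, `true_log2_diff`,
#'   `true_fold_change`).
#' @export
simulate_qpcr <- function(assays = NULL, reference_assay = "U6",
                          ct_noise_sd = 0.2, n_replicates = 3,
                          base_ct_range = c(18, 30), seed = NULL) {
  if (is.null(assays)) {
    assays <- log2(c(
      "mir-135a-5p" = 13.1587,
      "mir-451" = 1.2166,
      "hs-miR-126" = 6.0362,
      "hs-miR-21-5p" = 8.0140,
      "mir-153-3p" = 2.4902
    ))
  }
  if (is.null(names(assays)) || any(!nzchar(names(assays)))) {
    abort("`assays` must be a named numeric vector")
  }
  if (reference_assay %in% names(assays)) {
    abort("the reference assay must not appear among the target assays")
  }
  if (ct_noise_sd < 0) abort("`ct_noise_sd` must be >= 0")
  local_seed(seed, {
    all_assays <- c(assays, setNames(0, reference_assay))
    base_ct <- setNames(
      runif(length(all_assays), base_ct_range[1], base_ct_range[2]),
      names(all_assays)
    )
    grid <- tidyr::expand_grid(
      sample_id = c("UM", "IM"),
      assay = names(all_assays),
      replicate = seq_len(n_replicates)
    )
    ct <- grid |>
      mutate(
        latent = ifelse(.data$sample_id == "IM", all_assays[.data$assay], 0),
        ct = base_ct[.data$assay] - .data$latent +
          rnorm(nrow(grid), 0, ct_noise_sd)
      ) |>
      select("sample_id", "assay", "replicate", "ct")
    truth <- tibble(
      assay = names(assays),
      true_log2_diff = unname(assays),
      true_fold_change = 2^unname(assays)
    )
    list(ct = ct, truth = truth)
  })
}
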