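#' Percent new-object exploration
#'
#' Computes, for each test-phase subject, the percentage of total object
#' exploration devoted to the novel object:
#' `100 * new_time / sum(all six object times)`.
#'
#' @param data A data frame of test-phase exploration records with columns
#'   `subject_id`, `t_obj1`..`t_obj6` (seconds) and `novel_index` (1-based
#'   position of the novel object).
#'
#' @return A tibble with columns `subject_id`, `new_time`, `total_time` and
#'   `percent_new` (in `[0, 100]`).
#'
#' @details A subject whose six times are all equal scores exactly
#'   `100/6` percent. Zero total exploration has no defined percentage and is
#'   an error, not an `NaN`.
#'
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "m1",
#'   t_obj1 = 50, t_obj2 = 30, t_obj3 = 30, t_obj4 = 30, t_obj5 = 30,
#'   t_obj6 = 30, novel_index = 1
#' )
#' percent_new(rec)
#' @export
percent_new <- function(data) {
  check_object_columns(data)
  check_novel_index(data)
  times <- as.matrix(data[object_cols()])
  total <- rowSums(times)
  if (any(total <= 0)) {
    abort("total exploration is zero for at least one subject; percentage undefined")
  }
  new_time <- times[cbind(seq_len(nrow(times)), data$novel_index)]
  tibble(
    subject_id = data$subject_id,
    new_time = new_time,
    total_time = total,
    percent_new = 100 * new_time / total
  )
}

#' Classify subjects as Unimpaired or Impaired
#'
#' Applies the novel-object recognition criterion: a subject is Unimpaired
#' when its novel-object exploration time strictly exceeds the mean of the
#' five familiar-object times plus `k` standard deviations of those times,
#' and Impaired otherwise (equality counts as Impaired).
#'
#' @inheritParams percent_new
#' @param k Criterion multiplier on the familiar-object SD (default 1.5).
#' @param sd_type Which SD of the five familiar times to use: `"sample"`
#'   (denominator n-1, the default behavioral-statistics convention) or
#'   `"population"` (denominator n).
#'
#' @return A tibble with one row per subject: `subject_id`, `label`
#'   (`"Unimpaired"`/`"Impaired"`), `new_time`, `familiar_mean`,
#'   `familiar_sd`, `threshold` (= `familiar_mean + k * familiar_sd`) and `k`.
#'   A `group` column is carried through when present.
#'
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "m1",
#'   t_obj1 = 25, t_obj2 = 10, t_obj3 = 12, t_obj4 = 14, t_obj5 = 16,
#'   t_obj6 = 18, novel_index = 1
#' )
#' classify_subjects(rec)
#' @export
classify_subjects <- function(data, k = 1.5, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  check_object_columns(data)
  check_novel_index(data)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k)) {
    abort("`k` must be a single finite number")
  }
  times <- as.matrix(data[object_cols()])
  n <- nrow(times)
  new_time <- times[cbind(seq_len(n), data$novel_index)]
  fam <- t(vapply(
    seq_len(n),
    function(i) times[i, -data$novel_index[i]],
    numeric(5)
  ))
  fam_mean <- rowMeans(fam)
  fam_sd <- apply(fam, 1, sd)
  if (sd_type == "population") {
    fam_sd <- fam_sd * sqrt(4 / 5) # n-1 -> n denominator for 5 values
  }
  threshold <- fam_mean + k * fam_sd
  out <- tibble(
    subject_id = data$subject_id,
    label = ifelse(new_time > threshold, "Unimpaired", "Impaired"),
    new_time = new_time,
    familiar_mean = fam_mean,
    familiar_sd = fam_sd,
    threshold = threshold,
    k = k
  )
  if ("group" %in% names(data)) out$group <- data$group
  out
}

#' Tally phenotype calls across a cohort
#'
#' Counts Unimpaired and Impaired calls and reports each label's share of the
#' cohort, rounded to one decimal place (half away from zero).
#'
#' @param calls A data frame of phenotype calls as returned by
#'   [classify_subjects()] (only the `label` column is required).
#'
#' @return A tibble with columns `label`, `n` and `percent`. Counts always sum
#'   to the cohort size; percentages sum to 100 up to rounding.
#' @export
tally_phenotypes <- function(calls) {
  if (!"label" %in% names(calls)) {
    abort("`calls` must contain a `label` column")
  }
  if (nrow(calls) == 0) {
    abort("cannot tally an empty cohort")
  }
  bad <- setdiff(unique(calls$label), c("Unimpaired", "Impaired"))
  if (length(bad) > 0) {
    abort(paste0("unknown phenotype label(s): ", paste(bad, collapse = ", ")))
  }
  tibble(label = c("Unimpaired", "Impaired")) |>
    left_join(count(calls, .data$label), by = "label") |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      percent = round_half_up(100 * .data$n / sum(.data$n), 1)
    )
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Student's two-sample t-test with pooled variance, `df = nA + nB - 2`,
#' two-sided p-value. When both groups have zero variance and equal means the
#' statistic is 0 by convention; zero pooled variance with unequal means is a
#' degenerate input and errors.
#'
#' @param data A data frame with one row per subject.
#' @param value Column holding the response (tidy-eval).
#' @param group Column holding the two-level group label (tidy-eval).
#'
#' @return A one-row tibble with `t`, `df`, `p`, `mean_diff` (first level
#'   minus second, by factor order of `group`), `n1` and `n2`.
#' @export
unpaired_t <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations")
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled_var == 0) {
    if (mean(a) != mean(b)) {
      abort("zero pooled variance with unequal means: t is degenerate")
    }
    return(tibble(
      t = 0, df = df, p = 1, mean_diff = 0,
      n1 = length(a), n2 = length(b)
    ))
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value,
    mean_diff = mean(a) - mean(b),
    n1 = length(a), n2 = length(b)
  )
}

rm_anova_checks <- function(data, value, subject, within, between = NULL) {
  for (col in c(value, subject, within, between)) {
    if (!col %in% names(data)) abort(paste0("column `", col, "` not found"))
  }
  cells <- data |>
    count(.data[[subject]], .data[[within]]) |>
    dplyr::pull(n)
  n_levels <- length(unique(data[[within]]))
  n_subj <- length(unique(data[[subject]]))
  if (any(cells != 1) || length(cells) != n_subj * n_levels) {
    abort("design must be complete: exactly one value per subject x level cell")
  }
  if (n_levels < 2 || n_subj < 2) {
    abort("need at least 2 subjects and 2 within-subject levels")
  }
  invisible(list(n_subjects = n_subj, n_levels = n_levels))
}

extract_aov_row <- function(tab, term) {
  i <- match(term, trimws(rownames(tab)))
  f <- tab[i, "F value"]
  p <- tab[i, "Pr(>F)"]
  # zero effect SS (flat data) conventionally reported as F = 0
  if (!is.finite(f) && isTRUE(all.equal(tab[i, "Sum Sq"], 0))) {
    f <- 0
    p <- 1
  }
  list(F = f, p = p, df1 = tab[i, "Df"])
}

#' One-way repeated-measures ANOVA
#'
#' Univariate repeated-measures F-test for a single within-subject factor
#' (subject as the error stratum), with uncorrected degrees of freedom
#' `df1 = K - 1`, `df2 = (K - 1)(N - 1)`. No sphericity correction is applied.
#'
#' @param data Long-format data frame: one row per subject x level.
#' @param value,subject,within Column names (strings) holding the response,
#'   the subject identifier and the within-subject factor.
#'
#' @return An object of class `rm_anova`; use [tidy()] for the effect table or
#'   [glance()] for a one-row summary.
#'
#' @examples
#' d <- tidyr::expand_grid(subj = factor(1:4), obj = factor(1:3))
#' d$time <- stats::rnorm(nrow(d), mean = as.integer(d$obj))
#' tidy(anova_rm_oneway(d, "time", "subj", "obj"))
#' @export
anova_rm_oneway <- function(data, value, subject, within) {
  dims <- rm_anova_checks(data, value, subject, within)
  k <- dims$n_levels
  n <- dims$n_subjects
  # completely flat data carry zero effect SS: F = 0 by convention
  if (diff(range(data[[value]])) == 0) {
    return(structure(
      list(
        effects = tibble(
          term = "within",
          df1 = k - 1, df2 = (k - 1) * (n - 1), statistic = 0, p.value = 1
        ),
        n_subjects = n, n_levels = k,
        design = "one-way repeated measures"
      ),
      class = "rm_anova"
    ))
  }
  d <- data.frame(
    y = data[[value]],
    s = factor(data[[subject]]),
    w = factor(data[[within]])
  )
  fit <- aov(y ~ w + Error(s / w), data = d)
  tab <- summary(fit)[["Error: s:w"]][[1]]
  eff <- extract_aov_row(tab, "w")
  df2 <- tab[trimws(rownames(tab)) == "Residuals", "Df"]
  structure(
    list(
      effects = tibble(
        term = "within",
        df1 = eff$df1, df2 = df2, statistic = eff$F, p.value = eff$p
      ),
      n_subjects = dims$n_subjects,
      n_levels = dims$n_levels,
      design = "one-way repeated measures"
    ),
    class = "rm_anova"
  )
}

#' Mixed-design (split-plot) ANOVA
#'
#' Two-way ANOVA with one within-subject factor (repeated measure) and one
#' between-subject factor. Degrees of freedom follow the split-plot
#' decomposition: between `(G - 1, N - G)`; within and interaction
#' `(K - 1, (K - 1)(N - G))`, uncorrected.
#'
#' @inheritParams anova_rm_oneway
#' @param between Column name (string) of the per-subject group label.
#'
#' @return An object of class `rm_anova` with `within`, `between` and
#'   `interaction` rows in its effect table; see [tidy.rm_anova()].
#' @export
anova_rm_mixed <- function(data, value, subject, within, between) {
  dims <- rm_anova_checks(data, value, subject, within, between)
  grp_per_subj <- data |>
    dplyr::distinct(.data[[subject]], .data[[between]])
  if (nrow(grp_per_subj) != dims$n_subjects) {
    abort("each subject must belong to exactly one group")
  }
  grp_sizes <- count(grp_per_subj, .data[[between]])$n
  if (length(grp_sizes) < 2) abort("need at least two groups")
  if (any(grp_sizes < 2)) abort("every group needs at least 2 subjects")
  n <- dims$n_subjects
  k <- dims$n_levels
  n_g <- length(grp_sizes)
  if (diff(range(data[[value]])) == 0) {
    return(structure(
      list(
        effects = tibble(
          term = c("between", "within", "interaction"),
          df1 = c(n_g - 1, k - 1, (n_g - 1) * (k - 1)),
          df2 = c(n - n_g, (k - 1) * (n - n_g), (k - 1) * (n - n_g)),
          statistic = 0, p.value = 1
        ),
        n_subjects = n, n_levels = k, n_groups = n_g,
        design = "two-way mixed (split-plot)"
      ),
      class = "rm_anova"
    ))
  }
  d <- data.frame(
    y = data[[value]],
    s = factor(data[[subject]]),
    w = factor(data[[within]]),
    g = factor(data[[between]])
  )
  fit <- aov(y ~ g * w + Error(s / w), data = d)
  s_tab <- summary(fit)[["Error: s"]][[1]]
  sw_tab <- summary(fit)[["Error: s:w"]][[1]]
  btw <- extract_aov_row(s_tab, "g")
  wth <- extract_aov_row(sw_tab, "w")
  int <- extract_aov_row(sw_tab, "g:w")
  df2_s <- s_tab[trimws(rownames(s_tab)) == "Residuals", "Df"]
  df2_sw <- sw_tab[trimws(rownames(sw_tab)) == "Residuals", "Df"]
  structure(
    list(
      effects = tibble(
        term = c("between", "within", "interaction"),
        df1 = c(btw$df1, wth$df1, int$df1),
        df2 = c(df2_s, df2_sw, df2_sw),
        statistic = c(btw$F, wth$F, int$F),
        p.value = c(btw$p, wth$p, int$p)
      ),
      n_subjects = dims$n_subjects,
      n_levels = dims$n_levels,
      n_groups = length(grp_sizes),
      design = "two-way mixed (split-plot)"
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(x$design, "ANOVA:", x$n_subjects, "subjects x", x$n_levels, "levels\n")
  print(x$effects)
  invisible(x)
}

#' Tidy an rm_anova object
#'
#' @param x An `rm_anova` fit.
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `df1`, `df2`,
#'   `statistic` (F) and `p.value`.
#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' One-row summary of an rm_anova object
#'
#' @inheritParams tidy.rm_anova
#' @return A one-row tibble with the design dimensions and, for mixed designs,
#'   the interaction F and p.
#' @export
glance.rm_anova <- function(x, ...) {
  key <- if (nrow(x$effects) > 1) "interaction" else "within"
  row <- x$effects[x$effects$term == key, ]
  tibble(
    n_subjects = x$n_subjects,
    n_levels = x$n_levels,
    n_groups = x$n_groups %||% 1L,
    statistic = row$statistic,
    p.value = row$p.value
  )
}
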