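# Independent brute-force oracles, written from the standard sums-of-squares
# and moment formulas. They deliberately share no code with the package.

# one-way repeated-measures F by direct SS decomposition (subjects x levels)
oracle_rm_oneway <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  ss_treat <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_treat - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  list(F = (ss_treat / df1) / (ss_err / df2), df1 = df1, df2 = df2)
}

# balanced split-plot F statistics by direct SS decomposition;
# x: subjects x levels, g: per-subject group labels (equal group sizes)
oracle_rm_mixed <- function(x, g) {
  n <- nrow(x)
  k <- ncol(x)
  g <- factor(g)
  ng <- table(g)
  grand <- mean(x)
  subj_means <- rowMeans(x)
  grp_means <- tapply(seq_len(n), g, function(i) mean(x[i, , drop = FALSE]))
  lvl_means <- colMeans(x)
  cell_means <- t(sapply(levels(g), function(gg) {
    colMeans(x[g == gg, , drop = FALSE])
  }))
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(ng * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- n * sum((lvl_means - grand)^2)
  ss_cells <- 0
  for (i in seq_along(levels(g))) {
    ss_cells <- ss_cells + ng[i] * sum((cell_means[i, ] - grand)^2)
  }
  ss_int <- ss_cells - ss_group - ss_level
  ss_total <- sum((x - grand)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_level - ss_int
  df_g <- nlevels(g) - 1
  df_sw <- n - nlevels(g)
  df_l <- k - 1
  df_int <- df_g * df_l
  df_err <- df_l * df_sw
  list(
    F_between = (ss_group / df_g) / (ss_subj_within / df_sw),
    F_within = (ss_level / df_l) / (ss_err_within / df_err),
    F_interaction = (ss_int / df_int) / (ss_err_within / df_err),
    df_between = c(df_g, df_sw),
    df_within = c(df_l, df_err)
  )
}

# pooled-variance two-sample t from first principles
oracle_pooled_t <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df <- length(a) + length(b) - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r and its t-transform p from moment definitions
oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df))
}

# subjects x levels matrix (optionally with per-subject groups) to long form
long_from_matrix <- function(x, g = NULL) {
  d <- tidyr::expand_grid(subj = seq_len(nrow(x)), lvl = seq_len(ncol(x)))
  d$y <- x[cbind(d$subj, d$lvl)]
  if (!is.null(g)) d$grp <- g[d$subj]
  d
}

# deterministic test-phase exploration records with a chosen number of
# criterion-passing subjects: passers explore the novel object far above the
# familiar mean + 1.5 SD threshold, the rest exactly at the familiar level
make_test_records <- function(n_pass, n_fail) {
  n <- n_pass + n_fail
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    t_obj1 = c(rep(60, n_pass), rep(12, n_fail)),
    t_obj2 = 10, t_obj3 = 11, t_obj4 = 12, t_obj5 = 13, t_obj6 = 14,
    novel_index = 1L
  )
}
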