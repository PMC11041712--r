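test_that("percent_new matches hand-computed percentages", {
  rec <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    t_obj1 = c(50, 0, 35),
    t_obj2 = c(40, 25, 35), t_obj3 = c(40, 25, 35), t_obj4 = c(30, 25, 35),
    t_obj5 = c(20, 25, 35), t_obj6 = c(20, 0, 35),
    novel_index = c(1L, 1L, 1L)
  )
  out <- percent_new(rec)
  expect_equal(out$percent_new, c(25, 0, 100 * 35 / 210))
  expect_true(all(out$percent_new >= 0 & out$percent_new <= 100))
})

test_that("percent_new of six equal times is exactly 100/6", {
  rec <- tibble::tibble(
    subject_id = "a",
    t_obj1 = 17.3, t_obj2 = 17.3, t_obj3 = 17.3,
    t_obj4 = 17.3, t_obj5 = 17.3, t_obj6 = 17.3,
    novel_index = 4L
  )
  expect_equal(percent_new(rec)$percent_new, 100 / 6)
})

test_that("percent_new rejects undefined inputs", {
  rec <- tibble::tibble(
    subject_id = "a", t_obj1 = 0, t_obj2 = 0, t_obj3 = 0,
    t_obj4 = 0, t_obj5 = 0, t_obj6 = 0, novel_index = 1L
  )
  expect_error(percent_new(rec), "undefined")
  expect_error(percent_new(rec[, -8]), "novel_index")
})

test_that("classification reproduces hand-derived thresholds and labels", {
  rec <- tibble::tibble(
    subject_id = c("unimp", "tie", "below"),
    t_obj1 = c(25, 5, 18),
    t_obj2 = c(10, 5, 10), t_obj3 = c(12, 5, 12), t_obj4 = c(14, 5, 14),
    t_obj5 = c(16, 5, 16), t_obj6 = c(18, 5, 18),
    novel_index = 1L
  )
  out <- classify_subjects(rec)
  # familiar [10,12,14,16,18]: mean 14, sample SD sqrt(10)
  expect_equal(out$familiar_mean[c(1, 3)], c(14, 14))
  expect_equal(out$familiar_sd[c(1, 3)], rep(sqrt(10), 2))
  expect_equal(out$threshold[1], 14 + 1.5 * sqrt(10))
  expect_equal(out$label, c("Unimpaired", "Impaired", "Impaired"))
  # equality at a zero-SD threshold is Impaired: strict exceedance required
  expect_equal(out$threshold[2], 5)
})

test_that("classification is scale-equivariant and reduces to the mean at k = 0", {
  set.seed(42)
  for (i in 1:20) {
    times <- stats::rlnorm(6, log(15), 0.4)
    rec <- tibble::tibble(
      subject_id = "s",
      t_obj1 = times[1], t_obj2 = times[2], t_obj3 = times[3],
      t_obj4 = times[4], t_obj5 = times[5], t_obj6 = times[6],
      novel_index = sample.int(6, 1)
    )
    scaled <- rec
    c_mult <- stats::runif(1, 0.1, 10)
    scaled[paste0("t_obj", 1:6)] <- scaled[paste0("t_obj", 1:6)] * c_mult
    expect_identical(
      classify_subjects(rec)$label,
      classify_subjects(scaled)$label
    )
    k0 <- classify_subjects(rec, k = 0)
    expect_identical(
      k0$label,
      ifelse(k0$new_time > k0$familiar_mean, "Unimpaired", "Impaired")
    )
  }
})

test_that("population-SD mode shrinks the threshold by sqrt(4/5)", {
  rec <- make_test_records(1, 0)
  samp <- classify_subjects(rec, sd_type = "sample")
  pop <- classify_subjects(rec, sd_type = "population")
  expect_equal(pop$familiar_sd, samp$familiar_sd * sqrt(4 / 5))
})

test_that("cohort tallies report rounded percentages that sum to 100", {
  out <- tally_phenotypes(classify_subjects(make_test_records(16, 13)))
  expect_equal(out$n, c(16L, 13L))
  expect_equal(out$percent, c(55.2, 44.8))
  even <- tally_phenotypes(classify_subjects(make_test_records(3, 3)))
  expect_equal(even$percent, c(50, 50))
  all_um <- tally_phenotypes(classify_subjects(make_test_records(5, 0)))
  expect_equal(all_um$percent, c(100, 0))
  expect_equal(all_um$n[2], 0L)
  expect_error(tally_phenotypes(tibble::tibble(label = character(0))), "empty")
  # counts partition the cohort; percentages sum to 100 up to rounding
  for (np in c(1, 7, 28)) {
    t <- tally_phenotypes(classify_subjects(make_test_records(np, 29 - np)))
    expect_equal(sum(t$n), 29L)
    expect_lt(abs(sum(t$percent) - 100), 0.1)
  }
})

test_that("unpaired t matches the pooled-variance oracle and conventions", {
  out <- unpaired_t(
    tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3)),
    v, g
  )
  ora <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, ora$t) # -3.674 by hand: pooled var 1, SE sqrt(2/3)
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  expect_equal(out$p, ora$p)

  # group sizes 16 and 13 give df 27
  d <- tibble::tibble(
    v = stats::rnorm(29), g = rep(c("UM", "IM"), c(16, 13))
  )
  expect_equal(unpaired_t(d, v, g)$df, 27)

  # identical groups: t = 0, p = 1 by convention
  same <- tibble::tibble(v = rep(c(2, 2, 2), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(unpaired_t(same, v, g)$t, 0)
  expect_equal(unpaired_t(same, v, g)$p, 1)
  degen <- tibble::tibble(v = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  expect_error(unpaired_t(degen, v, g), "degenerate")
})

test_that("unpaired t is antisymmetric under group swap", {
  set.seed(7)
  d <- tibble::tibble(
    v = stats::rnorm(20), g = rep(c("a", "b"), c(12, 8))
  )
  d_swap <- dplyr::mutate(d, g = ifelse(g == "a", "z", "a"))
  expect_equal(unpaired_t(d, v, g)$t, -unpaired_t(d_swap, v, g)$t)
  expect_equal(unpaired_t(d, v, g)$p, unpaired_t(d_swap, v, g)$p)
})

test_that("one-way repeated-measures ANOVA matches the SS oracle", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(12), nrow = 4, ncol = 3)
    fit <- anova_rm_oneway(long_from_matrix(x), "y", "subj", "lvl")
    eff <- tidy(fit)
    ora <- oracle_rm_oneway(x)
    expect_equal(eff$statistic, ora$F, tolerance = 1e-10)
    expect_equal(eff$df1, ora$df1)
    expect_equal(eff$df2, ora$df2)
  }
})

test_that("one-way RM ANOVA df identity and flat-data convention hold", {
  x <- matrix(stats::rnorm(29 * 6), nrow = 29)
  eff <- tidy(anova_rm_oneway(long_from_matrix(x), "y", "subj", "lvl"))
  expect_equal(c(eff$df1, eff$df2), c(5, 140))
  flat <- matrix(3, nrow = 4, ncol = 3)
  eff_flat <- tidy(anova_rm_oneway(long_from_matrix(flat), "y", "subj", "lvl"))
  expect_equal(eff_flat$statistic, 0)
  # missing cells rejected
  d <- long_from_matrix(x)[-1, ]
  expect_error(anova_rm_oneway(d, "y", "subj", "lvl"), "complete")
})

test_that("mixed ANOVA matches the split-plot oracle on a balanced design", {
  set.seed(13)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(18), nrow = 6, ncol = 3)
    g <- rep(c("g1", "g2"), each = 3)
    eff <- tidy(anova_rm_mixed(long_from_matrix(x, g), "y", "subj", "lvl", "grp"))
    ora <- oracle_rm_mixed(x, g)
    expect_equal(
      eff$statistic,
      unname(c(ora$F_between, ora$F_within, ora$F_interaction)),
      tolerance = 1e-10
    )
    expect_equal(eff$df2[1], ora$df_between[2])
    expect_equal(eff$df2[3], ora$df_within[2])
  }
})

test_that("mixed ANOVA reports the split-plot df structure for 16 + 13 subjects", {
  set.seed(17)
  x <- matrix(stats::rnorm(29 * 6), nrow = 29)
  g <- rep(c("UM", "IM"), c(16, 13))
  eff <- tidy(anova_rm_mixed(long_from_matrix(x, g), "y", "subj", "lvl", "grp"))
  expect_equal(eff$term, c("between", "within", "interaction"))
  expect_equal(eff$df1, c(1, 5, 5))
  expect_equal(eff$df2, c(27, 135, 135))
  g1 <- glance(anova_rm_mixed(long_from_matrix(x, g), "y", "subj", "lvl", "grp"))
  expect_equal(g1$n_subjects, 29)
  expect_equal(g1$n_groups, 2L)
})

test_that("mixed ANOVA between-group F vanishes for identical groups", {
  set.seed(23)
  half <- matrix(stats::rnorm(9), nrow = 3)
  x <- rbind(half, half) # group b duplicates group a's subjects
  g <- rep(c("a", "b"), each = 3)
  eff <- tidy(anova_rm_mixed(long_from_matrix(x, g), "y", "subj", "lvl", "grp"))
  expect_equal(eff$statistic[eff$term == "between"], 0, tolerance = 1e-12)
  # fully flat data: every F is 0 by the zero-effect-SS convention
  flat <- tidy(anova_rm_mixed(
    long_from_matrix(matrix(2, 4, 3), rep(c("a", "b"), each = 2)),
    "y", "subj", "lvl", "grp"
  ))
  expect_identical(flat$statistic, rep(0, 3))
  expect_error(
    anova_rm_mixed(long_from_matrix(x, c("a", rep("b", 5))), "y", "subj", "lvl", "grp"),
    "at least 2 subjects"
  )
})
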