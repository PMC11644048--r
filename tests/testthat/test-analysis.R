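test_that("outlier removal is single-pass with population SD and strict bounds", {
  # hand oracle computed in place: mean and population SD once on the full
  # set, values strictly outside mean +/- 2 SD removed
  x <- c(1, 1.4, 0.8, 1.2, 1, 1.1, 80)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  res <- remove_outliers(x, k = 2)
  expect_equal(res$mean, m)
  expect_equal(res$sd, s)
  expect_equal(res$bounds, c(m - 2 * s, m + 2 * s))
  expect_true(80 > res$bounds[2])
  expect_equal(res$keep, c(rep(TRUE, 6), FALSE))
  expect_equal(res$n_removed, 1L)

  # values exactly on the bound are kept (strictly-outside rule). Two such
  # ties: {0, 2} with k = 1 has bounds [0, 2] exactly; and a 4-equal-plus-one
  # set at k = 2, where algebra puts the lone value exactly on the bound
  # (mean 20.8, population SD 39.6, upper bound 100)
  tie <- remove_outliers(c(0, 2), k = 1)
  expect_equal(tie$bounds, c(0, 2))
  expect_equal(tie$n_removed, 0L)
  tie2 <- remove_outliers(c(1, 1, 1, 1, 100), k = 2)
  expect_equal(tie2$mean, 20.8)
  expect_equal(tie2$sd, 39.6)
  expect_equal(tie2$n_removed, 0L)

  expect_equal(remove_outliers(rep(3.2, 10))$n_removed, 0L)   # SD = 0
  expect_equal(remove_outliers(c(1, 1, 1, 1, 100), k = Inf)$n_removed, 0L)
  expect_warning(res1 <- remove_outliers(4.2), "fewer than 2")
  expect_equal(res1$keep, TRUE)
})

test_that("outlier removal keeps the bulk of unimodal data", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- abs(rnorm(30, 2, 0.8))
    res <- remove_outliers(x, k = 2)
    expect_true(sum(res$keep) > sum(!res$keep))
  }
})

test_that("participant means average kept trials and flag empty sets", {
  tab <- cohort_table(
    participant_id = c("a", "a", "a", "b", "c"),
    group = "stroke", task_id = "t2", trial_id = c(1, 2, 3, 1, 1),
    final_error_cm = c(1, 2, 3, 4.2, 9))
  expect_equal(participant_mean(tab, "a", "t2")$mean_error_cm, 2.0)
  expect_equal(participant_mean(tab, "b", "t2")$mean_error_cm, 4.2)
  none <- participant_mean(tab, "c", "t2", keep = tab$participant_id != "c")
  expect_true(is.na(none$mean_error_cm))
  expect_equal(none$n_trials, 1L)
  expect_equal(none$n_used, 0L)

  expect_error(cohort_table("a", "g", "t", c(1, 1), c(1, 2)), "duplicate")
  expect_error(cohort_table("a", "g", "t", 1, -1), "non-negative")
})

test_that("cohort summaries remove outliers per group and task", {
  tab <- cohort_table(
    participant_id = c(rep("a", 5), rep("b", 5)),
    group = "older", task_id = "t2", trial_id = rep(1:5, 2),
    final_error_cm = c(1, 1.2, 0.9, 1.1, 1, 1, 1.1, 0.9, 1, 60))
  summ <- summarise_cohort(tab, k = 2)
  b <- summ[summ$participant_id == "b", ]
  expect_equal(b$n_used, 4L)                 # the 60 cm trial is discarded
  expect_equal(b$mean_error_cm, 1.0)
  a <- summ[summ$participant_id == "a", ]
  expect_equal(a$n_used, 5L)
})

test_that("normative flags compare to the upper reference tail", {
  ref <- normative_reference(1.5, 0.4, group = "older")
  expect_equal(normative_flag(1.5, ref), "within")
  expect_equal(normative_flag(1.5 + 2.5 * 0.4, ref), "above_2sd")
  expect_equal(normative_flag(1.5 + 3.5 * 0.4, ref), "above_3sd")
  # monotone in the mean error
  flags <- normative_flag(seq(0, 4, by = 0.1), ref)
  ranks <- match(flags, c("within", "above_2sd", "above_3sd"))
  expect_true(all(diff(ranks) >= 0))
  expect_true(is.na(normative_flag(NA_real_, ref)))
  expect_error(normative_reference(1, 0), "sd")
})

test_that("concurrent validity is a Pearson correlation over complete pairs", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- concurrent_validity(x, 2 * x + 1)
  expect_equal(perfect$r, 1.0)
  expect_equal(perfect$n_used, 5L)

  with_missing <- concurrent_validity(c(x, NA), c(2 * x + 1, 3))
  expect_equal(with_missing$n_used, 5L)
  expect_equal(with_missing$n_dropped, 1L)

  expect_error(concurrent_validity(x, rep(7, 5)), "zero variance")
  expect_error(concurrent_validity(1:2, 1:2), "at least 3")
  expect_error(concurrent_validity(1:4, 1:5), "paired")
})

test_that("under independence the correlation is small and p roughly uniform", {
  set.seed(21)
  n_rep <- 150
  rs <- numeric(n_rep)
  ps <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cv <- concurrent_validity(rnorm(60), rnorm(60))
    rs[i] <- cv$r
    ps[i] <- cv$p
  }
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(mean(abs(rs)), 0.2)
  frac05 <- mean(ps < 0.05)
  expect_gt(frac05, 0.005)
  expect_lt(frac05, 0.12)
})
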