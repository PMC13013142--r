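test_that("first/last correlations reproduce the textbook Pearson formula", {
  # perfect linear relation between first-call duration and size
  tab <- make_table(list(1, c(2, 9), c(3, 9, 9)), individuals = c("a", "b"))
  res <- first_last_correlation(tab)
  expect_equal(res$r_first, 1)
  expect_equal(res$n_sequences_used, 3L)

  # independent formula oracle on a random table
  set.seed(61)
  sizes <- sample(1:5, 40, replace = TRUE)
  tab2 <- make_table(lapply(sizes, function(n) stats::rlnorm(n, -1.5, 0.4)),
                     individuals = c("a", "b", "c"))
  res2 <- first_last_correlation(tab2)
  firsts <- vapply(split(tab2, tab2$sequence_id),
                   function(d) d$duration_s[d$position == 1], numeric(1))
  lasts <- vapply(split(tab2, tab2$sequence_id),
                  function(d) d$duration_s[which.max(d$position)], numeric(1))
  n <- vapply(split(tab2$position, tab2$sequence_id), max, integer(1))
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res2$r_first, pearson(firsts, n))
  expect_equal(res2$r_last, pearson(lasts, n))

  # zero variance is a signalled condition, not NaN propagation
  flat <- make_table(list(c(0.2, 0.5), c(0.2, 0.1, 0.7), c(0.2, 0.9)),
                     individuals = "a")
  expect_error(first_last_correlation(flat),
               class = "menzerath_degenerate_error")
})

test_that("singleton handling in the correlation is a documented switch", {
  tab <- make_table(list(0.9, c(0.2, 0.3), c(0.3, 0.2, 0.4), c(0.5, 0.1)),
                    individuals = c("a", "b"))
  with_singles <- first_last_correlation(tab)
  expect_equal(with_singles$n_sequences_used, 4L)
  without <- first_last_correlation(tab, include_singles = FALSE)
  expect_equal(without$n_sequences_used, 3L)
})

test_that("final lengthening reproduces the hand-computed paired t", {
  tab <- make_table(list(c(1, 1, 2), c(1, 3)))
  res <- final_lengthening_test(tab)
  # relative finals (1.5, 1.5); non-final means (0.75, 0.5);
  # paired differences (0.75, 1.0) -> t = 0.875 / (0.17678 / sqrt(2)) = 7
  expect_equal(res$mean_relative_final, 1.5)
  expect_equal(res$mean_relative_nonfinal, 0.625)
  expect_equal(res$t_statistic, 7.0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(res$n_sequences, 2L)
})

test_that("final lengthening is scale invariant and excludes singletons", {
  set.seed(62)
  sizes <- sample(1:4, 60, replace = TRUE)
  tab <- make_table(lapply(sizes, function(n) stats::rlnorm(n, -1.5, 0.3)),
                    individuals = c("a", "b"))
  res <- final_lengthening_test(tab)
  expect_equal(res$n_sequences, sum(sizes >= 2))
  expect_equal(res$df, sum(sizes >= 2) - 1L)
  scaled <- call_table(transform(as.data.frame(tab),
                                 duration_s = duration_s * 12))
  res_s <- final_lengthening_test(scaled)
  expect_equal(res_s$t_statistic, res$t_statistic)
  expect_equal(res_s$mean_relative_final, res$mean_relative_final)
})

test_that("zero-difference and boosted-final cases behave as specified", {
  same <- make_table(list(c(0.3, 0.3), c(0.3, 0.3, 0.3), c(0.3, 0.3)))
  res0 <- final_lengthening_test(same)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # multiplicative final-call boost must surface as t > 0
  set.seed(63)
  sizes <- sample(2:4, 80, replace = TRUE)
  durs <- lapply(sizes, function(n) {
    d <- stats::rlnorm(n, -1.5, 0.2)
    d[n] <- d[n] * 1.5
    d
  })
  boosted <- make_table(durs, individuals = c("a", "b"))
  resb <- final_lengthening_test(boosted)
  expect_gt(resb$mean_relative_final, resb$mean_relative_nonfinal)
  expect_gt(resb$t_statistic, 2)

  expect_error(final_lengthening_test(make_table(list(0.2, 0.3))),
               class = "menzerath_model_error")
})

test_that("relative durations within a sequence average to one", {
  set.seed(64)
  sizes <- sample(2:5, 20, replace = TRUE)
  tab <- make_table(lapply(sizes, function(n) stats::rlnorm(n)))
  res <- final_lengthening_test(tab)
  # reconstruct: mean over calls of relative duration is 1 per sequence, so
  # final + (n-1) * nonfinal_mean = n for every sequence
  by_seq <- split(tab$duration_s, tab$sequence_id)
  for (d in by_seq) {
    rel <- d / mean(d)
    expect_equal(sum(rel), length(d))
  }
  expect_true(is.finite(res$t_statistic))
})

test_that("boundary profile aggregates first/last means per size", {
  tab <- make_table(list(c(1, 2), c(3, 4), 5), individuals = "a")
  prof <- boundary_profile(tab)
  expect_equal(prof$size, c(1L, 2L))
  expect_equal(prof$mean_first[prof$size == 2], 2)   # mean of 1, 3
  expect_equal(prof$mean_last[prof$size == 2], 3)    # mean of 2, 4
  expect_equal(prof$n_sequences, c(1L, 2L))
})
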