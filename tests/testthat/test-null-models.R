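test_that("pseudo-sequence sampling obeys the strict 50%-overshoot rule", {
  # forced by a single-value pool: total 10 -> 3,3,3,3 overshoots by 2 > 1.5
  set.seed(1)
  expect_equal(generate_pseudo_sequence(10, pool = 3), c(3, 3, 3))
  # total 11 -> 3,3,3,3 overshoots by 1 <= 1.5, kept
  expect_equal(generate_pseudo_sequence(11, pool = 3), c(3, 3, 3, 3))
  # constant pools force pseudo sizes equal to real sizes
  for (n in 1:6) {
    expect_length(generate_pseudo_sequence(n * 0.25, pool = 0.25), n)
  }
  expect_error(generate_pseudo_sequence(1, pool = numeric(0)),
               class = "menzerath_config_error")
})

test_that("pseudo-sequence length distribution matches exhaustive enumeration", {
  # independent oracle: enumerate all sampling paths for pool {1, 3},
  # real total 4, applying the 50% rule to each terminal path
  enumerate_lengths <- function(pool, total) {
    probs <- new.env()
    recurse <- function(draws, p) {
      if (sum(draws) > total) {
        kept <- draws
        if (sum(draws) - total > 0.5 * draws[length(draws)]) {
          kept <- draws[-length(draws)]
        }
        key <- as.character(length(kept))
        probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + p
        return(invisible())
      }
      for (d in pool) recurse(c(draws, d), p / length(pool))
    }
    recurse(numeric(0), 1)
    out <- unlist(as.list(probs))
    out[order(as.integer(names(out)))]
  }
  expected <- enumerate_lengths(c(1, 3), 4)
  expect_equal(sum(expected), 1)

  set.seed(99)
  n_draws <- 20000L
  lens <- replicate(n_draws, length(generate_pseudo_sequence(4, c(1, 3))))
  observed <- table(factor(lens, levels = names(expected))) / n_draws
  # each category within 4 binomial SEs of the enumerated probability
  for (k in names(expected)) {
    se <- sqrt(expected[[k]] * (1 - expected[[k]]) / n_draws)
    expect_lt(abs(observed[[k]] - expected[[k]]), 4 * se + 1e-12)
  }
})

test_that("shuffle null is centered, deterministic, and p-values behave", {
  cfg <- synthetic_config(beta1 = -0.3, beta2 = 0, sigma_seq = 0.05,
                          sigma_ind = 0.05, sigma_pos = 0, sigma_eps = 0.2,
                          n_individuals = 3, sequences_per_individual = 150)
  tab <- simulate_call_table(cfg, seed = 41)
  nd <- shuffle_null(tab, n_iter = 60, seed = 6)
  expect_length(nd$slopes_size, 60)
  # shuffling destroys the size-duration association by construction
  expect_lt(abs(mean(nd$slopes_size)),
            4 * stats::sd(nd$slopes_size) / sqrt(60))
  expect_lte(nd$empirical_p_size, 0.05)
  expect_gte(nd$empirical_p_size, 1 / 61)

  nd2 <- shuffle_null(tab, n_iter = 60, seed = 6)
  expect_identical(nd$slopes_size, nd2$slopes_size)
  expect_identical(nd$slopes_position, nd2$slopes_position)
})

test_that("shuffle null on a constant-duration table gives exactly zero slopes", {
  tab <- make_table(list(c(0.4, 0.4), c(0.4, 0.4, 0.4), c(0.4, 0.4),
                         c(0.4, 0.4, 0.4)),
                    individuals = c("a", "b"))
  nd <- shuffle_null(tab, n_iter = 10, seed = 2)
  expect_equal(nd$slopes_size, rep(0, 10), tolerance = 1e-10)
  expect_equal(nd$slopes_position, rep(0, 10), tolerance = 1e-10)
})

test_that("empirical p-values use the (r+1)/(n+1) two-sided correction", {
  expect_equal(empirical_p(c(0.1, -0.2, 0.3), observed = 0.25), 2 / 4)
  expect_equal(empirical_p(c(0.1, -0.2, 0.3), observed = 2), 1 / 4)
  expect_equal(empirical_p(c(0.1, -0.2, 0.3), observed = 0), 1)
  # monotone non-increasing in |observed| for a fixed null sample
  set.seed(3)
  nulls <- stats::rnorm(200)
  ps <- vapply(seq(0, 3, by = 0.1), function(o) empirical_p(nulls, o),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 201 & ps <= 1))
})

test_that("production-constraint null matches durations and skews negative", {
  cfg <- synthetic_config(beta1 = 0, beta2 = 0, sigma_seq = 0.1,
                          sigma_ind = 0.1, sigma_pos = 0, sigma_eps = 0.35,
                          n_individuals = 3, sequences_per_individual = 60)
  tab <- simulate_call_table(cfg, seed = 51)
  nd <- production_constraint_null(tab, n_iter = 25, seed = 7)
  expect_equal(nd$pseudo_check$band_violations, 0L)
  # duration matching alone induces compression: longer pseudo-sequences
  # are the ones that happened to draw shorter calls
  expect_lt(mean(nd$slopes_size), 0)
  nd2 <- production_constraint_null(tab, n_iter = 25, seed = 7)
  expect_identical(nd$slopes_size, nd2$slopes_size)
})

test_that("constant-duration tables force pseudo sizes equal to real sizes", {
  tab <- make_table(list(c(0.3, 0.3), c(0.3, 0.3, 0.3), c(0.3, 0.3),
                         c(0.3, 0.3, 0.3)),
                    individuals = c("a", "b"))
  nd <- production_constraint_null(tab, n_iter = 10, seed = 4)
  expect_equal(nd$slopes_size, rep(0, 10), tolerance = 1e-10)
  expect_equal(nd$pseudo_check$band_violations, 0L)
  expect_equal(nd$pseudo_check$n_empty_sequences, 0L)
})
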