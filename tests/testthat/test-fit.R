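test_that("a constant-duration table yields zero slopes and log-c intercept", {
  tab <- make_table(list(c(0.5, 0.5), c(0.5, 0.5, 0.5), c(0.5, 0.5)),
                    individuals = c("a", "b"))
  fit <- fit_menzerath(tab)
  cf <- coef(fit)
  expect_equal(unname(cf[["log_size"]]), 0, tolerance = 1e-10)
  expect_equal(unname(cf[["position"]]), 0, tolerance = 1e-10)
  expect_equal(unname(cf[["(Intercept)"]]), log(0.5), tolerance = 1e-10)
  expect_true(all(fit$varcomp$variance < 1e-10))
})

test_that("slopes and t-statistics are invariant to duration rescaling", {
  tab <- quick_synth(seed = 21, n_seq = 150L)
  scaled <- call_table(transform(as.data.frame(tab),
                                 duration_s = duration_s * 37.5))
  f1 <- fit_menzerath(tab)
  f2 <- fit_menzerath(scaled)
  expect_equal(coef(f2)[["log_size"]], coef(f1)[["log_size"]],
               tolerance = 1e-4)
  expect_equal(coef(f2)[["position"]], coef(f1)[["position"]],
               tolerance = 1e-4)
  expect_equal(coef(f2)[["(Intercept)"]] - coef(f1)[["(Intercept)"]],
               log(37.5), tolerance = 1e-6)
  expect_equal(f2$coefficients$t[-1], f1$coefficients$t[-1],
               tolerance = 1e-4)
})

test_that("shifting every position moves only the intercept, by beta2*shift", {
  tab <- quick_synth(seed = 22, n_seq = 120L)
  mf <- menzerath:::model_frame_calls(tab)
  mf2 <- mf
  mf2$position <- mf$position + 3
  f1 <- menzerath:::fit_lmm_core(mf, "log_size + position", reml = TRUE,
                                 table = NULL)
  f2 <- menzerath:::fit_lmm_core(mf2, "log_size + position", reml = TRUE,
                                 table = NULL)
  expect_equal(coef(f2)[["log_size"]], coef(f1)[["log_size"]],
               tolerance = 1e-6)
  expect_equal(coef(f2)[["position"]], coef(f1)[["position"]],
               tolerance = 1e-6)
  expect_equal(coef(f1)[["(Intercept)"]] - coef(f2)[["(Intercept)"]],
               3 * coef(f1)[["position"]], tolerance = 1e-5)
})

test_that("estimates are invariant to input row order", {
  tab <- quick_synth(seed = 23, n_seq = 80L)
  set.seed(1)
  shuffled <- call_table(as.data.frame(tab)[sample(nrow(tab)), ])
  expect_equal(coef(fit_menzerath(shuffled)), coef(fit_menzerath(tab)),
               tolerance = 1e-8)
})

test_that("generate-then-refit recovers the generating slopes within the CI", {
  cfg <- synthetic_config(beta1 = -0.08, beta2 = 0.04,
                          n_individuals = 3, sequences_per_individual = 500)
  tab <- simulate_call_table(cfg, seed = 31)
  fit <- fit_menzerath(tab)
  ci <- confint(fit, parm = c("log_size", "position"))
  expect_gt(-0.08, ci["log_size", "lower"])
  expect_lt(-0.08, ci["log_size", "upper"])
  expect_gt(0.04, ci["position", "lower"])
  expect_lt(0.04, ci["position", "upper"])
  expect_equal(fit$n_obs, nrow(tab))
  expect_true(all(fit$coefficients$se > 0))
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
})

test_that("degenerate groupings are dropped with a warning, not silently", {
  one_ind <- make_table(list(c(0.2, 0.25), c(0.3, 0.2, 0.4), c(0.5, 0.3)))
  expect_warning(fit_menzerath(one_ind), "individual random intercept")
  all_singletons_and_pairs <- make_table(list(0.2, 0.3, c(0.2, 0.4)),
                                         individuals = c("a", "b"))
  expect_s3_class(suppressWarnings(fit_menzerath(all_singletons_and_pairs)),
                  "menzerath_fit")
  one_size <- make_table(list(c(0.2, 0.3), c(0.4, 0.2)),
                         individuals = c("a", "b"))
  expect_error(fit_menzerath(one_size), class = "menzerath_model_error")
})

test_that("include_singles = FALSE removes singleton sequences before fitting", {
  tab <- quick_synth(seed = 24, n_seq = 100L)
  n_singles <- sum(sequence_sizes(tab) == 1L)
  expect_gt(n_singles, 0L)
  f_all <- fit_menzerath(tab, include_singles = TRUE)
  f_multi <- fit_menzerath(tab, include_singles = FALSE)
  expect_equal(f_all$n_obs, nrow(tab))
  expect_equal(f_multi$n_obs, nrow(tab) - n_singles)
  expect_equal(f_multi$n_sequences, f_all$n_sequences - n_singles)
})

test_that("group interaction model is symmetric and recovers slope contrasts", {
  tab <- quick_synth(seed = 25, n_seq = 120L)
  dup <- as.data.frame(tab)
  dup$context <- "copy"
  dup$sequence_id <- paste0("copy_", dup$sequence_id)
  dup <- call_table(dup)
  expect_error(fit_group_interaction(tab, tab),
               class = "menzerath_model_error")
  sym <- fit_group_interaction(tab, dup)
  expect_equal(sym$interactions$estimate, c(0, 0), tolerance = 1e-8)

  # two generators differing only in beta1 by delta
  delta <- 0.12
  a <- simulate_call_table(synthetic_config(beta1 = -0.10, beta2 = 0.03,
    n_individuals = 3, sequences_per_individual = 400, context = "A"),
    seed = 26)
  b <- simulate_call_table(synthetic_config(beta1 = -0.10 + delta,
    beta2 = 0.03, n_individuals = 3, sequences_per_individual = 400,
    context = "B"), seed = 27)
  g <- fit_group_interaction(a, b)
  ix <- g$interactions
  est <- ix$estimate[grepl("log_size", ix$term)]
  se <- ix$se[grepl("log_size", ix$term)]
  expect_lt(abs(est - delta), 1.96 * se + 0.02)
})

test_that("the accuracy model estimates the cue slope on the proportion scale", {
  all_right <- data.frame(
    participant_id = rep(sprintf("p%d", 1:5), each = 40),
    cue_number = rep(1:8, 25), correct = TRUE)
  f0 <- fit_accuracy_model(all_right)
  expect_equal(coef(f0)[["cue_number"]], 0)

  cfg <- trial_config(accuracy_intercept = 0.99, accuracy_slope = -0.02,
                      n_participants = 26, trials_per_participant = 400)
  trials <- suppressMessages(simulate_trials(cfg, seed = 8))
  f <- fit_accuracy_model(trials)
  ci <- confint(f, parm = "cue_number")
  expect_gt(-0.02, ci[1, "lower"])
  expect_lt(-0.02, ci[1, "upper"])

  # a participant observed at a single cue level is dropped with a warning
  solo <- rbind(trials,
                data.frame(participant_id = "solo", cue_number = 3L,
                           correct = c(TRUE, FALSE)))
  expect_warning(f2 <- fit_accuracy_model(solo), "solo")
  expect_equal(f2$n_individuals, 26L)
})
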