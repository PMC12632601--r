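test_that("satiation summaries compute the stated arithmetic", {
  ratings <- dplyr::tibble(
    participant = "P01", session = 1,
    odor = rep(c("sated", "non_sated"), each = 2),
    phase = rep(c("pre", "post"), 2),
    z_rating = c(0.5, -0.5, 0.4, 0.4))
  premeal <- dplyr::tibble(participant = "P01", session = 1,
                           pair_type = "sweet_vs_savory",
                           chose_sated = rep(c(1, 0), each = 9))
  s <- satiation_summaries(ratings, premeal)
  expect_equal(s$sat_idx, -1)
  expect_equal(s$base_pref, 0.5)

  # identical pre/post ratings: zero index
  flat <- dplyr::mutate(ratings, z_rating = 0.3)
  expect_equal(satiation_summaries(flat, premeal)$sat_idx, 0)

  expect_error(satiation_summaries(dplyr::filter(ratings, phase == "pre"),
                                   premeal),
               class = "devaltms_input_error")
})

test_that("discrimination-learning test detects learning and demands two runs", {
  co <- small_cohort()
  mc <- test_discrimination_learning(co$discrimination)
  expect_s3_class(mc, "model_comparison")
  expect_gte(mc$statistic, 0)
  expect_equal(mc$df, 1)
  expect_lt(mc$p_value, 0.05)
  run_coef <- mc$fixed_effects$estimate[mc$fixed_effects$term == "run"]
  expect_gt(run_coef, 0)

  expect_error(test_discrimination_learning(
    dplyr::filter(co$discrimination, run == 1)),
    class = "devaltms_df_error")
})

test_that("pleasantness-change model recovers a generated satiation effect", {
  plans <- make_session_plans(24, seed = 4)
  ratings <- simulate_ratings(plans, satiation_effect = -1, noise_sd = 0.3,
                              seed = 9)
  pc <- pleasant_change_table(ratings, rating_col = "raw_rating")
  mc <- test_pleasantness_change(pc)
  est <- unname(mc$fixed_effects$estimate[mc$fixed_effects$term == "is_sated"])
  expect_equal(est, -1, tolerance = 0.2)
  expect_lt(mc$p_value, 0.01)

  # constant ratings carry no satiation signal: zero likelihood ratio
  pc0 <- dplyr::mutate(pc, pleasant_change = 1)
  mc0 <- suppressMessages(suppressWarnings(test_pleasantness_change(pc0)))
  expect_equal(mc0$statistic, 0, tolerance = 1e-6)
})

test_that("satiation-index moderator tests reduce to zero for constant moderators and recover injected ones", {
  co <- small_cohort()
  satidx <- dplyr::left_join(
    co$satiation,
    dplyr::distinct(co$plans, participant, session, condition, target_group,
                    sated_odor),
    by = c("participant", "session"))

  const <- dplyr::mutate(satidx, condition = "SS")
  mc0 <- test_satidx_moderators(const, "condition")
  expect_equal(mc0$statistic, 0)

  injected <- dplyr::mutate(satidx,
                            sat_idx = sat_idx + 3 * (condition == "SC"))
  mc1 <- test_satidx_moderators(injected, "condition")
  expect_lt(mc1$p_value, 0.05)
})

test_that("probe-choice model enforces its contrast, bounds fitted probabilities, and finds group-specific effects", {
  tr <- sim_reduced_choice_cohort(beta_tms = 0, seed = 17)
  fit <- probe_choice_model(tr, "day2_tms", "aOFC")
  expect_true(all(fit$fitted$fitted_prob >= 0 & fit$fitted$fitted_prob <= 1))
  expect_equal(mean(fit$trials$fitted), mean(fit$trials$choice),
               tolerance = 0.02)

  # missing contrast sessions
  expect_error(probe_choice_model(dplyr::filter(tr, condition == "SS"),
                                  "day2_tms", "aOFC"),
               class = "devaltms_input_error")
  expect_error(probe_choice_model(tr, "day1_tms", "aOFC"),
               class = "devaltms_input_error")

  # group-by-TMS interaction detected when the effect is confined to one group
  co <- simulate_cohort(32, seed = 19,
                        effects = cohort_effects(beta_tms_day1 = 0,
                                                 beta_tms_day2 = 1.6,
                                                 day2_group = "pOFC",
                                                 fc_shift = 0))
  both <- probe_choice_model(co$probe_trials, "day2_tms", "both")
  expect_false(is.null(both$interaction))
  pofc <- probe_choice_model(co$probe_trials, "day2_tms", "pOFC")
  aofc <- probe_choice_model(co$probe_trials, "day2_tms", "aOFC")
  expect_lt(pofc$comparison$p_value, 0.05)
  expect_gt(pofc$comparison$fixed_effects$estimate[
    pofc$comparison$fixed_effects$term == "tms"], 0)
  expect_gt(aofc$comparison$p_value, pofc$comparison$p_value)
})

test_that("fit evaluation matches brute-force AUC and flags degenerate outcomes", {
  withr::with_seed(5, {
    scores <- runif(20)
    labels <- rbinom(20, 1, 0.5)
  })
  expect_equal(rank_auc(scores, labels), brute_auc(scores, labels))
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(rank_auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  }
  # perfect predictor
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # prediction independent of outcome hovers at one half
  withr::with_seed(8, {
    aucs <- replicate(50, rank_auc(runif(60), rbinom(60, 1, 0.5)))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
  expect_warning(auc_na <- rank_auc(runif(5), rep(1, 5)))
  expect_true(is.na(auc_na))

  tr <- sim_reduced_choice_cohort(beta_tms = 0.8, seed = 23)
  ev <- evaluate_fit(probe_choice_model(tr, "day2_tms", "aOFC"))
  expect_gt(ev$participant_correlation, 0.5)
  expect_true(all(ev$auc_by_condition$auc > 0.5))
})

test_that("leave-one-subject-out runs one refit per participant and exposes an outlier-driven effect", {
  tr <- sim_reduced_choice_cohort(beta_tms = 0.8, seed = 29, n_ppt = 10)
  loso <- loso_sensitivity(tr, "day2_tms", "aOFC")
  expect_equal(nrow(loso$p_values), 10)
  expect_equal(loso$median_p, median(loso$p_values$p_value))

  # constructed fixture: one extreme participant drives the effect
  make_ppt <- function(id, n, choice) {
    dplyr::tibble(participant = id, session = rep(1:2, each = n / 2),
                  condition = rep(c("SS", "SC"), each = n / 2),
                  target_group = "aOFC", choice = choice,
                  value_diff = 0.3, sat_idx = -1, base_pref = 0.5)
  }
  withr::with_seed(11, {
    null_ppts <- purrr::map_dfr(sprintf("N%02d", 1:7), function(id) {
      make_ppt(id, 40, rbinom(40, 1, 0.5))
    })
  })
  driver <- make_ppt("Z99", 80, c(rep(0, 40), rep(1, 40))) # choices track TMS
  fix <- dplyr::bind_rows(null_ppts, driver)
  p_full <- probe_choice_model(fix, "day2_tms", "aOFC")$comparison$p_value
  p_wo <- probe_choice_model(dplyr::filter(fix, participant != "Z99"),
                             "day2_tms", "aOFC")$comparison$p_value
  expect_lt(p_full, 0.05)
  expect_gt(p_wo, p_full)

  expect_error(loso_sensitivity(driver, "day2_tms", "aOFC"),
               class = "devaltms_input_error")
})

test_that("behavioral TMS effects are condition differences of fitted probabilities", {
  fitted_tbl <- dplyr::tibble(
    participant = c("P01", "P01", "P02", "P02", "P03"),
    target_group = "aOFC",
    condition = c("SS", "SC", "SS", "SC", "SS"),
    fitted_prob = c(0.4, 0.6, 0.5, 0.5, 0.3))
  expect_message(eff <- behavioral_tms_effect(fitted_tbl), "P03")
  expect_equal(eff$effect[eff$participant == "P01"], 0.2)
  expect_equal(eff$effect[eff$participant == "P02"], 0)
  expect_false("P03" %in% eff$participant)
})

test_that("the paired pre/post choice shift matches the rank-based oracle", {
  withr::with_seed(3, {
    rates <- dplyr::tibble(participant = sprintf("P%02d", 1:15),
                           pre_rate = runif(15, 0.4, 0.8))
    rates$post_rate <- rates$pre_rate - runif(15, 0, 0.3)
  })
  out <- paired_choice_shift(rates)
  # independent signed-rank statistic: sum of positive-difference ranks
  d <- rates$post_rate - rates$pre_rate
  v_oracle <- sum(rank(abs(d))[d > 0])
  expect_equal(out$statistic, v_oracle)
  expect_lt(out$p_value, 0.05)
  expect_lt(out$median_shift, 0)
})
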