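test_that("agent-parameter hierarchy matches its stated priors", {
  # Monte-Carlo check of the session-mean prior Beta(8, 2): mean 0.8
  p <- sample_agent_params(n_participants = 1, n_sessions = 1e5, n_pairs = 1,
                           seed = 11)
  expect_equal(mean(p$mu$mu), 0.8, tolerance = 0.003)
  expect_true(all(p$alpha$alpha > 0 & p$alpha$alpha < 1))
  expect_true(p$K > 0)
  expect_true(all(p$k$k > 0))

  # concentration limit: huge K and k collapse alpha onto mu
  h <- agent_hyper(K_shape = 1e7, K_rate = 1, k_shape = 1e7, k_rate = 1)
  p2 <- sample_agent_params(4, 2, 3, hyper = h, seed = 3)
  joined <- dplyr::left_join(p2$alpha,
                             dplyr::rename(p2$mu, mu_val = mu), by = "session")
  expect_lt(max(abs(joined$alpha - joined$mu_val)), 0.01)

  expect_error(agent_hyper(K_rate = -1), class = "devaltms_input_error")
})

test_that("simulated learners follow the closed-form value recursion", {
  pairs <- make_cue_pairs(1)
  sched <- make_discrimination_schedule(pairs, seed = 2)
  alphas <- dplyr::tibble(pair_id = 1:12,
                          alpha = seq(0.05, 0.95, length.out = 12))
  out <- simulate_learner(sched, alphas, seed = 1)
  expect_equal(out$w, 1 - 0.5 * (1 - out$alpha)^(out$presentation - 1))
  expect_true(all(out$w >= 0.5 & out$w < 1))

  # near-zero rate pins w at chance; near-one rate saturates from the
  # second presentation on
  lo <- simulate_learner(sched, dplyr::mutate(alphas, alpha = 1e-9), seed = 1)
  expect_equal(lo$w, rep(0.5, nrow(lo)), tolerance = 1e-6)
  hi <- simulate_learner(sched, dplyr::mutate(alphas, alpha = 1 - 1e-9), seed = 1)
  expect_equal(hi$w[hi$presentation >= 2], rep(1, sum(hi$presentation >= 2)),
               tolerance = 1e-6)

  expect_error(simulate_learner(dplyr::mutate(sched, phase = "premeal"),
                                alphas, 1),
               class = "devaltms_phase_error")
  expect_error(simulate_learner(sched, dplyr::mutate(alphas, alpha = 1), 1),
               class = "devaltms_input_error")

  # expected accuracy rises across runs for a learning cohort
  acc <- out |>
    dplyr::group_by(run) |>
    dplyr::summarise(w = mean(w))
  expect_true(all(diff(acc$w) > 0))
})

test_that("rating generator produces the stated satiation structure and z-scaling", {
  plans <- make_session_plans(6, seed = 2)
  # no shift, no noise: satiation index identically zero
  r0 <- simulate_ratings(plans, satiation_effect = 0, noise_sd = 0, seed = 1)
  pc0 <- satiation_summaries(r0, premeal_choices = dplyr::tibble(
    participant = character(), session = integer(),
    pair_type = character(), chose_sated = integer()))
  expect_equal(pc0$sat_idx, rep(0, nrow(pc0)))

  # shift -1, no noise: raw-scale pleasantness-change difference is -1
  r1 <- simulate_ratings(plans, satiation_effect = -1, noise_sd = 0, seed = 1)
  pc1 <- r1 |>
    dplyr::group_by(participant, session, odor) |>
    dplyr::summarise(change = raw_rating[phase == "post"] - raw_rating[phase == "pre"],
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = odor, values_from = change)
  expect_equal(pc1$sated - pc1$non_sated, rep(-1, nrow(pc1)))

  # z-ratings have mean 0, sd 1 within participant
  r2 <- simulate_ratings(plans, seed = 5)
  zs <- r2 |>
    dplyr::group_by(participant) |>
    dplyr::summarise(m = mean(z_rating), s = sd(z_rating))
  expect_equal(zs$m, rep(0, nrow(zs)), tolerance = 1e-12)
  expect_equal(zs$s, rep(1, nrow(zs)), tolerance = 1e-12)
})

test_that("probe-choice generator hits its logistic rates and is recovered by the fitting model", {
  base <- dplyr::tibble(participant = rep(sprintf("P%02d", 1:20), each = 200),
                        is_ctbs = rep(c(0, 1), 2000),
                        base_pref = 0, sat_idx = 0, value_diff = 0)
  flat <- simulate_probe_choices(base, choice_gen_config(
    intercept = 0, beta_base = 0, beta_sat = 0, beta_val = 0, beta_tms = 0,
    ranef_sd = 0), seed = 2)
  expect_lt(abs(mean(flat$choice) - 0.5), 0.02)

  tms <- simulate_probe_choices(base, choice_gen_config(
    intercept = 0, beta_base = 0, beta_sat = 0, beta_val = 0, beta_tms = 1,
    ranef_sd = 0), seed = 3)
  expect_lt(abs(mean(tms$choice[tms$is_ctbs == 1]) - plogis(1)), 0.025)
  expect_lt(abs(mean(tms$choice[tms$is_ctbs == 0]) - 0.5), 0.025)

  # generative model and fitting model are mirrors: beta_tms recovered
  tr <- sim_reduced_choice_cohort(beta_tms = 0.8, seed = 31, n_ppt = 48,
                                  trials_per = 36)
  fit <- probe_choice_model(tr, contrast = "day2_tms", group = "aOFC")
  est <- fit$comparison$fixed_effects$estimate[
    fit$comparison$fixed_effects$term == "tms"]
  expect_lt(abs(est - 0.8), 0.25)

  expect_error(simulate_probe_choices(dplyr::mutate(base, sat_idx = NA), ),
               class = "devaltms_input_error")
})

test_that("connectivity generator yields 331 labeled sessions and a raw-space shift", {
  plans <- make_session_plans(48, seed = 8)
  fc <- simulate_fc_sessions(plans, fc_gen_config(condition_shift = 0.8), seed = 8)
  expect_equal(nrow(fc$features), 331)
  expect_equal(nrow(fc$missing), 5)
  expect_equal(ncol(fc$features), 102)
  expect_setequal(unique(fc$labels$condition), c("null", "sham", "cTBS"))
  # 7 sessions per participant before removal: 1 null + 6 post-TMS
  full_counts <- dplyr::count(fc$labels, participant)
  expect_true(all(full_counts$n <= 7))

  # zero noise and zero shift: all of a participant's sessions identical
  fc0 <- simulate_fc_sessions(plans, fc_gen_config(condition_shift = 0,
                                                   noise_sd = 1e-12,
                                                   n_missing_sessions = 0),
                              seed = 1)
  p1 <- fc0$features[fc0$labels$participant == "P01", ]
  expect_lt(max(abs(sweep(p1, 2, p1[1, ]))), 1e-9)

  # injected shift separates cTBS from null in raw feature space
  dists <- function(obj) {
    sapply(unique(obj$labels$participant), function(p) {
      idx <- obj$labels$participant == p
      cond <- obj$labels$condition[idx]
      if (!any(cond == "null") || !any(cond == "cTBS") || !any(cond == "sham"))
        return(c(NA, NA))
      X <- obj$features[idx, , drop = FALSE]
      nl <- colMeans(X[cond == "null", , drop = FALSE])
      d <- sqrt(colSums((t(X) - nl)^2))
      c(mean(d[cond == "cTBS"]), mean(d[cond == "sham"]))
    })
  }
  dd <- dists(fc)
  expect_gt(mean(dd[1, ], na.rm = TRUE), mean(dd[2, ], na.rm = TRUE))

  expect_identical(simulate_fc_sessions(plans, seed = 3)$features,
                   simulate_fc_sessions(plans, seed = 3)$features)
  expect_error(simulate_fc_sessions(plans,
                                    fc_gen_config(n_missing_sessions = 400)),
               class = "devaltms_input_error")
})

test_that("full cohort simulation is deterministic and internally consistent", {
  co <- small_cohort()
  expect_equal(nrow(co$discrimination), 8 * 3 * 120)
  expect_equal(nrow(co$probe_trials), 8 * 3 * 36)
  expect_true(all(co$probe_trials$choice %in% 0:1))
  expect_true(all(co$satiation$base_pref >= 0 & co$satiation$base_pref <= 1))
  co2 <- simulate_cohort(8, seed = 42)
  expect_identical(co$probe_trials, co2$probe_trials)
  expect_identical(co$fc$features, co2$fc$features)
})
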