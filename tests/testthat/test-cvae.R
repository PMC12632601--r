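test_that("feature standardization is exact and invertible", {
  X <- matrix(c(0, 2, 1, 5), 2, 2)
  std <- standardize_features(X)
  expect_equal(std$X[, 1], c(-1, 1)) # population-SD convention
  expect_equal(colMeans(std$X), c(0, 0))
  expect_equal(unstandardize_features(std), X)

  withr::with_seed(1, Z <- scale(matrix(rnorm(200), 20)))
  Zp <- sweep(sweep(Z, 2, apply(Z, 2, function(x) sqrt(mean(x^2))), "/"), 2,
              colMeans(Z))
  restd <- standardize_features(Zp)
  expect_lt(max(abs(restd$X - Zp)), 1e-12)

  Xc <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(standardize_features(Xc), regexp = "b",
               class = "devaltms_input_error")
})

test_that("the latent KL term matches its closed forms", {
  expect_equal(kl_standard_normal(0, 0), 0, tolerance = 1e-10)
  expect_equal(kl_standard_normal(1, 0), 0.5, tolerance = 1e-10)
  expect_equal(kl_standard_normal(0, log(2)), 0.5 * (1 - log(2)),
               tolerance = 1e-10)
  # additivity over dimensions and rows
  expect_equal(kl_standard_normal(c(1, 0), c(0, log(2))),
               0.5 + 0.5 * (1 - log(2)), tolerance = 1e-10)
  expect_gte(kl_standard_normal(rnorm(10), rnorm(10)), 0)
  expect_error(kl_standard_normal(0, Inf), class = "devaltms_input_error")
})

test_that("condition-matching diagnostics agree with the median-centered ANOVA oracle", {
  withr::with_seed(21, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    g <- rep(c("null", "sham", "cTBS"), each = 10)
  })
  md <- matching_diagnostics(X, g)
  expect_equal(nrow(md$per_feature), 10)
  for (j in c(1, 5, 10)) {
    expect_equal(md$per_feature$bf_stat[j], brute_brown_forsythe(X[, j], g),
                 tolerance = 1e-10)
  }
  if (requireNamespace("car", quietly = TRUE)) {
    lt <- car::leveneTest(X[, 2], factor(g), center = median)
    expect_equal(md$per_feature$bf_stat[2], lt$`F value`[1], tolerance = 1e-10)
  }
  # well-matched groups: no q < 0.05 flags expected at this scale
  expect_lte(md$n_var_significant, 1)
  expect_lte(md$n_mean_significant, 1)

  # a variance-doubled feature is detected at large n
  withr::with_seed(22, {
    Xb <- matrix(rnorm(600 * 4), 600, 4)
    gb <- rep(c("sham", "cTBS"), each = 300)
    Xb[gb == "cTBS", 2] <- Xb[gb == "cTBS", 2] * 2
  })
  mdb <- matching_diagnostics(Xb, gb)
  expect_lt(mdb$per_feature$bf_q[2], 0.05)
  expect_gt(min(mdb$per_feature$bf_q[-2]), 0.05)

  expect_error(matching_diagnostics(X[1:3, ], c("a", "a", "b")),
               class = "devaltms_degenerate_error")
})

test_that("training is reproducible, decreases the loss, and can reconstruct separable structure", {
  plans <- make_session_plans(12, seed = 2)
  fc <- simulate_fc_sessions(plans, fc_gen_config(n_features = 30,
                                                  n_missing_sessions = 0),
                             seed = 2)
  std <- standardize_features(fc$features)
  cfg <- cvae_config(input_dim = 30, n_conditions = 12, epochs = 120)
  m1 <- train_cvae(std$X, fc$labels$participant, cfg,
                   tms_condition = fc$labels$condition)
  m2 <- train_cvae(std$X, fc$labels$participant, cfg,
                   tms_condition = fc$labels$condition)
  expect_identical(m1$loss, m2$loss) # bit-identical traces
  expect_identical(m1$params, m2$params)

  # epoch-averaged loss decreases; KL stays non-negative; total >= recon
  expect_lt(mean(tail(m1$loss$total, 20)), mean(head(m1$loss$total, 20)))
  expect_true(all(m1$loss$kl >= 0))
  expect_true(all(m1$loss$total >= m1$loss$recon))

  # noiseless participant-structured input is reconstructed faithfully
  withr::with_seed(5, means <- matrix(rnorm(8 * 16, 0, 2), 8))
  Xcap <- means[rep(1:8, each = 4), ]
  cond <- rep(sprintf("C%d", 1:8), each = 4)
  cap_cfg <- cvae_config(input_dim = 16, n_conditions = 8, hidden_units = 32,
                         latent_dim = 4, epochs = 1500, learning_rate = 3e-3)
  mcap <- train_cvae(standardize_features(Xcap)$X, cond, cap_cfg)
  rf <- reconstruction_fidelity(mcap, standardize_features(Xcap)$X, cond,
                                rep("sham", length(cond)))
  expect_gt(mean(rf$per_session$r), 0.95)

  expect_error(train_cvae(std$X, fc$labels$participant[-1], cfg),
               class = "devaltms_input_error")
  expect_error(train_cvae(std$X * 1e300, fc$labels$participant,
                          cvae_config(input_dim = 30, n_conditions = 12,
                                      epochs = 5, learning_rate = 10)),
               class = "devaltms_training_error")
})

test_that("inverse-condition resampling balances expected draws per condition", {
  plans <- make_session_plans(16, seed = 3)
  fc <- simulate_fc_sessions(plans, fc_gen_config(n_features = 20,
                                                  n_missing_sessions = 0),
                             seed = 3)
  std <- standardize_features(fc$features)
  cfg <- cvae_config(input_dim = 20, n_conditions = 16, epochs = 400,
                     resampling = "inverse_condition_weight")
  m <- train_cvae(std$X, fc$labels$participant, cfg,
                  tms_condition = fc$labels$condition)
  counts <- m$resampling_counts
  expect_equal(length(counts), 3)
  # expected share per condition is one third; allow Monte-Carlo slack
  shares <- counts / sum(counts)
  expect_lt(max(abs(shares - 1 / 3)), 0.03)

  expect_error(train_cvae(std$X, fc$labels$participant, cfg),
               class = "devaltms_input_error")
})

test_that("reconstruction fidelity summarizes correlations over the correct label partition", {
  plans <- make_session_plans(10, seed = 6)
  fc <- simulate_fc_sessions(plans, fc_gen_config(n_features = 24,
                                                  n_missing_sessions = 0),
                             seed = 6)
  std <- standardize_features(fc$features)
  cfg <- cvae_config(input_dim = 24, n_conditions = 10, epochs = 100)
  m <- train_cvae(std$X, fc$labels$participant, cfg)
  rf <- reconstruction_fidelity(m, std$X, fc$labels$participant,
                                fc$labels$condition)
  xhat <- reconstruct_cvae(m, std$X, fc$labels$participant)
  r_oracle <- sapply(seq_len(nrow(std$X)), function(i) cor(std$X[i, ], xhat[i, ]))
  expect_equal(rf$per_session$r, r_oracle, tolerance = 1e-12)
  hand_means <- tapply(r_oracle, fc$labels$condition, mean)
  expect_equal(rf$by_condition$mean_r[match(names(hand_means),
                                            rf$by_condition$tms_condition)],
               as.numeric(hand_means), tolerance = 1e-12)
  expect_false(is.null(rf$test))
})

test_that("latent distances, the paired test, and brain-behavior correlation obey their geometry", {
  labels <- dplyr::tibble(
    participant = rep(c("P01", "P02", "P03"), each = 4),
    condition = rep(c("null", "sham", "cTBS", "sham"), 3))
  # embeddings equal to the null embedding: all distances zero
  mu0 <- matrix(1, 12, 5)
  eff0 <- latent_distances(NULL, NULL, labels, mu = mu0)
  expect_equal(eff0$dist_sham, rep(0, 3))
  expect_equal(eff0$effect, rep(0, 3))

  # 3-4-5 triangle in the first two latent coordinates
  mu1 <- matrix(0, 12, 5)
  mu1[3, 1:2] <- c(3, 4) # P01 cTBS session
  eff1 <- latent_distances(NULL, NULL, labels, mu = mu1)
  expect_equal(eff1$dist_ctbs[eff1$participant == "P01"], 5)

  # participants missing a null or a condition are excluded with a message
  labels2 <- labels
  labels2$condition[labels2$participant == "P03" & labels2$condition == "null"] <- "sham"
  expect_message(eff2 <- latent_distances(NULL, NULL, labels2, mu = mu0), "P03")
  expect_equal(nrow(eff2), 2)
  expect_equal(attr(eff2, "excluded"), "P03")

  # paired test equals the brute-force t on any fixture
  withr::with_seed(31, {
    eff <- dplyr::tibble(participant = sprintf("P%02d", 1:12),
                         dist_sham = runif(12, 1, 2),
                         dist_ctbs = runif(12, 1.2, 2.4))
  })
  eff$effect <- eff$dist_ctbs - eff$dist_sham
  pt <- paired_effect_test(eff)
  expect_equal(pt$t, brute_paired_t(eff$dist_ctbs, eff$dist_sham),
               tolerance = 1e-12)
  expect_equal(pt$df, 11)

  # near-degenerate direction check: constant unit differences, tiny jitter
  jit <- dplyr::tibble(participant = c("a", "b", "c"),
                       dist_sham = c(1, 1, 1),
                       dist_ctbs = c(2, 2 + 1e-6, 2 - 1e-6))
  expect_gt(paired_effect_test(jit)$t, 1e4)
  degen <- dplyr::mutate(jit, dist_ctbs = 2)
  expect_warning(pt_d <- paired_effect_test(degen), "degenerate")
  expect_true(is.na(pt_d$t))

  # exact linear coupling gives r = 1 in the coupled group only
  neural <- dplyr::tibble(participant = sprintf("P%02d", 1:12),
                          effect = seq(-0.5, 0.6, length.out = 12))
  behavioral <- neural
  behavioral$effect <- ifelse(seq_len(12) <= 6, 2 * neural$effect,
                              withr::with_seed(4, rnorm(12))[seq_len(12)])
  groups <- dplyr::tibble(participant = neural$participant,
                          target_group = rep(c("aOFC", "pOFC"), each = 6))
  bb <- brain_behavior_correlation(neural, behavioral, groups)
  expect_equal(bb$r[bb$target_group == "aOFC"], 1, tolerance = 1e-12)
  expect_lt(abs(bb$r[bb$target_group == "pOFC"]), 0.99)
})

test_that("an injected connectivity shift is detected end-to-end and the dimension sweep runs per dim", {
  plans <- make_session_plans(48, seed = 14)
  fc <- simulate_fc_sessions(plans, fc_gen_config(condition_shift = 0.5),
                             seed = 14)
  std <- standardize_features(fc$features)
  cfg <- cvae_config(epochs = 300)
  m <- train_cvae(std$X, fc$labels$participant, cfg,
                  tms_condition = fc$labels$condition)
  eff <- suppressMessages(latent_distances(m, std$X, fc$labels))
  expect_equal(nrow(eff), 46) # two participants lack required sessions
  pt <- paired_effect_test(eff)
  expect_gt(pt$mean_diff, 0)
  expect_lt(pt$p_value, 0.05)

  sweep_res <- latent_dim_sweep(std$X, fc$labels, dims = c(2, 8),
                                config = cvae_config(epochs = 120))
  expect_equal(nrow(sweep_res), 2)
  expect_equal(sweep_res$latent_dim, c(2, 8))
  expect_true(all(is.na(sweep_res$error)))
  expect_error(latent_dim_sweep(std$X, fc$labels, dims = numeric(0)),
               class = "devaltms_input_error")
})
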