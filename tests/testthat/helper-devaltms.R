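# Shared fixtures (memoized so expensive objects are built once per run)
# and independent brute-force oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(8, seed = 42)
  }
  .fixtures$cohort
}

small_rw_fit <- function() {
  if (is.null(.fixtures$rw_fit)) {
    co <- small_cohort()
    resp <- dplyr::select(co$discrimination, participant, session, pair_id,
                          presentation, response, run)
    .fixtures$rw_fit <- suppressWarnings(
      fit_hierarchical_rw(resp, chains = 2, draws = 250, warmup = 250,
                          adapt = 150, seed = 7))
  }
  .fixtures$rw_fit
}

# Trial-by-trial likelihood oracle: explicitly carries one value per pair
# through the schedule, independent of the closed-form path.
brute_loglik <- function(trials, alphas) {
  w <- setNames(rep(0.5, nrow(alphas)), alphas$pair_id)
  a <- setNames(alphas$alpha, alphas$pair_id)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    p <- as.character(trials$pair_id[i])
    ll <- ll + dbinom(trials$response[i], 1, w[p], log = TRUE)
    w[p] <- w[p] + a[p] * (1 - w[p])
  }
  ll
}

# Pairwise-concordance AUC oracle (ties count one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# Median-centered one-way ANOVA F (Brown-Forsythe) from first principles.
brute_brown_forsythe <- function(x, g) {
  g <- as.factor(g)
  d <- abs(x - tapply(x, g, median)[g])
  k <- nlevels(g); n <- length(d)
  grand <- mean(d)
  ssb <- sum(tapply(d, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(d, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Paired-t oracle from the mean and SD of the differences.
brute_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Generic reduced probe-choice cohort for calibration/power simulations:
# one TMS contrast (SS vs SC), session-level covariates, trial-level
# value differences, all participants in one target group.
sim_reduced_choice_cohort <- function(beta_tms, seed, n_ppt = 24,
                                      trials_per = 18) {
  ppts <- sprintf("P%02d", seq_len(n_ppt))
  sess <- tidyr::crossing(participant = ppts, condition = c("SS", "SC"))
  withr::with_seed(seed, {
    sess$base_pref <- rbeta(nrow(sess), 2, 2)
    sess$sat_idx <- rnorm(nrow(sess), -1, 0.5)
  })
  trials <- sess[rep(seq_len(nrow(sess)), each = trials_per), ]
  withr::with_seed(seed + 1, {
    trials$value_diff <- rnorm(nrow(trials), 0.3, 0.15)
  })
  trials$is_ctbs <- as.integer(trials$condition == "SC")
  trials$session <- ifelse(trials$condition == "SS", 1L, 2L)
  trials$target_group <- "aOFC"
  simulate_probe_choices(trials, choice_gen_config(beta_tms = beta_tms),
                         seed = seed + 2)
}
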