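# Synthetic cohort generation: learning-rate hierarchy, Rescorla-Wagner
# learners, pleasantness ratings under selective satiation, probe choices,
# and session-wise functional-connectivity vectors.

#' Hyperparameters of the learning-rate hierarchy
#'
#' Defaults follow the hierarchical priors used for modeling discrimination
#' learning: session-level population means `mu_c ~ Beta(8, 2)`, population
#' concentration `K ~ Gamma(shape = 1, rate = 0.1)`, and per-participant
#' concentrations `k_j ~ Gamma(shape = 1, rate = 0.1)`. Subject-session
#' means follow `a_jc ~ Beta(mu_c * K, (1 - mu_c) * K)` and pair-level
#' learning rates `alpha_jcp ~ Beta(a_jc * k_j, (1 - a_jc) * k_j)`
#' (mean/concentration parameterization).
#'
#' @param mu_shape1,mu_shape2 Beta shapes of the session population mean.
#' @param K_shape,K_rate Gamma shape/rate of the population concentration.
#' @param k_shape,k_rate Gamma shape/rate of the participant concentration.
#' @return A named list of hyperparameters.
#' @export
agent_hyper <- function(mu_shape1 = 8, mu_shape2 = 2,
                        K_shape = 1, K_rate = 0.1,
                        k_shape = 1, k_rate = 0.1) {
  for (nm in c("mu_shape1", "mu_shape2", "K_shape", "K_rate", "k_shape", "k_rate")) {
    check_scalar_number(get(nm), nm, min = 0, open = TRUE)
  }
  list(mu_shape1 = mu_shape1, mu_shape2 = mu_shape2,
       K_shape = K_shape, K_rate = K_rate, k_shape = k_shape, k_rate = k_rate)
}

#' Sample agent parameters from the learning-rate hierarchy
#'
#' Draws the full hierarchy: session population means, population
#' concentration, participant concentrations, subject-session mean learning
#' rates, and pair-level learning rates. All beta draws are clamped to the
#' open unit interval for numerical safety.
#'
#' @param n_participants,n_sessions,n_pairs Cohort dimensions.
#' @param hyper Hyperparameters from [agent_hyper()].
#' @param seed Integer seed.
#' @param participants Optional character labels (default `"P01"`, ...).
#' @return A list of class `"agent_params"` with tibbles `mu` (session-level
#'   means), `k` (participant concentrations), `a` (subject-session means),
#'   `alpha` (pair-level learning rates) and the scalar `K`.
#' @examples
#' p <- sample_agent_params(4, seed = 1)
#' head(p$alpha)
#' @export
sample_agent_params <- function(n_participants = 48, n_sessions = 3, n_pairs = 12,
                                hyper = agent_hyper(), seed = 1,
                                participants = NULL) {
  check_scalar_number(n_participants, "n_participants", min = 1, integer = TRUE)
  check_scalar_number(n_sessions, "n_sessions", min = 1, integer = TRUE)
  check_scalar_number(n_pairs, "n_pairs", min = 1, integer = TRUE)
  participants <- participants %||% sprintf("P%02d", seq_len(n_participants))
  eps <- 1e-6
  withr::with_seed(derive_seed(seed, "agent-params"), {
    mu <- tibble(session = seq_len(n_sessions),
                 mu = clamp(rbeta(n_sessions, hyper$mu_shape1, hyper$mu_shape2),
                            eps, 1 - eps))
    K <- rgamma(1, hyper$K_shape, rate = hyper$K_rate)
    k <- tibble(participant = participants,
                k = rgamma(n_participants, hyper$k_shape, rate = hyper$k_rate))
    a <- tidyr::crossing(participant = participants, session = seq_len(n_sessions)) |>
      left_join(mu, by = "session") |>
      mutate(a = clamp(rbeta(n(), .data$mu * K, (1 - .data$mu) * K), eps, 1 - eps)) |>
      select("participant", "session", "a")
    alpha <- tidyr::crossing(participant = participants,
                             session = seq_len(n_sessions),
                             pair_id = seq_len(n_pairs)) |>
      left_join(a, by = c("participant", "session")) |>
      left_join(k, by = "participant") |>
      mutate(alpha = clamp(rbeta(n(), .data$a * .data$k, (1 - .data$a) * .data$k),
                           eps, 1 - eps)) |>
      select("participant", "session", "pair_id", "alpha")
    structure(list(mu = mu, K = K, k = k, a = a, alpha = alpha),
              class = "agent_params")
  })
}

#' Simulate a Rescorla-Wagner learner on a discrimination schedule
#'
#' The learner tracks one value `w` per odor-predictive stimulus,
#' initialized at 0.5, and on each presentation of that pair updates
#' `w <- w + alpha * (1 - w)` after responding. Responses are Bernoulli
#' draws of the pre-update `w` (1 = odor-predictive stimulus chosen).
#'
#' @param schedule A discrimination trial tibble (see
#'   [make_discrimination_schedule()]); every row must have
#'   `phase == "discrimination"`.
#' @param alphas Tibble with `pair_id`, `alpha` (one learning rate per pair,
#'   each in the open unit interval).
#' @param seed Integer seed.
#' @return The schedule with added columns `presentation` (per-pair
#'   presentation count), `w` (pre-update value used on the trial), and
#'   `response`.
#' @export
simulate_learner <- function(schedule, alphas, seed = 1) {
  check_columns(schedule, c("trial_index", "phase", "pair_id"), "schedule")
  check_columns(alphas, c("pair_id", "alpha"), "alphas")
  if (!all(schedule$phase == "discrimination")) {
    abort("`schedule` must contain only discrimination-phase trials.",
          class = "devaltms_phase_error")
  }
  if (any(alphas$alpha <= 0 | alphas$alpha >= 1)) {
    abort("All learning rates must lie in the open interval (0, 1).",
          class = "devaltms_input_error")
  }
  out <- schedule |>
    arrange(.data$trial_index) |>
    left_join(select(alphas, "pair_id", "alpha"), by = "pair_id") |>
    group_by(.data$pair_id) |>
    mutate(presentation = row_number(),
           w = 1 - 0.5 * (1 - .data$alpha)^(.data$presentation - 1)) |>
    ungroup()
  if (anyNA(out$alpha)) {
    abort("`alphas` must provide a learning rate for every pair in the schedule.",
          class = "devaltms_input_error")
  }
  withr::with_seed(derive_seed(seed, "learner"), {
    out$response <- rbinom(nrow(out), 1, out$w)
  })
  out
}

#' Simulate pre/post-meal odor pleasantness ratings
#'
#' Raw ratings live on a -10..10 visual-analog scale. Per participant and
#' session, pre-meal ratings of the two selected odors are near-matched;
#' after the meal the rating of the sated (meal-matched) odor is shifted by
#' `satiation_effect`. Ratings are then z-scored within each participant
#' across all of their sessions, odors, and phases, matching the analysis
#' convention for individual scale use.
#'
#' @param plans Session plans from [make_session_plans()].
#' @param satiation_effect Shift (raw scale, typically negative) applied to
#'   the post-meal rating of the sated odor.
#' @param baseline_mean,baseline_sd Mean and SD of the participant-level
#'   baseline pleasantness of the selected odors.
#' @param noise_sd SD of the per-rating noise (raw scale).
#' @param seed Integer seed.
#' @return A tibble with one row per participant x session x odor x phase:
#'   `participant`, `session`, `odor` (`"sated"`/`"non_sated"`), `phase`
#'   (`"pre"`/`"post"`), `raw_rating`, `z_rating`.
#' @export
simulate_ratings <- function(plans, satiation_effect = -2, baseline_mean = 2,
                             baseline_sd = 1, noise_sd = 1, seed = 1) {
  check_columns(plans, c("participant", "session"), "plans")
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  grid <- tidyr::crossing(distinct(plans, .data$participant),
                          session = sort(unique(plans$session)),
                          odor = c("sated", "non_sated"),
                          phase = c("pre", "post"))
  withr::with_seed(derive_seed(seed, "ratings"), {
    base <- distinct(plans, .data$participant) |>
      mutate(base = rnorm(n(), baseline_mean, baseline_sd))
    out <- grid |>
      left_join(base, by = "participant") |>
      mutate(
        raw_rating = .data$base + rnorm(n(), 0, noise_sd) +
          ifelse(.data$odor == "sated" & .data$phase == "post", satiation_effect, 0),
        raw_rating = clamp(.data$raw_rating, -10, 10)
      )
  })
  out |>
    group_by(.data$participant) |>
    mutate(z_rating = if (sd(.data$raw_rating) > 0) {
      (.data$raw_rating - mean(.data$raw_rating)) / sd(.data$raw_rating)
    } else rep(0, n())) |>
    ungroup() |>
    select("participant", "session", "odor", "phase", "raw_rating", "z_rating")
}

#' Generative configuration of the probe-choice model
#'
#' Mirror of the covariate structure used to analyze post-meal probe
#' choices: the log-odds of choosing the sated-odor option are
#' `intercept + u_j + beta_base * BasePref + beta_sat * SatIdx +
#' beta_val * ValueDiff + beta_tms * 1[cTBS]`, with participant random
#' intercepts `u_j ~ N(0, ranef_sd^2)`.
#'
#' @param intercept Fixed intercept (log-odds).
#' @param beta_base Weight on the pre-meal baseline preference (0..1 scale).
#' @param beta_sat Weight on the satiation index (z-scale).
#' @param beta_val Weight on the learned value difference.
#' @param beta_tms Additive log-odds effect of cTBS.
#' @param ranef_sd SD of the participant random intercept.
#' @return A named list.
#' @export
choice_gen_config <- function(intercept = -1.5, beta_base = 3, beta_sat = 0.8,
                              beta_val = 1.5, beta_tms = 0, ranef_sd = 0.5) {
  vals <- list(intercept = intercept, beta_base = beta_base, beta_sat = beta_sat,
               beta_val = beta_val, beta_tms = beta_tms, ranef_sd = ranef_sd)
  purrr::iwalk(vals, function(v, nm) check_scalar_number(v, nm))
  check_scalar_number(ranef_sd, "ranef_sd", min = 0)
  vals
}

#' Simulate probe-choice responses from trial covariates
#'
#' @param trials Probe-trial tibble with columns `participant`, `is_ctbs`
#'   (0/1), `base_pref`, `sat_idx`, `value_diff`.
#' @param config Generative coefficients from [choice_gen_config()].
#' @param seed Integer seed (also drives the participant random intercepts).
#' @return `trials` with added columns `p_sated` (choice probability) and
#'   `choice` (1 = sated-odor option chosen).
#' @export
simulate_probe_choices <- function(trials, config = choice_gen_config(), seed = 1) {
  check_columns(trials, c("participant", "is_ctbs", "base_pref", "sat_idx",
                          "value_diff"), "trials")
  if (anyNA(trials[c("is_ctbs", "base_pref", "sat_idx", "value_diff")])) {
    abort("Probe-trial covariates contain missing values.",
          class = "devaltms_input_error")
  }
  ppts <- sort(unique(trials$participant))
  withr::with_seed(derive_seed(seed, "probe-ranef"), {
    u <- setNames(rnorm(length(ppts), 0, config$ranef_sd), ppts)
  })
  eta <- config$intercept + u[trials$participant] +
    config$beta_base * trials$base_pref +
    config$beta_sat * trials$sat_idx +
    config$beta_val * trials$value_diff +
    config$beta_tms * trials$is_ctbs
  withr::with_seed(derive_seed(seed, "probe-choices"), {
    trials |>
      mutate(p_sated = logistic(eta),
             choice = rbinom(n(), 1, .data$p_sated))
  })
}

#' Generative configuration of synthetic connectivity sessions
#'
#' @param n_features Length of each session's connectivity vector.
#' @param subject_signature_sd SD of the stable participant signature.
#' @param condition_shift Either a scalar (recycled across features) or a
#'   length-`n_features` vector added to cTBS sessions.
#' @param noise_sd SD of session-level noise.
#' @param n_missing_sessions Number of (participant, session) entries
#'   removed cohort-wide (default 5).
#' @return A named list of class `"fc_gen_config"`.
#' @export
fc_gen_config <- function(n_features = 102, subject_signature_sd = 1,
                          condition_shift = 0.5, noise_sd = 1,
                          n_missing_sessions = 5) {
  check_scalar_number(n_features, "n_features", min = 2, integer = TRUE)
  check_scalar_number(subject_signature_sd, "subject_signature_sd", min = 0, open = TRUE)
  check_scalar_number(noise_sd, "noise_sd", min = 0, open = TRUE)
  check_scalar_number(n_missing_sessions, "n_missing_sessions", min = 0, integer = TRUE)
  if (!length(condition_shift) %in% c(1L, n_features) || anyNA(condition_shift)) {
    abort("`condition_shift` must be a scalar or length-n_features vector.",
          class = "devaltms_input_error")
  }
  structure(list(n_features = as.integer(n_features),
                 subject_signature_sd = subject_signature_sd,
                 condition_shift = rep(condition_shift, length.out = n_features),
                 noise_sd = noise_sd,
                 n_missing_sessions = as.integer(n_missing_sessions)),
            class = "fc_gen_config")
}

# Fixed default set of removed scans: one participant loses the null
# baseline, one loses both cTBS sessions, and two lose one sham session
# each. With 48 participants this leaves 331 retained sessions and 46
# participants eligible for the paired latent-distance analysis.
default_missing_sessions <- function(labels) {
  ppts <- sort(unique(labels$participant))
  pick <- function(i) ppts[min(i, length(ppts))]
  rules <- list(
    list(participant = pick(7), condition = "null", which = 1),
    list(participant = pick(19), condition = "cTBS", which = 1),
    list(participant = pick(19), condition = "cTBS", which = 2),
    list(participant = pick(31), condition = "sham", which = 2),
    list(participant = pick(40), condition = "sham", which = 3)
  )
  purrr::map_chr(rules, function(r) {
    rows <- filter(labels, .data$participant == r$participant,
                   .data$condition == r$condition)
    rows$session_uid[min(r$which, nrow(rows))]
  }) |> unique()
}

#' Simulate session-wise connectivity vectors for a cohort
#'
#' Each participant contributes 7 resting-state sessions (1 unstimulated
#' null baseline plus 6 post-TMS scans across the three two-day sessions).
#' A session's feature vector is the participant's stable signature plus a
#' condition shift on cTBS sessions plus independent noise. A configurable
#' set of (participant, session) entries is removed to emulate missing
#' scans (default 5, leaving 331 of 336 sessions at n = 48).
#'
#' @param plans Session plans from [make_session_plans()].
#' @param config Generator settings from [fc_gen_config()].
#' @param seed Integer seed.
#' @param missing Optional character vector of session uids
#'   (`"participant:label"`) to remove; `NULL` uses the fixed default set
#'   of `n_missing_sessions` entries.
#' @return A list of class `"fc_sessions"`: `features` (sessions x features
#'   matrix, rownames = session uid), `labels` (tibble `session_uid`,
#'   `participant`, `session_label`, `condition`), `missing` (labels of
#'   removed sessions), and `config`.
#' @export
simulate_fc_sessions <- function(plans, config = fc_gen_config(), seed = 1,
                                 missing = NULL) {
  check_columns(plans, c("participant", "session", "condition"), "plans")
  ppts <- sort(unique(plans$participant))
  labels <- purrr::map_dfr(ppts, function(p) {
    pl <- filter(plans, .data$participant == p) |> arrange(.data$session)
    day_cond <- purrr::map_dfr(seq_len(nrow(pl)), function(i) {
      cond <- pl$condition[i]
      tibble(session_label = sprintf("ses%d_day%d", pl$session[i], 1:2),
             condition = c(ifelse(cond == "CS", "cTBS", "sham"),
                           ifelse(cond == "SC", "cTBS", "sham")))
    })
    bind_rows(tibble(session_label = "null", condition = "null"), day_cond) |>
      mutate(participant = p)
  }) |>
    mutate(session_uid = paste(.data$participant, .data$session_label, sep = ":")) |>
    select("session_uid", "participant", "session_label", "condition")

  total <- nrow(labels)
  if (config$n_missing_sessions >= total) {
    abort("`n_missing_sessions` must be smaller than the total session count.",
          class = "devaltms_input_error")
  }
  withr::with_seed(derive_seed(seed, "fc-sessions"), {
    signature <- matrix(rnorm(length(ppts) * config$n_features, 0,
                              config$subject_signature_sd),
                        nrow = length(ppts),
                        dimnames = list(ppts, NULL))
    noise <- matrix(rnorm(total * config$n_features, 0, config$noise_sd),
                    nrow = total)
    X <- signature[labels$participant, , drop = FALSE] + noise
    is_ctbs <- labels$condition == "cTBS"
    X[is_ctbs, ] <- sweep(X[is_ctbs, , drop = FALSE], 2, config$condition_shift, "+")
    rownames(X) <- labels$session_uid
  })

  if (is.null(missing) && config$n_missing_sessions > 0) {
    missing <- head(default_missing_sessions(labels), config$n_missing_sessions)
  }
  missing <- missing %||% character(0)
  bad <- setdiff(missing, labels$session_uid)
  if (length(bad) > 0) {
    abort(sprintf("Unknown session uid(s) in `missing`: %s.",
                  paste(bad, collapse = ", ")), class = "devaltms_input_error")
  }
  keep <- !(labels$session_uid %in% missing)
  structure(list(features = X[keep, , drop = FALSE],
                 labels = labels[keep, ],
                 missing = filter(labels, !keep),
                 config = config),
            class = "fc_sessions")
}

#' Study-condition effect sizes for cohort simulation
#'
#' Defaults emulate the effect structure reported for the study: a robust
#' selective-satiation shift in ratings, a cTBS effect on probe choices in
#' the posterior-OFC group when stimulation precedes the meal (Day 2) and
#' in the anterior-OFC group when it precedes learning (Day 1), and a
#' condition shift in cTBS connectivity sessions.
#'
#' @param satiation Raw-scale post-meal shift of the sated odor's rating.
#' @param beta_tms_day1,beta_tms_day2 Log-odds cTBS effects on sated-odor
#'   choices for the Day 1 (`"CS"`) and Day 2 (`"SC"`) stimulation contrasts.
#' @param day1_group,day2_group Target groups in which those effects act.
#' @param fc_shift Connectivity condition shift (per feature) on cTBS
#'   sessions.
#' @return A named list.
#' @export
cohort_effects <- function(satiation = -2, beta_tms_day1 = 0.8,
                           beta_tms_day2 = 0.8, day1_group = "aOFC",
                           day2_group = "pOFC", fc_shift = 0.5) {
  list(satiation = satiation, beta_tms_day1 = beta_tms_day1,
       beta_tms_day2 = beta_tms_day2, day1_group = day1_group,
       day2_group = day2_group, fc_shift = fc_shift)
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator covering every data stream the analysis consumes:
#' session plans, cue pairs, discrimination schedules and learner responses,
#' pleasantness ratings, pre-meal choices (baseline preference), post-meal
#' probe choices with their generative covariates, and session-wise
#' connectivity vectors.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; all streams derive their own seeds from it.
#' @param effects Effect sizes from [cohort_effects()].
#' @param hyper Learning-rate hyperparameters from [agent_hyper()].
#' @param choice_config Baseline probe-choice coefficients (its `beta_tms`
#'   is ignored; TMS effects come from `effects`).
#' @param fc_config Connectivity generator settings; its `condition_shift`
#'   is overridden by `effects$fc_shift`.
#' @param n_runs Discrimination runs per session.
#' @param realized Passed to [make_session_plans()].
#' @return A list of class `"cohort_sim"` with elements `plans`, `pairs`,
#'   `params`, `discrimination` (trials with learner responses), `ratings`,
#'   `premeal_choices`, `probe_trials` (post-meal sweet-vs-savory trials
#'   with covariates and simulated choices), `satiation` (per-session
#'   summaries), `fc` (an `"fc_sessions"` object), and `seed`.
#' @export
simulate_cohort <- function(n_participants = 48, seed = 1,
                            effects = cohort_effects(),
                            hyper = agent_hyper(),
                            choice_config = choice_gen_config(),
                            fc_config = fc_gen_config(),
                            n_runs = 5, realized = FALSE) {
  plans <- make_session_plans(n_participants, seed = seed, realized = realized)
  params <- sample_agent_params(n_participants, n_sessions = 3, n_pairs = 12,
                                hyper = hyper, seed = derive_seed(seed, "params"),
                                participants = sort(unique(plans$participant)))
  pairs <- purrr::map(1:3, make_cue_pairs)

  sessions <- distinct(plans, .data$participant, .data$session,
                       .data$condition, .data$sated_odor, .data$target_group)

  # Day 1: discrimination schedules + simulated learners.
  discrimination <- purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    p <- sessions$participant[i]; s <- sessions$session[i]
    sched <- make_discrimination_schedule(pairs[[s]], n_runs = n_runs,
                                          participant = p, session = s, seed = seed)
    al <- filter(params$alpha, .data$participant == p, .data$session == s)
    simulate_learner(sched, al, seed = derive_seed(seed, p, s, "learn")) |>
      mutate(participant = p, session = s)
  })

  ratings <- simulate_ratings(plans, satiation_effect = effects$satiation,
                              seed = derive_seed(seed, "ratings"))

  # Participant-level latent sweetness preference drives pre-meal choices.
  ppts <- sort(unique(plans$participant))
  withr::with_seed(derive_seed(seed, "sweet-pref"), {
    sweet_pref <- setNames(rnorm(length(ppts), 0, 1), ppts)
  })

  premeal_choices <- purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    p <- sessions$participant[i]; s <- sessions$session[i]
    sated <- sessions$sated_odor[i]
    sched <- make_premeal_test(pairs[[s]], seed = derive_seed(seed, p, s, "premeal"))
    sched <- mutate(sched, participant = p, session = s)
    sated_side_left <- sched$left_category == sated
    is_svs <- sched$pair_type == "sweet_vs_savory"
    pref_dir <- if (sated == "sweet") sweet_pref[p] else -sweet_pref[p]
    p_choose <- ifelse(is_svs, logistic(pref_dir), logistic(2))
    withr::with_seed(derive_seed(seed, p, s, "premeal-choice"), {
      # For sweet-vs-savory trials the tracked event is choosing the sated
      # option; for odor-vs-air trials, choosing the odor option.
      chose <- rbinom(nrow(sched), 1, p_choose)
    })
    mutate(sched, chose_sated = ifelse(is_svs, chose, NA_integer_),
           chose_odor = ifelse(is_svs, NA_integer_, chose),
           sated_left = sated_side_left)
  })

  satiation <- satiation_summaries(ratings, premeal_choices)

  # Terminal learned values per discrimination pair (generative truth).
  w_final <- discrimination |>
    group_by(.data$participant, .data$session, .data$pair_id) |>
    summarise(n_pres = max(.data$presentation), alpha = .data$alpha[1],
              .groups = "drop") |>
    mutate(w_final = 1 - 0.5 * (1 - .data$alpha)^.data$n_pres)

  probe_trials <- purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    p <- sessions$participant[i]; s <- sessions$session[i]
    sated <- sessions$sated_odor[i]
    sched <- make_postmeal_test(pairs[[s]], seed = derive_seed(seed, p, s, "postmeal")) |>
      filter(.data$pair_type == "sweet_vs_savory") |>
      mutate(participant = p, session = s,
             condition = sessions$condition[i],
             target_group = sessions$target_group[i],
             sated_odor = sated)
    wf <- filter(w_final, .data$participant == p, .data$session == s)
    wmap <- setNames(wf$w_final, wf$pair_id)
    # stim_1 is always sweet, stim_2 savory in sweet-vs-savory pairs.
    w_sweet <- wmap[as.character(sched$src_pair_1)]
    w_savory <- wmap[as.character(sched$src_pair_2)]
    sat <- filter(satiation, .data$participant == p, .data$session == s)
    sched |>
      mutate(
        value_diff = if (sated == "sweet") w_sweet - w_savory else w_savory - w_sweet,
        sat_idx = sat$sat_idx[1],
        base_pref = sat$base_pref[1],
        is_ctbs_day1 = as.integer(.data$condition == "CS"),
        is_ctbs_day2 = as.integer(.data$condition == "SC")
      )
  })

  # TMS effects act group-specifically; fold them into a single generative
  # is_ctbs term by scaling, then simulate with the base configuration.
  eta_tms <- effects$beta_tms_day1 * probe_trials$is_ctbs_day1 *
    (probe_trials$target_group == effects$day1_group) +
    effects$beta_tms_day2 * probe_trials$is_ctbs_day2 *
    (probe_trials$target_group == effects$day2_group)
  cfg <- choice_config
  cfg$beta_tms <- 1
  probe_trials <- simulate_probe_choices(mutate(probe_trials, is_ctbs = eta_tms),
                                         config = cfg,
                                         seed = derive_seed(seed, "probe")) |>
    mutate(is_ctbs = NULL)

  fc_cfg <- fc_config
  fc_cfg$condition_shift <- rep(effects$fc_shift, length.out = fc_cfg$n_features)
  fc <- simulate_fc_sessions(plans, config = fc_cfg,
                             seed = derive_seed(seed, "fc"))

  structure(list(plans = plans, pairs = pairs, params = params,
                 discrimination = discrimination, ratings = ratings,
                 premeal_choices = premeal_choices, satiation = satiation,
                 probe_trials = probe_trials, w_final = w_final, fc = fc,
                 effects = effects, seed = seed),
            class = "cohort_sim")
}
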