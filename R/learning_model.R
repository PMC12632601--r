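# Hierarchical Bayesian Rescorla-Wagner model of discrimination learning:
# closed-form value updates, Bernoulli response likelihood, JAGS fit with
# session-wise Beta/Gamma priors, and posterior value trajectories.

#' Rescorla-Wagner value update
#'
#' On each presentation of an odor-predictive stimulus, its value moves
#' toward the delivered outcome (coded 1) by a fraction `alpha` of the
#' prediction error: `w + alpha * (1 - w)`.
#'
#' @param w Current value(s) in `[0, 1]`.
#' @param alpha Learning rate(s) in the open interval `(0, 1)`.
#' @return Updated value(s).
#' @examples
#' rw_update(0.5, 0.3)
#' @export
rw_update <- function(w, alpha) {
  if (!is.numeric(w) || anyNA(w) || any(w < 0 | w > 1)) {
    abort("`w` must lie in [0, 1].", class = "devaltms_input_error")
  }
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie in the open interval (0, 1).",
          class = "devaltms_input_error")
  }
  w + alpha * (1 - w)
}

#' Closed-form Rescorla-Wagner value after n updates
#'
#' Starting from `w = 0.5`, n applications of the update rule give
#' `1 - 0.5 * (1 - alpha)^n`.
#'
#' @param alpha Learning rate(s) in `(0, 1)`.
#' @param n Number of updates (>= 0), vectorized.
#' @return Value(s) after `n` updates.
#' @export
rw_value <- function(alpha, n) {
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie in the open interval (0, 1).",
          class = "devaltms_input_error")
  }
  if (any(n < 0)) abort("`n` must be non-negative.", class = "devaltms_input_error")
  1 - 0.5 * (1 - alpha)^n
}

#' Pre-update value trajectory of one pair
#'
#' Returns the sequence of values in force on presentations `1..n` (the
#' pre-update `w` that generates the response on each presentation).
#'
#' @inheritParams rw_value
#' @param n Number of presentations.
#' @return Numeric vector of length `n`; element k is
#'   `1 - 0.5 * (1 - alpha)^(k - 1)`.
#' @export
rw_trajectory <- function(alpha, n) {
  check_scalar_number(n, "n", min = 1, integer = TRUE)
  rw_value(alpha, seq_len(n) - 1)
}

#' Bernoulli log-likelihood of discrimination responses
#'
#' Sums the Bernoulli log-mass of each response under the pre-update value
#' of its pair at that presentation. A response contradicting a degenerate
#' value (`w` exactly 0 or 1) yields `-Inf` with a warning.
#'
#' @param responses Tibble with columns `pair_id`, `presentation` (1-based
#'   per-pair presentation count), `response` (0/1).
#' @param alphas Tibble with `pair_id`, `alpha`.
#' @return Scalar log-likelihood.
#' @export
rw_log_likelihood <- function(responses, alphas) {
  check_columns(responses, c("pair_id", "presentation", "response"), "responses")
  check_columns(alphas, c("pair_id", "alpha"), "alphas")
  df <- left_join(responses, select(alphas, "pair_id", "alpha"), by = "pair_id")
  if (anyNA(df$alpha)) {
    abort("Missing learning rate for at least one pair.",
          class = "devaltms_input_error")
  }
  w <- 1 - 0.5 * (1 - df$alpha)^(df$presentation - 1)
  ll <- dbinom(df$response, 1, w, log = TRUE)
  if (any(is.infinite(ll))) {
    warn("Response contradicts a degenerate value (w of 0 or 1); log-likelihood is -Inf.")
  }
  sum(ll)
}

rw_model_string <- function(prior_reading = c("mean_concentration", "literal"),
                            hyper = agent_hyper(), include_likelihood = TRUE) {
  prior_reading <- match.arg(prior_reading)
  a_line <- switch(prior_reading,
    mean_concentration = "a[s] ~ dbeta(mu[sess[s]] * K, (1 - mu[sess[s]]) * K) T(0.001, 0.999)",
    literal = "a[s] ~ dbeta(mu[sess[s]] * K, 1 - mu[sess[s]] * K) T(0.001, 0.999)")
  alpha_line <- switch(prior_reading,
    mean_concentration = "alpha[p] ~ dbeta(a[ssrow[p]] * k[subj[p]], (1 - a[ssrow[p]]) * k[subj[p]]) T(0.001, 0.999)",
    literal = "alpha[p] ~ dbeta(a[ssrow[p]] * k[subj[p]], 1 - a[ssrow[p]] * k[subj[p]]) T(0.001, 0.999)")
  lik_block <- if (include_likelihood) "
  for (i in 1:n_tr) {
    w[i] <- min(1 - 0.5 * pow(1 - alpha[pairrow[i]], pres[i] - 1), 0.9999999)
    y[i] ~ dbern(w[i])
  }" else ""
  sprintf("model {
  K ~ dgamma(%g, %g)
  for (c in 1:n_c) { mu[c] ~ dbeta(%g, %g) }
  for (j in 1:n_j) { k[j] ~ dgamma(%g, %g) }
  for (s in 1:n_ss) { %s }
  for (p in 1:n_pr) { %s }%s
}", hyper$K_shape, hyper$K_rate, hyper$mu_shape1, hyper$mu_shape2,
    hyper$k_shape, hyper$k_rate, a_line, alpha_line, lik_block)
}

# Split-Rhat (Gelman et al. 2013): split each chain in half, compute the
# classic potential scale reduction over the 2 * n_chains half-chains.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical Bayesian Rescorla-Wagner model
#'
#' Fits the session-wise hierarchy (population means `mu_c ~ Beta(8, 2)`,
#' concentrations `K, k_j ~ Gamma(1, 0.1)`, subject-session means `a_jc`,
#' pair-level learning rates `alpha_jcp`) to binary discrimination
#' responses, with the Bernoulli response model on the closed-form
#' pre-update values. Sampling is done in JAGS with beta nodes truncated
#' away from the unit-interval boundaries; split-Rhat and effective sample
#' sizes are attached to every fit and a warning is raised when split-Rhat
#' exceeds 1.01.
#'
#' @param responses Tibble with columns `participant`, `session`,
#'   `pair_id`, `presentation`, `response` (0/1).
#' @param hyper Hyperparameters from [agent_hyper()].
#' @param chains,draws,warmup,adapt Sampler settings (kept draws per chain,
#'   burn-in iterations, JAGS adaptation iterations).
#' @param seed Integer seed (per-chain RNG seeds derive from it).
#' @param prior_reading `"mean_concentration"` (default) parameterizes the
#'   beta priors by mean and concentration, `Beta(a*k, (1-a)*k)`;
#'   `"literal"` uses `Beta(a*k, 1 - a*k)` (valid only while `a*k < 1`).
#' @param prior_only If `TRUE`, sample the prior hierarchy without any
#'   likelihood contribution (`responses` may then be an empty tibble, and
#'   `n_participants`/`n_sessions`/`n_pairs` give the structure).
#' @param n_participants,n_sessions,n_pairs Structure used when
#'   `prior_only = TRUE`.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"rw_fit"`: `draws` (matrix, iterations x
#'   parameters, chains stacked), `chain` (chain index per row),
#'   `diagnostics` (tibble with split-Rhat and ESS per parameter),
#'   `a_index`/`alpha_index` (parameter bookkeeping), `data`, and `config`.
#' @export
fit_hierarchical_rw <- function(responses, hyper = agent_hyper(), chains = 4,
                                draws = 1000, warmup = 1000, adapt = 300,
                                seed = 1,
                                prior_reading = c("mean_concentration", "literal"),
                                prior_only = FALSE, n_participants = 1,
                                n_sessions = 3, n_pairs = 12, quiet = TRUE) {
  prior_reading <- match.arg(prior_reading)
  check_scalar_number(chains, "chains", min = 1, integer = TRUE)
  check_scalar_number(draws, "draws", min = 1, integer = TRUE)

  if (!prior_only) {
    check_columns(responses, c("participant", "session", "pair_id",
                               "presentation", "response"), "responses")
    if (nrow(responses) == 0) {
      abort("`responses` is empty; supply data or set `prior_only = TRUE`.",
            class = "devaltms_input_error")
    }
    if (!all(responses$response %in% c(0, 1))) {
      abort("`response` must be binary 0/1.", class = "devaltms_input_error")
    }
    ppts <- sort(unique(responses$participant))
    sessions <- sort(unique(responses$session))
    a_index <- distinct(responses, .data$participant, .data$session) |>
      arrange(.data$participant, .data$session) |>
      mutate(s = row_number())
    alpha_index <- distinct(responses, .data$participant, .data$session,
                            .data$pair_id) |>
      arrange(.data$participant, .data$session, .data$pair_id) |>
      mutate(p = row_number()) |>
      left_join(select(a_index, "participant", "session", "s"),
                by = c("participant", "session"))
    resp <- responses |>
      left_join(select(alpha_index, "participant", "session", "pair_id", "p"),
                by = c("participant", "session", "pair_id"))
    dat <- list(
      y = resp$response, pres = resp$presentation, pairrow = resp$p,
      ssrow = alpha_index$s, subj = match(alpha_index$participant, ppts),
      sess = match(a_index$session, sessions),
      n_tr = nrow(resp), n_pr = nrow(alpha_index), n_ss = nrow(a_index),
      n_j = length(ppts), n_c = length(sessions)
    )
  } else {
    ppts <- sprintf("P%02d", seq_len(n_participants))
    sessions <- seq_len(n_sessions)
    a_index <- tidyr::crossing(participant = ppts, session = sessions) |>
      mutate(s = row_number())
    alpha_index <- tidyr::crossing(participant = ppts, session = sessions,
                                   pair_id = seq_len(n_pairs)) |>
      mutate(p = row_number()) |>
      left_join(select(a_index, "participant", "session", "s"),
                by = c("participant", "session"))
    dat <- list(
      ssrow = alpha_index$s, subj = match(alpha_index$participant, ppts),
      sess = match(a_index$session, sessions),
      n_pr = nrow(alpha_index), n_ss = nrow(a_index),
      n_j = length(ppts), n_c = length(sessions)
    )
  }

  model_str <- rw_model_string(prior_reading, hyper,
                               include_likelihood = !prior_only)

  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, "chain", ch))
  })
  fit <- tryCatch({
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            n.chains = chains, n.adapt = adapt, inits = inits,
                            quiet = quiet)
    if (warmup > 0) update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("mu", "K", "k", "a", "alpha"), n.iter = draws,
                        progress.bar = "none")
  }, error = function(e) {
    abort(sprintf("Sampler failure in the hierarchical Rescorla-Wagner fit: %s",
                  conditionMessage(e)),
          class = "devaltms_sampler_error", parent = e)
  })

  mats <- lapply(fit, as.matrix)
  # JAGS drops the index on length-1 vectors; normalize to name[1]
  fix_names <- function(m) {
    cn <- colnames(m)
    idx <- cn %in% c("mu", "k", "a", "alpha")
    cn[idx] <- paste0(cn[idx], "[1]")
    colnames(m) <- cn
    m
  }
  mats <- lapply(mats, fix_names)
  draws_mat <- do.call(rbind, mats)
  chain_id <- rep(seq_len(chains), each = draws)

  params <- colnames(draws_mat)
  ess_vals <- coda::effectiveSize(fit)
  scalar <- names(ess_vals) %in% c("mu", "k", "a", "alpha")
  names(ess_vals)[scalar] <- paste0(names(ess_vals)[scalar], "[1]")
  diag <- tibble(
    parameter = params,
    rhat = vapply(params, function(p) {
      split_rhat(lapply(mats, function(m) m[, p]))
    }, numeric(1)),
    ess = as.numeric(ess_vals)[match(params, names(ess_vals))]
  )
  n_bad <- sum(diag$rhat > 1.01, na.rm = TRUE)
  if (n_bad > 0) {
    warn(sprintf("%d parameter(s) have split-Rhat > 1.01; consider more draws.",
                 n_bad))
  }

  structure(list(draws = draws_mat, chain = chain_id, diagnostics = diag,
                 a_index = a_index, alpha_index = alpha_index,
                 participants = ppts, sessions = sessions,
                 data = if (prior_only) NULL else responses,
                 config = list(chains = chains, draws = draws, warmup = warmup,
                               adapt = adapt, seed = seed, hyper = hyper,
                               prior_reading = prior_reading,
                               prior_only = prior_only)),
            class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Rescorla-Wagner fit: %d participants, %d sessions, %d parameters\n",
              length(x$participants), length(x$sessions), ncol(x$draws)))
  cat(sprintf("  %d chains x %d draws (warmup %d); max split-Rhat %.3f, min ESS %.0f\n",
              x$config$chains, x$config$draws, x$config$warmup,
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn fit_hierarchical_rw Posterior summary, one row per parameter
#'   (mean, sd, central 95% interval, split-Rhat, ESS).
#' @param x An `"rw_fit"` object.
#' @param ... Unused.
#' @export
tidy.rw_fit <- function(x, ...) {
  tibble(
    parameter = colnames(x$draws),
    mean = colMeans(x$draws),
    sd = apply(x$draws, 2, sd),
    q2.5 = apply(x$draws, 2, quantile, 0.025),
    q50 = apply(x$draws, 2, quantile, 0.5),
    q97.5 = apply(x$draws, 2, quantile, 0.975)
  ) |>
    left_join(x$diagnostics, by = "parameter")
}

#' @describeIn fit_hierarchical_rw One-row fit summary.
#' @export
glance.rw_fit <- function(x, ...) {
  tibble(n_parameters = ncol(x$draws),
         chains = x$config$chains, draws = x$config$draws,
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess, na.rm = TRUE))
}

# Posterior means of the subject-session mean learning rates a_jc.
#' Extract posterior-mean subject-session learning rates
#'
#' @param fit An `"rw_fit"` object.
#' @return Tibble `participant`, `session`, `a_mean`.
#' @export
posterior_a_means <- function(fit) {
  stopifnot(inherits(fit, "rw_fit"))
  cols <- sprintf("a[%d]", fit$a_index$s)
  fit$a_index |>
    mutate(a_mean = colMeans(fit$draws[, cols, drop = FALSE])) |>
    select("participant", "session", "a_mean")
}

#' Posterior value trajectories and terminal values per pair
#'
#' Computes, for every subject-session-pair in the fit, the value
#' trajectory implied by the posterior-mean learning rate (default) or
#' averaged over posterior draws, along with the terminal value `w_final`
#' after the pair's final presentation. Terminal Day 1 values carry to the
#' Day 2 probe unchanged, since no further feedback occurs.
#'
#' @param fit An `"rw_fit"` object fitted to data.
#' @param n_presentations Either a single count applied to all pairs or a
#'   tibble `participant`, `session`, `pair_id`, `n_pres`; `NULL` takes the
#'   per-pair maximum presentation from the fitted data.
#' @param method `"mean"` plugs the posterior-mean alpha into the closed
#'   form; `"draws"` averages the closed form over posterior draws.
#' @return Tibble `participant`, `session`, `pair_id`, `alpha_hat`,
#'   `n_pres`, `w_final`, and a list-column `trajectory` of pre-update
#'   values.
#' @export
posterior_value_trajectories <- function(fit, n_presentations = NULL,
                                         method = c("mean", "draws")) {
  stopifnot(inherits(fit, "rw_fit"))
  method <- match.arg(method)
  idx <- fit$alpha_index
  if (is.null(n_presentations)) {
    if (is.null(fit$data)) {
      abort("No fitted data; supply `n_presentations`.",
            class = "devaltms_input_error")
    }
    np <- fit$data |>
      group_by(.data$participant, .data$session, .data$pair_id) |>
      summarise(n_pres = max(.data$presentation), .groups = "drop")
  } else if (is.numeric(n_presentations) && length(n_presentations) == 1) {
    np <- mutate(select(idx, "participant", "session", "pair_id"),
                 n_pres = as.integer(n_presentations))
  } else {
    np <- check_columns(n_presentations,
                        c("participant", "session", "pair_id", "n_pres"),
                        "n_presentations")
  }
  out <- idx |>
    left_join(np, by = c("participant", "session", "pair_id"))
  if (anyNA(out$n_pres)) {
    abort("A pair in the fit has no presentation count.",
          class = "devaltms_lookup_error")
  }
  cols <- sprintf("alpha[%d]", out$p)
  missing_cols <- setdiff(cols, colnames(fit$draws))
  if (length(missing_cols) > 0) {
    abort("Pair absent from the posterior draws.", class = "devaltms_lookup_error")
  }
  alpha_hat <- colMeans(fit$draws[, cols, drop = FALSE])
  if (method == "mean") {
    w_final <- 1 - 0.5 * (1 - alpha_hat)^out$n_pres
    traj <- purrr::map2(alpha_hat, out$n_pres, rw_trajectory)
  } else {
    w_final <- purrr::map2_dbl(cols, out$n_pres, function(cl, n) {
      mean(1 - 0.5 * (1 - fit$draws[, cl])^n)
    })
    traj <- purrr::map2(cols, out$n_pres, function(cl, n) {
      a_d <- fit$draws[, cl]
      vapply(seq_len(n) - 1, function(m) mean(1 - 0.5 * (1 - a_d)^m), numeric(1))
    })
  }
  out |>
    mutate(alpha_hat = alpha_hat, w_final = w_final, trajectory = traj) |>
    select("participant", "session", "pair_id", "alpha_hat", "n_pres",
           "w_final", "trajectory")
}

#' Learned value difference for probe trials
#'
#' For each post-meal sweet-vs-savory probe trial, looks up the terminal
#' learned values of the two stimuli's source discrimination pairs and
#' returns `w(sated-associated stimulus) - w(non-sated stimulus)`.
#'
#' @param trajectories Output of [posterior_value_trajectories()].
#' @param probe_trials Probe-trial tibble with columns `participant`,
#'   `session`, `src_pair_1` (sweet), `src_pair_2` (savory), `sated_odor`.
#' @return `probe_trials` with a `value_diff` column (existing `value_diff`
#'   is replaced).
#' @export
probe_value_diff <- function(trajectories, probe_trials) {
  check_columns(probe_trials, c("participant", "session", "src_pair_1",
                                "src_pair_2", "sated_odor"), "probe_trials")
  wmap <- select(trajectories, "participant", "session", "pair_id", "w_final")
  out <- probe_trials |>
    select(-dplyr::any_of("value_diff")) |>
    left_join(rename(wmap, src_pair_1 = "pair_id", w_sweet = "w_final"),
              by = c("participant", "session", "src_pair_1")) |>
    left_join(rename(wmap, src_pair_2 = "pair_id", w_savory = "w_final"),
              by = c("participant", "session", "src_pair_2")) |>
    mutate(value_diff = ifelse(.data$sated_odor == "sweet",
                               .data$w_sweet - .data$w_savory,
                               .data$w_savory - .data$w_sweet)) |>
    select(-"w_sweet", -"w_savory")
  if (anyNA(out$value_diff)) {
    abort("Probe trial references a pair absent from the trajectories.",
          class = "devaltms_lookup_error")
  }
  out
}

#' Posterior-predictive discrimination accuracy per run
#'
#' Simulates responses from posterior draws of the pair-level learning
#' rates and summarizes choice accuracy (probability of selecting the
#' odor-predictive stimulus) per run with an uncertainty band.
#'
#' @param fit An `"rw_fit"` object fitted to data that carries a `run`
#'   column (otherwise supply `trials`).
#' @param trials Optional trial tibble with `participant`, `session`,
#'   `pair_id`, `presentation`, `run`.
#' @param n_draws Number of posterior draws to simulate from.
#' @param seed Integer seed.
#' @param probs Quantiles of the band.
#' @return Tibble `run`, `accuracy` (posterior-predictive mean), `lo`, `hi`.
#' @export
posterior_predictive_accuracy <- function(fit, trials = NULL, n_draws = 100,
                                          seed = 1, probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "rw_fit"))
  trials <- trials %||% fit$data
  check_columns(trials, c("participant", "session", "pair_id", "presentation",
                          "run"), "trials")
  trials <- trials |>
    left_join(select(fit$alpha_index, "participant", "session", "pair_id", "p"),
              by = c("participant", "session", "pair_id"))
  if (anyNA(trials$p)) {
    abort("Trial references a pair absent from the posterior.",
          class = "devaltms_lookup_error")
  }
  take <- withr::with_seed(derive_seed(seed, "ppc-draws"),
                           sample(nrow(fit$draws), min(n_draws, nrow(fit$draws))))
  cols <- sprintf("alpha[%d]", trials$p)
  acc <- withr::with_seed(derive_seed(seed, "ppc-sim"), {
    vapply(take, function(d) {
      alpha <- fit$draws[d, cols]
      w <- 1 - 0.5 * (1 - alpha)^(trials$presentation - 1)
      resp <- rbinom(length(w), 1, w)
      tapply(resp, trials$run, mean)
    }, numeric(length(unique(trials$run))))
  })
  runs <- sort(unique(trials$run))
  tibble(run = runs,
         accuracy = rowMeans(acc),
         lo = apply(acc, 1, quantile, probs[1]),
         hi = apply(acc, 1, quantile, probs[2]))
}
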