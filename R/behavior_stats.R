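# Behavioral inference: discrimination-learning test, satiation summaries
# and moderator models, covariate-adjusted probe-choice models with TMS
# contrasts, fit evaluation, and leave-one-subject-out sensitivity.

new_model_comparison <- function(full, reduced, term) {
  ll_full <- logLik(full); ll_red <- logLik(reduced)
  diff <- 2 * (as.numeric(ll_full) - as.numeric(ll_red))
  # degenerate saturated fits can give Inf - Inf; identical models score 0
  stat <- if (is.nan(diff)) 0 else max(0, diff)
  df <- attr(ll_full, "df") - attr(ll_red, "df")
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  coefs <- tryCatch({
    sm <- summary(full)$coefficients
    tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2])
  }, error = function(e) tibble(term = character(), estimate = numeric(),
                                std_error = numeric()))
  re_var <- tryCatch({
    vc <- as.data.frame(lme4::VarCorr(full))
    vc$vcov[vc$grp != "Residual"][1]
  }, error = function(e) NA_real_)
  structure(list(term = term, statistic = stat, df = df, p_value = p,
                 loglik_full = as.numeric(ll_full),
                 loglik_reduced = as.numeric(ll_red),
                 fixed_effects = coefs, ranef_variance = re_var,
                 full = full, reduced = reduced),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test of `%s`: chi-square(%d) = %.3f, p = %.4g\n",
              x$term, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' @rdname test_discrimination_learning
#' @param x A `"model_comparison"` object.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) {
  x$fixed_effects
}

#' @rdname test_discrimination_learning
#' @export
glance.model_comparison <- function(x, ...) {
  tibble(term = x$term, statistic = x$statistic, df = x$df,
         p_value = x$p_value, loglik_full = x$loglik_full,
         loglik_reduced = x$loglik_reduced, ranef_variance = x$ranef_variance)
}

check_converged <- function(fit, what) {
  code <- fit@optinfo$conv$opt
  if (!is.null(code) && code != 0) {
    abort(sprintf("Mixed-model optimizer failed to converge in %s (code %d).",
                  what, code), class = "devaltms_convergence_error")
  }
  invisible(fit)
}

#' Test discrimination learning across runs
#'
#' Fits a logistic mixed model of odor-predictive choices with a fixed
#' effect of run and a participant random intercept, and compares it by
#' likelihood-ratio test against the intercept-only model
#' (`OdorChosen ~ Run + (1|Ppt)` vs `OdorChosen ~ (1|Ppt)`).
#'
#' @param trials Tibble with columns `participant`, `run` (1..5),
#'   `response` (0/1; odor-predictive stimulus chosen).
#' @return A `"model_comparison"` object.
#' @export
test_discrimination_learning <- function(trials) {
  check_columns(trials, c("participant", "run", "response"), "trials")
  if (length(unique(trials$run)) < 2) {
    abort("At least two distinct runs are required to test learning.",
          class = "devaltms_df_error")
  }
  dat <- mutate(trials, run = as.numeric(.data$run))
  full <- lme4::glmer(response ~ run + (1 | participant), data = dat,
                      family = stats::binomial())
  reduced <- lme4::glmer(response ~ (1 | participant), data = dat,
                         family = stats::binomial())
  check_converged(full, "the discrimination-learning model")
  new_model_comparison(full, reduced, "run")
}

#' Per-session satiation summaries
#'
#' Computes, per participant-session: the pre-to-post pleasantness change
#' of each odor (`PleasantChange`, z-scale by default), the satiation index
#' `SatIdx = PleasantChange(sated) - PleasantChange(non-sated)`, and the
#' baseline preference `BasePref`, the proportion of sated-odor choices
#' among pre-meal sweet-vs-savory trials.
#'
#' @param ratings Rating tibble as from [simulate_ratings()] (columns
#'   `participant`, `session`, `odor`, `phase`, and the rating column).
#' @param premeal_choices Pre-meal choice trials with `participant`,
#'   `session`, `pair_type`, `chose_sated`.
#' @param rating_col Which rating column to difference (default
#'   `"z_rating"`).
#' @return Tibble `participant`, `session`, `pleasant_change_sated`,
#'   `pleasant_change_non_sated`, `sat_idx`, `base_pref`.
#' @export
satiation_summaries <- function(ratings, premeal_choices,
                                rating_col = "z_rating") {
  check_columns(ratings, c("participant", "session", "odor", "phase", rating_col),
                "ratings")
  check_columns(premeal_choices, c("participant", "session", "pair_type",
                                   "chose_sated"), "premeal_choices")
  if (!all(c("pre", "post") %in% ratings$phase)) {
    abort("`ratings` must contain both pre and post phases.",
          class = "devaltms_input_error")
  }
  pc <- ratings |>
    group_by(.data$participant, .data$session, .data$odor, .data$phase) |>
    summarise(rating = mean(.data[[rating_col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "rating") |>
    mutate(pleasant_change = .data$post - .data$pre) |>
    select("participant", "session", "odor", "pleasant_change") |>
    tidyr::pivot_wider(names_from = "odor", values_from = "pleasant_change",
                       names_prefix = "pleasant_change_")
  bp <- premeal_choices |>
    filter(.data$pair_type == "sweet_vs_savory") |>
    group_by(.data$participant, .data$session) |>
    summarise(base_pref = mean(.data$chose_sated), .groups = "drop")
  pc |>
    mutate(sat_idx = .data$pleasant_change_sated - .data$pleasant_change_non_sated) |>
    left_join(bp, by = c("participant", "session"))
}

#' Test the selective-satiation effect on pleasantness change
#'
#' Linear mixed model of per-odor pleasantness change with a fixed effect
#' of sated status and a participant random intercept, compared by LRT
#' against the intercept-only model (models fitted by maximum likelihood).
#'
#' @param pc_data Tibble with `participant`, `pleasant_change`, `is_sated`
#'   (0/1). Use [pleasant_change_table()] to build it from ratings.
#' @return A `"model_comparison"` object.
#' @export
test_pleasantness_change <- function(pc_data) {
  check_columns(pc_data, c("participant", "pleasant_change", "is_sated"),
                "pc_data")
  full <- lme4::lmer(pleasant_change ~ is_sated + (1 | participant),
                     data = pc_data, REML = FALSE)
  reduced <- lme4::lmer(pleasant_change ~ (1 | participant), data = pc_data,
                        REML = FALSE)
  new_model_comparison(full, reduced, "is_sated")
}

#' Per-odor pleasantness-change table
#'
#' @inheritParams satiation_summaries
#' @return Tibble `participant`, `session`, `odor`, `is_sated`,
#'   `pleasant_change`.
#' @export
pleasant_change_table <- function(ratings, rating_col = "z_rating") {
  check_columns(ratings, c("participant", "session", "odor", "phase", rating_col),
                "ratings")
  ratings |>
    group_by(.data$participant, .data$session, .data$odor, .data$phase) |>
    summarise(rating = mean(.data[[rating_col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "rating") |>
    mutate(pleasant_change = .data$post - .data$pre,
           is_sated = as.integer(.data$odor == "sated")) |>
    select("participant", "session", "odor", "is_sated", "pleasant_change")
}

#' Test a single moderator of the satiation index
#'
#' Linear mixed model `SatIdx ~ moderator + (1|Ppt)` compared by LRT
#' against the intercept-only model. A moderator column with a single
#' unique value yields a zero LRT by construction.
#'
#' @param satidx Tibble with `participant`, `sat_idx`, and the moderator
#'   column.
#' @param moderator Name of the moderator column (e.g. `"condition"`,
#'   `"target_group"`, `"session"`, `"sated_odor"`).
#' @return A `"model_comparison"` object.
#' @export
test_satidx_moderators <- function(satidx, moderator) {
  check_columns(satidx, c("participant", "sat_idx", moderator), "satidx")
  reduced <- lme4::lmer(sat_idx ~ (1 | participant), data = satidx, REML = FALSE)
  if (length(unique(satidx[[moderator]])) < 2) {
    return(new_model_comparison(reduced, reduced, moderator))
  }
  fml <- stats::as.formula(sprintf("sat_idx ~ %s + (1 | participant)", moderator))
  full <- lme4::lmer(fml, data = satidx, REML = FALSE)
  new_model_comparison(full, reduced, moderator)
}

probe_contrast_sessions <- function(contrast) {
  switch(contrast,
         day2_tms = c("SS", "SC"),
         day1_tms = c("SS", "CS"))
}

#' Covariate-adjusted probe-choice model with a TMS contrast
#'
#' Fits the logistic mixed model
#' `Choice ~ TMScond + ValueDiff + SatIdx + BasePref + (1|Ppt)` to post-meal
#' sweet-vs-savory probe trials and tests the TMS term by likelihood-ratio
#' test against the covariates-only model. The Day 2 contrast compares
#' sham-sham against sham-cTBS sessions; the Day 1 contrast compares
#' sham-sham against cTBS-sham (Day 2 TMS held at sham). With
#' `group = "both"` an additional model with a TMScond-by-target-group
#' interaction is tested.
#'
#' @param probe_trials Probe-trial tibble with `participant`, `session`,
#'   `condition` (`"CS"`/`"SC"`/`"SS"`), `target_group`, `choice` (1 =
#'   sated-odor option), `value_diff`, `sat_idx`, `base_pref`.
#' @param contrast `"day2_tms"` or `"day1_tms"`.
#' @param group `"aOFC"`, `"pOFC"`, or `"both"`.
#' @return An object of class `"probe_fit"`: the TMS `"model_comparison"`
#'   (`$comparison`), the interaction comparison when `group = "both"`
#'   (`$interaction`), per-participant mean fitted probabilities by
#'   condition (`$fitted`), and the trial table with per-trial fitted
#'   probabilities (`$trials`).
#' @export
probe_choice_model <- function(probe_trials,
                               contrast = c("day2_tms", "day1_tms"),
                               group = c("both", "aOFC", "pOFC")) {
  contrast <- match.arg(contrast)
  group <- match.arg(group)
  check_columns(probe_trials, c("participant", "session", "condition",
                                "target_group", "choice", "value_diff",
                                "sat_idx", "base_pref"), "probe_trials")
  keep <- probe_contrast_sessions(contrast)
  dat <- filter(probe_trials, .data$condition %in% keep)
  if (group != "both") dat <- filter(dat, .data$target_group == group)
  if (!all(keep %in% dat$condition)) {
    abort(sprintf("Contrast `%s` requires sessions %s in the data.",
                  contrast, paste(keep, collapse = " and ")),
          class = "devaltms_input_error")
  }
  dat <- mutate(dat, tms = as.integer(.data$condition == setdiff(keep, "SS")))
  full <- lme4::glmer(choice ~ tms + value_diff + sat_idx + base_pref +
                        (1 | participant),
                      data = dat, family = stats::binomial())
  reduced <- lme4::glmer(choice ~ value_diff + sat_idx + base_pref +
                           (1 | participant),
                         data = dat, family = stats::binomial())
  check_converged(full, "the probe-choice model")
  comparison <- new_model_comparison(full, reduced, "tms")

  interaction <- NULL
  if (group == "both" && length(unique(dat$target_group)) > 1) {
    fi <- lme4::glmer(choice ~ tms * target_group + value_diff + sat_idx +
                        base_pref + (1 | participant),
                      data = dat, family = stats::binomial())
    ri <- lme4::glmer(choice ~ tms + target_group + value_diff + sat_idx +
                        base_pref + (1 | participant),
                      data = dat, family = stats::binomial())
    interaction <- new_model_comparison(fi, ri, "tms:target_group")
  }

  dat$fitted <- stats::fitted(full)
  fitted_tbl <- dat |>
    group_by(.data$participant, .data$target_group, .data$condition) |>
    summarise(fitted_prob = mean(.data$fitted),
              observed_rate = mean(.data$choice),
              n_trials = n(), .groups = "drop")

  structure(list(comparison = comparison, interaction = interaction,
                 fitted = fitted_tbl, trials = dat, contrast = contrast,
                 group = group),
            class = "probe_fit")
}

#' @export
print.probe_fit <- function(x, ...) {
  cat(sprintf("Probe-choice model (%s, group %s)\n", x$contrast, x$group))
  print(x$comparison)
  if (!is.null(x$interaction)) print(x$interaction)
  invisible(x)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the rank (Mann-Whitney) statistic:
#' the probability that a randomly drawn positive trial receives a higher
#' score than a randomly drawn negative one (ties count one half).
#'
#' @param scores Numeric predictions.
#' @param labels Binary outcomes (0/1).
#' @return Scalar AUC, or `NA` with a warning when only one class occurs.
#' @export
rank_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must align.", class = "devaltms_input_error")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: only one outcome class present.")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate probe-model fit at participant and trial level
#'
#' Reports (1) the correlation between per-participant mean fitted
#' probability and observed mean choice rate, and (2) trial-level ROC AUC,
#' pooled within each target group x TMS condition and overall.
#'
#' @param fit A `"probe_fit"` object.
#' @return A list with `participant_correlation` (scalar),
#'   `participant_table`, `auc_overall`, and `auc_by_condition` (tibble
#'   `target_group`, `condition`, `auc`, `n`).
#' @export
evaluate_fit <- function(fit) {
  stopifnot(inherits(fit, "probe_fit"))
  per_ppt <- fit$trials |>
    group_by(.data$participant) |>
    summarise(fitted_prob = mean(.data$fitted),
              observed_rate = mean(.data$choice), .groups = "drop")
  r <- if (sd(per_ppt$fitted_prob) > 0 && sd(per_ppt$observed_rate) > 0) {
    cor(per_ppt$fitted_prob, per_ppt$observed_rate)
  } else NA_real_
  by_cond <- fit$trials |>
    group_by(.data$target_group, .data$condition) |>
    summarise(auc = rank_auc(.data$fitted, .data$choice), n = n(),
              .groups = "drop")
  list(participant_correlation = r, participant_table = per_ppt,
       auc_overall = rank_auc(fit$trials$fitted, fit$trials$choice),
       auc_by_condition = by_cond)
}

#' Leave-one-subject-out sensitivity of the probe-choice test
#'
#' Refits the probe-choice model excluding each participant in turn and
#' collects the TMS likelihood-ratio p-values.
#'
#' @inheritParams probe_choice_model
#' @return A list with `p_values` (tibble `left_out`, `p_value`),
#'   `median_p`, and `range_p`.
#' @export
loso_sensitivity <- function(probe_trials,
                             contrast = c("day2_tms", "day1_tms"),
                             group = c("both", "aOFC", "pOFC")) {
  contrast <- match.arg(contrast)
  group <- match.arg(group)
  ppts <- sort(unique(probe_trials$participant))
  if (length(ppts) < 3) {
    abort("Leave-one-subject-out requires at least 3 participants.",
          class = "devaltms_input_error")
  }
  ps <- purrr::map_dbl(ppts, function(p) {
    fit <- probe_choice_model(filter(probe_trials, .data$participant != p),
                              contrast = contrast, group = group)
    fit$comparison$p_value
  })
  tbl <- tibble(left_out = ppts, p_value = ps)
  list(p_values = tbl, median_p = median(ps), range_p = range(ps))
}

#' Per-participant behavioral TMS effect
#'
#' The behavioral effect of cTBS for one participant is the difference in
#' mean model-fitted probability of choosing the sated-odor option between
#' that participant's cTBS and sham conditions of the contrast.
#'
#' @param fit A `"probe_fit"` object (or its `$fitted` table).
#' @return Tibble `participant`, `target_group`, `fitted_ctbs`,
#'   `fitted_sham`, `effect`. Participants missing a condition are dropped
#'   with a message.
#' @export
behavioral_tms_effect <- function(fit) {
  fitted_tbl <- if (inherits(fit, "probe_fit")) fit$fitted else fit
  check_columns(fitted_tbl, c("participant", "target_group", "condition",
                              "fitted_prob"), "fitted")
  ctbs_cond <- setdiff(unique(fitted_tbl$condition), "SS")
  wide <- fitted_tbl |>
    mutate(role = ifelse(.data$condition == "SS", "fitted_sham", "fitted_ctbs")) |>
    select("participant", "target_group", "role", "fitted_prob") |>
    tidyr::pivot_wider(names_from = "role", values_from = "fitted_prob")
  dropped <- wide$participant[!stats::complete.cases(wide)]
  if (length(dropped) > 0) {
    message(sprintf("Excluding %d participant(s) lacking a condition: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  wide |>
    filter(stats::complete.cases(wide)) |>
    mutate(effect = .data$fitted_ctbs - .data$fitted_sham)
}

#' Paired pre/post-meal choice shift
#'
#' Two-sided Wilcoxon signed-rank test of per-participant sated-odor choice
#' rates after versus before the meal.
#'
#' @param rates Tibble with `participant`, `pre_rate`, `post_rate`.
#' @return Tibble `statistic` (V), `p_value`, `n`, `median_shift`.
#' @export
paired_choice_shift <- function(rates) {
  check_columns(rates, c("participant", "pre_rate", "post_rate"), "rates")
  wt <- suppressWarnings(wilcox.test(rates$post_rate, rates$pre_rate,
                                     paired = TRUE, exact = FALSE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n = nrow(rates),
         median_shift = median(rates$post_rate - rates$pre_rate))
}
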