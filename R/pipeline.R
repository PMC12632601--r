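# End-to-end orchestration over the synthetic cohort: design, simulation,
# learning-model fit, behavioral inference, and latent embedding, with
# artifact writing, manifests, and input validation.

#' Pipeline configuration
#'
#' Bundles and validates the settings of a full analysis run. Every output
#' directory receives a serialized copy so a run is reproducible from its
#' artifacts alone.
#'
#' @param n_participants Cohort size (default 8, a demonstration scale).
#' @param seed Global seed; every stage derives its own stream from it.
#' @param effects Effect sizes from [cohort_effects()].
#' @param sampler List of hierarchical-fit settings (`chains`, `draws`,
#'   `warmup`, `adapt`).
#' @param cvae A [cvae_config()] (its `input_dim`/`n_conditions` are
#'   aligned to the cohort automatically).
#' @param n_runs Discrimination runs per session.
#' @param stages Character vector of stages to run, in order, from
#'   `c("design", "simulate", "learning", "behavior", "embedding")`.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_participants = 8, seed = 1,
                            effects = cohort_effects(),
                            sampler = list(chains = 2, draws = 300,
                                           warmup = 300, adapt = 200),
                            cvae = cvae_config(epochs = 150),
                            n_runs = 5,
                            stages = c("design", "simulate", "learning",
                                       "behavior", "embedding")) {
  check_scalar_number(n_participants, "n_participants", min = 2, integer = TRUE)
  check_scalar_number(seed, "seed")
  bad <- setdiff(stages, c("design", "simulate", "learning", "behavior",
                           "embedding"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")),
          class = "devaltms_input_error")
  }
  structure(list(n_participants = as.integer(n_participants), seed = seed,
                 effects = effects, sampler = sampler, cvae = cvae,
                 n_runs = n_runs, stages = stages),
            class = "pipeline_config")
}

stage_require <- function(bundle, what, needed_by) {
  if (is.null(bundle[[what]])) {
    abort(sprintf("Stage `%s` requires `%s`, which was skipped or failed.",
                  needed_by, what), class = "devaltms_dependency_error")
  }
  invisible(bundle[[what]])
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: design + cohort simulation, the hierarchical
#' Rescorla-Wagner fit, the behavioral inference stages (discrimination
#' learning, pleasantness change, probe-choice contrasts with fitted
#' probabilities and behavioral TMS effects), and the latent-embedding
#' stage (feature standardization, conditional-VAE training, latent
#' distances, paired test, brain-behavior correlation). When `outdir` is
#' given, every artifact is written as TSV/JSON together with the
#' serialized configuration and a manifest of MD5 checksums.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return A list of class `"pipeline_result"` with elements `cohort`,
#'   `rw_fit`, `trajectories`, `behavior` (list of comparisons and effect
#'   tables), `embedding` (model, effects, tests), `manifest` (tibble of
#'   written files and checksums, when `outdir` is used), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list(config = config)
  stages <- config$stages

  if ("simulate" %in% stages || "design" %in% stages) {
    bundle$cohort <- simulate_cohort(config$n_participants, seed = config$seed,
                                     effects = config$effects,
                                     n_runs = config$n_runs)
  }

  if ("learning" %in% stages) {
    cohort <- stage_require(bundle, "cohort", "learning")
    responses <- select(cohort$discrimination, "participant", "session",
                        "pair_id", "presentation", "response", "run")
    bundle$rw_fit <- fit_hierarchical_rw(
      responses, chains = config$sampler$chains, draws = config$sampler$draws,
      warmup = config$sampler$warmup, adapt = config$sampler$adapt,
      seed = derive_seed(config$seed, "rw-fit"))
    bundle$trajectories <- posterior_value_trajectories(bundle$rw_fit)
    bundle$probe_trials <- probe_value_diff(bundle$trajectories,
                                            cohort$probe_trials)
  }

  if ("behavior" %in% stages) {
    cohort <- stage_require(bundle, "cohort", "behavior")
    probe <- bundle$probe_trials %||% cohort$probe_trials
    disc <- cohort$discrimination
    behavior <- list(
      discrimination = test_discrimination_learning(disc),
      pleasantness = test_pleasantness_change(
        left_join(pleasant_change_table(cohort$ratings),
                  distinct(cohort$plans, .data$participant, .data$session,
                           .data$condition),
                  by = c("participant", "session"))),
      probe_day2 = probe_choice_model(probe, "day2_tms", "both"),
      probe_day1 = probe_choice_model(probe, "day1_tms", "both")
    )
    behavior$fit_evaluation <- evaluate_fit(behavior$probe_day2)
    behavior$tms_effect_day1 <- behavioral_tms_effect(behavior$probe_day1)
    bundle$behavior <- behavior
  }

  if ("embedding" %in% stages) {
    cohort <- stage_require(bundle, "cohort", "embedding")
    fc <- cohort$fc
    std <- standardize_features(fc$features)
    cfg <- config$cvae
    cfg$input_dim <- ncol(std$X)
    cfg$n_conditions <- length(unique(fc$labels$participant))
    model <- train_cvae(std$X, fc$labels$participant, cfg,
                        tms_condition = fc$labels$condition)
    effects <- suppressMessages(latent_distances(model, std$X, fc$labels))
    embedding <- list(
      standardization = std, model = model, effects = effects,
      paired_test = paired_effect_test(effects),
      diagnostics = matching_diagnostics(std$X, fc$labels$condition)
    )
    if (!is.null(bundle$behavior)) {
      embedding$brain_behavior <- brain_behavior_correlation(
        effects, bundle$behavior$tms_effect_day1,
        distinct(cohort$plans, .data$participant, .data$target_group))
    }
    bundle$embedding <- embedding
  }

  if (!is.null(outdir)) {
    bundle$manifest <- write_pipeline_artifacts(bundle, outdir)
  }
  structure(bundle, class = "pipeline_result")
}

mc_to_row <- function(mc, label) {
  tibble(test = label, term = mc$term, statistic = mc$statistic, df = mc$df,
         p_value = mc$p_value, loglik_full = mc$loglik_full,
         loglik_reduced = mc$loglik_reduced)
}

write_pipeline_artifacts <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_tsv <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_plain(df, path)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
  }

  cfg <- bundle$config
  emit_json(list(n_participants = cfg$n_participants, seed = cfg$seed,
                 effects = cfg$effects, sampler = cfg$sampler,
                 cvae = unclass(cfg$cvae), n_runs = cfg$n_runs,
                 stages = cfg$stages), "config.json")

  if (!is.null(bundle$cohort)) {
    co <- bundle$cohort
    emit_tsv(co$plans, "session_plans.tsv")
    emit_tsv(select(co$discrimination, -dplyr::any_of("trajectory")),
             "discrimination_events.tsv")
    emit_tsv(co$ratings, "ratings.tsv")
    emit_tsv(co$satiation, "satiation_summaries.tsv")
    emit_tsv(select(co$probe_trials, -dplyr::any_of("trajectory")),
             "probe_trials.tsv")
    fc_df <- as.data.frame(co$fc$features)
    names(fc_df) <- sprintf("f%03d", seq_len(ncol(fc_df)))
    emit_tsv(cbind(co$fc$labels, fc_df), "fc_sessions.tsv")
    emit_json(list(missing = co$fc$missing$session_uid,
                   n_features = co$fc$config$n_features,
                   conditions = co$fc$labels$condition), "fc_sidecar.json")
  }
  if (!is.null(bundle$rw_fit)) {
    emit_tsv(tidy(bundle$rw_fit), "rw_posterior_summary.tsv")
    emit_tsv(select(bundle$trajectories, -"trajectory"), "value_trajectories.tsv")
  }
  if (!is.null(bundle$behavior)) {
    be <- bundle$behavior
    emit_tsv(bind_rows(
      mc_to_row(be$discrimination, "discrimination_learning"),
      mc_to_row(be$pleasantness, "pleasantness_change"),
      mc_to_row(be$probe_day2$comparison, "probe_day2_tms"),
      mc_to_row(be$probe_day1$comparison, "probe_day1_tms")
    ), "behavior_tests.tsv")
    emit_tsv(be$probe_day2$fitted, "fitted_probabilities_day2.tsv")
    emit_tsv(be$tms_effect_day1, "behavioral_tms_effect_day1.tsv")
  }
  if (!is.null(bundle$embedding)) {
    em <- bundle$embedding
    emit_tsv(em$model$loss, "cvae_loss_trace.tsv")
    emit_tsv(as_tibble(em$effects), "neural_effects.tsv")
    emit_json(list(paired_test = as.list(em$paired_test),
                   n_var_significant = em$diagnostics$n_var_significant,
                   n_mean_significant = em$diagnostics$n_mean_significant),
              "embedding_report.json")
    if (!is.null(em$brain_behavior)) {
      emit_tsv(em$brain_behavior, "brain_behavior_correlation.tsv")
    }
  }

  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  write_tsv_plain(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}

#' Validate behavioral event tables
#'
#' Schema, range, and design-invariant checks over the cohort's event
#' tables. All violations are collected and returned, not thrown.
#'
#' @param tables Named list with any of `discrimination` (needs
#'   `participant`, `run`, `pair_id`, `response`), `probe_trials` (needs
#'   `participant`, `condition`, `choice`, `value_diff`, `sat_idx`,
#'   `base_pref`), `ratings` (needs `participant`, `session`, `odor`,
#'   `phase`, `raw_rating`).
#' @param n_runs Maximum run index allowed in the discrimination design.
#' @return Tibble `table`, `check`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(tables, n_runs = 5) {
  violations <- list()
  note <- function(tb, check, msg) {
    violations[[length(violations) + 1]] <<- tibble(table = tb, check = check,
                                                    message = msg)
  }
  need <- function(df, cols, tb) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      note(tb, "schema", sprintf("missing column(s): %s",
                                 paste(missing, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  if (!is.null(tables$discrimination)) {
    d <- tables$discrimination
    if (need(d, c("participant", "run", "pair_id", "response"), "discrimination")) {
      if (!all(d$response %in% c(0, 1))) {
        note("discrimination", "range", "response values outside {0, 1}")
      }
      if (any(d$run < 1 | d$run > n_runs)) {
        note("discrimination", "design",
             sprintf("run index outside 1..%d (found %s)", n_runs,
                     paste(sort(unique(d$run[d$run < 1 | d$run > n_runs])),
                           collapse = ", ")))
      }
      if (any(d$pair_id < 1 | d$pair_id > 12)) {
        note("discrimination", "design", "pair_id outside 1..12")
      }
    }
  }
  if (!is.null(tables$probe_trials)) {
    p <- tables$probe_trials
    if (need(p, c("participant", "condition", "choice", "value_diff",
                  "sat_idx", "base_pref"), "probe_trials")) {
      if (!all(p$choice %in% c(0, 1))) {
        note("probe_trials", "range", "choice values outside {0, 1}")
      }
      if (!all(p$condition %in% c("CS", "SC", "SS"))) {
        note("probe_trials", "range", "condition outside {CS, SC, SS}")
      }
      if (any(p$base_pref < 0 | p$base_pref > 1, na.rm = TRUE)) {
        note("probe_trials", "range", "base_pref outside [0, 1]")
      }
      if (anyNA(p[c("value_diff", "sat_idx", "base_pref")])) {
        note("probe_trials", "range", "missing covariate values")
      }
    }
  }
  if (!is.null(tables$ratings)) {
    r <- tables$ratings
    if (need(r, c("participant", "session", "odor", "phase", "raw_rating"),
             "ratings")) {
      if (any(r$raw_rating < -10 | r$raw_rating > 10)) {
        note("ratings", "range", "raw_rating outside -10..10")
      }
      if (!all(r$phase %in% c("pre", "post"))) {
        note("ratings", "range", "phase outside {pre, post}")
      }
    }
  }
  if (length(violations) == 0) {
    tibble(table = character(), check = character(), message = character())
  } else {
    bind_rows(violations)
  }
}
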