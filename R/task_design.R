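# Deterministic generators for the two-day outcome-devaluation design:
# cohort session plans, cue-pair structures, discrimination runs, and the
# pre-/post-meal choice tests.

tms_condition_orders <- function() {
  # The six permutations of the three Day1-Day2 TMS conditions.
  list(c("CS", "SC", "SS"), c("CS", "SS", "SC"),
       c("SC", "CS", "SS"), c("SC", "SS", "CS"),
       c("SS", "CS", "SC"), c("SS", "SC", "CS"))
}

#' Generate counterbalanced session plans for a cohort
#'
#' Each participant completes three two-day sessions and experiences each of
#' the three TMS conditions (cTBS-sham `"CS"`, sham-cTBS `"SC"`, sham-sham
#' `"SS"`) exactly once, in an order counterbalanced across the cohort. The
#' sated meal alternates between sweet and savory across a participant's
#' sessions, with half the cohort starting sweet. Participants are assigned
#' to an anterior-OFC or posterior-OFC stimulation-target group, constant
#' across their sessions.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the full plan is reproducible from it.
#' @param realized If `TRUE` (requires `n_participants = 48`), reproduce the
#'   condition-order allocation realized in the study cohort after dropout
#'   (9, 7, 8, 8, 8, 8 participants per order) instead of the fully balanced
#'   default (8 per order at n = 48).
#' @return A tibble with one row per participant-session: `participant`,
#'   `target_group` (`"aOFC"`/`"pOFC"`), `session` (1..3), `condition`
#'   (`"CS"`/`"SC"`/`"SS"`), `sated_odor` (`"sweet"`/`"savory"`).
#' @examples
#' plans <- make_session_plans(6, seed = 1)
#' dplyr::count(plans, condition, session)
#' @export
make_session_plans <- function(n_participants, seed = 1, realized = FALSE) {
  check_scalar_number(n_participants, "n_participants", min = 1, integer = TRUE)
  orders <- tms_condition_orders()
  n <- as.integer(n_participants)

  if (realized) {
    if (n != 48) {
      abort("`realized = TRUE` reproduces the 48-participant cohort allocation; set n_participants = 48.",
            class = "devaltms_input_error")
    }
    counts <- c(9L, 7L, 8L, 8L, 8L, 8L)
  } else {
    counts <- rep(n %/% 6L, 6L)
    rem <- n %% 6L
    if (rem > 0) {
      # Remainder orders follow a Latin-square sequence: within either
      # triple {1,4,5} or {2,3,6} every condition appears once per session
      # position, so condition-position balance stays within +/- 1.
      triples <- withr::with_seed(derive_seed(seed, "order-remainder"), {
        lapply(sample(list(c(1L, 4L, 5L), c(2L, 3L, 6L))), sample)
      })
      extra <- unlist(triples)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
  }

  order_idx <- shuffle_with_seed(rep(1:6, times = counts),
                                 derive_seed(seed, "order-assignment"))
  sweet_first <- shuffle_with_seed(rep(c(TRUE, FALSE), length.out = n),
                                   derive_seed(seed, "sated-first"))
  group <- shuffle_with_seed(rep(c("aOFC", "pOFC"), length.out = n),
                             derive_seed(seed, "target-group"))

  purrr::map_dfr(seq_len(n), function(i) {
    odors <- if (sweet_first[i]) c("sweet", "savory", "sweet") else c("savory", "sweet", "savory")
    tibble(
      participant = sprintf("P%02d", i),
      target_group = group[i],
      session = 1:3,
      condition = orders[[order_idx[i]]],
      sated_odor = odors
    )
  })
}

#' Build the cue-pair structure of one session
#'
#' A session's discrimination task uses 12 stimulus pairs: two sets (A, B)
#' crossed with the two odor categories (sweet, savory), three
#' non-overlapping pairs per combination. Each pair opposes one
#' odor-predictive stimulus and one clean-air stimulus, for 24 distinct
#' stimuli per session. Stimulus labels are abstract integers, offset by
#' session so no stimulus repeats across a participant's three sessions.
#'
#' @param session Session index (1..3); shifts the stimulus label range.
#' @return A tibble with columns `pair_id` (1..12), `stimulus_set`
#'   (`"A"`/`"B"`), `odor_category` (`"sweet"`/`"savory"`), `odor_stimulus`,
#'   `air_stimulus` (integer labels).
#' @examples
#' make_cue_pairs(1)
#' @export
make_cue_pairs <- function(session = 1) {
  check_scalar_number(session, "session", min = 1, integer = TRUE)
  offset <- (as.integer(session) - 1L) * 24L
  tibble(
    pair_id = 1:12,
    stimulus_set = rep(c("A", "B"), each = 6),
    odor_category = rep(rep(c("sweet", "savory"), each = 3), 2),
    odor_stimulus = offset + 1:12,
    air_stimulus = offset + 13:24
  )
}

check_discrimination_pairs <- function(pairs) {
  check_columns(pairs, c("pair_id", "stimulus_set", "odor_category",
                         "odor_stimulus", "air_stimulus"), "session_pairs")
  comp <- dplyr::count(pairs, .data$stimulus_set, .data$odor_category)
  if (nrow(pairs) != 12 || nrow(comp) != 4 || any(comp$n != 3)) {
    abort("A discrimination session needs 12 pairs: 2 sets x 2 odor categories x 3 pairs.",
          class = "devaltms_design_error")
  }
  stimuli <- c(pairs$odor_stimulus, pairs$air_stimulus)
  if (anyDuplicated(stimuli)) {
    abort("Stimulus labels must be distinct across a session's pairs.",
          class = "devaltms_design_error")
  }
  invisible(pairs)
}

#' Generate one run of the discrimination task
#'
#' A run presents each of the session's 12 pairs twice, once with the
#' odor-predictive stimulus on the left and once on the right, in an order
#' randomized by `seed` (24 trials).
#'
#' @param session_pairs Cue-pair tibble from [make_cue_pairs()].
#' @param run_index Run number (1..5 in the standard design).
#' @param seed Integer seed for the trial-order shuffle.
#' @return A trial tibble with columns `trial_index`, `phase`
#'   (`"discrimination"`), `run`, `pair_id`, `stimulus_set`, `odor_category`,
#'   `left_stimulus`, `right_stimulus`, `odor_stimulus`, `odor_side`, `iti`.
#' @examples
#' run1 <- make_discrimination_run(make_cue_pairs(1), 1, seed = 7)
#' nrow(run1)
#' @export
make_discrimination_run <- function(session_pairs, run_index = 1, seed = 1) {
  check_discrimination_pairs(session_pairs)
  check_scalar_number(run_index, "run_index", min = 1, integer = TRUE)
  trials <- tidyr::crossing(pair_id = session_pairs$pair_id,
                            odor_side = c("left", "right")) |>
    left_join(session_pairs, by = "pair_id") |>
    mutate(
      left_stimulus = ifelse(.data$odor_side == "left", .data$odor_stimulus, .data$air_stimulus),
      right_stimulus = ifelse(.data$odor_side == "right", .data$odor_stimulus, .data$air_stimulus)
    )
  perm <- shuffle_with_seed(seq_len(nrow(trials)), seed)
  trials[perm, ] |>
    mutate(trial_index = row_number(), phase = "discrimination",
           run = as.integer(run_index), iti = 6) |>
    select("trial_index", "phase", "run", "pair_id", "stimulus_set",
           "odor_category", "left_stimulus", "right_stimulus",
           "odor_stimulus", "odor_side", "iti")
}

#' Generate a full five-run discrimination schedule
#'
#' Stacks [make_discrimination_run()] over runs with per-run seeds derived
#' from `(seed, participant, session, run)` so that runs are independently
#' shuffled but jointly reproducible.
#'
#' @inheritParams make_discrimination_run
#' @param n_runs Number of runs (default 5).
#' @param participant,session Labels entering the per-run seed derivation.
#' @param seed Base integer seed.
#' @return A trial tibble as in [make_discrimination_run()], with
#'   `trial_index` renumbered contiguously across runs.
#' @export
make_discrimination_schedule <- function(session_pairs, n_runs = 5,
                                         participant = "P01", session = 1,
                                         seed = 1) {
  check_scalar_number(n_runs, "n_runs", min = 1, integer = TRUE)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    make_discrimination_run(session_pairs, r,
                            seed = derive_seed(seed, participant, session, "disc", r))
  }) |>
    mutate(trial_index = row_number())
}

# Unique choice-test pairs for the requested stimulus sets: per set, the
# 3 sweet-vs-air and 3 savory-vs-air discrimination pairs plus the 9
# sweet-vs-savory combinations of odor-predictive stimuli.
make_choice_pairs <- function(session_pairs, sets) {
  check_discrimination_pairs(session_pairs)
  purrr::map_dfr(sets, function(s) {
    sub <- filter(session_pairs, .data$stimulus_set == s)
    ova <- mutate(sub,
                  choice_pair_id = sprintf("%s-%s%d-air", s,
                                           substr(.data$odor_category, 1, 2),
                                           .data$pair_id),
                  pair_type = "odor_vs_air",
                  stim_1 = .data$odor_stimulus, cat_1 = .data$odor_category,
                  src_pair_1 = .data$pair_id,
                  stim_2 = .data$air_stimulus, cat_2 = "clean_air",
                  src_pair_2 = NA_integer_) |>
      select("choice_pair_id", "pair_type", stimulus_set = "stimulus_set",
             "stim_1", "cat_1", "src_pair_1", "stim_2", "cat_2", "src_pair_2")
    sweet <- filter(sub, .data$odor_category == "sweet")
    savory <- filter(sub, .data$odor_category == "savory")
    svs <- tidyr::crossing(i = seq_len(nrow(sweet)), j = seq_len(nrow(savory))) |>
      mutate(
        choice_pair_id = sprintf("%s-sw%d-sv%d", s, sweet$pair_id[.data$i],
                                 savory$pair_id[.data$j]),
        pair_type = "sweet_vs_savory", stimulus_set = s,
        stim_1 = sweet$odor_stimulus[.data$i], cat_1 = "sweet",
        src_pair_1 = sweet$pair_id[.data$i],
        stim_2 = savory$odor_stimulus[.data$j], cat_2 = "savory",
        src_pair_2 = savory$pair_id[.data$j]
      ) |>
      select(-"i", -"j")
    bind_rows(ova, svs)
  })
}

finish_choice_schedule <- function(choice_pairs, phase, seed) {
  trials <- tidyr::crossing(choice_pair_id = choice_pairs$choice_pair_id,
                            first_left = c(TRUE, FALSE)) |>
    left_join(choice_pairs, by = "choice_pair_id") |>
    mutate(
      left_stimulus = ifelse(.data$first_left, .data$stim_1, .data$stim_2),
      right_stimulus = ifelse(.data$first_left, .data$stim_2, .data$stim_1),
      left_category = ifelse(.data$first_left, .data$cat_1, .data$cat_2),
      right_category = ifelse(.data$first_left, .data$cat_2, .data$cat_1)
    )
  perm <- shuffle_with_seed(seq_len(nrow(trials)), seed)
  trials[perm, ] |>
    mutate(trial_index = row_number(), phase = phase, run = NA_integer_, iti = 6) |>
    select("trial_index", "phase", "run", "choice_pair_id", "pair_type",
           "stimulus_set", "left_stimulus", "right_stimulus",
           "left_category", "right_category", "stim_1", "cat_1", "src_pair_1",
           "stim_2", "cat_2", "src_pair_2", "iti")
}

#' Generate the pre-meal choice test (30 trials, set A)
#'
#' The pre-meal test draws only on set-A stimuli: 3 sweet-vs-air pairs, 3
#' savory-vs-air pairs, and 9 sweet-vs-savory pairs, each presented twice
#' with left/right positions swapped.
#'
#' @inheritParams make_discrimination_run
#' @return A 30-row choice-trial tibble (see [make_postmeal_test()] for the
#'   column layout).
#' @export
make_premeal_test <- function(session_pairs, seed = 1) {
  cp <- make_choice_pairs(session_pairs, "A")
  stopifnot(nrow(cp) == 15)
  finish_choice_schedule(cp, "premeal", seed)
}

#' Generate the post-meal choice test (60 trials, sets A and B)
#'
#' The post-meal test mirrors the pre-meal composition in both stimulus
#' sets: per set, 3 sweet-vs-air, 3 savory-vs-air, and 9 sweet-vs-savory
#' unique pairs, each presented twice with sides swapped (30 unique pairs,
#' 60 trials). No odor outcomes are attached to post-meal trials.
#'
#' @inheritParams make_discrimination_run
#' @return A 60-row choice-trial tibble with columns `trial_index`, `phase`,
#'   `run` (NA), `choice_pair_id`, `pair_type`, `stimulus_set`,
#'   `left_stimulus`, `right_stimulus`, `left_category`, `right_category`,
#'   the underlying pair members `stim_1`/`stim_2` with their categories and
#'   source discrimination pairs, and a fixed placeholder `iti`.
#' @export
make_postmeal_test <- function(session_pairs, seed = 1) {
  cp <- make_choice_pairs(session_pairs, c("A", "B"))
  stopifnot(nrow(cp) == 30)
  finish_choice_schedule(cp, "postmeal", seed)
}

#' Write trial schedules as a BIDS-style events table
#'
#' One row per trial: onset index, phase, run, pair, left/right stimulus and
#' categories. Written as an uncompressed TSV.
#'
#' @param trials A trial tibble from the schedule generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  check_columns(trials, c("trial_index", "phase", "left_stimulus", "right_stimulus"),
                "trials")
  write_tsv_plain(trials, path)
}
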