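# ggplot2 visualizations of the main result types.

#' Plot discrimination learning curves
#'
#' Observed per-run accuracy (thin participant lines, thick group mean),
#' optionally overlaid with a posterior-predictive band from
#' [posterior_predictive_accuracy()].
#'
#' @param trials Discrimination trials with `participant`, `run`,
#'   `response`.
#' @param ppc Optional tibble `run`, `accuracy`, `lo`, `hi`.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(trials, ppc = NULL) {
  check_columns(trials, c("participant", "run", "response"), "trials")
  per <- trials |>
    group_by(.data$participant, .data$run) |>
    summarise(accuracy = mean(.data$response), .groups = "drop")
  grp <- per |>
    group_by(.data$run) |>
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  p <- ggplot2::ggplot(per, ggplot2::aes(x = .data$run, y = .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = grp, linewidth = 1.1, color = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Run", y = "P(choose odor-predictive stimulus)") +
    ggplot2::theme_minimal()
  if (!is.null(ppc)) {
    p <- p + ggplot2::geom_ribbon(
      data = ppc, ggplot2::aes(x = .data$run, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2, fill = "#b2182b")
  }
  p
}

#' Plot satiation effects on pleasantness ratings
#'
#' Pre- versus post-meal ratings by odor (sated vs non-sated).
#'
#' @param ratings Rating tibble from [simulate_ratings()].
#' @param rating_col Which column to plot.
#' @return A ggplot object.
#' @export
plot_satiation <- function(ratings, rating_col = "z_rating") {
  check_columns(ratings, c("odor", "phase", rating_col), "ratings")
  dat <- ratings |>
    mutate(phase = factor(.data$phase, levels = c("pre", "post")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data[[rating_col]],
                                    fill = .data$odor)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Meal phase", y = "Pleasantness (z)", fill = "Odor") +
    ggplot2::theme_minimal()
}

#' @describeIn train_cvae Loss-trace plot (total, reconstruction, KL).
#' @param object A `"cvae_model"`.
#' @export
autoplot.cvae_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$loss, c("total", "recon", "kl"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss") +
    ggplot2::theme_minimal()
}

#' @describeIn latent_distances Paired-dot plot of per-participant
#'   distances to the null baseline under sham and cTBS.
#' @param object A `"neural_effects"` tibble.
#' @param ... Unused.
#' @export
autoplot.neural_effects <- function(object, ...) {
  long <- object |>
    select("participant", sham = "dist_sham", cTBS = "dist_ctbs") |>
    tidyr::pivot_longer(c("sham", "cTBS"), names_to = "condition",
                        values_to = "distance") |>
    mutate(condition = factor(.data$condition, levels = c("sham", "cTBS")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$distance)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant), alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$condition), size = 2) +
    ggplot2::labs(x = "TMS condition", y = "Latent distance to null baseline") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' @describeIn probe_choice_model Paired-dot plot of per-participant fitted
#'   sated-choice probabilities by condition and target group.
#' @param object A `"probe_fit"`.
#' @param ... Unused.
#' @export
autoplot.probe_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$condition, y = .data$fitted_prob)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant), alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$condition), size = 2) +
    ggplot2::facet_wrap(~target_group) +
    ggplot2::labs(x = "TMS condition", y = "Fitted P(choose sated option)") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}
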