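# Participant-conditioned variational autoencoder over session-wise
# functional-connectivity vectors, plus the latent-space deviation
# statistics quantifying TMS effects. The network, back-propagation, and
# Adam optimizer are implemented directly in matrix arithmetic.

#' Configuration of the conditional VAE
#'
#' Defaults mirror the reference architecture: a 64-unit ReLU hidden layer
#' in encoder and decoder, a 10-dimensional Gaussian latent space, Adam
#' with learning rate 3e-4, and a fixed seed of 42. Both encoder and
#' decoder are conditioned on the participant one-hot vector.
#'
#' @param input_dim Number of connectivity features (default 102).
#' @param n_conditions Number of participants (one-hot length, default 48).
#' @param hidden_units Hidden-layer width (default 64).
#' @param latent_dim Latent dimensionality (default 10).
#' @param learning_rate Adam learning rate (default 3e-4).
#' @param epochs Training epochs, full-batch (default 500).
#' @param seed RNG seed for initialization and reparameterization noise.
#' @param resampling `"none"` trains on all sessions each epoch;
#'   `"inverse_condition_weight"` draws each epoch's batch with weights
#'   inversely proportional to the number of sessions in that session's
#'   TMS condition, balancing sham and cTBS exposure.
#' @param logvar_clamp Absolute bound on the latent log-variance.
#' @return A named list of class `"cvae_config"`.
#' @export
cvae_config <- function(input_dim = 102, n_conditions = 48, hidden_units = 64,
                        latent_dim = 10, learning_rate = 3e-4, epochs = 500,
                        seed = 42, resampling = c("none", "inverse_condition_weight"),
                        logvar_clamp = 10) {
  resampling <- match.arg(resampling)
  for (nm in c("input_dim", "n_conditions", "hidden_units", "latent_dim", "epochs")) {
    check_scalar_number(get(nm), nm, min = 1, integer = TRUE)
  }
  check_scalar_number(learning_rate, "learning_rate", min = 0, open = TRUE)
  check_scalar_number(logvar_clamp, "logvar_clamp", min = 0, open = TRUE)
  structure(list(input_dim = as.integer(input_dim),
                 n_conditions = as.integer(n_conditions),
                 hidden_units = as.integer(hidden_units),
                 latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = seed, resampling = resampling,
                 logvar_clamp = logvar_clamp),
            class = "cvae_config")
}

#' Standardize connectivity features across sessions
#'
#' Z-scores every feature to zero mean and (by default population-)unit
#' variance across all sessions, pooling conditions; a constant feature is
#' an error naming the column.
#'
#' @param X Numeric matrix (sessions x features).
#' @param sd_type `"population"` (divide by sqrt(mean squared deviation),
#'   default) or `"sample"`.
#' @return A list of class `"standardized_features"`: `X` (standardized
#'   matrix), `center`, `scale`, `sd_type`.
#' @export
standardize_features <- function(X, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  if (nrow(X) < 2) {
    abort("At least two sessions are required to standardize.",
          class = "devaltms_input_error")
  }
  center <- colMeans(X)
  dev <- sweep(X, 2, center)
  denom <- if (sd_type == "population") nrow(X) else nrow(X) - 1
  scale <- sqrt(colSums(dev^2) / denom)
  if (any(scale == 0)) {
    cn <- colnames(X) %||% as.character(seq_len(ncol(X)))
    abort(sprintf("Constant feature(s) cannot be standardized: %s.",
                  paste(cn[scale == 0], collapse = ", ")),
          class = "devaltms_input_error")
  }
  structure(list(X = sweep(dev, 2, scale, "/"), center = center,
                 scale = scale, sd_type = sd_type),
            class = "standardized_features")
}

#' Invert feature standardization
#'
#' @param std A `"standardized_features"` object.
#' @param X Standardized matrix (defaults to `std$X`).
#' @return The matrix on the original scale.
#' @export
unstandardize_features <- function(std, X = std$X) {
  sweep(sweep(as.matrix(X), 2, std$scale, "*"), 2, std$center, "+")
}

#' Condition-matching diagnostics of standardized features
#'
#' Per-feature Brown-Forsythe tests (one-way ANOVA on absolute deviations
#' from the group median) for variance differences and Welch one-way tests
#' for mean differences across conditions, each with Benjamini-Hochberg
#' FDR correction, plus pooled session-level tests (Welch tests of the
#' per-session feature variance and feature mean across conditions).
#'
#' @param X Numeric matrix (sessions x features).
#' @param condition Condition label per session (e.g. null/sham/cTBS).
#' @param q FDR threshold for the significance counts (default 0.05).
#' @return A list with `per_feature` (tibble `feature`, `bf_stat`, `bf_p`,
#'   `bf_q`, `welch_stat`, `welch_p`, `welch_q`), `n_var_significant`,
#'   `n_mean_significant`, and `pooled` (tibble `test`, `statistic`,
#'   `p_value`).
#' @export
matching_diagnostics <- function(X, condition, q = 0.05) {
  X <- as.matrix(X)
  condition <- as.factor(condition)
  if (length(condition) != nrow(X)) {
    abort("`condition` must label every session (row).",
          class = "devaltms_input_error")
  }
  sizes <- table(condition)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Each of >= 2 conditions needs >= 2 sessions.",
          class = "devaltms_degenerate_error")
  }
  bf_test <- function(x) {
    med <- tapply(x, condition, median)
    d <- abs(x - med[condition])
    ft <- stats::oneway.test(d ~ condition, var.equal = TRUE)
    c(ft$statistic, ft$p.value)
  }
  welch_test <- function(x) {
    ft <- stats::oneway.test(x ~ condition, var.equal = FALSE)
    c(ft$statistic, ft$p.value)
  }
  bf <- apply(X, 2, bf_test)
  we <- apply(X, 2, welch_test)
  per_feature <- tibble(
    feature = colnames(X) %||% as.character(seq_len(ncol(X))),
    bf_stat = bf[1, ], bf_p = bf[2, ], bf_q = p.adjust(bf[2, ], "BH"),
    welch_stat = we[1, ], welch_p = we[2, ], welch_q = p.adjust(we[2, ], "BH")
  )
  sess_var <- apply(X, 1, var)
  sess_mean <- rowMeans(X)
  pooled <- bind_rows(
    {
      ft <- stats::oneway.test(sess_var ~ condition, var.equal = FALSE)
      tibble(test = "pooled_variance", statistic = unname(ft$statistic),
             p_value = ft$p.value)
    },
    {
      ft <- stats::oneway.test(sess_mean ~ condition, var.equal = FALSE)
      tibble(test = "pooled_mean", statistic = unname(ft$statistic),
             p_value = ft$p.value)
    }
  )
  list(per_feature = per_feature,
       n_var_significant = sum(per_feature$bf_q < q),
       n_mean_significant = sum(per_feature$welch_q < q),
       pooled = pooled)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, summed over
#' latent dimensions (and over rows if matrices are supplied).
#'
#' @param mu,logvar Numeric vectors or matrices of matching shape.
#' @return Scalar KL divergence (non-negative).
#' @export
kl_standard_normal <- function(mu, logvar) {
  if (length(mu) != length(logvar)) {
    abort("`mu` and `logvar` must match in shape.",
          class = "devaltms_input_error")
  }
  if (anyNA(mu) || anyNA(logvar) || any(!is.finite(mu)) || any(!is.finite(logvar))) {
    abort("`mu` and `logvar` must be finite.", class = "devaltms_input_error")
  }
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
}

one_hot <- function(cond, levels = NULL) {
  f <- factor(cond, levels = levels %||% sort(unique(as.character(cond))))
  if (anyNA(f)) {
    abort("Condition label outside the model's participant set.",
          class = "devaltms_input_error")
  }
  Y <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

relu <- function(x) (x > 0) * x

cvae_init_params <- function(cfg) {
  d <- cfg$input_dim; c <- cfg$n_conditions; h <- cfg$hidden_units
  L <- cfg$latent_dim
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  xav <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(1 / nin)), nin, nout)
  list(W1 = he(d + c, h), b1 = rep(0, h),
       Wmu = xav(h, L), bmu = rep(0, L),
       Wlv = xav(h, L), blv = rep(0, L),
       W4 = he(L + c, h), b4 = rep(0, h),
       W5 = xav(h, d), b5 = rep(0, d))
}

cvae_forward <- function(params, X, Y, cfg, eps = NULL) {
  A <- cbind(X, Y)
  H1 <- relu(sweep(A %*% params$W1, 2, params$b1, "+"))
  mu <- sweep(H1 %*% params$Wmu, 2, params$bmu, "+")
  lv_raw <- sweep(H1 %*% params$Wlv, 2, params$blv, "+")
  lv <- clamp(lv_raw, -cfg$logvar_clamp, cfg$logvar_clamp)
  z <- if (is.null(eps)) mu else mu + eps * exp(0.5 * lv)
  B <- cbind(z, Y)
  H2 <- relu(sweep(B %*% params$W4, 2, params$b4, "+"))
  xhat <- sweep(H2 %*% params$W5, 2, params$b5, "+")
  list(A = A, H1 = H1, mu = mu, lv_raw = lv_raw, lv = lv, z = z, B = B,
       H2 = H2, xhat = xhat, eps = eps)
}

cvae_backward <- function(params, X, fw, cfg) {
  n <- nrow(X); L <- cfg$latent_dim
  G_xhat <- 2 * (fw$xhat - X) / n
  gW5 <- crossprod(fw$H2, G_xhat); gb5 <- colSums(G_xhat)
  G_H2 <- tcrossprod(G_xhat, params$W5) * (fw$H2 > 0)
  gW4 <- crossprod(fw$B, G_H2); gb4 <- colSums(G_H2)
  G_B <- tcrossprod(G_H2, params$W4)
  G_z <- G_B[, seq_len(L), drop = FALSE]
  G_mu <- G_z + fw$mu / n
  G_lv <- G_z * fw$eps * 0.5 * exp(0.5 * fw$lv) + 0.5 * (exp(fw$lv) - 1) / n
  G_lv <- G_lv * (abs(fw$lv_raw) < cfg$logvar_clamp)
  gWmu <- crossprod(fw$H1, G_mu); gbmu <- colSums(G_mu)
  gWlv <- crossprod(fw$H1, G_lv); gblv <- colSums(G_lv)
  G_H1 <- (tcrossprod(G_mu, params$Wmu) + tcrossprod(G_lv, params$Wlv)) *
    (fw$H1 > 0)
  gW1 <- crossprod(fw$A, G_H1); gb1 <- colSums(G_H1)
  list(W1 = gW1, b1 = gb1, Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
}

#' Train the participant-conditioned VAE
#'
#' Full-batch gradient training with the Adam optimizer on the combined
#' loss: per-batch mean of the summed squared reconstruction error plus
#' the KL divergence of the approximate posterior from the standard
#' Gaussian prior, with the reparameterization trick
#' `z = mu + eps * exp(0.5 * logvar)`. Training is bit-reproducible given
#' the configuration seed.
#'
#' @param X Standardized feature matrix (sessions x features).
#' @param cond Participant label per session (conditioning variable).
#' @param config A [cvae_config()]; `input_dim` and `n_conditions` must
#'   match the data.
#' @param tms_condition TMS condition label per session; required when
#'   `config$resampling = "inverse_condition_weight"`.
#' @return An object of class `"cvae_model"`: `params` (weights), `config`,
#'   `cond_levels`, `loss` (tibble `epoch`, `total`, `recon`, `kl`), and,
#'   under resampling, `resampling_counts` (total draws per TMS condition
#'   across epochs).
#' @export
train_cvae <- function(X, cond, config = cvae_config(), tms_condition = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(cond)) {
    abort("`cond` must label every session (row) of `X`.",
          class = "devaltms_input_error")
  }
  if (ncol(X) != config$input_dim) {
    abort(sprintf("`X` has %d features but config$input_dim = %d.",
                  ncol(X), config$input_dim), class = "devaltms_input_error")
  }
  Y <- one_hot(cond)
  if (ncol(Y) > config$n_conditions) {
    abort("More participants than config$n_conditions.",
          class = "devaltms_input_error")
  }
  if (ncol(Y) < config$n_conditions) {
    Y <- cbind(Y, matrix(0, nrow(Y), config$n_conditions - ncol(Y)))
  }
  weights <- NULL
  if (config$resampling == "inverse_condition_weight") {
    if (is.null(tms_condition)) {
      abort("`tms_condition` is required for inverse-condition resampling.",
            class = "devaltms_input_error")
    }
    counts <- table(tms_condition)
    weights <- 1 / as.numeric(counts[as.character(tms_condition)])
  }
  n <- nrow(X); L <- config$latent_dim
  draw_counts <- NULL
  if (!is.null(weights)) {
    draw_counts <- setNames(numeric(length(unique(tms_condition))),
                            sort(unique(as.character(tms_condition))))
  }

  withr::with_seed(derive_seed(config$seed, "cvae-train"), {
    params <- cvae_init_params(config)
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    lr <- config$learning_rate
    loss <- matrix(NA_real_, config$epochs, 3)

    for (epoch in seq_len(config$epochs)) {
      rows <- if (is.null(weights)) seq_len(n) else
        sample.int(n, n, replace = TRUE, prob = weights)
      if (!is.null(draw_counts)) {
        tb <- table(as.character(tms_condition)[rows])
        draw_counts[names(tb)] <- draw_counts[names(tb)] + as.numeric(tb)
      }
      Xb <- X[rows, , drop = FALSE]; Yb <- Y[rows, , drop = FALSE]
      eps <- matrix(rnorm(length(rows) * L), length(rows), L)
      fw <- cvae_forward(params, Xb, Yb, config, eps)
      recon <- sum((fw$xhat - Xb)^2) / length(rows)
      kl <- kl_standard_normal(fw$mu, fw$lv) / length(rows)
      if (!is.finite(recon) || !is.finite(kl)) {
        abort(sprintf("Non-finite loss at epoch %d (recon %.3g, kl %.3g); check feature scaling.",
                      epoch, recon, kl), class = "devaltms_training_error")
      }
      loss[epoch, ] <- c(recon + kl, recon, kl)
      grads <- cvae_backward(params, Xb, fw, config)
      for (nm in names(params)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * grads[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- mstate[[nm]] / (1 - b1^epoch)
        vhat <- vstate[[nm]] / (1 - b2^epoch)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
  })

  structure(list(params = params, config = config,
                 cond_levels = colnames(Y)[colnames(Y) != ""] %||% levels(factor(cond)),
                 loss = tibble(epoch = seq_len(config$epochs),
                               total = loss[, 1], recon = loss[, 2],
                               kl = loss[, 3]),
                 resampling_counts = draw_counts),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Conditional VAE: %d features -> %d latent dims (hidden %d, %d participants)\n",
              cfg$input_dim, cfg$latent_dim, cfg$hidden_units, cfg$n_conditions))
  cat(sprintf("  %d epochs, lr %g, seed %s; final loss %.4f (recon %.4f, KL %.4f)\n",
              cfg$epochs, cfg$learning_rate, format(cfg$seed),
              x$loss$total[cfg$epochs], x$loss$recon[cfg$epochs],
              x$loss$kl[cfg$epochs]))
  invisible(x)
}

#' @describeIn train_cvae Loss trace, one row per epoch.
#' @param x A `"cvae_model"`.
#' @param ... Unused.
#' @export
tidy.cvae_model <- function(x, ...) x$loss

#' @describeIn train_cvae One-row training summary.
#' @export
glance.cvae_model <- function(x, ...) {
  tibble(epochs = x$config$epochs, latent_dim = x$config$latent_dim,
         final_loss = x$loss$total[nrow(x$loss)],
         final_recon = x$loss$recon[nrow(x$loss)],
         final_kl = x$loss$kl[nrow(x$loss)])
}

#' Encode sessions into the latent space
#'
#' @param model A `"cvae_model"`.
#' @param X Feature matrix (standardized with the training convention).
#' @param cond Participant label per session.
#' @param deterministic If `TRUE` (default) return the posterior mean
#'   `mu`; otherwise draw `z` via the reparameterization trick under
#'   `seed`.
#' @param seed Seed for the sampled-z option.
#' @return A list with `mu`, `logvar`, and (if sampled) `z`.
#' @export
encode_cvae <- function(model, X, cond, deterministic = TRUE, seed = 1) {
  stopifnot(inherits(model, "cvae_model"))
  X <- as.matrix(X)
  Y <- one_hot(cond, levels = model$cond_levels)
  if (ncol(Y) < model$config$n_conditions) {
    Y <- cbind(Y, matrix(0, nrow(Y), model$config$n_conditions - ncol(Y)))
  }
  eps <- if (deterministic) NULL else
    withr::with_seed(derive_seed(seed, "encode"),
                     matrix(rnorm(nrow(X) * model$config$latent_dim),
                            nrow(X), model$config$latent_dim))
  fw <- cvae_forward(model$params, X, Y, model$config, eps)
  out <- list(mu = fw$mu, logvar = fw$lv)
  if (!deterministic) out$z <- fw$z
  out
}

#' Reconstruct sessions through the trained model
#'
#' Deterministic reconstruction: the decoder is applied to the posterior
#' mean embedding.
#'
#' @inheritParams encode_cvae
#' @return Matrix of reconstructed feature vectors.
#' @export
reconstruct_cvae <- function(model, X, cond) {
  stopifnot(inherits(model, "cvae_model"))
  X <- as.matrix(X)
  Y <- one_hot(cond, levels = model$cond_levels)
  if (ncol(Y) < model$config$n_conditions) {
    Y <- cbind(Y, matrix(0, nrow(Y), model$config$n_conditions - ncol(Y)))
  }
  cvae_forward(model$params, X, Y, model$config, eps = NULL)$xhat
}

#' Reconstruction fidelity per session and condition
#'
#' Pearson correlation between each session's input and reconstruction
#' (deterministic mode), summarized per TMS condition, with a Welch t-test
#' comparing sham and cTBS fidelity.
#'
#' @param model A `"cvae_model"`.
#' @param X,cond Sessions and participant labels.
#' @param tms_condition TMS condition per session.
#' @return A list with `per_session` (tibble `tms_condition`, `r`),
#'   `by_condition` (mean r per condition), and `test` (tibble `t`, `df`,
#'   `p_value` for sham vs cTBS).
#' @export
reconstruction_fidelity <- function(model, X, cond, tms_condition) {
  X <- as.matrix(X)
  xhat <- reconstruct_cvae(model, X, cond)
  r <- vapply(seq_len(nrow(X)), function(i) {
    if (sd(xhat[i, ]) == 0) {
      warn(sprintf("Constant reconstruction for session %d; r undefined.", i))
      return(NA_real_)
    }
    cor(X[i, ], xhat[i, ])
  }, numeric(1))
  per_session <- tibble(tms_condition = as.character(tms_condition), r = r)
  by_condition <- per_session |>
    group_by(.data$tms_condition) |>
    summarise(mean_r = mean(.data$r, na.rm = TRUE), n = n(), .groups = "drop")
  test <- NULL
  if (all(c("sham", "cTBS") %in% per_session$tms_condition)) {
    tt <- t.test(r ~ tms_condition,
                 data = filter(per_session, .data$tms_condition %in% c("cTBS", "sham")))
    test <- tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  }
  list(per_session = per_session, by_condition = by_condition, test = test)
}

#' Latent-space distances to the null baseline
#'
#' Embeds every session at its posterior mean and computes, per
#' participant, the Euclidean distance of each sham and cTBS session
#' embedding from that participant's null-baseline embedding. Per-condition
#' means and the neural TMS effect (cTBS minus sham) follow. Participants
#' lacking a null session or all sessions of a condition are excluded with
#' a message.
#'
#' @param model A `"cvae_model"`.
#' @param X Feature matrix (sessions x features).
#' @param labels Tibble aligned with the rows of `X`: `participant`,
#'   `condition` (`"null"`/`"sham"`/`"cTBS"`).
#' @param mu Optional precomputed embedding matrix (rows aligned with
#'   `labels`); bypasses the model (used for fixtures and oracles).
#' @return A tibble of class `"neural_effects"`: `participant`,
#'   `dist_sham`, `dist_ctbs`, `effect` (= cTBS - sham), `n_sham`,
#'   `n_ctbs`. Excluded participants are recorded in the `"excluded"`
#'   attribute.
#' @export
latent_distances <- function(model, X, labels, mu = NULL) {
  check_columns(labels, c("participant", "condition"), "labels")
  if (is.null(mu)) {
    stopifnot(inherits(model, "cvae_model"))
    mu <- encode_cvae(model, X, labels$participant, deterministic = TRUE)$mu
  }
  if (nrow(mu) != nrow(labels)) {
    abort("`labels` must align with the embedded sessions.",
          class = "devaltms_input_error")
  }
  ppts <- sort(unique(labels$participant))
  rows <- purrr::map(ppts, function(p) {
    idx <- which(labels$participant == p)
    cond <- labels$condition[idx]
    if (sum(cond == "null") < 1 || !any(cond == "sham") || !any(cond == "cTBS")) {
      return(p) # excluded; reason = missing required sessions
    }
    null_mu <- colMeans(mu[idx[cond == "null"], , drop = FALSE])
    dist_to_null <- sqrt(colSums((t(mu[idx, , drop = FALSE]) - null_mu)^2))
    tibble(participant = p,
           dist_sham = mean(dist_to_null[cond == "sham"]),
           dist_ctbs = mean(dist_to_null[cond == "cTBS"]),
           n_sham = sum(cond == "sham"), n_ctbs = sum(cond == "cTBS"))
  })
  excluded <- unlist(purrr::keep(rows, is.character))
  if (length(excluded) > 0) {
    message(sprintf("Excluding %d participant(s) without the required sessions: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  out <- bind_rows(purrr::keep(rows, is.data.frame)) |>
    mutate(effect = .data$dist_ctbs - .data$dist_sham)
  attr(out, "excluded") <- excluded
  class(out) <- c("neural_effects", class(out))
  out
}

#' Paired test of cTBS versus sham latent deviation
#'
#' Two-sided paired t-test across participants of the mean
#' distance-to-null under cTBS against the mean under sham.
#'
#' @param effects A `"neural_effects"` tibble from [latent_distances()].
#' @return Tibble `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_effect_test <- function(effects) {
  check_columns(effects, c("dist_ctbs", "dist_sham"), "effects")
  if (nrow(effects) < 3) {
    abort("Paired test requires >= 3 participants with both conditions.",
          class = "devaltms_input_error")
  }
  d <- effects$dist_ctbs - effects$dist_sham
  if (sd(d) == 0) {
    warn("Zero-variance paired differences; test degenerate.")
    return(tibble(t = NA_real_, df = nrow(effects) - 1, p_value = NA_real_,
                  mean_diff = mean(d), n = nrow(effects)))
  }
  tt <- t.test(effects$dist_ctbs, effects$dist_sham, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate),
         n = nrow(effects))
}

#' Brain-behavior correlation of TMS effects
#'
#' Pearson correlation, within each stimulation-target group, between the
#' per-participant neural TMS effect (latent deviation, cTBS minus sham)
#' and the behavioral TMS effect (change in fitted sated-choice
#' probability).
#'
#' @param neural Tibble `participant`, `effect` (neural).
#' @param behavioral Tibble `participant`, `effect` (behavioral).
#' @param groups Tibble `participant`, `target_group`.
#' @return Tibble `target_group`, `n`, `r`, `p_value`; groups with fewer
#'   than 3 matched participants get `NA` with a warning.
#' @export
brain_behavior_correlation <- function(neural, behavioral, groups) {
  check_columns(neural, c("participant", "effect"), "neural")
  check_columns(behavioral, c("participant", "effect"), "behavioral")
  check_columns(groups, c("participant", "target_group"), "groups")
  merged <- neural |>
    select("participant", neural_effect = "effect") |>
    dplyr::inner_join(select(behavioral, "participant", behavioral_effect = "effect"),
                      by = "participant") |>
    dplyr::inner_join(groups, by = "participant")
  merged |>
    group_by(.data$target_group) |>
    summarise(n = n(),
              r = if (n() >= 3) cor(.data$neural_effect, .data$behavioral_effect) else {
                warn("Fewer than 3 matched participants in a group; r undefined.")
                NA_real_
              },
              p_value = if (n() >= 3) {
                cor.test(.data$neural_effect, .data$behavioral_effect)$p.value
              } else NA_real_,
              .groups = "drop")
}

#' Sensitivity of the latent deviation effect to latent dimensionality
#'
#' Retrains the conditional VAE for each latent dimensionality with all
#' other settings fixed, recomputes the latent distances to the null
#' baseline, and runs the paired cTBS-vs-sham test. Per-dimension failures
#' are captured, not propagated.
#'
#' @param X Feature matrix (sessions x features).
#' @param labels Session labels as in [latent_distances()].
#' @param dims Latent dimensionalities to sweep (default 2, 4, 8, 12, 16,
#'   32).
#' @param config Base [cvae_config()].
#' @return Tibble `latent_dim`, `t`, `df`, `p_value`, `mean_diff`, `n`,
#'   `error` (message or `NA`).
#' @export
latent_dim_sweep <- function(X, labels, dims = c(2, 4, 8, 12, 16, 32),
                             config = cvae_config()) {
  if (length(dims) == 0) {
    abort("`dims` must be non-empty.", class = "devaltms_input_error")
  }
  purrr::map_dfr(dims, function(d) {
    res <- tryCatch({
      cfg <- config
      cfg$latent_dim <- as.integer(d)
      model <- train_cvae(X, labels$participant, cfg,
                          tms_condition = labels$condition)
      eff <- suppressMessages(latent_distances(model, X, labels))
      cbind(tibble(latent_dim = d), paired_effect_test(eff),
            tibble(error = NA_character_))
    }, error = function(e) {
      tibble(latent_dim = d, t = NA_real_, df = NA_real_, p_value = NA_real_,
             mean_diff = NA_real_, n = NA_integer_,
             error = conditionMessage(e))
    })
    res
  })
}
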