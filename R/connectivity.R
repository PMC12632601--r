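# Array-level connectivity construction: multi-echo tSNR-weighted
# combination, framewise displacement, nuisance regression, ROI and
# ROI-to-atlas correlations, and network contrasts.

#' Combine multi-echo fMRI signals with tSNR x TE weighting
#'
#' Parallel-acquired inhomogeneity-desensitized (PAID) combination: per
#' voxel, each echo's temporal signal-to-noise ratio (mean over time
#' divided by SD over time) is multiplied by its echo time and the products
#' are normalized across echoes to weights summing to one; the combined
#' signal is the weighted sum of the echo signals. Voxels where every
#' echo's tSNR is undefined (zero temporal variance) fall back to equal
#' weights, with a message.
#'
#' @param echoes List of >= 2 numeric matrices (voxels x time), identical
#'   dimensions, ordered by echo.
#' @param te Echo times (ms), strictly increasing, one per echo.
#' @return A list of class `"paid_combined"`: `signal` (voxels x time
#'   combined matrix), `weights` (voxels x echoes matrix), `te`.
#' @export
paid_combine <- function(echoes, te) {
  if (!is.list(echoes) || length(echoes) < 2) {
    abort("`echoes` must be a list of at least two aligned arrays.",
          class = "devaltms_input_error")
  }
  dims <- lapply(echoes, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    abort("All echoes must share the same dimensions.",
          class = "devaltms_input_error")
  }
  if (length(te) != length(echoes) || any(diff(te) <= 0)) {
    abort("`te` must supply strictly increasing echo times, one per echo.",
          class = "devaltms_input_error")
  }
  echoes <- lapply(echoes, function(e) {
    if (is.null(dim(e))) matrix(e, nrow = 1) else as.matrix(e)
  })
  tsnr <- vapply(echoes, function(e) {
    mu <- rowMeans(e)
    s <- apply(e, 1, sd)
    ifelse(s > 0, mu / s, NA_real_)
  }, numeric(nrow(echoes[[1]])))
  tsnr <- matrix(tsnr, nrow = nrow(echoes[[1]]))
  raw_w <- sweep(tsnr, 2, te, "*")
  undef <- apply(raw_w, 1, function(r) all(!is.finite(r)))
  if (any(undef)) {
    message(sprintf("%d voxel(s) with undefined tSNR: equal weights used.",
                    sum(undef)))
    raw_w[undef, ] <- 1
  }
  raw_w[!is.finite(raw_w)] <- 0
  weights <- raw_w / rowSums(raw_w)
  combined <- Reduce(`+`, purrr::map2(echoes, seq_along(echoes), function(e, i) {
    e * weights[, i]
  }))
  structure(list(signal = combined, weights = weights, te = te),
            class = "paid_combined")
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' changes in the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of radius `radius`. The
#' first volume's FD is zero by definition; the session summary is the sum
#' over all subsequent volumes.
#'
#' @param motion Numeric matrix (volumes x 6): three translations in mm,
#'   then three rotations in radians.
#' @param radius Rotation-to-displacement sphere radius in mm (default 50).
#' @return A list with `fd` (per-volume vector, first element 0) and
#'   `total` (sum over volumes).
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    abort("`motion` must have 6 columns: 3 translations (mm) + 3 rotations (rad).",
          class = "devaltms_input_error")
  }
  check_scalar_number(radius, "radius", min = 0, open = TRUE)
  if (nrow(motion) < 2) return(list(fd = rep(0, nrow(motion)), total = 0))
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, total = sum(fd))
}

#' Regress nuisance signals out of time series
#'
#' Ordinary least-squares nuisance regression: the regressors are z-scored,
#' an intercept is added, and the fitted values are removed from every
#' series. Collinear (rank-deficient) regressor sets raise an error naming
#' the offending columns.
#'
#' @param timeseries Numeric matrix (time x series).
#' @param regressors Numeric matrix or data frame (time x regressors);
#'   column names are used in error messages.
#' @return Residual matrix with the dimensions of `timeseries`.
#' @export
nuisance_regress <- function(timeseries, regressors) {
  Y <- as.matrix(timeseries)
  X <- as.matrix(regressors)
  if (nrow(Y) != nrow(X)) {
    abort("`timeseries` and `regressors` must have the same number of time points.",
          class = "devaltms_input_error")
  }
  cn <- colnames(X) %||% sprintf("regressor_%d", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant regressor(s) cannot be z-scored: %s.",
                  paste(cn[sds == 0], collapse = ", ")),
          class = "devaltms_input_error")
  }
  Xz <- cbind(intercept = 1, scale(X))
  qrX <- qr(Xz)
  if (qrX$rank < ncol(Xz)) {
    dropped <- setdiff(colnames(Xz), colnames(Xz)[qrX$pivot[seq_len(qrX$rank)]])
    abort(sprintf("Rank-deficient regressor set; collinear column(s): %s.",
                  paste(dropped, collapse = ", ")),
          class = "devaltms_rank_error")
  }
  Y - Xz %*% qr.coef(qrX, Y)
}

#' Compute session functional-connectivity matrices
#'
#' Pearson correlations among the four experimental ROI series (symmetric
#' 4 x 4 matrix with unit diagonal) and between each ROI and every atlas
#' region series. Atlas regions with undefined correlations (constant or
#' missing series) are dropped and recorded so the feature indexing stays
#' stable across sessions.
#'
#' @param roi_ts Numeric matrix (time x 4), columns named with ROI roles
#'   (e.g. `aOFC`, `pOFC`, `aLPFC`, `pLPFC`).
#' @param atlas_ts Numeric matrix (time x regions), columns named by
#'   region.
#' @return A list of class `"session_fc"`: `fc_roi` (ROI x ROI),
#'   `fc_pattern` (ROI x kept regions), `dropped_regions` (character).
#' @export
compute_fc <- function(roi_ts, atlas_ts) {
  roi_ts <- as.matrix(roi_ts); atlas_ts <- as.matrix(atlas_ts)
  if (nrow(roi_ts) != nrow(atlas_ts)) {
    abort("ROI and atlas series must share time points.",
          class = "devaltms_input_error")
  }
  if (is.null(colnames(roi_ts))) colnames(roi_ts) <- sprintf("roi_%d", seq_len(ncol(roi_ts)))
  if (is.null(colnames(atlas_ts))) colnames(atlas_ts) <- sprintf("region_%d", seq_len(ncol(atlas_ts)))
  bad_roi <- apply(roi_ts, 2, function(x) anyNA(x) || sd(x) == 0)
  if (any(bad_roi)) {
    abort(sprintf("ROI series with undefined variance: %s.",
                  paste(colnames(roi_ts)[bad_roi], collapse = ", ")),
          class = "devaltms_input_error")
  }
  bad <- apply(atlas_ts, 2, function(x) anyNA(x) || sd(x) == 0)
  if (any(bad)) {
    message(sprintf("Dropping %d atlas region(s) with undefined signal: %s",
                    sum(bad), paste(colnames(atlas_ts)[bad], collapse = ", ")))
  }
  kept <- atlas_ts[, !bad, drop = FALSE]
  structure(list(fc_roi = stats::cor(roi_ts),
                 fc_pattern = stats::cor(roi_ts, kept),
                 dropped_regions = colnames(atlas_ts)[bad]),
            class = "session_fc")
}

#' Regions shared by every session's connectivity pattern
#'
#' @param sessions List of `"session_fc"` objects.
#' @return Character vector of region names present in all sessions.
#' @export
common_fc_regions <- function(sessions) {
  Reduce(intersect, lapply(sessions, function(s) colnames(s$fc_pattern)))
}

#' AAL atlas region labels
#'
#' The 116-region Automated Anatomical Labeling parcellation lookup table
#' shipped with the package.
#'
#' @return Tibble `index`, `region`.
#' @export
aal_regions <- function() {
  path <- system.file("extdata", "aal116_regions.tsv", package = "devaltms")
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Within-network, between-LPFC, and cross-network contrasts
#'
#' From each session's 4 x 4 ROI correlation matrix computes: the
#' within-network connectivity (mean of each OFC seed's correlation with
#' its corresponding LPFC target), the between-LPFC connectivity
#' (correlation between the two LPFC targets), and the cross-network
#' connectivity (mean of each OFC seed's correlation with the
#' non-corresponding LPFC target). The two orderings (within greater than
#' between-LPFC; between-LPFC greater than cross) are tested with linear
#' mixed models with participant random intercepts.
#'
#' @param sessions List of `"session_fc"` objects whose `fc_roi` matrices
#'   carry dimnames containing `aOFC`, `pOFC`, `aLPFC`, `pLPFC`.
#' @param participants Character vector aligning participants to
#'   `sessions`.
#' @param fisher_z Apply the Fisher z-transform before the mixed-model
#'   contrasts (correlation summaries stay raw).
#' @return A list with `summaries` (tibble `participant`, `within`,
#'   `between_lpfc`, `cross`) and `tests` (tibble of the two
#'   `"model_comparison"` results: contrast, statistic, df, p, estimate).
#' @export
network_contrasts <- function(sessions, participants, fisher_z = FALSE) {
  if (length(sessions) != length(participants)) {
    abort("`sessions` and `participants` must align.",
          class = "devaltms_input_error")
  }
  roles <- c("aOFC", "pOFC", "aLPFC", "pLPFC")
  summaries <- purrr::map2_dfr(sessions, participants, function(s, p) {
    m <- s$fc_roi
    if (is.null(rownames(m)) || !all(roles %in% rownames(m))) {
      abort("ROI roles aOFC, pOFC, aLPFC, pLPFC must label the 4 x 4 matrix.",
            class = "devaltms_input_error")
    }
    tibble(participant = p,
           within = mean(c(m["aOFC", "aLPFC"], m["pOFC", "pLPFC"])),
           between_lpfc = m["aLPFC", "pLPFC"],
           cross = mean(c(m["aOFC", "pLPFC"], m["pOFC", "aLPFC"])))
  })
  long <- tidyr::pivot_longer(summaries, c("within", "between_lpfc", "cross"),
                              names_to = "type", values_to = "fc")
  if (fisher_z) long$fc <- atanh(clamp(long$fc, -1 + 1e-12, 1 - 1e-12))
  test_pair <- function(types, label) {
    dat <- filter(long, .data$type %in% types) |>
      mutate(type = factor(.data$type, levels = types))
    if (sd(dat$fc) == 0) {
      return(tibble(contrast = label, statistic = 0, df = 1, p_value = 1,
                    estimate = 0))
    }
    if (dplyr::n_distinct(dat$participant) < 2) {
      # participant random intercept needs >= 2 levels
      return(tibble(contrast = label, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_,
                    estimate = mean(dat$fc[dat$type == types[1]]) -
                      mean(dat$fc[dat$type == types[2]])))
    }
    full <- lme4::lmer(fc ~ type + (1 | participant), data = dat, REML = FALSE)
    reduced <- lme4::lmer(fc ~ (1 | participant), data = dat, REML = FALSE)
    mc <- new_model_comparison(full, reduced, label)
    est <- -unname(lme4::fixef(full)[2]) # first level minus second level
    tibble(contrast = label, statistic = mc$statistic, df = mc$df,
           p_value = mc$p_value, estimate = est)
  }
  tests <- bind_rows(
    test_pair(c("within", "between_lpfc"), "within_vs_between"),
    test_pair(c("between_lpfc", "cross"), "between_vs_cross")
  )
  list(summaries = summaries, tests = tests)
}
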