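test_that("multi-echo combination weights by tSNR times TE and normalizes", {
  # two echoes, one voxel, exact means and SDs by construction:
  # echo 1: mean 100, sd 10 -> tSNR 10, TE 15 -> 150
  # echo 2: mean 50, sd 10 -> tSNR 5, TE 60 -> 300
  e1 <- matrix(c(90, 110, 90, 110), 1)
  e2 <- matrix(c(40, 60, 40, 60), 1)
  s <- sd(c(90, 110, 90, 110))
  out <- paid_combine(list(e1, e2), te = c(15, 60))
  w1 <- (100 / s * 15) / (100 / s * 15 + 50 / s * 60)
  expect_equal(unname(out$weights[1, ]), c(w1, 1 - w1), tolerance = 1e-12)
  expect_equal(unname(out$weights[1, ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(out$signal[1, ], (e1[1, ] + 2 * e2[1, ]) / 3, tolerance = 1e-12)

  # identical echoes reproduce the input; weights always sum to one
  withr::with_seed(2, e <- matrix(rnorm(60, 100, 5), 6))
  id <- paid_combine(list(e, e, e), te = c(14.6, 39.04, 63.48))
  expect_equal(id$signal, e, tolerance = 1e-12)
  expect_equal(rowSums(id$weights), rep(1, 6), tolerance = 1e-12)

  # common rescaling of all echoes rescales the output (tSNR unchanged)
  withr::with_seed(3, {
    a <- matrix(rnorm(40, 100, 8), 4)
    b <- matrix(rnorm(40, 60, 8), 4)
  })
  base <- paid_combine(list(a, b), te = c(15, 60))
  scaled <- paid_combine(list(3 * a, 3 * b), te = c(15, 60))
  expect_equal(scaled$signal, 3 * base$signal, tolerance = 1e-10)
  expect_equal(scaled$weights, base$weights, tolerance = 1e-12)

  # zero-variance voxel falls back to equal weights, with a message
  z1 <- matrix(5, 1, 4); z2 <- matrix(9, 1, 4)
  expect_message(fz <- paid_combine(list(z1, z2), te = c(15, 60)), "equal weights")
  expect_equal(unname(fz$weights[1, ]), c(0.5, 0.5))

  expect_error(paid_combine(list(e1), te = 15), class = "devaltms_input_error")
  expect_error(paid_combine(list(e1, e2), te = c(60, 15)),
               class = "devaltms_input_error")
})

test_that("framewise displacement follows the Power formulation and adds over concatenation", {
  expect_equal(framewise_displacement(matrix(0, 10, 6))$total, 0)

  step <- matrix(0, 5, 6); step[3:5, 1] <- 1 # 1 mm x-translation step
  fd <- framewise_displacement(step)
  expect_equal(fd$fd, c(0, 0, 1, 0, 0))
  expect_equal(fd$total, 1)

  pitch <- matrix(0, 3, 6); pitch[2:3, 4] <- 0.01 # 0.01 rad step
  expect_equal(framewise_displacement(pitch, radius = 50)$fd[2], 0.5)

  # concatenation at a shared joint position sums the totals
  withr::with_seed(4, m1 <- matrix(cumsum(rnorm(60, 0, 0.05)), 10, 6))
  m2 <- m1[rep(10, 8), ] + matrix(cumsum(rnorm(48, 0, 0.05)), 8, 6) -
    matrix(rep(cumsum(rnorm(48, 0, 0.05))[1:6], each = 8), 8, 6) * 0
  m2[1, ] <- m1[10, ] # trace 2 starts where trace 1 ended
  t_sep <- framewise_displacement(m1)$total + framewise_displacement(m2)$total
  t_cat <- framewise_displacement(rbind(m1, m2[-1, , drop = FALSE]))$total
  expect_equal(t_cat, t_sep, tolerance = 1e-12)

  expect_error(framewise_displacement(matrix(0, 5, 5)),
               class = "devaltms_input_error")
})

test_that("nuisance regression yields residuals orthogonal to all regressors", {
  withr::with_seed(6, {
    Y <- matrix(rnorm(300), 30)
    X <- matrix(rnorm(120), 30)
  })
  res <- nuisance_regress(Y, X)
  design <- cbind(1, scale(X))
  expect_lt(max(abs(crossprod(design, res))), 1e-8)

  # a series regressed on itself vanishes
  y <- rnorm(30)
  expect_lt(max(abs(nuisance_regress(matrix(y), matrix(y)))), 1e-10)

  # 5-timepoint system against hand-solved normal equations
  Y5 <- matrix(c(1, 3, 2, 5, 4), 5)
  X5 <- matrix(c(1, 2, 3, 4, 5, 2, 1, 2, 1, 2), 5)
  design5 <- cbind(1, scale(X5))
  beta <- solve(crossprod(design5), crossprod(design5, Y5))
  expect_equal(nuisance_regress(Y5, X5), Y5 - design5 %*% beta,
               tolerance = 1e-12, ignore_attr = TRUE)

  # rank deficiency names the collinear column
  Xc <- cbind(a = rnorm(30), b = rnorm(30))
  Xc <- cbind(Xc, c = Xc[, "a"] + Xc[, "b"])
  expect_error(nuisance_regress(Y, Xc), class = "devaltms_rank_error")
  expect_error(nuisance_regress(Y, cbind(flat = rep(1, 30))),
               regexp = "flat", class = "devaltms_input_error")
})

test_that("connectivity matrices are symmetric, scale-invariant, and drop dead regions", {
  withr::with_seed(9, {
    roi <- matrix(rnorm(4000), 1000, 4,
                  dimnames = list(NULL, c("aOFC", "pOFC", "aLPFC", "pLPFC")))
    atlas <- matrix(rnorm(8000), 1000, 8,
                    dimnames = list(NULL, paste0("R", 1:8)))
  })
  atlas[, "R3"] <- 0
  expect_message(fc <- compute_fc(roi, atlas), "R3")
  expect_equal(fc$fc_roi, t(fc$fc_roi))
  expect_equal(unname(diag(fc$fc_roi)), rep(1, 4))
  expect_equal(fc$dropped_regions, "R3")
  expect_equal(ncol(fc$fc_pattern), 7)
  # independent noise at long series: correlations near zero
  expect_lt(max(abs(fc$fc_pattern)), 0.15)

  # invariance to linear rescaling of inputs
  fc2 <- suppressMessages(compute_fc(roi %*% diag(c(2, 3, 4, 5)), atlas))
  expect_equal(unname(fc$fc_pattern), unname(fc2$fc_pattern), tolerance = 1e-12)

  expect_error(compute_fc(cbind(roi[, 1:3], 0), atlas),
               class = "devaltms_input_error")
})

test_that("network contrasts read the labeled matrix cells and recover a built-in ordering", {
  roles <- c("aOFC", "pOFC", "aLPFC", "pLPFC")
  make_fc <- function(within, between, cross) {
    m <- diag(4); dimnames(m) <- list(roles, roles)
    m["aOFC", "aLPFC"] <- m["aLPFC", "aOFC"] <- within
    m["pOFC", "pLPFC"] <- m["pLPFC", "pOFC"] <- within
    m["aLPFC", "pLPFC"] <- m["pLPFC", "aLPFC"] <- between
    m["aOFC", "pLPFC"] <- m["pLPFC", "aOFC"] <- cross
    m["pOFC", "aLPFC"] <- m["aLPFC", "pOFC"] <- cross
    structure(list(fc_roi = m), class = "session_fc")
  }
  # hand-indexed oracle on one labeled fixture
  s <- make_fc(0.6, 0.4, 0.1)
  nc1 <- network_contrasts(list(s), "P01")
  expect_equal(nc1$summaries$within, 0.6)
  expect_equal(nc1$summaries$between_lpfc, 0.4)
  expect_equal(nc1$summaries$cross, 0.1)
  expect_equal(nc1$tests$estimate, c(0.2, 0.3)) # single-participant fallback

  # constructed ordering recovered as positive contrasts across a cohort
  withr::with_seed(12, {
    sessions <- purrr::map(1:20, function(i) {
      make_fc(0.6 + rnorm(1, 0, 0.05), 0.4 + rnorm(1, 0, 0.05),
              0.1 + rnorm(1, 0, 0.05))
    })
  })
  nc <- network_contrasts(sessions, sprintf("P%02d", 1:20))
  expect_true(all(nc$tests$estimate > 0))
  expect_true(all(nc$tests$p_value < 0.01))

  # identical connectivity everywhere: zero contrasts
  flat <- network_contrasts(list(make_fc(0.3, 0.3, 0.3)), "P01")
  expect_equal(flat$summaries$within - flat$summaries$cross, 0)
  expect_equal(flat$tests$estimate, c(0, 0))

  bad <- structure(list(fc_roi = diag(4)), class = "session_fc")
  expect_error(network_contrasts(list(bad), "P01"),
               class = "devaltms_input_error")
})

test_that("the packaged atlas lookup has 116 uniquely named regions", {
  aal <- aal_regions()
  expect_equal(nrow(aal), 116)
  expect_equal(anyDuplicated(aal$region), 0)
})
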