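test_that("median polish handles constant and exactly additive plates", {
  mp <- medianPolish(matrix(5, 2, 2))
  expect_equal(mp@overall, 5)
  expect_true(all(mp@rowEffects == 0) && all(mp@colEffects == 0))
  expect_true(all(mp@residuals == 0))

  r <- c(-2, 0, 2); cc <- c(-1, 0, 1)
  m <- 10 + outer(r, cc, "+")
  mp <- medianPolish(m)
  expect_true(all(abs(mp@residuals) < 1e-12))
  expect_equal(mp@rowEffects - median(mp@rowEffects), r, tolerance = 1e-12)
  expect_equal(mp@colEffects - median(mp@colEffects), cc, tolerance = 1e-12)
  expect_equal(polishFitted(mp) + mp@residuals, m, tolerance = 1e-12)
})

test_that("a single outlier lands entirely in its residual (manual sweep oracle)", {
  m <- matrix(10, 3, 3)
  m[1, 1] <- 19
  mp <- medianPolish(m)
  expect_equal(mp@residuals[1, 1], 9)
  expect_true(all(abs(mp@residuals[-1]) < 1e-12))
})

test_that("median polish agrees with stats::medpolish where the fit is exact", {
  set.seed(8)
  for (i in 1:20) {
    m <- rnorm(1) + outer(rnorm(8), rnorm(12), "+")
    mine <- medianPolish(m)
    ref <- stats::medpolish(m, maxiter = 50L, trace.iter = FALSE)
    expect_lt(max(abs(mine@residuals)), 1e-9)
    expect_lt(max(abs(ref$residuals)), 1e-6)
    expect_equal(polishFitted(mine), m, tolerance = 1e-9)
  }
})

test_that("decomposition identity and residual medians hold on noisy plates", {
  set.seed(11)
  nConverged <- 0L
  for (i in 1:10) {
    m <- matrix(rlnorm(16 * 24, 10, 0.3), 16, 24)
    mp <- medianPolish(m, maxSweeps = 200L)
    expect_equal(polishFitted(mp) + mp@residuals, m, tolerance = 1e-9)
    if (mp@converged) {
      nConverged <- nConverged + 1L
      ## one more full sweep would change nothing beyond tol, so row and
      ## column medians of the residuals are pinned near zero
      expect_lt(max(abs(apply(mp@residuals, 1, median))), mp@tol * 2)
      expect_lt(max(abs(apply(mp@residuals, 2, median))), mp@tol * 2)
    }
  }
  expect_gt(nConverged, 5L)
})

test_that("median polish rejects bad input", {
  expect_error(medianPolish(matrix(1, 1, 5)), "2 rows")
  expect_error(medianPolish(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})

test_that("B-scores divide residuals by the robust MAD scale", {
  ## plate whose sample residuals are exactly -2,-1,0,1,2 per row block
  spec <- plateEffectSpec(rowGradient = 0, colGradient = 0,
                          edgeDepression = 0, noiseCv = 0.2, spikeRate = 0,
                          seed = 13L)
  pl <- simulateScreen(spec, nPlates = 1L)$plates[[1L]]
  bs <- bScore(pl)
  masked <- wellValues(pl)
  masked[wellRoles(pl) != "sample"] <- NA
  ref <- stats::medpolish(masked, maxiter = 10L, trace.iter = FALSE,
                          na.rm = TRUE)
  sres <- ref$residuals[wellRoles(pl) == "sample"]
  refScale <- 1.4826 * median(abs(sres - median(sres, na.rm = TRUE)),
                              na.rm = TRUE)
  expect_equal(robustScale(bs), refScale, tolerance = 0.05)
  ## location invariance: adding a constant leaves scores unchanged
  pl2 <- new("PlateGrid", plateId = plateId(pl),
             values = wellValues(pl) + 100, roles = wellRoles(pl),
             compoundIds = compoundIds(pl))
  expect_equal(bScores(bScore(pl2)), bScores(bs), tolerance = 1e-9)
  ## row/column offset equivariance (exact in the limit; the finite sweep
  ## tolerance leaves sub-1e-3 discrepancies)
  off <- outer(seq_len(16) * 7, seq_len(24) * 3, "+")
  pl3 <- new("PlateGrid", plateId = plateId(pl),
             values = wellValues(pl) + off, roles = wellRoles(pl),
             compoundIds = compoundIds(pl))
  expect_equal(bScores(bScore(pl3, maxSweeps = 50L)),
               bScores(bScore(pl, maxSweeps = 50L)), tolerance = 1e-3)
})

test_that("a spiked well carries the plate's maximum B-score", {
  spec <- plateEffectSpec(rowGradient = 0.3, colGradient = -0.2,
                          edgeDepression = 0.2, noiseCv = 0.1,
                          spikeRate = 0, seed = 17L)
  scr <- simulateScreen(spec, nPlates = 1L)
  pl <- scr$plates[[1L]]
  v <- wellValues(pl)
  ## plant one spike at +8 robust units, computed independently
  masked <- v; masked[wellRoles(pl) != "sample"] <- NA
  ref <- stats::medpolish(masked, maxiter = 10L, trace.iter = FALSE,
                          na.rm = TRUE)
  sres <- ref$residuals[!is.na(ref$residuals)]
  scale <- 1.4826 * median(abs(sres - median(sres)))
  target <- which(wellRoles(pl) == "sample")[100L]
  v[target] <- v[target] + 8 * scale
  pl2 <- new("PlateGrid", plateId = "spiked", values = v,
             roles = wellRoles(pl), compoundIds = compoundIds(pl))
  bs <- bScores(bScore(pl2))
  expect_identical(which.max(bs), target)
  expect_gt(bs[target], 4)
})

test_that("degenerate plates with zero residual scale are an error", {
  roles <- matrix("sample", 4, 4)
  cids <- matrix(sprintf("C%02d", 1:16), 4, 4)
  pl <- new("PlateGrid", plateId = "flat", values = matrix(7, 4, 4),
            roles = roles, compoundIds = cids)
  expect_error(bScore(pl), "degenerate")
})

test_that("top-N triage equals the full sort oracle and breaks ties by id", {
  set.seed(23)
  scores <- data.frame(compound_id = sprintf("CMP%05d", sample(1e5, 10240)),
                       b_score = rnorm(10240))
  top <- selectTopHits(scores, 80L)
  oracle <- scores[order(-scores$b_score, scores$compound_id), ][1:80, ]
  expect_identical(top$compound_id, oracle$compound_id)
  ## explicit tie at the boundary
  tied <- data.frame(compound_id = c("B", "A", "C"), b_score = c(1, 1, 2))
  expect_identical(selectTopHits(tied, 2L)$compound_id, c("C", "A"))
  expect_identical(nrow(selectTopHits(tied, 80L)), 3L)
  expect_error(selectTopHits(tied[0, ], 5L), "no scored")
})

test_that("confirmation threshold is mean + 3 sample SD", {
  expect_equal(confirmationThreshold(c(90, 100, 100, 110)),
               100 + 3 * sd(c(90, 100, 100, 110)))
  expect_equal(confirmationThreshold(c(90, 100, 100, 110)), 124.4949,
               tolerance = 1e-4)
  expect_equal(confirmationThreshold(rep(77, 5)), 77)
  k <- 3.7
  expect_equal(confirmationThreshold(k * c(90, 100, 100, 110)),
               k * confirmationThreshold(c(90, 100, 100, 110)))
  expect_error(confirmationThreshold(100), "two")
})

test_that("hit calling is a strict greater-than comparison in input order", {
  confirm <- data.frame(compound_id = c("a", "b", "c"),
                        signal = c(5, 10, 15))
  calls <- callHits(confirm, 10)
  expect_identical(calls$is_hit, c(FALSE, FALSE, TRUE))
  expect_identical(calls$compound_id, confirm$compound_id)
  expect_identical(nrow(callHits(confirm[0, ], 10)), 0L)
  set.seed(31)
  big <- data.frame(compound_id = sprintf("c%04d", 1:1000),
                    signal = runif(1000, 0, 2e6))
  thr <- 1.2e6
  expect_identical(callHits(big, thr)$is_hit, big$signal > thr)
})

test_that("plate CSV round-trips values and roles", {
  scr <- simulateScreen(plateEffectSpec(seed = 2L), nPlates = 2L)
  f <- tempfile(fileext = ".csv")
  writePlateCsv(scr$plates, f)
  back <- readPlateCsv(f)
  expect_identical(length(back), 2L)
  expect_equal(wellValues(back[["plate001"]]), wellValues(scr$plates[[1L]]),
               tolerance = 1e-6)
  expect_identical(wellRoles(back[["plate001"]]), wellRoles(scr$plates[[1L]]))
})
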