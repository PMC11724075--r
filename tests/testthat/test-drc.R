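test_that("normalization anchors the controls at 0 and 100 percent", {
  drc <- data.frame(compound_id = c("x", "x", "", ""),
                    conc_molar = c(1e-6, 1e-6, NA, NA),
                    replicate = c(1L, 2L, 1L, 1L),
                    value = c(550, 325, 1000, 100),
                    role = c("sample", "sample", "pos", "neg"))
  norm <- normalizeToReference(drc)
  expect_equal(norm$value, c(50, 25, 100, 0))
  ## x equal to a control mean maps exactly to its anchor
  drc$value[1] <- 1000
  expect_equal(normalizeToReference(drc)$value[1], 100)
  drc$value[1] <- 100
  expect_equal(normalizeToReference(drc)$value[1], 0)
  ## joint affine transforms of signal and controls cancel out
  shifted <- drc
  shifted$value <- 3.5 * drc$value + 777
  expect_equal(normalizeToReference(shifted)$value,
               normalizeToReference(drc)$value, tolerance = 1e-12)
  flat <- drc
  flat$value[3:4] <- 500
  expect_error(normalizeToReference(flat), "degenerate")
})

test_that("noise-free simulate -> normalize -> fit recovers the parameters", {
  tr <- c(bottom = 0, top = 100, ec50 = 1e-5, hill = 1)
  fit <- fit4PL(normalizeToReference(
    simulateDoseResponse(tr, noiseCv = 0, seed = 1L)))
  expect_true(fit@converged)
  expect_lt(abs(fit@coefficients[["bottom"]] - tr[["bottom"]]) / 100, 1e-6)
  for (p in c("top", "ec50", "hill"))
    expect_lt(abs(fit@coefficients[[p]] - tr[[p]]) / tr[[p]], 1e-6)
  ## midpoint identity of the fitted curve
  co <- fit@coefficients
  expect_equal(fourPL(co[["ec50"]], co), (co[["bottom"]] + co[["top"]]) / 2,
               tolerance = 1e-9)
  ## a second, asymmetric parameter set
  tr2 <- c(bottom = 8, top = 28, ec50 = 1.05e-5, hill = 1.7)
  fit2 <- fit4PL(normalizeToReference(
    simulateDoseResponse(tr2, noiseCv = 0, seed = 2L)))
  for (p in c("bottom", "top", "ec50", "hill"))
    expect_lt(abs(fit2@coefficients[[p]] - tr2[[p]]) / tr2[[p]], 1e-6)
})

test_that("the fitted 4PL is monotone between bottom and top", {
  tr <- c(bottom = 5, top = 60, ec50 = 4e-6, hill = 2)
  fit <- fit4PL(normalizeToReference(
    simulateDoseResponse(tr, noiseCv = 0.05, seed = 11L)))
  x <- 10^seq(-8.5, -3.5, length.out = 200)
  y <- fourPL(x, fit)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > fit@coefficients[["bottom"]] - 1e-9))
  expect_true(all(y < fit@coefficients[["top"]] + 1e-9))
})

test_that("descending curves are fitted with negative hill (IC50)", {
  tr <- c(bottom = 0, top = 100, ec50 = 3.2e-8, hill = -1)
  fit <- fitInhibition(normalizeToReference(
    simulateDoseResponse(tr, concentrations = 1e-9 * 2^(0:9), noiseCv = 0,
                         seed = 3L)))
  expect_true(fit@converged)
  expect_lt(abs(fit@coefficients[["ec50"]] - 3.2e-8) / 3.2e-8, 1e-6)
  expect_lt(fit@coefficients[["hill"]], 0)
})

test_that("a flat response curve is flagged, not silently fitted", {
  set.seed(7)
  flat <- data.frame(compound_id = "x",
                     conc_molar = rep(drcConcentrations(), each = 3L),
                     replicate = rep(1:3, 10L),
                     value = rnorm(30, 50, 0.5), role = "sample")
  fit <- fitInhibition(flat)
  expect_false(fit@converged)
  expect_error(fit4PL(flat[flat$conc_molar < 3e-7, ]), "4 distinct")
})

test_that("potentiation is the percent change of the fitted top", {
  tr <- c(bottom = 0, top = 25, ec50 = 1e-5, hill = 1)
  base <- normalizeToReference(simulateDoseResponse(tr, noiseCv = 0, seed = 5L))
  same <- potentiationAnalysis(base, list(`0` = base))
  expect_equal(same$potentiation_pct, 0, tolerance = 1e-6)
  tr2 <- tr; tr2[["top"]] <- 50
  doubled <- normalizeToReference(simulateDoseResponse(tr2, noiseCv = 0,
                                                       seed = 6L))
  expect_equal(potentiationAnalysis(base, list(`1e-6` = doubled))$potentiation_pct,
               100, tolerance = 1e-6)
  zero <- base; zero$value <- zero$value - 1000
  expect_error(potentiationAnalysis(zero, list(a = base)), "positive")
})
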