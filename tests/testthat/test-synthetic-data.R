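test_that("degenerate plate spec yields exactly the grand mean everywhere", {
  spec <- plateEffectSpec(grandMean = 5e5, rowGradient = 0, colGradient = 0,
                          edgeDepression = 0, noiseCv = 0, spikeRate = 0,
                          seed = 1L)
  scr <- simulateScreen(spec, nPlates = 1L)
  pl <- scr$plates[[1L]]
  expect_true(all(wellValues(pl)[wellRoles(pl) == "sample"] == 5e5))
})

test_that("screen simulation is byte-reproducible and truth-consistent", {
  spec <- plateEffectSpec(spikeRate = 0.02, seed = 42L)
  a <- simulateScreen(spec, nPlates = 10L)
  b <- simulateScreen(spec, nPlates = 10L)
  expect_identical(a, b)
  ## every sample well appears exactly once in the truth table
  nSample <- sum(vapply(a$plates, function(p) sum(wellRoles(p) == "sample"),
                        numeric(1)))
  expect_identical(nrow(a$truth), as.integer(nSample))
  expect_false(anyDuplicated(a$truth$compound_id) > 0L)
  expect_gt(sum(a$truth$active), 0L)
})

test_that("row gradient shows up in row means exactly as the generative formula says", {
  spec <- plateEffectSpec(rowGradient = 0.3, colGradient = 0,
                          edgeDepression = 0, noiseCv = 0, spikeRate = 0,
                          seed = 3L)
  scr <- simulateScreen(spec, nPlates = 1L)
  v <- wellValues(scr$plates[[1L]])
  v[wellRoles(scr$plates[[1L]]) != "sample"] <- NA
  expected <- expectedWellMeans(spec)
  expected[wellRoles(scr$plates[[1L]]) != "sample"] <- NA
  expect_equal(v, expected, tolerance = 1e-12)
  expect_true(all(diff(rowMeans(v, na.rm = TRUE)) > 0))
  colM <- colMeans(v, na.rm = TRUE)
  colM <- colM[is.finite(colM)]   # drop all-control columns
  expect_lt(max(abs(diff(colM))) / mean(v, na.rm = TRUE), 1e-12)
})

test_that("simulated means match the generative formula within 3 SE across seeds", {
  spec0 <- plateEffectSpec(rowGradient = 0.2, colGradient = -0.2,
                           edgeDepression = 0.1, noiseCv = 0.08,
                           spikeRate = 0, seed = 1L)
  expected <- expectedWellMeans(spec0)
  nSeeds <- 100L
  acc <- matrix(0, 16L, 24L)
  for (s in seq_len(nSeeds)) {
    sp <- spec0; sp@seed <- s
    acc <- acc + wellValues(simulateScreen(sp, nPlates = 1L)$plates[[1L]])
  }
  roles <- wellRoles(simulateScreen(spec0, nPlates = 1L)$plates[[1L]])
  sampleIdx <- roles == "sample"
  avg <- (acc / nSeeds)[sampleIdx]
  se <- expected[sampleIdx] * spec0@noiseCv / sqrt(nSeeds)
  expect_true(mean(abs(avg - expected[sampleIdx]) <= 3 * se) > 0.99)
})

test_that("non-rectangular layout is rejected", {
  expect_error(simulateScreen(plateEffectSpec(), plateDim = c(16.5, 24)),
               "rectangular")
  expect_error(simulateScreen(plateEffectSpec(), plateDim = 384), "rectangular")
})

test_that("library composition is forced at the extremes", {
  one <- generateLibrary(librarySpec(nCompounds = 40L, activeFraction = 1,
                                     seed = 5L))
  expect_true(all(rdkitMatches(smilesOf(one$library), "c1ccccc1C(=O)N")))
  zero <- generateLibrary(librarySpec(nCompounds = 40L, activeFraction = 0,
                                      seed = 6L))
  expect_false(any(rdkitMatches(smilesOf(zero$library), "c1ccccc1C(=O)N")))
})

test_that("library truth equals brute-force substructure matching", {
  gen <- generateLibrary(librarySpec(nCompounds = 400L, activeFraction = 0.1,
                                     labelNoise = 0, seed = 7L))
  truthN <- sum(gen$truth$carrier)
  oracleFlags <- rdkitMatches(smilesOf(gen$library), "c1ccccc1C(=O)N")
  expect_identical(sum(oracleFlags), truthN)
  ## with zero label noise the observed labels equal carrier status
  expect_identical(gen$truth$label, gen$truth$carrier)
  expect_identical(unname(oracleFlags),
                   unname(gen$truth$carrier[match(compoundIds(gen$library),
                                                  gen$truth$compound_id)]))
})

test_that("an unparsable pharmacophore is a pattern error", {
  expect_error(generateLibrary(librarySpec(pharmacophore = "c1ccc(")),
               "pattern")
})

test_that("noise-free dose-response points lie exactly on the 4PL curve", {
  tr <- c(bottom = 5, top = 80, ec50 = 2e-6, hill = 1.3)
  drc <- simulateDoseResponse(tr, noiseCv = 0, seed = 1L)
  s <- drc[drc$role == "sample", ]
  norm <- normalizeToReference(drc)
  expect_equal(norm$value[norm$role == "sample"],
               fourPL(s$conc_molar, tr), tolerance = 1e-12)
  ## midpoint identity at the EC50
  mid <- simulateDoseResponse(tr, concentrations = tr[["ec50"]], nReps = 1L,
                              noiseCv = 0, seed = 1L)
  midN <- normalizeToReference(mid)
  expect_equal(midN$value[midN$role == "sample"],
               (tr[["bottom"]] + tr[["top"]]) / 2, tolerance = 1e-12)
})

test_that("replicate noise matches a direct Monte-Carlo of the noise model", {
  ## per-concentration sample CV should sit in [0.01, 0.12] for >= 95% of
  ## seeds at noiseCv = 0.05, n = 4 (compared against the same envelope
  ## computed from the raw noise model)
  tr <- c(bottom = 0, top = 100, ec50 = 1e-5, hill = 1)
  conc <- drcConcentrations()[1:8]
  inBand <- logical(1000L)
  for (s in seq_len(1000L)) {
    drc <- simulateDoseResponse(tr, concentrations = conc, nReps = 4L,
                                noiseCv = 0.05, seed = s)
    d <- normalizeToReference(drc)
    d <- d[d$role == "sample" & d$conc_molar == max(conc), ]
    cv <- sd(d$value) / mean(d$value)
    inBand[s] <- cv >= 0.01 & cv <= 0.12
  }
  expect_gte(mean(inBand), 0.95)
})

test_that("negative concentrations are a domain error", {
  expect_error(simulateDoseResponse(c(bottom = 0, top = 1, ec50 = 1, hill = 1),
                                    concentrations = c(-1, 1)), "positive")
})

test_that("cell images honour the spec and are deterministic", {
  spec <- cellImageSpec(imageShape = c(256L, 256L), nCells = 0L, seed = 1L)
  img <- renderCellImage(spec)
  expect_identical(nrow(img$truth), 0L)
  expect_lt(max(img$image), spec@backgroundIntensity + 8 * spec@noiseSd)
  spec2 <- cellImageSpec(imageShape = c(300L, 300L), nCells = 4L,
                         cellAreaRange = c(2500, 5000), seed = 9L)
  a <- renderCellImage(spec2)
  b <- renderCellImage(spec2)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("a disk-shaped cell has truth area within 1% of pi r^2", {
  A <- pi * 50^2
  spec <- cellImageSpec(imageShape = c(256L, 256L), nCells = 1L,
                        cellAreaRange = c(A, A), noiseSd = 0, seed = 4L)
  img <- renderCellImage(spec)
  expect_lt(abs(img$truth$area_pixels - A) / A, 0.01)
})

test_that("impossible packing raises a packing error", {
  expect_error(renderCellImage(cellImageSpec(imageShape = c(96L, 96L),
                                             nCells = 30L,
                                             cellAreaRange = c(2000, 2000),
                                             seed = 1L)),
               "pack")
})

test_that("fixtures cover all input kinds, rerun byte-identically, and count truth", {
  d1 <- file.path(tempdir(), "fxA"); d2 <- file.path(tempdir(), "fxB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- writeFixtures(d1, seed = 12L)
  m2 <- writeFixtures(d2, seed = 12L)
  expect_true(all(c("plates", "library", "drc", "image") %in% m1$kind))
  expect_identical(m1$md5, m2$md5)
  manifest <- jsonlite::read_json(file.path(d1, "truth_manifest.json"),
                                  simplifyVector = TRUE)
  ## one truth row per generated entity
  lib <- readSmi(file.path(d1, "library.smi"))
  expect_identical(nrow(manifest$truth$library), length(lib))
  plates <- readPlateCsv(file.path(d1, "plates.csv"))
  nSample <- sum(vapply(plates, function(p) sum(wellRoles(p) == "sample"),
                        numeric(1)))
  expect_identical(nrow(manifest$truth$plate_wells), as.integer(nSample))
})
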