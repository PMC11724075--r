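test_that("intensity statistics follow the histogram rules", {
  s <- intensityStats(matrix(7, 4, 4))
  expect_identical(s$mode_nonzero, 7L)
  expect_equal(s$sd, 0)
  s2 <- intensityStats(matrix(c(0, 0, 5, 5, 5, 9), 2))
  expect_identical(s2$mode_nonzero, 5L)
  ## bimodal tie resolves to the lowest intensity
  s3 <- intensityStats(matrix(c(rep(100, 5), rep(200, 5)), 2))
  expect_identical(s3$mode_nonzero, 100L)
  expect_error(intensityStats(matrix(0, 3, 3)), "no signal")
})

test_that("nucleus segmentation applies the area and overlap filters", {
  h <- 200L; w <- 200L
  dapi <- matrix(10, h, w); cell <- matrix(10, h, w)
  disk <- function(cy, cx, r) {
    idx <- which(outer((1:h - cy)^2, (1:w - cx)^2, "+") <= r^2)
    cbind((idx - 1) %% h + 1, (idx - 1) %/% h + 1)
  }
  ## nucleus A (r=17, area ~908) over bright cell; nucleus B same size over
  ## background; nucleus C small (r=11, area ~380 < 500)
  a <- disk(50, 50, 17); b <- disk(50, 150, 17); c3 <- disk(150, 50, 11)
  dapi[a] <- 5000; dapi[b] <- 5000; dapi[c3] <- 5000
  cellBody <- disk(50, 50, 30)
  cell[cellBody] <- 4000
  res <- segmentNuclei(dapi, cell)
  expect_identical(res$counts[["initial"]], 3L)
  expect_identical(res$counts[["area_removed"]], 1L)
  expect_identical(res$counts[["overlap_removed"]], 1L)
  expect_identical(res$counts[["retained"]], 1L)
  ## the retained nucleus is the on-cell one
  expect_true(all(res$labels[a] == 1L))
  expect_true(all(res$labels[b] == 0L))
  ## a sub-500-px nucleus alone yields zero nuclei
  dapi2 <- matrix(10, h, w); dapi2[c3] <- 5000
  res2 <- segmentNuclei(dapi2, cell)
  expect_identical(res2$counts[["retained"]], 0L)
  expect_error(segmentNuclei(matrix(0, h, w), cell), "no signal")
})

test_that("the cell mask follows threshold, morphology and low-intensity removal", {
  h <- 100L; w <- 100L
  cell <- matrix(100L, h, w)
  cell[30:69, 20:79] <- 5000L   # bright 40 x 60 rectangle
  mask <- cellMask(cell)
  ## oracle: same chain with set-operation morphology
  s <- intensityStats(cell)
  ref <- cell > s$mode_nonzero + 0.5 * s$sd
  ref <- erode4(ref)
  ref <- dilate4(dilate4(ref))
  ref[cell < s$mode_nonzero - 0.5 * s$sd] <- FALSE
  expect_identical(unname(mask), unname(ref))
  ## uniform dim background below threshold -> empty mask
  dim2 <- matrix(80L, h, w)
  expect_error(cellMask(dim2 * 0L), "no signal")
  expect_identical(sum(cellMask(dim2)), 0L)
  ## the final-removal rule is absolute
  noisy <- matrix(sample(100:120, h * w, replace = TRUE), h, w)
  noisy[40:60, 40:60] <- 6000L
  m <- cellMask(noisy)
  s2 <- intensityStats(noisy)
  expect_false(any(noisy[m] < s2$mode_nonzero - 0.5 * s2$sd))
})

test_that("the gradient image has the declared range and edge response", {
  flat <- matrix(500L, 80L, 80L)
  g <- gradientImage(flat)
  expect_true(all(g == 0L))
  step <- matrix(100L, 80L, 80L); step[, 41:80] <- 4000L
  g2 <- gradientImage(step)
  expect_true(all(g2 >= 0L & g2 <= 255L))
  ## the maximum-gradient column sits within 2 px of the true edge
  interior <- g2[20:60, ]
  peak <- which.max(colSums(interior))
  expect_lte(abs(peak - 40.5), 2.5)
})

test_that("compact watershed honours seeds, mask and geometry", {
  h <- 60L; w <- 120L
  mask <- matrix(FALSE, h, w)
  ## dumbbell: two 20-px-radius lobes joined by a thin neck
  lobe <- function(cy, cx, r) outer((1:h - cy)^2, (1:w - cx)^2, "+") <= r^2
  mask[lobe(30, 30, 20)] <- TRUE
  mask[lobe(30, 90, 20)] <- TRUE
  mask[28:32, 30:90] <- TRUE
  grad <- matrix(0L, h, w)
  seeds <- matrix(0L, h, w)
  seeds[30, 30] <- 1L; seeds[30, 90] <- 2L
  lab <- watershedCells(grad, seeds, mask, compactness = 0.1)
  expect_identical(sort(unique(as.vector(lab[mask]))), c(1L, 2L))
  expect_true(all(lab[!mask] == 0L))
  expect_identical(lab[30, 30], 1L)
  expect_identical(lab[30, 90], 2L)
  ## the boundary falls in the neck region
  lab1Cols <- which(apply(lab == 1L, 2, any))
  lab2Cols <- which(apply(lab == 2L, 2, any))
  expect_lt(max(lab1Cols), 70)
  expect_gt(min(lab2Cols), 50)
  ## one seed floods the whole connected mask
  seeds1 <- matrix(0L, h, w); seeds1[30, 30] <- 1L
  lab1 <- watershedCells(grad, seeds1, mask)
  expect_identical(sum(lab1 == 1L), sum(mask))
  ## zero seeds give an empty labeling
  expect_true(all(watershedCells(grad, matrix(0L, h, w), mask) == 0L))
})

test_that("post-processing removes border objects, fills holes, prunes protrusions", {
  h <- 100L; w <- 100L
  lab <- matrix(0L, h, w)
  lab[1:20, 10:30] <- 1L                  # touches the top border
  lab[40:79, 40:79] <- 2L                 # 40 x 40 square
  lab[55:64, 50:59] <- 2L
  holed <- lab
  res <- postprocessAndMeasure(lab)
  expect_identical(res@stageCounts[["border_removed"]], 1L)
  expect_false(1L %in% res@cells$label)
  expect_identical(res@cells$csa_pixels[res@cells$label == 2L], 1576L)
  ## a 10-px internal hole is refilled into the CSA
  lab2 <- matrix(0L, h, w)
  lab2[40:79, 40:79] <- 2L
  lab2[60, 55:64] <- 0L                   # 10-px slit hole
  res2 <- postprocessAndMeasure(lab2)
  expect_identical(res2@cells$csa_pixels, 1576L)
  ## a 2-px-wide protrusion is erased by the 3-erosion opening
  lab3 <- matrix(0L, h, w)
  lab3[40:79, 40:79] <- 3L
  lab3[50:51, 80:95] <- 3L                # 2 x 16 protrusion
  res3 <- postprocessAndMeasure(lab3)
  ## oracle for the protrusion case: set-operation morphology (the opening
  ## erases the arm except a 2-px stub at its base)
  sel <- lab3 == 3L
  ref <- sel
  for (i in 1:3) ref <- erode4(ref)
  for (i in 1:3) ref <- dilate4(ref)
  expect_identical(res3@cells$csa_pixels, as.integer(sum(ref)))
  expect_lt(res3@cells$csa_pixels, 1600L)
})

test_that("the full CSA chain is deterministic and empty-safe", {
  spec <- cellImageSpec(imageShape = c(256L, 256L), nCells = 3L,
                        cellAreaRange = c(2500, 5000), seed = 21L)
  img <- renderCellImage(spec)
  r1 <- quantifyCSA(img$image)
  r2 <- quantifyCSA(img$image)
  expect_identical(csaTable(r1), csaTable(r2))
  expect_identical(labelImage(r1), labelImage(r2))
  expect_identical(nrow(csaTable(r1)), 3L)
  ## every reported cell is seeded by a retained nucleus
  expect_true(all(csaTable(r1)$seed_nucleus %in%
                    seq_len(r1@stageCounts[["retained"]])))
  ## stage counts are additive: initial components minus removals equals
  ## reported cells
  sc <- stageCounts(r1)
  expect_identical(sc[["initial"]] - sc[["area_removed"]] -
                     sc[["overlap_removed"]] - sc[["border_removed"]] -
                     sc[["eroded_away"]], sc[["reported"]])
  ## blank image -> empty table
  blank <- array(5L, c(2L, 128L, 128L))
  resB <- quantifyCSA(blank)
  expect_identical(nrow(csaTable(resB)), 0L)
})
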