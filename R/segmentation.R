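## Automated cardiomyocyte cross-sectional-area (CSA) quantification on
## two-channel images (nuclei + cell body), reimplementing the published
## mode/SD-threshold + seeded compact-watershed algorithm with its printed
## constants (see SegmentationParams).  All morphology uses a 4-connected
## (cross) structuring element; component labeling is 4-connected.

#' Constructor for SegmentationParams
#'
#' All arguments default to the published constants; see
#' \linkS4class{SegmentationParams}.
#'
#' @param minNucleusArea,overlapCoefficient,cellThresholdCoefficient
#'   nucleus-stage constants.
#' @param lowIntensityCoefficient,maskErosions,maskDilations cell-mask
#'   constants.
#' @param gradientErosionKernel,gaussianSigma,gradientDilationKernel
#'   gradient-stage constants.
#' @param watershedCompactness compact-watershed energy weight.
#' @param postErosions,postDilations per-object cleanup passes.
#' @export
segmentationParams <- function(minNucleusArea = 500,
                               overlapCoefficient = 0.5,
                               cellThresholdCoefficient = 0.5,
                               lowIntensityCoefficient = 0.5,
                               maskErosions = 1L, maskDilations = 2L,
                               gradientErosionKernel = 3L, gaussianSigma = 3,
                               gradientDilationKernel = 5L,
                               watershedCompactness = 0.1,
                               postErosions = 3L, postDilations = 3L) {
  new("SegmentationParams", minNucleusArea = minNucleusArea,
      overlapCoefficient = overlapCoefficient,
      cellThresholdCoefficient = cellThresholdCoefficient,
      lowIntensityCoefficient = lowIntensityCoefficient,
      maskErosions = as.integer(maskErosions),
      maskDilations = as.integer(maskDilations),
      gradientErosionKernel = as.integer(gradientErosionKernel),
      gaussianSigma = gaussianSigma,
      gradientDilationKernel = as.integer(gradientDilationKernel),
      watershedCompactness = watershedCompactness,
      postErosions = as.integer(postErosions),
      postDilations = as.integer(postDilations))
}

#' Channel intensity statistics
#'
#' The mode is the maximum of the integer histogram of nonzero pixel
#' values (ties broken toward the lowest value); the median and SD are
#' taken over all pixels, zeros included.
#'
#' @param img integer matrix of pixel intensities.
#' @param excludeZeroForMode exclude zero-valued pixels from the mode
#'   histogram (default TRUE, as in the published algorithm).
#' @return list with \code{mode_nonzero}, \code{median}, \code{sd}.
#' @examples
#' intensityStats(matrix(c(0, 0, 5, 5, 5, 9), 2))
#' @export
intensityStats <- function(img, excludeZeroForMode = TRUE) {
  v <- as.integer(round(img))
  pool <- if (excludeZeroForMode) v[v > 0L] else v
  if (!length(pool))
    stop("no signal: image has no nonzero pixels", call. = FALSE)
  counts <- tabulate(pool + 1L)          # value 0 -> bin 1
  m <- which.max(counts) - 1L            # which.max takes the first maximum
  list(mode_nonzero = m, median = median(as.numeric(v)), sd = sd(as.numeric(v)))
}

## 4-connected components of a binary matrix (EBImage::bwlabel)
.label4 <- function(binary) {
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary), ncol(binary)))
  matrix(as.integer(lab), nrow(binary), ncol(binary))
}

#' Segment nuclei
#'
#' Thresholds the nuclear channel at \code{mode + SD}, labels 4-connected
#' components, removes components smaller than \code{minNucleusArea}
#' pixels and components whose mean cell-channel intensity is below
#' \code{median_A + overlapCoefficient * SD_A} (nuclei not lying on a
#' cell), then relabels sequentially.
#'
#' @param dapi,cell integer matrices (nuclear and cell-body channels, same
#'   shape).
#' @param params a \linkS4class{SegmentationParams}.
#' @return list: \code{labels} (integer matrix), \code{counts} (named:
#'   \code{initial}, \code{area_removed}, \code{overlap_removed},
#'   \code{retained}).
#' @export
segmentNuclei <- function(dapi, cell, params = segmentationParams()) {
  stopifnot(all(dim(dapi) == dim(cell)))
  sd_ <- intensityStats(dapi)
  sa <- intensityStats(cell)
  binary <- dapi > sd_$mode_nonzero + sd_$sd
  lab <- .label4(binary)
  nInit <- max(lab)
  keep <- integer(0)
  areaRemoved <- 0L; overlapRemoved <- 0L
  overlapCut <- sa$median + params@overlapCoefficient * sa$sd
  if (nInit > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = nInit)
    for (l in seq_len(nInit)) {
      if (areas[l] < params@minNucleusArea) { areaRemoved <- areaRemoved + 1L; next }
      if (mean(cell[lab == l]) < overlapCut) { overlapRemoved <- overlapRemoved + 1L; next }
      keep <- c(keep, l)
    }
  }
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  list(labels = out,
       counts = c(initial = nInit, area_removed = areaRemoved,
                  overlap_removed = overlapRemoved, retained = length(keep)))
}

## binary morphology with the 4-connected cross element and background
## (FALSE) outside the image, the convention of the ndimage-style tools
## this algorithm class is built on; EBImage's erode ignores out-of-image
## kernel pixels instead, so these are implemented by shifted set
## operations
.shiftBg <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
  okR <- rs >= 1L & rs <= h; okC <- cs >= 1L & cs <= w
  out[rs[okR], cs[okC]] <- m[okR, okC]
  out
}

.binErode1 <- function(m) {
  m & .shiftBg(m, 1L, 0L) & .shiftBg(m, -1L, 0L) &
    .shiftBg(m, 0L, 1L) & .shiftBg(m, 0L, -1L)
}

.binDilate1 <- function(m) {
  m | .shiftBg(m, 1L, 0L) | .shiftBg(m, -1L, 0L) |
    .shiftBg(m, 0L, 1L) | .shiftBg(m, 0L, -1L)
}

.binMorph <- function(binary, op, passes) {
  b <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  for (i in seq_len(passes)) b <- op(b)
  b
}

#' Cell-body mask
#'
#' Thresholds the cell channel at \code{mode_nonzero +
#' cellThresholdCoefficient * SD}, applies one pass of binary erosion and
#' two passes of binary dilation (4-connected cross element), then removes
#' any pixel with intensity below \code{mode_nonzero -
#' lowIntensityCoefficient * SD}.
#'
#' @param cell integer matrix (cell-body channel).
#' @param params a \linkS4class{SegmentationParams}.
#' @return logical matrix.
#' @export
cellMask <- function(cell, params = segmentationParams()) {
  sa <- intensityStats(cell)
  mask <- cell > sa$mode_nonzero + params@cellThresholdCoefficient * sa$sd
  mask <- .binMorph(mask, .binErode1, params@maskErosions)
  mask <- .binMorph(mask, .binDilate1, params@maskDilations)
  mask[cell < sa$mode_nonzero - params@lowIntensityCoefficient * sa$sd] <- FALSE
  mask
}

## gray-scale box morphology with edge replication (min/max filters); kept
## in-package so that border pixels follow replicate semantics and a
## constant image stays constant
.shiftRep <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  x[ri, ci, drop = FALSE]
}

.grayBox <- function(x, k, fun) {
  r <- (k - 1L) %/% 2L
  acc <- x
  for (d in seq_len(r)) acc <- fun(acc, .shiftRep(x, d, 0), .shiftRep(x, -d, 0))
  out <- acc
  for (d in seq_len(r)) out <- fun(out, .shiftRep(acc, 0, d), .shiftRep(acc, 0, -d))
  out
}

.grayErode <- function(x, k) .grayBox(x, k, pmin)
.grayDilate <- function(x, k) .grayBox(x, k, pmax)

#' Gradient image for watershed
#'
#' Gray erosion (3x3 box) of the raw cell channel, Gaussian blur (sigma 3
#' px), Scharr gradient magnitude, linear min-max rescale to 8-bit
#' integers (a constant image maps to zeros), then gray dilation (5x5
#' box).
#'
#' @param cell integer matrix (cell-body channel).
#' @param params a \linkS4class{SegmentationParams}.
#' @return integer matrix in \code{[0, 255]}.
#' @export
gradientImage <- function(cell, params = segmentationParams()) {
  x <- matrix(as.numeric(cell), nrow(cell), ncol(cell))
  x <- .grayErode(x, params@gradientErosionKernel)
  x <- EBImage::gblur(x, sigma = params@gaussianSigma, boundary = "replicate")
  sch <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3L, 3L, byrow = TRUE)
  gx <- EBImage::filter2(x, sch, boundary = "replicate")
  gy <- EBImage::filter2(x, t(sch), boundary = "replicate")
  g <- sqrt(gx^2 + gy^2)
  rng <- range(g)
  ## a (near-)constant image has no gradient; the sub-1e-6 range guard also
  ## absorbs FFT round-off from the convolution
  g8 <- if (rng[2L] - rng[1L] > 1e-6)
    round((g - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  else matrix(0, nrow(g), ncol(g))
  g8 <- .grayDilate(g8, params@gradientDilationKernel)
  matrix(as.integer(pmin(255, pmax(0, round(g8)))), nrow(cell), ncol(cell))
}

#' Seeded compact watershed
#'
#' Priority flooding of the gradient image from the nucleus seeds,
#' confined to the cell mask, with flooding energy \code{gradient +
#' compactness * squared distance to the seed centroid}. Seed pixels
#' outside the mask are clipped (and counted in a message).
#'
#' @param gradient integer matrix (e.g. from \code{\link{gradientImage}}).
#' @param seeds integer label matrix of nucleus seeds.
#' @param mask logical matrix restricting the flood.
#' @param compactness energy weight (default 0.1).
#' @return integer label matrix; every label contains its seed.
#' @export
watershedCells <- function(gradient, seeds, mask,
                           compactness = 0.1) {
  stopifnot(all(dim(gradient) == dim(seeds)), all(dim(gradient) == dim(mask)))
  nClipped <- sum(seeds > 0L & !mask)
  if (nClipped > 0L) {
    message(nClipped, " seed pixel(s) outside the mask were clipped")
    seeds[!mask] <- 0L
  }
  labs <- sort(unique(seeds[seeds > 0L]))
  if (!length(labs)) return(matrix(0L, nrow(gradient), ncol(gradient)))
  ## relabel 1..K for the C++ core, then map back
  remap <- match(seeds, c(0L, labs)) - 1L
  seedsK <- matrix(as.integer(remap), nrow(seeds), ncol(seeds))
  cy <- vapply(seq_along(labs), function(k) mean(which(seedsK == k, arr.ind = TRUE)[, 1L]), numeric(1))
  cx <- vapply(seq_along(labs), function(k) mean(which(seedsK == k, arr.ind = TRUE)[, 2L]), numeric(1))
  out <- compact_watershed_cpp(matrix(as.numeric(gradient), nrow(gradient)),
                               seedsK, mask, compactness, cy, cx)
  out[out > 0L] <- labs[out[out > 0L]]
  out
}

#' Post-process watershed labels and measure CSA
#'
#' Per label: remove it if any pixel touches the image border; fill
#' internal holes; apply \code{postErosions} binary erosions followed by
#' \code{postDilations} dilations (cross element) to remove small
#' protrusions; report the remaining pixel count as the CSA. Labels
#' emptied by the erosions are dropped and counted.
#'
#' @param labels integer label matrix (labels are the seed-nucleus ids).
#' @param params a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{SegmentationResult} (stage counts:
#'   \code{watershed_labels}, \code{border_removed}, \code{eroded_away},
#'   \code{reported}).
#' @export
postprocessAndMeasure <- function(labels, params = segmentationParams()) {
  h <- nrow(labels); w <- ncol(labels)
  ids <- sort(unique(labels[labels > 0L]))
  out <- matrix(0L, h, w)
  rows <- list()
  borderRemoved <- 0L; erodedAway <- 0L
  for (l in ids) {
    sel <- labels == l
    rc <- which(sel, arr.ind = TRUE)
    if (any(rc[, 1L] %in% c(1L, h)) || any(rc[, 2L] %in% c(1L, w))) {
      borderRemoved <- borderRemoved + 1L
      next
    }
    ## work in a padded bounding box so morphology cannot wrap
    pad <- params@postErosions + params@postDilations + 1L
    r0 <- max(1L, min(rc[, 1L]) - pad); r1 <- min(h, max(rc[, 1L]) + pad)
    c0 <- max(1L, min(rc[, 2L]) - pad); c1 <- min(w, max(rc[, 2L]) + pad)
    sub <- matrix(as.numeric(sel[r0:r1, c0:c1]), r1 - r0 + 1L, c1 - c0 + 1L)
    sub <- EBImage::fillHull(sub) > 0
    sub <- .binMorph(sub, .binErode1, params@postErosions)
    sub <- .binMorph(sub, .binDilate1, params@postDilations)
    csa <- sum(sub)
    if (csa == 0L) { erodedAway <- erodedAway + 1L; next }
    block <- out[r0:r1, c0:c1]
    block[sub] <- l
    out[r0:r1, c0:c1] <- block
    rows[[length(rows) + 1L]] <- data.frame(label = l, csa_pixels = csa,
                                            seed_nucleus = l)
  }
  cells <- if (length(rows)) do.call(rbind, rows)
           else data.frame(label = integer(), csa_pixels = integer(),
                           seed_nucleus = integer())
  new("SegmentationResult", labels = out, cells = cells,
      stageCounts = c(watershed_labels = length(ids),
                      border_removed = borderRemoved,
                      eroded_away = erodedAway, reported = nrow(cells)))
}

#' Quantify cardiomyocyte cross-sectional areas
#'
#' Runs the full chain: nucleus segmentation, cell-body mask, gradient
#' image, seeded compact watershed and per-object post-processing. The
#' pipeline is fully deterministic.
#'
#' @param image integer array \code{c(2, height, width)} (channel 1
#'   nuclei, channel 2 cell body) or a list with elements \code{nuclei}
#'   and \code{cell}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{SegmentationResult}; stage counts concatenate
#'   the nucleus-filter and post-processing counters.
#' @examples
#' img <- renderCellImage(cellImageSpec(imageShape = c(256L, 256L),
#'                                      nCells = 3L,
#'                                      cellAreaRange = c(2000, 4000),
#'                                      seed = 2L))
#' quantifyCSA(img$image)
#' @export
quantifyCSA <- function(image, params = segmentationParams()) {
  if (is.list(image)) {
    dapi <- image$nuclei; cell <- image$cell
  } else {
    stopifnot(length(dim(image)) == 3L, dim(image)[1L] >= 2L)
    dapi <- image[1L, , ]; cell <- image[2L, , ]
  }
  nuc <- segmentNuclei(dapi, cell, params)
  if (nuc$counts[["retained"]] == 0L) {
    return(new("SegmentationResult",
               labels = matrix(0L, nrow(dapi), ncol(dapi)),
               cells = data.frame(label = integer(), csa_pixels = integer(),
                                  seed_nucleus = integer()),
               stageCounts = c(nuc$counts, watershed_labels = 0L,
                               border_removed = 0L, eroded_away = 0L,
                               reported = 0L)))
  }
  mask <- cellMask(cell, params)
  grad <- gradientImage(cell, params)
  labels <- watershedCells(grad, nuc$labels, mask, params@watershedCompactness)
  res <- postprocessAndMeasure(labels, params)
  new("SegmentationResult", labels = res@labels, cells = res@cells,
      stageCounts = c(nuc$counts, res@stageCounts))
}
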