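## Synthetic two-channel fluorescence micrographs with exact per-cell
## pixel-area ground truth.  Cells are near-disk star-convex shapes (small
## random radial harmonics, radius corrected for the harmonic area factor)
## rasterized onto a 16-bit canvas; each cell contains one nuclear disk.
## Channel 1 emulates the nuclear stain (DAPI), channel 2 the cell-body
## stain (phalloidin).

#' Constructor for CellImageSpec
#'
#' @param imageShape height, width in pixels (>= 64).
#' @param nCells number of cells to pack.
#' @param cellAreaRange,nucleusAreaRange target pixel-area ranges.
#' @param cellIntensity,nucleusIntensity,backgroundIntensity 16-bit
#'   grayscale levels.
#' @param noiseSd additive Gaussian noise SD (clipped to the bit depth).
#' @param allowBorder also place cells crossing the image border (to
#'   exercise border removal).
#' @param seed integer RNG seed.
#' @export
cellImageSpec <- function(imageShape = c(1024L, 1024L), nCells = 20L,
                          cellAreaRange = c(2000, 20000),
                          nucleusAreaRange = c(700, 1300),
                          cellIntensity = 12000, nucleusIntensity = 30000,
                          backgroundIntensity = 400, noiseSd = 150,
                          allowBorder = FALSE, seed = 1L) {
  new("CellImageSpec", imageShape = as.integer(imageShape),
      nCells = as.integer(nCells), cellAreaRange = cellAreaRange,
      nucleusAreaRange = nucleusAreaRange, cellIntensity = cellIntensity,
      nucleusIntensity = nucleusIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      allowBorder = allowBorder, seed = as.integer(seed))
}

## rasterize a star-convex shape r(theta) = r0 * (1 + a1 cos(t + p1) +
## a2 cos(2 t + p2)) centred at (cy, cx); returns pixel indices (matrix
## row/col) within the image
.rasterStar <- function(cy, cx, r0, amp, phase, shape) {
  rmax <- r0 * (1 + sum(abs(amp)))
  ys <- max(1L, floor(cy - rmax)):min(shape[1L], ceiling(cy + rmax))
  xs <- max(1L, floor(cx - rmax)):min(shape[2L], ceiling(cx + rmax))
  dy <- ys - cy
  dx <- xs - cx
  d <- sqrt(outer(dy^2, dx^2, "+"))
  th <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  rth <- r0 * (1 + amp[1L] * cos(th + phase[1L]) + amp[2L] * cos(2 * th + phase[2L]))
  inside <- d <= rth
  idx <- which(inside, arr.ind = TRUE)
  cbind(ys[idx[, 1L]], xs[idx[, 2L]])
}

#' Render a synthetic two-channel cell image with ground truth
#'
#' @param spec a \linkS4class{CellImageSpec}.
#' @return list with \code{image} (integer array \code{c(2, height,
#'   width)}; channel 1 nuclei, channel 2 cell bodies), \code{truthLabels}
#'   (integer matrix of true cell labels) and \code{truth} (data.frame:
#'   \code{cell}, \code{area_pixels} — the exact rasterized pixel count —
#'   \code{nucleus_area}, \code{border}).
#' @examples
#' img <- renderCellImage(cellImageSpec(imageShape = c(256L, 256L),
#'                                      nCells = 3L,
#'                                      cellAreaRange = c(2000, 4000),
#'                                      seed = 2L))
#' img$truth
#' @export
renderCellImage <- function(spec) {
  stopifnot(is(spec, "CellImageSpec"))
  validObject(spec)
  h <- spec@imageShape[1L]; w <- spec@imageShape[2L]
  withSeed(spec@seed, {
    labels <- matrix(0L, h, w)
    nucLabels <- matrix(0L, h, w)
    rows <- list()
    centres <- matrix(numeric(0), 0, 3)  # cy, cx, rmax
    nBorder <- if (spec@allowBorder && spec@nCells >= 1L)
      max(1L, round(0.25 * spec@nCells)) else 0L
    ## draw all shape parameters first, then place largest-first (greedy
    ## packing is much more reliable that way); labels follow placement
    targetAs <- sort(runif(spec@nCells, spec@cellAreaRange[1L],
                           spec@cellAreaRange[2L]), decreasing = TRUE)
    borderSet <- if (nBorder > 0L) resample(seq_len(spec@nCells), nBorder)
                 else integer(0)
    for (cell in seq_len(spec@nCells)) {
      targetA <- targetAs[cell]
      amp <- runif(2, 0, 0.10)
      phase <- runif(2, 0, 2 * pi)
      ## harmonic area factor: area = pi r0^2 (1 + sum(amp^2)/2)
      r0 <- sqrt(targetA / (pi * (1 + sum(amp^2) / 2)))
      rmax <- r0 * (1 + sum(amp))
      border <- cell %in% borderSet
      placed <- FALSE
      for (try in seq_len(4000L)) {
        if (border) {
          ## centre just inside an edge so the body crosses it but the
          ## nucleus (radius <= 0.6 r0) can still be placed fully inside
          side <- resample(1:4, 1L)
          off <- runif(1, 0.5 * r0, 0.75 * r0)
          cy <- switch(side, off, h + 1 - off, runif(1, rmax + 2, h - rmax - 2),
                       runif(1, rmax + 2, h - rmax - 2))
          cx <- switch(side, runif(1, rmax + 2, w - rmax - 2),
                       runif(1, rmax + 2, w - rmax - 2), off, w + 1 - off)
        } else {
          cy <- runif(1, rmax + 3, h - rmax - 3)
          cx <- runif(1, rmax + 3, w - rmax - 3)
        }
        if (nrow(centres) == 0L ||
            all(sqrt((centres[, 1L] - cy)^2 + (centres[, 2L] - cx)^2) >
                centres[, 3L] + rmax + 8)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not pack ", spec@nCells, " cells into the image",
             call. = FALSE)
      centres <- rbind(centres, c(cy, cx, rmax))
      px <- .rasterStar(cy, cx, r0, amp, phase, c(h, w))
      labels[px] <- cell
      nr0 <- sqrt(runif(1, spec@nucleusAreaRange[1L], spec@nucleusAreaRange[2L]) / pi)
      nr0 <- min(nr0, 0.6 * r0)   # keep the nucleus inside the cell
      npx <- .rasterStar(cy, cx, nr0, c(0, 0), c(0, 0), c(h, w))
      nucLabels[npx] <- cell
      rows[[cell]] <- data.frame(cell = cell, area_pixels = nrow(px),
                                 nucleus_area = nrow(npx), border = border)
    }
    nuc <- matrix(spec@backgroundIntensity, h, w)
    nuc[nucLabels > 0L] <- spec@nucleusIntensity
    body <- matrix(spec@backgroundIntensity, h, w)
    body[labels > 0L] <- spec@cellIntensity
    if (spec@noiseSd > 0) {
      nuc <- nuc + rnorm(h * w, 0, spec@noiseSd)
      body <- body + rnorm(h * w, 0, spec@noiseSd)
    }
    clip <- function(x) matrix(as.integer(pmin(65535, pmax(0, round(x)))), h, w)
    img <- array(0L, c(2L, h, w))
    img[1L, , ] <- clip(nuc)
    img[2L, , ] <- clip(body)
    list(image = img, truthLabels = labels,
         truth = if (length(rows)) do.call(rbind, rows)
                 else data.frame(cell = integer(), area_pixels = integer(),
                                 nucleus_area = integer(), border = logical()))
  })
}

#' Write / read two-channel 16-bit TIFF images
#'
#' Channel axis first, uncompressed (deterministic bytes for checksum
#' comparisons).
#'
#' @param image integer array \code{c(channels, height, width)} in
#'   \code{[0, 65535]}.
#' @param path TIFF path.
#' @return \code{readCellTiff}: the integer array.
#' @export
writeCellTiff <- function(image, path) {
  pages <- lapply(seq_len(dim(image)[1L]), function(ch)
    image[ch, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeCellTiff
#' @export
readCellTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- array(0L, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (ch in seq_along(pages))
    img[ch, , ] <- as.integer(round(pages[[ch]] * 65535))
  img
}
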