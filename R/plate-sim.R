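## Synthetic primary screens: multiplicative row/column gradients, edge
## depression, log-normal well noise and spiked true actives, on a
## configurable 384-well layout with dedicated control columns.

#' Constructor for PlateEffectSpec
#'
#' @param grandMean baseline sample-well signal (luminescence counts).
#' @param rowGradient,colGradient fractional gradient across rows/columns
#'   (total span, centred: the first row sits at \code{-rowGradient/2}, the
#'   last at \code{+rowGradient/2}).
#' @param edgeDepression fractional signal loss on outermost wells.
#' @param noiseCv coefficient of variation of the multiplicative
#'   (log-normal, unit-mean) well noise.
#' @param spikeRate fraction of sample wells that are true actives.
#' @param spikeEffect active signal increment in units of the plate's
#'   robust residual scale (1.4826 x MAD of sample-well residuals).
#' @param seed integer RNG seed.
#' @export
plateEffectSpec <- function(grandMean = 1e6, rowGradient = 0.3,
                            colGradient = -0.3, edgeDepression = 0.2,
                            noiseCv = 0.1, spikeRate = 0.02, spikeEffect = 8,
                            seed = 1L) {
  new("PlateEffectSpec", grandMean = grandMean, rowGradient = rowGradient,
      colGradient = colGradient, edgeDepression = edgeDepression,
      noiseCv = noiseCv, spikeRate = spikeRate, spikeEffect = spikeEffect,
      seed = as.integer(seed))
}

## expected (noise-free) sample-well surface of a plate
.plateSurface <- function(spec, nr, nc) {
  rowEff <- if (nr > 1L) spec@rowGradient * ((seq_len(nr) - 1L) / (nr - 1L) - 0.5)
            else 0
  colEff <- if (nc > 1L) spec@colGradient * ((seq_len(nc) - 1L) / (nc - 1L) - 0.5)
            else 0
  edge <- matrix(0, nr, nc)
  edge[c(1L, nr), ] <- spec@edgeDepression
  edge[, c(1L, nc)] <- spec@edgeDepression
  spec@grandMean * outer(1 + rowEff, 1 + colEff) * (1 - edge)
}

#' Simulate a primary screen with ground truth
#'
#' Sample wells follow \code{grandMean * (1 + row) * (1 + col) * (1 - edge)
#' * noise} with unit-mean log-normal noise; a Bernoulli
#' \code{spikeRate} subset of sample wells are true actives, raised
#' additively by \code{spikeEffect} robust residual scales (computed
#' per plate from the pre-spike residuals). Positive/negative controls
#' occupy two dedicated columns and are subject to the same artifacts.
#' Output is fully determined by the spec's seed.
#'
#' @param spec a \linkS4class{PlateEffectSpec}.
#' @param nPlates number of plates.
#' @param plateDim rectangular layout, rows x columns (default 16 x 24).
#' @param posColumn,negColumn 1-based control column indices (defaults 2
#'   and \code{ncol - 1}, i.e. edge-adjacent).
#' @param posLevel,negLevel control signal levels as multiples of
#'   \code{grandMean}.
#' @return list with \code{plates} (list of \linkS4class{PlateGrid}) and
#'   \code{truth} (data.frame: \code{plate_id}, \code{row}, \code{col}
#'   0-based, \code{compound_id}, \code{active}).
#' @examples
#' scr <- simulateScreen(plateEffectSpec(seed = 1L), nPlates = 2L)
#' sum(scr$truth$active)
#' @export
simulateScreen <- function(spec, nPlates = 10L, plateDim = c(16L, 24L),
                           posColumn = 2L, negColumn = NULL,
                           posLevel = 5, negLevel = 1) {
  stopifnot(is(spec, "PlateEffectSpec"))
  validObject(spec)
  if (length(plateDim) != 2L || any(plateDim < 2L) || any(plateDim != round(plateDim)))
    stop("plate layout must be rectangular with at least 2 rows and 2 columns",
         call. = FALSE)
  nr <- as.integer(plateDim[1L]); nc <- as.integer(plateDim[2L])
  if (is.null(negColumn)) negColumn <- nc - 1L
  if (posColumn == negColumn || any(c(posColumn, negColumn) < 1L) ||
      any(c(posColumn, negColumn) > nc))
    stop("control columns must be distinct and inside the plate", call. = FALSE)

  roles <- matrix("sample", nr, nc)
  roles[, posColumn] <- "pos"
  roles[, negColumn] <- "neg"
  surface <- .plateSurface(spec, nr, nc)
  level <- matrix(1, nr, nc)
  level[, posColumn] <- posLevel
  level[, negColumn] <- negLevel
  sdlog <- sqrt(log(1 + spec@noiseCv^2))

  withSeed(spec@seed, {
    plates <- vector("list", nPlates)
    truth <- vector("list", nPlates)
    cmpCounter <- 0L
    for (p in seq_len(nPlates)) {
      noise <- if (spec@noiseCv > 0)
        matrix(exp(rnorm(nr * nc, -sdlog^2 / 2, sdlog)), nr, nc)
      else matrix(1, nr, nc)
      values <- surface * level * noise
      sampleIdx <- which(roles == "sample")
      resid <- values[sampleIdx] - surface[sampleIdx]
      robust <- 1.4826 * median(abs(resid - median(resid)))
      active <- matrix(FALSE, nr, nc)
      active[sampleIdx] <- runif(length(sampleIdx)) < spec@spikeRate
      values[active] <- values[active] + spec@spikeEffect * robust
      cids <- matrix("", nr, nc)
      cids[sampleIdx] <- sprintf("CMP%06d", cmpCounter + seq_along(sampleIdx))
      cmpCounter <- cmpCounter + length(sampleIdx)
      pid <- sprintf("plate%03d", p)
      plates[[p]] <- new("PlateGrid", plateId = pid, values = values,
                         roles = roles, compoundIds = cids)
      rc <- arrayInd(sampleIdx, c(nr, nc))
      truth[[p]] <- data.frame(plate_id = pid, row = rc[, 1L] - 1L,
                               col = rc[, 2L] - 1L,
                               compound_id = cids[sampleIdx],
                               active = active[sampleIdx])
    }
    list(plates = plates, truth = do.call(rbind, truth))
  })
}

#' Expected well means of the generative model
#'
#' Recomputes the noise-free expectation of every sample well directly from
#' the spec (the generative formula), for checking simulated means against
#' first principles.
#'
#' @param spec a \linkS4class{PlateEffectSpec}.
#' @param plateDim rows x columns.
#' @return numeric matrix of expectations.
#' @export
expectedWellMeans <- function(spec, plateDim = c(16L, 24L)) {
  .plateSurface(spec, as.integer(plateDim[1L]), as.integer(plateDim[2L]))
}

#' Simulate a dose-response table with controls
#'
#' Draws raw signals \code{neg + (pos - neg) * y/100} where \code{y} is the
#' four-parameter logistic response (percent of the reference window) times
#' multiplicative Gaussian noise \code{(1 + N(0, noiseCv))}. Replicated
#' positive (reference ligand) and negative control rows are included so
#' that normalization can be exercised.
#'
#' @param trueParams named numeric: \code{bottom}, \code{top} (percent),
#'   \code{ec50} (molar), \code{hill}.
#' @param concentrations molar concentrations (default: the 2-fold series
#'   0.0625 to 32 micromolar).
#' @param nReps replicates per concentration.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer RNG seed.
#' @param compoundId id recorded in the table.
#' @param posSignal,negSignal raw control levels (luminescence counts).
#' @param nControlReps replicates per control.
#' @return data.frame: \code{compound_id}, \code{conc_molar},
#'   \code{replicate}, \code{value}, \code{role}.
#' @examples
#' drc <- simulateDoseResponse(c(bottom = 0, top = 100, ec50 = 1e-5,
#'                               hill = 1), noiseCv = 0, seed = 1L)
#' @export
simulateDoseResponse <- function(trueParams,
                                 concentrations = drcConcentrations(),
                                 nReps = 4L, noiseCv = 0.05, seed = 1L,
                                 compoundId = "CMP000001",
                                 posSignal = 1e6, negSignal = 1e5,
                                 nControlReps = 8L) {
  stopifnot(all(c("bottom", "top", "ec50", "hill") %in% names(trueParams)))
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  y <- fourPL(concentrations, trueParams)
  withSeed(seed, {
    rows <- expand.grid(replicate = seq_len(nReps),
                        conc = concentrations, KEEP.OUT.ATTRS = FALSE)
    mu <- rep(y, each = nReps)
    eps <- if (noiseCv > 0) rnorm(nrow(rows), 0, noiseCv) else 0
    resp <- mu * (1 + eps)
    raw <- negSignal + (posSignal - negSignal) * resp / 100
    ctrlNoise <- function(n) if (noiseCv > 0) 1 + rnorm(n, 0, noiseCv) else rep(1, n)
    out <- rbind(
      data.frame(compound_id = compoundId, conc_molar = rows$conc,
                 replicate = rows$replicate, value = raw, role = "sample"),
      data.frame(compound_id = "", conc_molar = NA_real_,
                 replicate = seq_len(nControlReps),
                 value = posSignal * ctrlNoise(nControlReps), role = "pos"),
      data.frame(compound_id = "", conc_molar = NA_real_,
                 replicate = seq_len(nControlReps),
                 value = negSignal * ctrlNoise(nControlReps), role = "neg"))
    rownames(out) <- NULL
    out
  })
}

#' The standard 2-fold dilution series
#'
#' Ten 2-fold steps from 0.0625 to 32 micromolar, in molar units.
#'
#' @return numeric vector of concentrations (molar).
#' @export
drcConcentrations <- function() 0.0625e-6 * 2^(0:9)
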