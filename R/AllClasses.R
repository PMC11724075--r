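## Central S4 classes.  Validity methods enforce the structural contracts;
## accessors live in AllGenerics.R / the module files.

.WELL_ROLES <- c("sample", "pos", "neg", "empty")

#' PlateGrid: one microtiter plate of raw well signals
#'
#' Holds the raw luminescence signal of a single (by default 16 x 24 = 384
#' well) plate together with a same-shape matrix of well roles
#' (\code{sample}, \code{pos}, \code{neg}, \code{empty}) and compound
#' identifiers for sample wells.
#'
#' @slot plateId single character identifier.
#' @slot values numeric matrix of raw signals (finite, non-negative).
#' @slot roles character matrix of well roles, same shape as \code{values}.
#' @slot compoundIds character matrix, same shape; \code{""} for non-sample
#'   wells, a unique compound id for every sample well.
#' @aliases PlateGrid-class
#' @exportClass PlateGrid
setClass("PlateGrid",
  slots = c(plateId = "character", values = "matrix",
            roles = "matrix", compoundIds = "matrix"))

setValidity("PlateGrid", function(object) {
  v <- object@values; r <- object@roles; cid <- object@compoundIds
  if (length(object@plateId) != 1L) return("plateId must be length 1")
  if (!all(dim(v) == dim(r)) || !all(dim(v) == dim(cid)))
    return("values, roles and compoundIds must have identical dimensions")
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
    return("values must be finite and >= 0")
  if (!all(r %in% .WELL_ROLES))
    return(sprintf("roles must be one of %s", paste(.WELL_ROLES, collapse = ", ")))
  if (any(r == "sample" & (is.na(cid) | cid == "")))
    return("every sample well needs a compound id")
  TRUE
})

#' MedianPolishDecomposition: additive decomposition of a plate
#'
#' Result of iterative row/column median sweeps: \code{values = overall +
#' rowEffects[i] + colEffects[j] + residuals[i, j]} (exactly, by
#' construction). Wells excluded from the fit (controls) carry \code{NA}
#' residuals.
#'
#' @slot overall grand effect (signal units).
#' @slot rowEffects,colEffects per-row / per-column offsets.
#' @slot residuals residual matrix.
#' @slot nSweeps number of full row+column sweeps performed.
#' @slot converged TRUE if the maximum absolute change fell below \code{tol}.
#' @slot tol convergence tolerance used (signal units).
#' @aliases MedianPolishDecomposition-class
#' @exportClass MedianPolishDecomposition
setClass("MedianPolishDecomposition",
  slots = c(overall = "numeric", rowEffects = "numeric", colEffects = "numeric",
            residuals = "matrix", nSweeps = "integer", converged = "logical",
            tol = "numeric"))

setValidity("MedianPolishDecomposition", function(object) {
  if (length(object@overall) != 1L) return("overall must be length 1")
  d <- dim(object@residuals)
  if (length(object@rowEffects) != d[1L] || length(object@colEffects) != d[2L])
    return("effect lengths must match residual dimensions")
  TRUE
})

#' BScorePlate: robust per-well scores for one plate
#'
#' B-scores are median-polish residuals divided by the robust scale
#' \code{1.4826 * MAD} of the plate's sample-well residuals. Control and
#' empty wells carry \code{NA}.
#'
#' @slot plateId plate identifier.
#' @slot scores matrix of B-scores (dimensionless).
#' @slot robustScale the 1.4826 * MAD denominator (signal units).
#' @slot polish the \linkS4class{MedianPolishDecomposition} it came from.
#' @aliases BScorePlate-class
#' @exportClass BScorePlate
setClass("BScorePlate",
  slots = c(plateId = "character", scores = "matrix", robustScale = "numeric",
            polish = "MedianPolishDecomposition"))

setValidity("BScorePlate", function(object) {
  if (length(object@robustScale) != 1L || object@robustScale < 0)
    return("robustScale must be a single non-negative number")
  if (object@robustScale > 0 && any(!is.finite(object@scores[!is.na(object@scores)])))
    return("scores must be finite where defined")
  TRUE
})

#' CompoundLibrary: a set of compounds as SMILES with optional labels
#'
#' @slot ids unique compound identifiers.
#' @slot smiles SMILES strings, parallel to \code{ids}.
#' @slot activity logical activity labels (may be NA when unknown).
#' @slot provenance one of \code{"hitlist"}, \code{"reference"},
#'   \code{"candidate"}, \code{"synthetic"}.
#' @slot graphs optional list of pre-built molecular graphs (internal
#'   representation) parallel to \code{ids}; empty list means parse on demand.
#' @aliases CompoundLibrary-class
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
  slots = c(ids = "character", smiles = "character", activity = "logical",
            provenance = "character", graphs = "list"))

setValidity("CompoundLibrary", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("compound ids must be unique")
  if (length(object@smiles) != n) return("smiles and ids lengths differ")
  if (length(object@activity) != n) return("activity and ids lengths differ")
  if (length(object@provenance) != 1L ||
      !object@provenance %in% c("hitlist", "reference", "candidate", "synthetic"))
    return("provenance must be one of hitlist/reference/candidate/synthetic")
  if (length(object@graphs) && length(object@graphs) != n)
    return("graphs, when present, must parallel ids")
  TRUE
})

#' MCSPatternSet: deduplicated maximum-common-substructure patterns
#'
#' @slot smarts SMARTS pattern strings, one per unique pattern.
#' @slot nAtoms,nBonds heavy-atom and bond counts of each pattern.
#' @slot supportPairs number of compound pairs whose MCS produced the pattern.
#' @slot supportCompounds number of hit compounds containing the pattern.
#' @slot graphs molecular graphs of the fragments (internal representation).
#' @aliases MCSPatternSet-class
#' @exportClass MCSPatternSet
setClass("MCSPatternSet",
  slots = c(smarts = "character", nAtoms = "integer", nBonds = "integer",
            supportPairs = "integer", supportCompounds = "integer",
            graphs = "list"))

setValidity("MCSPatternSet", function(object) {
  n <- length(object@smarts)
  if (anyDuplicated(object@smarts)) return("patterns must be unique")
  for (s in c("nAtoms", "nBonds", "supportPairs", "supportCompounds", "graphs"))
    if (length(slot(object, s)) != n) return(sprintf("slot %s has wrong length", s))
  TRUE
})

#' MCSClusterSet: k-means clustering of MCS patterns
#'
#' @slot k number of clusters.
#' @slot assignments integer cluster index per pattern.
#' @slot medoids index (into the pattern set) of the member closest to each
#'   cluster centroid.
#' @slot patterns the clustered \linkS4class{MCSPatternSet}.
#' @slot featureConfig fingerprint parameters used for the embedding.
#' @aliases MCSClusterSet-class
#' @exportClass MCSClusterSet
setClass("MCSClusterSet",
  slots = c(k = "integer", assignments = "integer", medoids = "integer",
            patterns = "MCSPatternSet", featureConfig = "list"))

setValidity("MCSClusterSet", function(object) {
  n <- length(object@patterns@smarts)
  if (length(object@assignments) != n) return("one assignment per pattern required")
  if (length(object@medoids) != object@k) return("one medoid per cluster required")
  for (cl in seq_len(object@k)) {
    if (!object@medoids[cl] %in% which(object@assignments == cl))
      return("each medoid must be a member of its cluster")
  }
  TRUE
})

#' FingerprintMatrix: folded circular (Morgan-style) fingerprints
#'
#' @slot bits 0/1 integer matrix, compounds in rows.
#' @slot ids compound ids parallel to rows.
#' @slot radius bond radius of the circular environments.
#' @slot nBits folded width.
#' @aliases FingerprintMatrix-class
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  slots = c(bits = "matrix", ids = "character", radius = "integer",
            nBits = "integer"))

setValidity("FingerprintMatrix", function(object) {
  if (nrow(object@bits) != length(object@ids)) return("one row per id required")
  if (ncol(object@bits) != object@nBits) return("bit width mismatch")
  if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
  TRUE
})

#' ActivityModel: random-forest activity classifier
#'
#' @slot forest the fitted \code{ranger} probability forest.
#' @slot config training configuration (trees, seed, class weighting).
#' @slot cvMetrics stratified cross-validation metrics (AUROC, precision,
#'   recall).
#' @slot trainingIds compound ids used in training (excluded at prediction).
#' @slot fpConfig fingerprint configuration the model expects.
#' @aliases ActivityModel-class
#' @exportClass ActivityModel
setClass("ActivityModel",
  slots = c(forest = "ANY", config = "list", cvMetrics = "list",
            trainingIds = "character", fpConfig = "list"))

#' FourPLFit: four-parameter logistic dose-response fit
#'
#' Model: \code{y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) -
#' log10(x))))}, responses in percent of the reference-ligand window.
#'
#' @slot coefficients named numeric: \code{bottom}, \code{top}, \code{ec50}
#'   (molar), \code{hill}.
#' @slot se standard errors, same names.
#' @slot rss residual sum of squares.
#' @slot converged honest convergence flag from the optimizer plus sanity
#'   checks.
#' @slot model \code{"agonist"} (hill > 0) or \code{"inhibition"} (hill < 0).
#' @slot nPoints number of observations fitted.
#' @aliases FourPLFit-class
#' @exportClass FourPLFit
setClass("FourPLFit",
  slots = c(coefficients = "numeric", se = "numeric", rss = "numeric",
            converged = "logical", model = "character", nPoints = "integer"))

setValidity("FourPLFit", function(object) {
  need <- c("bottom", "top", "ec50", "hill")
  if (!all(need %in% names(object@coefficients)))
    return("coefficients must contain bottom, top, ec50, hill")
  if (is.finite(object@coefficients[["ec50"]]) && object@coefficients[["ec50"]] <= 0)
    return("ec50 must be positive")
  if (!object@model %in% c("agonist", "inhibition"))
    return("model must be 'agonist' or 'inhibition'")
  TRUE
})

#' SegmentationParams: constants of the cross-sectional-area algorithm
#'
#' Defaults are the printed values of the published algorithm: 500-px
#' minimum nucleus area, 0.5 coefficients for the overlap / cell-threshold /
#' low-intensity rules, 1 erosion + 2 dilations on the cell mask, 3x3 gray
#' erosion, Gaussian sigma 3 px, 5x5 gray dilation, watershed compactness
#' 0.1, and 3 post-hoc erosions + 3 dilations, all with 4-connectivity.
#'
#' @aliases SegmentationParams-class
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  slots = c(minNucleusArea = "numeric", overlapCoefficient = "numeric",
            cellThresholdCoefficient = "numeric", lowIntensityCoefficient = "numeric",
            maskErosions = "integer", maskDilations = "integer",
            gradientErosionKernel = "integer", gaussianSigma = "numeric",
            gradientDilationKernel = "integer", watershedCompactness = "numeric",
            postErosions = "integer", postDilations = "integer"),
  prototype = list(minNucleusArea = 500, overlapCoefficient = 0.5,
            cellThresholdCoefficient = 0.5, lowIntensityCoefficient = 0.5,
            maskErosions = 1L, maskDilations = 2L,
            gradientErosionKernel = 3L, gaussianSigma = 3,
            gradientDilationKernel = 5L, watershedCompactness = 0.1,
            postErosions = 3L, postDilations = 3L))

setValidity("SegmentationParams", function(object) {
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      return(sprintf("slot %s must be a single non-negative finite number", s))
  }
  if (object@gradientErosionKernel %% 2L != 1L || object@gradientDilationKernel %% 2L != 1L)
    return("gray-morphology kernels must have odd size")
  TRUE
})

#' SegmentationResult: per-cell label image and CSA table
#'
#' @slot labels integer label image; 0 is background.
#' @slot cells data.frame with columns \code{label}, \code{csa_pixels},
#'   \code{seed_nucleus}.
#' @slot stageCounts named integer vector of objects removed / retained at
#'   each filter stage.
#' @aliases SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  slots = c(labels = "matrix", cells = "data.frame", stageCounts = "integer"))

setValidity("SegmentationResult", function(object) {
  if (nrow(object@cells) &&
      !all(c("label", "csa_pixels", "seed_nucleus") %in% names(object@cells)))
    return("cells table must have label, csa_pixels, seed_nucleus")
  if (nrow(object@cells) && any(object@cells$csa_pixels <= 0))
    return("every retained cell must have CSA > 0")
  TRUE
})

## ---- synthetic-data specification objects -------------------------------

#' PlateEffectSpec: generative model of plate artifacts
#'
#' Sample wells are drawn as \code{grandMean * (1 + row effect) * (1 + col
#' effect) * (1 - edge depression) * noise}, with multiplicative log-normal
#' noise of coefficient of variation \code{noiseCv}; a fraction
#' \code{spikeRate} of sample wells are true actives raised additively by
#' \code{spikeEffect} robust residual scales.
#'
#' @aliases PlateEffectSpec-class
#' @exportClass PlateEffectSpec
setClass("PlateEffectSpec",
  slots = c(grandMean = "numeric", rowGradient = "numeric",
            colGradient = "numeric", edgeDepression = "numeric",
            noiseCv = "numeric", spikeRate = "numeric", spikeEffect = "numeric",
            seed = "integer"),
  prototype = list(grandMean = 1e6, rowGradient = 0.3, colGradient = -0.3,
            edgeDepression = 0.2, noiseCv = 0.1, spikeRate = 0.02,
            spikeEffect = 8, seed = 1L))

setValidity("PlateEffectSpec", function(object) {
  if (object@grandMean <= 0) return("grandMean must be > 0")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (object@spikeRate < 0 || object@spikeRate > 1)
    return("spikeRate must be in [0, 1]")
  if (object@edgeDepression < 0 || object@edgeDepression >= 1)
    return("edgeDepression must be in [0, 1)")
  TRUE
})

#' LibrarySpec: generative model of a compound library
#'
#' Compounds are assembled from a fixed fragment grammar (aromatic and
#' aliphatic rings, chains, polar decorations); a fraction
#' \code{activeFraction} additionally carry the \code{pharmacophore}
#' substructure. Activity labels equal carrier status, then
#' \code{labelNoise} random flips are applied.
#'
#' @aliases LibrarySpec-class
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  slots = c(nCompounds = "integer", pharmacophore = "character",
            activeFraction = "numeric", labelNoise = "numeric", seed = "integer"),
  prototype = list(nCompounds = 1000L, pharmacophore = "c1ccccc1C(=O)N",
            activeFraction = 0.1, labelNoise = 0, seed = 1L))

setValidity("LibrarySpec", function(object) {
  if (object@activeFraction < 0 || object@activeFraction > 1)
    return("activeFraction must be in [0, 1]")
  if (object@labelNoise < 0 || object@labelNoise > 1)
    return("labelNoise must be in [0, 1]")
  if (object@nCompounds < 1L) return("nCompounds must be >= 1")
  TRUE
})

#' CellImageSpec: generative model of two-channel cell micrographs
#'
#' Disk-like cells with one nucleus each are packed without overlap into a
#' 16-bit two-channel image (channel 1 nuclei, channel 2 cell bodies);
#' additive Gaussian noise is clipped to the bit depth.
#'
#' @aliases CellImageSpec-class
#' @exportClass CellImageSpec
setClass("CellImageSpec",
  slots = c(imageShape = "integer", nCells = "integer",
            cellAreaRange = "numeric", nucleusAreaRange = "numeric",
            cellIntensity = "numeric", nucleusIntensity = "numeric",
            backgroundIntensity = "numeric", noiseSd = "numeric",
            allowBorder = "logical", seed = "integer"),
  prototype = list(imageShape = c(1024L, 1024L), nCells = 20L,
            cellAreaRange = c(2000, 20000), nucleusAreaRange = c(700, 1300),
            cellIntensity = 12000, nucleusIntensity = 30000,
            backgroundIntensity = 400, noiseSd = 150,
            allowBorder = FALSE, seed = 1L))

setValidity("CellImageSpec", function(object) {
  if (any(object@imageShape < 64L)) return("imageShape must be at least 64 x 64")
  if (any(object@cellAreaRange <= 0) || any(object@nucleusAreaRange <= 0))
    return("areas must be positive")
  ints <- c(object@cellIntensity, object@nucleusIntensity, object@backgroundIntensity)
  if (any(ints < 0) || any(ints > 65535))
    return("intensities must lie within the 16-bit range")
  TRUE
})
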