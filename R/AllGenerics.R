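## Accessor generics.  Slot access outside the package should go through
## these.

#' @rdname PlateGrid-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname PlateGrid-class
#' @export
setGeneric("wellValues", function(object) standardGeneric("wellValues"))
#' @rdname PlateGrid-class
#' @export
setGeneric("wellRoles", function(object) standardGeneric("wellRoles"))
#' @rdname PlateGrid-class
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname BScorePlate-class
#' @export
setGeneric("bScores", function(object) standardGeneric("bScores"))
#' @rdname BScorePlate-class
#' @export
setGeneric("robustScale", function(object) standardGeneric("robustScale"))

#' @rdname MCSPatternSet-class
#' @export
setGeneric("patternSmarts", function(object) standardGeneric("patternSmarts"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("csaTable", function(object) standardGeneric("csaTable"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname CompoundLibrary-class
#' @export
setGeneric("smilesOf", function(object) standardGeneric("smilesOf"))
#' @rdname CompoundLibrary-class
#' @export
setGeneric("activityOf", function(object) standardGeneric("activityOf"))

setMethod("plateId", "PlateGrid", function(object) object@plateId)
setMethod("wellValues", "PlateGrid", function(object) object@values)
setMethod("wellRoles", "PlateGrid", function(object) object@roles)
setMethod("compoundIds", "PlateGrid", function(object) object@compoundIds)

setMethod("plateId", "BScorePlate", function(object) object@plateId)
setMethod("bScores", "BScorePlate", function(object) object@scores)
setMethod("robustScale", "BScorePlate", function(object) object@robustScale)

setMethod("patternSmarts", "MCSPatternSet", function(object) object@smarts)

setMethod("csaTable", "SegmentationResult", function(object) object@cells)
setMethod("labelImage", "SegmentationResult", function(object) object@labels)
setMethod("stageCounts", "SegmentationResult", function(object) object@stageCounts)

setMethod("compoundIds", "CompoundLibrary", function(object) object@ids)
setMethod("smilesOf", "CompoundLibrary", function(object) object@smiles)
setMethod("activityOf", "CompoundLibrary", function(object) object@activity)

#' @rdname CompoundLibrary-class
#' @export
setMethod("length", "CompoundLibrary", function(x) length(x@ids))

#' @rdname CompoundLibrary-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CompoundLibrary", ids = x@ids[i], smiles = x@smiles[i],
      activity = x@activity[i], provenance = x@provenance,
      graphs = if (length(x@graphs)) x@graphs[i] else list())
})

#' @rdname MCSPatternSet-class
#' @export
setMethod("length", "MCSPatternSet", function(x) length(x@smarts))

## ---- show methods -------------------------------------------------------

#' @noRd
#' @export
setMethod("show", "PlateGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("PlateGrid '%s': %d x %d wells (%d sample, %d pos, %d neg)\n",
              object@plateId, d[1L], d[2L],
              sum(object@roles == "sample"), sum(object@roles == "pos"),
              sum(object@roles == "neg")))
})

#' @noRd
#' @export
setMethod("show", "MedianPolishDecomposition", function(object) {
  cat(sprintf(paste0("MedianPolishDecomposition: %d x %d, overall = %.4g, ",
                     "%d sweeps, converged = %s\n"),
              nrow(object@residuals), ncol(object@residuals), object@overall,
              object@nSweeps, object@converged))
})

#' @noRd
#' @export
setMethod("show", "BScorePlate", function(object) {
  cat(sprintf("BScorePlate '%s': robust scale %.4g, %d scored wells\n",
              object@plateId, object@robustScale, sum(!is.na(object@scores))))
})

#' @noRd
#' @export
setMethod("show", "CompoundLibrary", function(object) {
  cat(sprintf("CompoundLibrary (%s): %d compounds, %d labeled active\n",
              object@provenance, length(object@ids),
              sum(object@activity, na.rm = TRUE)))
  if (length(object@ids))
    cat("  e.g.", object@ids[1L], object@smiles[1L], "\n")
})

#' @noRd
#' @export
setMethod("show", "MCSPatternSet", function(object) {
  cat(sprintf("MCSPatternSet: %d unique patterns (%d-%d atoms)\n",
              length(object@smarts),
              if (length(object@nAtoms)) min(object@nAtoms) else 0L,
              if (length(object@nAtoms)) max(object@nAtoms) else 0L))
  for (i in head(seq_along(object@smarts), 5L))
    cat(sprintf("  %s (pairs %d, compounds %d)\n", object@smarts[i],
                object@supportPairs[i], object@supportCompounds[i]))
  if (length(object@smarts) > 5L) cat("  ...\n")
})

#' @noRd
#' @export
setMethod("show", "MCSClusterSet", function(object) {
  cat(sprintf("MCSClusterSet: k = %d over %d patterns\n", object@k,
              length(object@patterns@smarts)))
  for (cl in seq_len(object@k))
    cat(sprintf("  cluster %d: %d members, medoid %s\n", cl,
                sum(object@assignments == cl),
                object@patterns@smarts[object@medoids[cl]]))
})

#' @noRd
#' @export
setMethod("show", "FourPLFit", function(object) {
  co <- object@coefficients
  cat(sprintf(paste0("FourPLFit (%s): bottom %.3g, top %.3g, %s %.3g M, ",
                     "hill %.3g, converged = %s\n"),
              object@model, co[["bottom"]], co[["top"]],
              if (object@model == "inhibition") "IC50" else "EC50",
              co[["ec50"]], co[["hill"]], object@converged))
})

#' @noRd
#' @export
setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d compounds x %d bits (radius %d)\n",
              nrow(object@bits), object@nBits, object@radius))
})

#' @noRd
#' @export
setMethod("show", "ActivityModel", function(object) {
  cat(sprintf("ActivityModel: %d trees, %d training compounds, CV AUROC %.3f\n",
              object@config$nTrees, length(object@trainingIds),
              if (is.null(object@cvMetrics$auroc)) NA_real_ else object@cvMetrics$auroc))
})

#' @noRd
#' @export
setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d cells", nrow(object@cells)))
  if (nrow(object@cells))
    cat(sprintf(", CSA %d-%d px", min(object@cells$csa_pixels),
                max(object@cells$csa_pixels)))
  cat("\n  stages: ", paste(names(object@stageCounts), object@stageCounts,
                            sep = "=", collapse = ", "), "\n", sep = "")
})
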