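## Fold-enrichment of substructure patterns: how much more frequent a
## pattern is in a hit list than in a reference library.  Occurrence counts
## compounds containing the pattern (not embeddings).

#' Fold-enrichment of patterns in a hit list versus a reference library
#'
#' For each pattern, \code{fold = (h/H) / (r/R)} where \code{h}/\code{r}
#' are the numbers of hit / reference compounds containing the pattern and
#' \code{H}/\code{R} the parseable library sizes. A pattern absent from the
#' reference yields an infinite fold flagged in \code{zero_reference}
#' unless \code{pseudocount = TRUE}, in which case 0.5 is used for
#' \code{r}. Unparsable structures are excluded from the denominators with
#' a logged count.
#'
#' @param patterns character vector of SMARTS or an
#'   \linkS4class{MCSPatternSet}.
#' @param hits,reference \linkS4class{CompoundLibrary} objects.
#' @param pseudocount replace a zero reference count by 0.5 instead of
#'   reporting infinity.
#' @return data.frame with columns \code{pattern}, \code{h}, \code{H},
#'   \code{r}, \code{R}, \code{fold}, \code{zero_reference}.
#' @export
enrichmentFold <- function(patterns, hits, reference, pseudocount = FALSE) {
  if (is(patterns, "MCSPatternSet")) patterns <- patterns@smarts
  stopifnot(is.character(patterns), length(patterns) >= 1L,
            is(hits, "CompoundLibrary"), is(reference, "CompoundLibrary"),
            length(hits) > 0L, length(reference) > 0L)
  out <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    mh <- matchesSubstructure(hits, p, quiet = TRUE)
    mr <- matchesSubstructure(reference, p, quiet = TRUE)
    nBad <- sum(is.na(mh)) + sum(is.na(mr))
    if (nBad > 0L)
      message(nBad, " unparsable structure(s) excluded for pattern ", p)
    h <- sum(mh, na.rm = TRUE); H <- sum(!is.na(mh))
    r <- sum(mr, na.rm = TRUE); R <- sum(!is.na(mr))
    rEff <- if (r == 0L && pseudocount) 0.5 else r
    fold <- if (rEff == 0) Inf else (h / H) / (rEff / R)
    out[[i]] <- data.frame(pattern = p, h = h, H = H, r = r, R = R,
                           fold = fold, zero_reference = r == 0L)
  }
  do.call(rbind, out)
}

#' Select analogues containing a pattern
#'
#' Returns the sub-library of compounds containing the SMARTS pattern as a
#' substructure, ordered by compound id.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param pattern a single SMARTS (or the medoid of an
#'   \linkS4class{MCSPatternSet} if one is supplied with an index
#'   attribute).
#' @return a \linkS4class{CompoundLibrary} subset, provenance
#'   \code{"candidate"}.
#' @export
selectAnalogues <- function(library, pattern) {
  stopifnot(is(library, "CompoundLibrary"), is.character(pattern),
            length(pattern) == 1L)
  m <- matchesSubstructure(library, pattern, quiet = TRUE)
  keep <- which(!is.na(m) & m)
  keep <- keep[order(library@ids[keep])]
  sel <- library[keep]
  sel@provenance <- "candidate"
  sel
}

#' Per-cluster enrichment summary
#'
#' Reports, for every cluster of an \linkS4class{MCSClusterSet}, the
#' medoid pattern's fold-enrichment together with the member patterns'
#' individual enrichments.
#'
#' @param clusters an \linkS4class{MCSClusterSet}.
#' @param hits,reference \linkS4class{CompoundLibrary} objects.
#' @param pseudocount see \code{\link{enrichmentFold}}.
#' @return data.frame with one row per pattern: \code{cluster},
#'   \code{is_medoid}, plus the \code{\link{enrichmentFold}} columns.
#' @export
clusterEnrichment <- function(clusters, hits, reference, pseudocount = FALSE) {
  stopifnot(is(clusters, "MCSClusterSet"))
  ef <- enrichmentFold(clusters@patterns, hits, reference, pseudocount)
  ef$cluster <- clusters@assignments
  ef$is_medoid <- seq_len(nrow(ef)) %in% clusters@medoids
  ef[order(ef$cluster, -ef$fold), ]
}
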