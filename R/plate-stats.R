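## Plate normalization and hit calling: median polish, B-scores, top-N
## triage and the mean + 3 SD confirmation threshold.

#' Median polish of a plate
#'
#' Alternating row-then-column median sweeps decompose a plate into
#' \code{overall + rowEffects + colEffects + residuals}, the standard
#' robust correction for row, column and edge artifacts in plate-based
#' screens. Sweeping stops when the largest absolute change falls below
#' \code{tol} or after \code{maxSweeps} full sweeps. \code{NA} entries
#' (e.g. control wells masked out of the fit) are ignored by the medians
#' and carry \code{NA} residuals; the additive identity holds exactly on
#' all fitted wells.
#'
#' @param values numeric matrix, at least 2 x 2; non-finite entries other
#'   than \code{NA} are an error.
#' @param maxSweeps maximum number of full row+column sweeps (default 10).
#' @param tol convergence tolerance in signal units; default \code{1e-6}
#'   times the absolute plate median (or 1e-6 for an all-zero plate).
#' @return a \linkS4class{MedianPolishDecomposition}.
#' @examples
#' mp <- medianPolish(outer(c(-2, 0, 2), c(-1, 0, 1), "+") + 10)
#' max(abs(mp@residuals))
#' @export
medianPolish <- function(values, maxSweeps = 10L, tol = NULL) {
  if (!is.matrix(values) || nrow(values) < 2L || ncol(values) < 2L)
    stop("values must be a matrix with at least 2 rows and 2 columns",
         call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite (NA allowed for masked wells)", call. = FALSE)
  if (is.null(tol)) {
    m <- median(abs(values), na.rm = TRUE)
    tol <- 1e-6 * if (is.finite(m) && m > 0) m else 1
  }
  r <- values
  rowEff <- numeric(nrow(values))
  colEff <- numeric(ncol(values))
  overall <- 0
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(maxSweeps)) {
    sweeps <- s
    delta <- 0
    rm <- apply(r, 1L, median, na.rm = TRUE)
    rm[is.na(rm)] <- 0
    r <- r - rm
    rowEff <- rowEff + rm
    cm <- median(rowEff)
    rowEff <- rowEff - cm
    overall <- overall + cm
    delta <- max(delta, max(abs(rm)))
    cmed <- apply(r, 2L, median, na.rm = TRUE)
    cmed[is.na(cmed)] <- 0
    r <- sweep(r, 2L, cmed)
    colEff <- colEff + cmed
    cm <- median(colEff)
    colEff <- colEff - cm
    overall <- overall + cm
    delta <- max(delta, max(abs(cmed)))
    if (delta < tol) { converged <- TRUE; break }
  }
  new("MedianPolishDecomposition", overall = overall, rowEffects = rowEff,
      colEffects = colEff, residuals = r, nSweeps = sweeps,
      converged = converged, tol = tol)
}

#' Reconstruct fitted values of a median polish
#'
#' @param polish a \linkS4class{MedianPolishDecomposition}.
#' @return matrix \code{overall + rowEffects + colEffects}.
#' @export
polishFitted <- function(polish) {
  polish@overall + outer(polish@rowEffects, polish@colEffects, "+")
}

#' B-scores for a plate
#'
#' Control and empty wells are masked out, the sample wells are median
#' polished, and each sample residual is divided by the robust scale
#' \code{1.4826 * MAD} of the sample residuals (the standard B-score).
#'
#' @param plate a \linkS4class{PlateGrid}.
#' @param polish optional precomputed \linkS4class{MedianPolishDecomposition}
#'   of the control-masked plate; computed if missing.
#' @param ... passed to \code{\link{medianPolish}}.
#' @return a \linkS4class{BScorePlate}; control wells carry \code{NA}.
#' @export
bScore <- function(plate, polish = NULL, ...) {
  stopifnot(is(plate, "PlateGrid"))
  masked <- plate@values
  masked[plate@roles != "sample"] <- NA
  if (is.null(polish)) polish <- medianPolish(masked, ...)
  res <- polish@residuals
  sampleRes <- res[plate@roles == "sample"]
  sampleRes <- sampleRes[!is.na(sampleRes)]
  scale <- 1.4826 * median(abs(sampleRes - median(sampleRes)))
  if (scale <= 0)
    stop("degenerate plate: robust residual scale is zero", call. = FALSE)
  scores <- res / scale
  scores[plate@roles != "sample"] <- NA
  new("BScorePlate", plateId = plate@plateId, scores = scores,
      robustScale = scale, polish = polish)
}

#' Score a whole screen
#'
#' Median-polishes and B-scores every plate, returning one long table.
#'
#' @param plates list of \linkS4class{PlateGrid}.
#' @param ... passed to \code{\link{medianPolish}}.
#' @return data.frame: \code{compound_id}, \code{plate_id}, \code{row},
#'   \code{col} (0-based), \code{b_score}.
#' @export
scoreScreen <- function(plates, ...) {
  out <- lapply(plates, function(pl) {
    bs <- bScore(pl, ...)
    idx <- which(pl@roles == "sample")
    rc <- arrayInd(idx, dim(pl@values))
    data.frame(compound_id = pl@compoundIds[idx], plate_id = pl@plateId,
               row = rc[, 1L] - 1L, col = rc[, 2L] - 1L,
               b_score = bs@scores[idx])
  })
  do.call(rbind, out)
}

#' Top-N triage by B-score
#'
#' Sorts compounds by B-score descending, breaking ties by compound id
#' ascending, and returns the first \code{min(n, #compounds)}.
#'
#' @param scores data.frame as returned by \code{\link{scoreScreen}} (needs
#'   \code{compound_id} and \code{b_score}).
#' @param n number of compounds to select (default 80, the usual triage
#'   depth of this cascade).
#' @return the selected rows, ranked.
#' @export
selectTopHits <- function(scores, n = 80L) {
  if (is.null(scores) || nrow(scores) == 0L)
    stop("no scored compounds to select from", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  ord <- order(-scores$b_score, scores$compound_id)
  head(scores[ord, , drop = FALSE], n)
}

#' Confirmation-screen hit threshold
#'
#' \code{mean + 3 * SD} of the negative-control signals (sample SD,
#' denominator n - 1).
#'
#' @param negControls numeric vector of at least two negative-control
#'   signals.
#' @return the threshold (signal units).
#' @examples
#' confirmationThreshold(c(90, 100, 100, 110))
#' @export
confirmationThreshold <- function(negControls) {
  if (length(negControls) < 2L || any(!is.finite(negControls)))
    stop("need at least two finite negative-control values", call. = FALSE)
  mean(negControls) + 3 * sd(negControls)
}

#' Call hits against a threshold
#'
#' A compound is a hit iff its confirmation signal is strictly greater
#' than the threshold. Input order is preserved.
#'
#' @param confirm data.frame with \code{compound_id} and \code{signal}.
#' @param threshold finite threshold (signal units).
#' @return data.frame: \code{compound_id}, \code{signal},
#'   \code{threshold}, \code{is_hit}.
#' @export
callHits <- function(confirm, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (is.null(confirm) || nrow(confirm) == 0L)
    return(data.frame(compound_id = character(), signal = numeric(),
                      threshold = numeric(), is_hit = logical()))
  data.frame(compound_id = confirm$compound_id, signal = confirm$signal,
             threshold = threshold, is_hit = confirm$signal > threshold)
}
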