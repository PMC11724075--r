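## Folded circular (Morgan-style) fingerprints on the internal molecular
## graph.  Atom environments of increasing bond radius are hashed from an
## initial invariant (element, heavy degree, implicit H count, aromaticity)
## and the sorted (bond type, neighbour hash) lists, then folded modulo the
## bit width.  Atom numbering does not affect the result, so different
## writings of the same structure map to identical rows.

mgMorganBits <- function(mg, radius = 2L, nBits = 2048L) {
  n <- mgNAtoms(mg)
  if (n == 0L) return(integer(0))
  deg <- tabulate(c(mg$bonds$a1, mg$bonds$a2), nbins = n)
  hs <- mgImplicitH(mg)
  el <- match(mg$element, names(.VALENCE))
  cur <- vapply(seq_len(n), function(a)
    hashIntVector(c(el[a], deg[a], hs[a], as.integer(mg$aromatic[a]))),
    numeric(1))
  adj <- mgAdjacency(mg)
  bcol <- mgBondColor(mg)
  all <- cur
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (!nrow(nb)) return(hashIntVector(c(r, cur[a])))
      pairs <- sort(bcol[nb[, 2L]] * 2147483648 + cur[nb[, 1L]])
      hashIntVector(c(r, cur[a], pairs %/% 2147483648, pairs %% 2147483648))
    }, numeric(1))
    all <- c(all, nxt)
    cur <- nxt
  }
  sort(unique(as.integer(all %% nBits))) + 1L
}

#' Circular (Morgan-style) fingerprints for a compound library
#'
#' @param library a \linkS4class{CompoundLibrary} (or character vector of
#'   SMILES).
#' @param radius bond radius of the circular environments (default 2).
#' @param nBits folded width (default 2048).
#' @param quiet suppress the skipped-structure message.
#' @return a \linkS4class{FingerprintMatrix}; unparsable structures are
#'   skipped with a logged count (error if nothing parses).
#' @examples
#' fp <- morganFingerprints(c("CCO", "OCC"))
#' stopifnot(identical(fp@bits[1, ], fp@bits[2, ]))
#' @export
morganFingerprints <- function(library, radius = 2L, nBits = 2048L,
                               quiet = FALSE) {
  if (is.character(library))
    library <- new("CompoundLibrary", ids = sprintf("CMP%06d", seq_along(library)),
                   smiles = library, activity = rep(NA, length(library)),
                   provenance = "candidate", graphs = list())
  graphs <- libraryGraphs(library, quiet = quiet)
  ok <- !vapply(graphs, is.null, logical(1))
  if (!any(ok)) stop("no structure could be parsed", call. = FALSE)
  if (!quiet && any(!ok))
    message(sum(!ok), " structure(s) skipped during fingerprinting")
  bits <- matrix(0L, nrow = sum(ok), ncol = nBits)
  rows <- which(ok)
  for (i in seq_along(rows))
    bits[i, mgMorganBits(graphs[[rows[i]]], radius, nBits)] <- 1L
  new("FingerprintMatrix", bits = bits, ids = library@ids[ok],
      radius = as.integer(radius), nBits = as.integer(nBits))
}

## Tanimoto similarity between two fingerprint rows (used in tests and
## diagnostics)
tanimoto <- function(a, b) {
  num <- sum(a & b)
  den <- sum(a | b)
  if (den == 0) return(0)
  num / den
}
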