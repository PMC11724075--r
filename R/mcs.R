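## Maximum common substructure mining.
##
## The per-pair MCS is the maximum common *connected induced* substructure
## under exact atom (element + aromaticity) and bond (order / aromatic)
## matching, found by a branch-and-bound mapping search: at each node the
## lowest-indexed frontier atom of the first molecule is either mapped to
## each compatible atom of the second or permanently excluded.  A per-pair
## wall-clock deadline aborts pathological pairs (skip-and-log, as for the
## screening use case a missing pair only costs support).

mcsPair <- function(gA, gB, timeoutSec = 2) {
  nA <- mgNAtoms(gA); nB <- mgNAtoms(gB)
  acA <- mgAtomColor(gA); acB <- mgAtomColor(gB)
  matA <- matrix(0L, nA, nA); matB <- matrix(0L, nB, nB)
  bcA <- mgBondColor(gA); bcB <- mgBondColor(gB)
  for (k in seq_len(mgNBonds(gA))) {
    matA[gA$bonds$a1[k], gA$bonds$a2[k]] <- bcA[k]
    matA[gA$bonds$a2[k], gA$bonds$a1[k]] <- bcA[k]
  }
  for (k in seq_len(mgNBonds(gB))) {
    matB[gB$bonds$a1[k], gB$bonds$a2[k]] <- bcB[k]
    matB[gB$bonds$a2[k], gB$bonds$a1[k]] <- bcB[k]
  }
  neighborsA <- lapply(seq_len(nA), function(a) which(matA[a, ] != 0L))

  deadline <- Sys.time() + timeoutSec
  timedOut <- FALSE
  calls <- 0L
  bestAtoms <- integer(0)

  search <- function(mapA, mapB, excluded, usedB) {
    if (timedOut) return()
    calls <<- calls + 1L
    if (calls %% 256L == 0L && Sys.time() > deadline) {
      timedOut <<- TRUE
      return()
    }
    size <- length(mapA)
    if (size > length(bestAtoms)) bestAtoms <<- mapA
    avail <- !excluded
    if (size) avail[mapA] <- FALSE
    cand <- if (size) {
      fr <- unique(unlist(neighborsA[mapA], use.names = FALSE))
      fr[avail[fr]]
    } else which(avail)
    if (!length(cand)) return()
    ## optimistic bound: everything available could still be mapped
    if (size + min(sum(avail), nB - size) <= length(bestAtoms)) return()
    a <- min(cand)
    bs <- which(!usedB & acB == acA[a])
    for (b in bs) {
      if (size == 0L || all(matB[b, mapB] == matA[a, mapA])) {
        usedB[b] <- TRUE
        search(c(mapA, a), c(mapB, b), excluded, usedB)
        usedB[b] <- FALSE
        if (timedOut) return()
      }
    }
    excluded[a] <- TRUE
    search(mapA, mapB, excluded, usedB)
  }
  search(integer(0), integer(0), logical(nA), logical(nB))
  list(atoms = sort(bestAtoms), size = length(bestAtoms), timedOut = timedOut)
}

#' Mine maximum common substructures over a hit list
#'
#' Computes the MCS of every unordered pair of compounds, drops fragments
#' below \code{minAtoms} heavy atoms, deduplicates patterns by exact
#' colored-graph isomorphism and records pair support and the number of hit
#' compounds containing each pattern.
#'
#' @param hits a \linkS4class{CompoundLibrary} with at least two parseable
#'   compounds.
#' @param minAtoms minimum fragment size in heavy atoms (default 4).
#' @param timeoutSec per-pair search deadline in seconds; timed-out pairs
#'   are skipped and counted in a message (default 2).
#' @return an \linkS4class{MCSPatternSet}.
#' @export
pairwiseMCS <- function(hits, minAtoms = 4L, timeoutSec = 2) {
  stopifnot(is(hits, "CompoundLibrary"))
  graphs <- libraryGraphs(hits)
  ok <- which(!vapply(graphs, is.null, logical(1)))
  if (length(ok) < 2L)
    stop("need at least two parseable hit compounds", call. = FALSE)
  pats <- list()     # list of (graph, hash)
  support <- integer(0)
  nSkipped <- 0L
  for (ii in seq_len(length(ok) - 1L)) {
    for (jj in seq(ii + 1L, length(ok))) {
      gA <- graphs[[ok[ii]]]; gB <- graphs[[ok[jj]]]
      res <- mcsPair(gA, gB, timeoutSec)
      if (res$timedOut) { nSkipped <- nSkipped + 1L; next }
      if (res$size < minAtoms) next
      frag <- mgSubgraph(gA, res$atoms)
      h <- mgInvariantHash(frag)
      found <- FALSE
      for (p in seq_along(pats)) {
        if (pats[[p]]$hash == h && mgIsomorphic(pats[[p]]$graph, frag)) {
          support[p] <- support[p] + 1L
          found <- TRUE
          break
        }
      }
      if (!found) {
        pats[[length(pats) + 1L]] <- list(graph = frag, hash = h)
        support <- c(support, 1L)
      }
    }
  }
  if (nSkipped > 0L)
    message(nSkipped, " pair(s) hit the MCS deadline and were skipped")
  fragGraphs <- lapply(pats, `[[`, "graph")
  smarts <- vapply(fragGraphs, mgToSmarts, character(1))
  supportCompounds <- vapply(smarts, function(s)
    sum(matchesSubstructure(hits, s, quiet = TRUE), na.rm = TRUE), numeric(1))
  new("MCSPatternSet", smarts = unname(smarts),
      nAtoms = vapply(fragGraphs, mgNAtoms, integer(1)),
      nBonds = vapply(fragGraphs, mgNBonds, integer(1)),
      supportPairs = support,
      supportCompounds = as.integer(supportCompounds),
      graphs = fragGraphs)
}

#' Cluster MCS patterns by k-means on fragment fingerprints
#'
#' Each fragment is embedded as a binary circular fingerprint (default 1024
#' bits, radius 2) and clustered with k-means (Euclidean on 0/1 vectors,
#' multiple restarts under a fixed seed). The medoid of a cluster is the
#' member nearest its centroid (ties to the lowest pattern index).
#' Duplicate fingerprint rows are collapsed before k-means so that \code{k}
#' may equal the number of *distinct* fingerprints.
#'
#' @param patterns an \linkS4class{MCSPatternSet}.
#' @param k number of clusters (default 10).
#' @param seed integer RNG seed.
#' @param nBits,radius fingerprint parameters for the embedding.
#' @param nstart k-means restarts.
#' @return an \linkS4class{MCSClusterSet}.
#' @export
clusterMCS <- function(patterns, k = 10L, seed = 1L, nBits = 1024L,
                       radius = 2L, nstart = 10L) {
  stopifnot(is(patterns, "MCSPatternSet"))
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  n <- length(patterns@smarts)
  if (k > n) stop("k exceeds the number of patterns", call. = FALSE)
  fp <- matrix(0, nrow = n, ncol = nBits)
  for (i in seq_len(n))
    fp[i, mgMorganBits(patterns@graphs[[i]], radius, nBits)] <- 1
  key <- apply(fp, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  um <- fp[uniq, , drop = FALSE]
  if (k > nrow(um))
    stop("k exceeds the number of distinct fingerprints (", nrow(um), ")",
         call. = FALSE)
  if (k == nrow(um)) {
    ## every distinct fingerprint is its own cluster (kmeans proper
    ## requires k < n)
    km <- list(cluster = seq_len(k), centers = um)
  } else {
    km <- withSeed(seed, kmeans(um, centers = k, nstart = nstart,
                                iter.max = 100L))
  }
  assignments <- km$cluster[match(key, key[uniq])]
  medoids <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(assignments == cl)
    d2 <- colSums((t(fp[members, , drop = FALSE]) - km$centers[cl, ])^2)
    medoids[cl] <- members[which.min(d2)]
  }
  new("MCSClusterSet", k = k, assignments = as.integer(assignments),
      medoids = medoids, patterns = patterns,
      featureConfig = list(nBits = as.integer(nBits),
                           radius = as.integer(radius),
                           nstart = as.integer(nstart), seed = as.integer(seed)))
}
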