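## Synthetic compound libraries from a fixed fragment grammar.
##
## Molecules are assembled directly as molecular graphs (rings, chains and
## polar decorations joined at free valences), so every emitted SMILES is
## valid by construction and substructure content is controllable.  A
## carrier additionally receives the pharmacophore grafted as a fragment;
## carrier status is then *verified* by an actual substructure match, and
## non-carriers that accidentally contain the pattern are resampled, so the
## ground-truth labels are exact by definition.

.frgBenzene <- function() molGraph(rep("C", 6), rep(TRUE, 6),
  data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 1L, aromatic = TRUE))

.frgPyridine <- function() molGraph(c("N", rep("C", 5)), rep(TRUE, 6),
  data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 1L, aromatic = TRUE))

.frgRing <- function(k) molGraph(rep("C", k), rep(FALSE, k),
  data.frame(a1 = seq_len(k), a2 = c(seq_len(k)[-1L], 1L),
             order = 1L, aromatic = FALSE))

.frgChain <- function(k) molGraph(rep("C", k), rep(FALSE, k),
  if (k > 1L) data.frame(a1 = seq_len(k - 1L), a2 = 2:k, order = 1L,
                         aromatic = FALSE)
  else data.frame(a1 = integer(), a2 = integer(), order = integer(),
                  aromatic = logical()))

.frgAtom <- function(el) molGraph(el, FALSE,
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             aromatic = logical()))

.frgCarbonyl <- function() molGraph(c("C", "O"), c(FALSE, FALSE),
  data.frame(a1 = 1L, a2 = 2L, order = 2L, aromatic = FALSE))

.frgAmide <- function() molGraph(c("C", "O", "N"), rep(FALSE, 3),
  data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L), order = c(2L, 1L),
             aromatic = FALSE))

## decorations: generator closures; `carbonylHead` marks fragments whose
## attachment atom is a carbonyl carbon (kept off aromatic rings for
## non-carriers so an aryl-carbonyl pharmacophore cannot arise by accident)
.decorations <- list(
  list(f = function() .frgChain(1L),  carbonylHead = FALSE),
  list(f = function() .frgChain(2L),  carbonylHead = FALSE),
  list(f = function() .frgChain(3L),  carbonylHead = FALSE),
  list(f = function() .frgAtom("O"),  carbonylHead = FALSE),
  list(f = function() .frgAtom("N"),  carbonylHead = FALSE),
  list(f = function() .frgAtom("S"),  carbonylHead = FALSE),
  list(f = function() mgCombine(.frgAtom("O"), .frgChain(1L), 1L, 1L),
       carbonylHead = FALSE),
  list(f = function() mgCombine(.frgAtom("S"), .frgChain(1L), 1L, 1L),
       carbonylHead = FALSE),
  list(f = function() mgCombine(.frgCarbonyl(), .frgChain(1L), 1L, 1L),
       carbonylHead = TRUE),
  list(f = function() mgCombine(.frgAmide(), .frgChain(1L), 3L, 1L),
       carbonylHead = TRUE))

.scaffolds <- list(
  function() .frgBenzene(),
  function() .frgPyridine(),
  function() .frgRing(6L),
  function() .frgRing(5L),
  function() .frgChain(4L),
  function() .frgChain(5L))

## attach a decoration at a random free valence; returns mg unchanged when
## no legal site exists
.attachRandom <- function(mg, deco, forbidAromaticCarbonyl) {
  d <- deco$f()
  free <- which(mgFreeValence(mg) >= 1)
  if (forbidAromaticCarbonyl && deco$carbonylHead)
    free <- free[!mg$aromatic[free]]
  if (!length(free)) return(mg)
  at <- resample(free, 1L)
  mgCombine(mg, d, at, 1L)
}

## one random molecule from the grammar; carriers start from the
## pharmacophore graph and may gain a scaffold plus decorations
.randomMolecule <- function(carrier, pharmGraph) {
  if (carrier) {
    mg <- pharmGraph
    if (runif(1) < 0.5) {
      sc <- .scaffolds[[resample(seq_along(.scaffolds), 1L)]]()
      freeM <- which(mgFreeValence(mg) >= 1)
      freeS <- which(mgFreeValence(sc) >= 1)
      if (length(freeM) && length(freeS))
        mg <- mgCombine(mg, sc, resample(freeM, 1L), resample(freeS, 1L))
    }
    nDec <- resample(0:2, 1L)
    forbid <- FALSE
  } else {
    mg <- .scaffolds[[resample(seq_along(.scaffolds), 1L)]]()
    nDec <- resample(1:3, 1L)
    forbid <- TRUE
  }
  for (i in seq_len(nDec))
    mg <- .attachRandom(mg, .decorations[[resample(seq_along(.decorations), 1L)]],
                        forbid)
  mg
}

#' Generate a synthetic compound library with exact activity ground truth
#'
#' Compounds are assembled from the fragment grammar; a fraction
#' \code{activeFraction} carries the pharmacophore substructure of the
#' \linkS4class{LibrarySpec}. Carrier status is verified by an OpenBabel
#' substructure match, and accidental carriers among the non-carrier draws
#' are resampled, so the truth table is exact. Observed activity labels are
#' the carrier flags with \code{labelNoise} random flips.
#'
#' @param spec a \linkS4class{LibrarySpec}.
#' @return list with elements \code{library} (a
#'   \linkS4class{CompoundLibrary} carrying the *observed* labels) and
#'   \code{truth} (data.frame with \code{compound_id}, \code{carrier},
#'   \code{label}).
#' @examples
#' lib <- generateLibrary(librarySpec(nCompounds = 50L, seed = 7L))
#' table(lib$truth$carrier)
#' @export
generateLibrary <- function(spec) {
  stopifnot(is(spec, "LibrarySpec"))
  validObject(spec)
  pharm <- parseSmilesGraphs(spec@pharmacophore, quiet = TRUE)[[1L]]
  if (is.null(pharm) || !isValidSmarts(spec@pharmacophore))
    stop("pharmacophore does not parse as a valid pattern: ",
         spec@pharmacophore, call. = FALSE)
  n <- spec@nCompounds
  nActive <- round(n * spec@activeFraction)
  carrier <- c(rep(TRUE, nActive), rep(FALSE, n - nActive))

  withSeed(spec@seed, {
    graphs <- lapply(carrier, .randomMolecule, pharmGraph = pharm)
    smiles <- vapply(graphs, mgWriteSmiles, character(1))
    ## verify composition; resample disagreements (accidental carriers or
    ## failed grafts) until truth matches construction
    for (round in seq_len(26L)) {
      hit <- matchesSubstructure(smiles, spec@pharmacophore, quiet = TRUE)
      bad <- which(is.na(hit) | hit != carrier)
      if (!length(bad)) break
      if (round == 26L)
        stop("library composition did not converge; pharmacophore may be ",
             "unavoidable or ungraftable under the grammar", call. = FALSE)
      for (i in bad) {
        graphs[[i]] <- .randomMolecule(carrier[i], pharm)
        smiles[i] <- mgWriteSmiles(graphs[[i]])
      }
    }
    label <- carrier
    nFlip <- round(n * spec@labelNoise)
    if (nFlip > 0L) {
      flip <- resample(seq_len(n), nFlip)
      label[flip] <- !label[flip]
    }
    ids <- sprintf("SYN%06d", seq_len(n))
    ## shuffle so carriers are not a prefix block
    ord <- sample.int(n)
    lib <- new("CompoundLibrary", ids = ids, smiles = smiles[ord],
               activity = label[ord], provenance = "synthetic",
               graphs = graphs[ord])
    list(library = lib,
         truth = data.frame(compound_id = ids, carrier = carrier[ord],
                            label = label[ord]))
  })
}

#' Constructor for LibrarySpec
#'
#' @param nCompounds library size.
#' @param pharmacophore SMARTS/SMILES of the planted substructure.
#' @param activeFraction fraction of compounds carrying it.
#' @param labelNoise fraction of activity labels flipped at random.
#' @param seed integer RNG seed.
#' @export
librarySpec <- function(nCompounds = 1000L, pharmacophore = "c1ccccc1C(=O)N",
                        activeFraction = 0.1, labelNoise = 0, seed = 1L) {
  new("LibrarySpec", nCompounds = as.integer(nCompounds),
      pharmacophore = pharmacophore, activeFraction = activeFraction,
      labelNoise = labelNoise, seed = as.integer(seed))
}

#' Grammar motif patterns
#'
#' SMARTS patterns for substructure motifs the fragment grammar embeds;
#' useful as planted patterns in enrichment benchmarks.
#'
#' @param n number of patterns (up to 20).
#' @return character vector of SMARTS.
#' @export
grammarPatterns <- function(n = 20L) {
  pats <- c("c1ccccc1C(=O)N", "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCCC1",
            "c1ccccc1C", "c1ccccc1O", "c1ccccc1N", "c1ccccc1OC", "c1ccccc1S",
            "C1CCCCC1C", "c1ccncc1C", "CC(=O)N", "NC(=O)C", "CCCC",
            "COC", "CSC", "CCN", "CCO", "CC(=O)C")
  head(pats, n)
}

#' Read / write SMILES libraries
#'
#' \code{readSmi} and \code{writeSmi} use the conventional two-column
#' \code{SMILES<tab>compound_id} format; \code{writeLibrarySdf} exports an
#' SDF via ChemmineR/OpenBabel.
#'
#' @param path file path.
#' @param provenance provenance tag for the returned library.
#' @return \code{readSmi}: a \linkS4class{CompoundLibrary}.
#' @export
readSmi <- function(path, provenance = "candidate") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1))
  if (anyNA(ids)) ids <- ifelse(is.na(ids), sprintf("CMP%06d", seq_along(ids)), ids)
  new("CompoundLibrary", ids = ids, smiles = smiles,
      activity = rep(NA, length(ids)), provenance = provenance, graphs = list())
}

#' @rdname readSmi
#' @param lib a \linkS4class{CompoundLibrary}.
#' @export
writeSmi <- function(lib, path) {
  stopifnot(is(lib, "CompoundLibrary"))
  writeLines(paste(lib@smiles, lib@ids, sep = "\t"), path)
  invisible(path)
}

#' @rdname readSmi
#' @export
writeLibrarySdf <- function(lib, path) {
  stopifnot(is(lib, "CompoundLibrary"))
  smi <- lib@smiles
  names(smi) <- lib@ids
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  ChemmineR::write.SDF(sdf, path)
  invisible(path)
}
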