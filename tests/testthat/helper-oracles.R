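## Independent oracles used across the suite.

## Brute-force substructure counting through RDKit (an implementation
## independent of the package's OpenBabel matcher).  Returns, per pattern,
## the number of molecules containing it.
rdkitSubstructCounts <- function(smiles, patterns) {
  smiFile <- tempfile(fileext = ".smi")
  patFile <- tempfile(fileext = ".txt")
  outFile <- tempfile(fileext = ".json")
  pyFile <- tempfile(fileext = ".py")
  on.exit(unlink(c(smiFile, patFile, outFile, pyFile)))
  writeLines(smiles, smiFile)
  writeLines(patterns, patFile)
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "smis = [l.split()[0] for l in open(sys.argv[1]) if l.strip()]",
    "pats = [l.strip() for l in open(sys.argv[2]) if l.strip()]",
    "mols = [Chem.MolFromSmiles(s) for s in smis]",
    "out = [sum(1 for m in mols",
    "           if m is not None and m.HasSubstructMatch(Chem.MolFromSmarts(p)))",
    "       for p in pats]",
    "json.dump(out, open(sys.argv[3], 'w'))"), pyFile)
  status <- system2("python", shQuote(c(pyFile, smiFile, patFile, outFile)))
  stopifnot(status == 0L)
  unlist(jsonlite::read_json(outFile))
}

## Per-molecule RDKit match flags for a single pattern.
rdkitMatches <- function(smiles, pattern) {
  smiFile <- tempfile(fileext = ".smi")
  outFile <- tempfile(fileext = ".json")
  pyFile <- tempfile(fileext = ".py")
  on.exit(unlink(c(smiFile, outFile, pyFile)))
  writeLines(smiles, smiFile)
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "smis = [l.split()[0] for l in open(sys.argv[1]) if l.strip()]",
    "q = Chem.MolFromSmarts(sys.argv[2])",
    "mols = [Chem.MolFromSmiles(s) for s in smis]",
    "out = [bool(m is not None and m.HasSubstructMatch(q)) for m in mols]",
    "json.dump(out, open(sys.argv[3], 'w'))"), pyFile)
  status <- system2("python", shQuote(c(pyFile, smiFile, pattern, outFile)))
  stopifnot(status == 0L)
  unlist(jsonlite::read_json(outFile))
}

## Set-operation binary morphology with the 4-connected cross element, the
## brute-force counterpart of the EBImage-based stages.
shift4 <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
  okR <- rs >= 1 & rs <= h; okC <- cs >= 1 & cs <= w
  out[rs[okR], cs[okC]] <- m[which(okR), which(okC)]
  out
}

erode4 <- function(m) {
  m & shift4(m, 1, 0) & shift4(m, -1, 0) & shift4(m, 0, 1) & shift4(m, 0, -1)
}

dilate4 <- function(m) {
  m | shift4(m, 1, 0) | shift4(m, -1, 0) | shift4(m, 0, 1) | shift4(m, 0, -1)
}

## Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Build an MCSPatternSet directly from SMILES fragments (for clustering
## tests where the patterns are planted rather than mined).
patternSetFromSmiles <- function(smiles) {
  graphs <- DimerScreen:::parseSmilesGraphs(smiles, quiet = TRUE)
  stopifnot(!any(vapply(graphs, is.null, logical(1))))
  new("MCSPatternSet",
      smarts = vapply(graphs, DimerScreen:::mgToSmarts, character(1)),
      nAtoms = vapply(graphs, DimerScreen:::mgNAtoms, integer(1)),
      nBonds = vapply(graphs, DimerScreen:::mgNBonds, integer(1)),
      supportPairs = rep(1L, length(graphs)),
      supportCompounds = rep(1L, length(graphs)),
      graphs = graphs)
}

## Match segmented cells to ground-truth cells by majority overlap with the
## truth label image; returns per-cell relative area errors (NA when a
## segmented cell overlaps no truth cell).
csaRelativeErrors <- function(result, truthLabels, truthTable) {
  cells <- csaTable(result)
  lab <- labelImage(result)
  vapply(seq_len(nrow(cells)), function(i) {
    tl <- truthLabels[lab == cells$label[i]]
    tl <- tl[tl > 0]
    if (!length(tl)) return(NA_real_)
    tmode <- as.integer(names(sort(table(tl), decreasing = TRUE))[1L])
    ta <- truthTable$area_pixels[truthTable$cell == tmode]
    abs(cells$csa_pixels[i] - ta) / ta
  }, numeric(1))
}
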