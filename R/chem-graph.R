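## Internal molecular-graph representation.
##
## A `molGraph` is a plain list:
##   element  - character vector of element symbols (heavy atoms only)
##   aromatic - logical vector, per atom
##   bonds    - data.frame(a1, a2, order, aromatic) with a1 < a2
##
## The representation is deliberately small: it is what the fragment
## grammar, the MCS miner and the circular fingerprints operate on.
## Parsing of external SMILES goes through ChemmineR/OpenBabel; aromaticity
## of kekulized input is re-perceived on alternating rings (6-rings and
## 5-rings of C/N/O/S).  Fused aromatic systems are outside the generator's
## grammar and may be perceived ring-by-ring.

.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3)

molGraph <- function(element, aromatic = logical(length(element)),
                     bonds = data.frame(a1 = integer(), a2 = integer(),
                                        order = integer(), aromatic = logical())) {
  stopifnot(length(element) == length(aromatic),
            all(element %in% names(.VALENCE)))
  if (nrow(bonds)) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    stopifnot(all(bonds$a1 >= 1L), all(bonds$a2 <= length(element)),
              all(bonds$a1 != bonds$a2))
  }
  structure(list(element = element, aromatic = aromatic, bonds = bonds),
            class = "molGraph")
}

mgNAtoms <- function(mg) length(mg$element)
mgNBonds <- function(mg) nrow(mg$bonds)

## adjacency: list, per atom, of matrix cols (neighbour, bond row index)
mgAdjacency <- function(mg) {
  n <- mgNAtoms(mg)
  adj <- rep(list(cbind(nbr = integer(), bond = integer())), n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- rbind(adj[[b$a1[k]]], c(b$a2[k], k))
    adj[[b$a2[k]]] <- rbind(adj[[b$a2[k]]], c(b$a1[k], k))
  }
  adj
}

## integer atom/bond colours used by the MCS miner and isomorphism tests
mgAtomColor <- function(mg) {
  match(mg$element, names(.VALENCE)) * 2L + as.integer(mg$aromatic)
}
mgBondColor <- function(mg) {
  ifelse(mg$bonds$aromatic, 9L, as.integer(mg$bonds$order))
}

## bond order sum seen by an atom, aromatic bonds counting 1.5
.mgBondOrderSum <- function(mg) {
  s <- numeric(mgNAtoms(mg))
  b <- mg$bonds
  ord <- ifelse(b$aromatic, 1.5, b$order)
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + ord[k]
    s[b$a2[k]] <- s[b$a2[k]] + ord[k]
  }
  s
}

## free valence per atom (how many more single bonds it can accept)
mgFreeValence <- function(mg) {
  pmax(0, .VALENCE[mg$element] - ceiling(.mgBondOrderSum(mg)))
}

## implicit hydrogen count (used as a fingerprint invariant)
mgImplicitH <- function(mg) {
  pmax(0L, as.integer(.VALENCE[mg$element] - ceiling(.mgBondOrderSum(mg))))
}

## disjoint union of two graphs plus one connecting bond
mgCombine <- function(a, b, atomA, atomB, order = 1L) {
  off <- mgNAtoms(a)
  bonds <- rbind(
    a$bonds,
    data.frame(a1 = b$bonds$a1 + off, a2 = b$bonds$a2 + off,
               order = b$bonds$order, aromatic = b$bonds$aromatic),
    data.frame(a1 = atomA, a2 = atomB + off, order = as.integer(order),
               aromatic = FALSE))
  molGraph(c(a$element, b$element), c(a$aromatic, b$aromatic), bonds)
}

## induced subgraph on a set of atoms (used for MCS fragments)
mgSubgraph <- function(mg, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- match(seq_len(mgNAtoms(mg)), atoms)
  keep <- mg$bonds$a1 %in% atoms & mg$bonds$a2 %in% atoms
  b <- mg$bonds[keep, , drop = FALSE]
  b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2]
  rownames(b) <- NULL
  molGraph(mg$element[atoms], mg$aromatic[atoms], b)
}

mgToIgraph <- function(mg) {
  g <- igraph::make_empty_graph(n = mgNAtoms(mg), directed = FALSE)
  if (mgNBonds(mg))
    g <- igraph::add_edges(g, rbind(mg$bonds$a1, mg$bonds$a2))
  g
}

## exact colored-isomorphism test (VF2) between two fragments
mgIsomorphic <- function(a, b) {
  if (mgNAtoms(a) != mgNAtoms(b) || mgNBonds(a) != mgNBonds(b)) return(FALSE)
  if (!identical(sort(mgAtomColor(a)), sort(mgAtomColor(b)))) return(FALSE)
  if (!identical(sort(mgBondColor(a)), sort(mgBondColor(b)))) return(FALSE)
  igraph::isomorphic(mgToIgraph(a), mgToIgraph(b), method = "vf2",
                     vertex.color1 = mgAtomColor(a),
                     vertex.color2 = mgAtomColor(b),
                     edge.color1 = mgBondColor(a),
                     edge.color2 = mgBondColor(b))
}

## cheap isomorphism-invariant hash for bucketing fragments before the VF2
## confirmation
mgInvariantHash <- function(mg) {
  ac <- mgAtomColor(mg)
  bc <- mgBondColor(mg)
  deg <- tabulate(c(mg$bonds$a1, mg$bonds$a2), nbins = mgNAtoms(mg))
  hashIntVector(c(sort(ac * 100L + deg), 0L, sort(bc)))
}

## ---- SMILES / SMARTS writing -------------------------------------------

.atomToken <- function(el, aromatic) {
  if (aromatic) tolower(el) else el
}

.bondToken <- function(order, aromatic, smarts) {
  if (aromatic) { if (smarts) ":" else "" }
  else if (order == 2L) "="
  else if (order == 3L) "#"
  else if (smarts) "-"
  else ""
}

## Depth-first SMILES/SMARTS writer with ring-closure digits.  For SMILES
## output an explicit "-" is written between two aromatic atoms joined by a
## non-aromatic single bond (e.g. biphenyl).
mgWriteSmiles <- function(mg, smarts = FALSE) {
  n <- mgNAtoms(mg)
  stopifnot(n >= 1L)
  adj <- mgAdjacency(mg)
  visited <- logical(n)
  bondUsed <- logical(mgNBonds(mg))
  closure <- vector("list", n)   # per atom: list of c(digit, bondIdx)
  nextDigit <- 0L

  ## first pass: classify tree/back edges, assign closure digits
  classify <- function(root) {
    stack <- list(c(root, NA_integer_))
    order <- integer(0)
    parentBond <- rep(NA_integer_, n)
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- top[1L]
      if (visited[a]) next
      visited[a] <<- TRUE
      parentBond[a] <- top[2L]
      if (!is.na(top[2L])) bondUsed[top[2L]] <<- TRUE
      nb <- adj[[a]]
      if (nrow(nb)) for (k in rev(seq_len(nrow(nb)))) {
        v <- nb[k, 1L]; bk <- nb[k, 2L]
        if (!visited[v]) {
          stack[[length(stack) + 1L]] <- c(v, bk)
        } else if (!bondUsed[bk]) {
          bondUsed[bk] <<- TRUE
          nextDigit <<- nextDigit + 1L
          if (nextDigit > 9L) stop("molecule too ring-dense for the writer")
          closure[[a]] <<- c(closure[[a]], list(c(nextDigit, bk)))
          closure[[v]] <<- c(closure[[v]], list(c(nextDigit, bk)))
        }
      }
    }
    parentBond
  }

  emit <- function(a, inBond, parentBond) {
    b <- mg$bonds
    tok <- if (is.na(inBond)) "" else {
      bt <- .bondToken(b$order[inBond], b$aromatic[inBond], smarts)
      if (!smarts && bt == "" && !b$aromatic[inBond] &&
          mg$aromatic[b$a1[inBond]] && mg$aromatic[b$a2[inBond]]) bt <- "-"
      bt
    }
    tok <- paste0(tok, .atomToken(mg$element[a], mg$aromatic[a]))
    for (cl in closure[[a]]) {
      bt <- .bondToken(b$order[cl[2L]], b$aromatic[cl[2L]], smarts = FALSE)
      tok <- paste0(tok, bt, cl[1L])
    }
    kids <- integer(0); kidBonds <- integer(0)
    nb <- adj[[a]]
    if (nrow(nb)) for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1L]; bk <- nb[k, 2L]
      if (!is.na(parentBond[v]) && parentBond[v] == bk) {
        kids <- c(kids, v); kidBonds <- c(kidBonds, bk)
      }
    }
    if (length(kids)) {
      for (k in seq_along(kids)) {
        sub <- emit(kids[k], kidBonds[k], parentBond)
        tok <- if (k < length(kids)) paste0(tok, "(", sub, ")")
               else paste0(tok, sub)
      }
    }
    tok
  }

  out <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    parentBond <- classify(root)
    out <- c(out, emit(root, NA_integer_, parentBond))
  }
  paste(out, collapse = ".")
}

mgToSmarts <- function(mg) mgWriteSmiles(mg, smarts = TRUE)

## ---- parsing (SDF via ChemmineR/OpenBabel) ------------------------------

## enumerate simple cycles of length <= maxLen (small molecules only)
.mgCycles <- function(mg, maxLen = 6L) {
  adj <- mgAdjacency(mg)
  cycles <- list()
  seen <- character(0)
  n <- mgNAtoms(mg)
  walk <- function(path) {
    a <- path[length(path)]
    nb <- adj[[a]]
    if (!nrow(nb)) return()
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1L]
      if (v == path[1L] && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!v %in% path && length(path) < maxLen && v > path[1L]) {
        walk(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  cycles
}

## mark alternating 5/6-rings of C/N/O/S as aromatic (kekulized input)
.mgPerceiveAromatic <- function(mg) {
  if (!mgNBonds(mg)) return(mg)
  bondAt <- matrix(NA_integer_, mgNAtoms(mg), mgNAtoms(mg))
  for (k in seq_len(mgNBonds(mg))) {
    bondAt[mg$bonds$a1[k], mg$bonds$a2[k]] <- k
    bondAt[mg$bonds$a2[k], mg$bonds$a1[k]] <- k
  }
  for (cyc in .mgCycles(mg, 6L)) {
    len <- length(cyc)
    if (len < 5L) next
    ringBonds <- vapply(seq_len(len), function(i)
      bondAt[cyc[i], cyc[i %% len + 1L]], integer(1))
    ord <- mg$bonds$order[ringBonds]
    if (any(!ord %in% c(1L, 2L)) && !any(mg$bonds$aromatic[ringBonds])) next
    isDouble <- ord == 2L
    nd <- sum(isDouble)
    adjacentDoubles <- any(isDouble & isDouble[c(2:len, 1L)])
    alternating <- nd == floor(len / 2) && !adjacentDoubles
    if (alternating || all(mg$bonds$order[ringBonds] == 4L)) {
      mg$aromatic[cyc] <- TRUE
      mg$bonds$aromatic[ringBonds] <- TRUE
      mg$bonds$order[ringBonds] <- 1L
    }
  }
  mg
}

## one ChemmineR SDF -> molGraph
mgFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  keep <- el %in% names(.VALENCE)   # drop explicit H and exotic atoms
  idx <- cumsum(keep)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                      aromatic = logical())
  if (!is.null(bb) && nrow(bb)) {
    a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L])
    ord <- as.integer(bb[, 3L])
    ok <- keep[a1] & keep[a2]
    bonds <- data.frame(a1 = idx[a1[ok]], a2 = idx[a2[ok]],
                        order = ord[ok], aromatic = ord[ok] == 4L)
  }
  mg <- molGraph(el[keep], aromatic = logical(sum(keep)), bonds = bonds)
  .mgPerceiveAromatic(mg)
}

#' Parse SMILES into the package's molecular-graph representation
#'
#' Uses ChemmineR/OpenBabel for the SMILES-to-connection-table conversion,
#' then re-perceives aromaticity on alternating 5/6-rings. Unparsable
#' entries yield \code{NULL} with a logged count.
#'
#' @param smiles character vector of SMILES.
#' @param quiet suppress the skipped-structure message.
#' @return list of internal graph objects (NULL where unparsable).
#' @keywords internal
parseSmilesGraphs <- function(smiles, quiet = FALSE) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    names(smiles) <- sprintf("m%06d", seq_len(n))
    sdfs <- suppressWarnings(tryCatch(
      ChemmineR::smiles2sdf(smiles[ok]), error = function(e) NULL))
    if (!is.null(sdfs)) {
      got <- ChemmineR::sdfid(sdfs)
      for (k in seq_along(sdfs)) {
        i <- match(got[k], names(smiles))
        g <- tryCatch(mgFromSDF(sdfs[[k]]), error = function(e) NULL)
        if (!is.na(i)) out[[i]] <- g
      }
    }
  }
  bad <- sum(vapply(out, is.null, logical(1)))
  if (!quiet && bad > 0L)
    message(bad, " structure(s) could not be parsed into graphs")
  out
}

## graphs of a CompoundLibrary, using the cached slot when present
libraryGraphs <- function(lib, quiet = TRUE) {
  if (length(lib@graphs)) lib@graphs else parseSmilesGraphs(lib@smiles, quiet)
}
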