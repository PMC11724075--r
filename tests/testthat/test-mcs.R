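mkLibrary <- function(smiles, ids = sprintf("H%03d", seq_along(smiles))) {
  new("CompoundLibrary", ids = ids, smiles = smiles,
      activity = rep(NA, length(smiles)), provenance = "hitlist",
      graphs = list())
}

test_that("the MCS of identical molecules is the whole molecule", {
  lib <- mkLibrary(c("c1ccccc1O", "c1ccccc1O"))
  ps <- pairwiseMCS(lib, minAtoms = 4L)
  expect_identical(length(ps), 1L)
  expect_identical(ps@nAtoms, 7L)
  expect_identical(ps@supportCompounds, 2L)
})

test_that("element matching forces the ethane/ethanol MCS to CC", {
  g <- DimerScreen:::parseSmilesGraphs(c("CC", "CCO"))
  res <- DimerScreen:::mcsPair(g[[1L]], g[[2L]])
  expect_identical(res$size, 2L)
  frag <- DimerScreen:::mgSubgraph(g[[1L]], res$atoms)
  expect_identical(frag$element, c("C", "C"))
})

test_that("a shared benzamide scaffold is mined with full pair support", {
  ## four molecules sharing the benzamide scaffold; all pairwise MCSs
  ## contain it, so the scaffold pattern must appear with support 6 pairs
  ## every pairwise MCS of these four molecules is exactly the 9-atom
  ## benzamide scaffold (checked by hand on the molecular graphs), so the
  ## unique set collapses to one pattern with support 6 pairs
  lib <- mkLibrary(c("c1ccccc1C(=O)N", "c1ccccc1C(=O)NC",
                     "c1ccc(O)cc1C(=O)N", "c1ccc(CC)cc1C(=O)N"))
  ps <- pairwiseMCS(lib, minAtoms = 4L)
  expect_identical(length(ps), 1L)
  expect_identical(ps@supportPairs, 6L)
  expect_identical(ps@nAtoms, 9L)
  expect_identical(ps@supportCompounds, 4L)
  ## and the emitted SMARTS matches all four via the independent oracle
  expect_true(all(rdkitMatches(smilesOf(lib), ps@smarts)))
})

test_that("MCS is symmetric under argument order", {
  smis <- c("c1ccccc1CCO", "c1ccncc1CC(=O)N", "C1CCCCC1OC")
  gs <- DimerScreen:::parseSmilesGraphs(smis)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- DimerScreen:::mcsPair(gs[[i]], gs[[j]])
    b <- DimerScreen:::mcsPair(gs[[j]], gs[[i]])
    expect_identical(a$size, b$size)
    fa <- DimerScreen:::mgSubgraph(gs[[i]], a$atoms)
    fb <- DimerScreen:::mgSubgraph(gs[[j]], b$atoms)
    expect_true(DimerScreen:::mgIsomorphic(fa, fb))
  }
})

test_that("k-means clustering of patterns is deterministic with valid medoids", {
  smis <- c("c1ccccc1C(=O)N", "c1ccccc1C(=O)NC", "c1ccc(C)cc1C(=O)N",
            "CCOCC", "CCOC", "CCCOC")
  ps <- patternSetFromSmiles(smis)
  cl1 <- clusterMCS(ps, k = 2L, seed = 4L)
  cl2 <- clusterMCS(ps, k = 2L, seed = 4L)
  expect_identical(cl1@assignments, cl2@assignments)
  expect_identical(cl1@medoids, cl2@medoids)
  for (k in seq_len(cl1@k))
    expect_true(cl1@medoids[k] %in% which(cl1@assignments == k))
  ## k = 1 puts everything together
  expect_true(all(clusterMCS(ps, k = 1L, seed = 1L)@assignments == 1L))
  ## k = number of distinct fingerprints isolates every pattern
  clN <- clusterMCS(ps, k = length(smis), seed = 1L)
  expect_identical(sort(unique(clN@assignments)), seq_len(length(smis)))
  expect_error(clusterMCS(ps, k = 0L), "positive")
  expect_error(clusterMCS(ps, k = 99L), "exceeds")
})

test_that("two planted pattern families are recovered exactly (ARI = 1)", {
  amides <- c("c1ccccc1C(=O)N", "c1ccccc1C(=O)NC", "c1ccc(C)cc1C(=O)N",
              "c1ccc(O)cc1C(=O)NC", "c1ccccc1C(=O)NCC")
  ethers <- c("CCOCC", "CCOC", "CCCOCC", "CC(C)OCC", "CCOCCC")
  ps <- patternSetFromSmiles(c(amides, ethers))
  labels <- rep(1:2, each = 5L)
  for (s in 1:10) {
    cl <- clusterMCS(ps, k = 2L, seed = s)
    expect_equal(ari(cl@assignments, labels), 1)
  }
})

test_that("enrichment folds follow the counting definition", {
  gen <- generateLibrary(librarySpec(nCompounds = 150L, activeFraction = 0.2,
                                     seed = 23L))
  ref <- gen$library
  hits <- ref[which(activityOf(ref))]
  hits@provenance <- "hitlist"
  ef <- enrichmentFold("c1ccccc1C(=O)N", hits, ref)
  expect_equal(ef$fold, (ef$h / ef$H) / (ef$r / ef$R))
  expect_identical(ef$h, ef$H)  # every hit carries the pharmacophore
  ## direct arithmetic example: h=2,H=4,r=10,R=1000 -> 50
  expect_equal((2 / 4) / (10 / 1000), 50)
  ## a pattern matching everything has fold exactly 1
  one <- enrichmentFold("C", ref, ref)
  expect_lte(abs(one$fold - 1), 1e-12)
})

test_that("zero reference support is flagged infinite or pseudocounted", {
  hits <- mkLibrary(c("c1ccccc1C(=O)N", "c1ccccc1C(=O)NC"))
  ref <- mkLibrary(c("CCO", "CCC", "CCN", "CCOC"), sprintf("R%02d", 1:4))
  ef <- enrichmentFold("c1ccccc1C(=O)N", hits, ref)
  expect_true(ef$zero_reference)
  expect_identical(ef$fold, Inf)
  efp <- enrichmentFold("c1ccccc1C(=O)N", hits, ref, pseudocount = TRUE)
  expect_equal(efp$fold, (2 / 2) / (0.5 / 4))
})

test_that("analogue selection returns exactly the planted carriers, id-ordered", {
  gen <- generateLibrary(librarySpec(nCompounds = 200L, activeFraction = 0.1,
                                     seed = 29L))
  sel <- selectAnalogues(gen$library, "c1ccccc1C(=O)N")
  planted <- sort(gen$truth$compound_id[gen$truth$carrier])
  expect_identical(compoundIds(sel), planted)
  none <- selectAnalogues(gen$library, "c1ccccc1C(=S)N")
  expect_identical(length(none), 0L)
})
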