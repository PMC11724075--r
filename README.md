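# DimerScreen

Small-molecule agonists of receptor dimerization — for instance compounds
that trigger ERBB4 homodimerization the way the natural ligand NRG1 does —
are found by a cascade that starts from a plate-based high-throughput
screen and ends in cell-image phenotyping. **DimerScreen** implements that
whole computational cascade as a tested, reusable R package:

1. **Plate statistics** — median-polish correction of row/column/edge
   artifacts, B-score normalization, top-N triage, and confirmation-screen
   hit calling at `mean(neg) + 3 * SD(neg)`.
2. **Pharmacophore mining** — pairwise maximum common substructure (MCS)
   analysis of the confirmed hits, k-means clustering of the unique
   patterns on circular fingerprints, and fold-enrichment of each pattern
   against a reference library: `fold = (h/H) / (r/R)`.
3. **Machine-learning hit expansion** — a random-forest activity
   classifier on folded circular (Morgan-style) fingerprints that ranks
   unscreened library compounds.
4. **Dose-response pharmacology** — normalization to the reference-ligand
   window and variable-slope four-parameter logistic fits,
   `y = bottom + (top - bottom) / (1 + 10^(hill (log10 EC50 - log10 x)))`,
   for EC50/Emax, descending IC50 curves, and potentiation of the
   reference ligand by a co-applied modulator
   (`100 * (top_mod - top_base) / top_base`).
5. **Cross-sectional-area (CSA) segmentation** — the automated
   cardiomyocyte hypertrophy readout: mode/SD thresholds on the nuclear
   and cell-body channels, a Scharr gradient image, seeded *compact
   watershed* (energy = gradient + 0.1 × squared seed distance), border
   removal, hole filling and a 3-erosion/3-dilation opening, reporting
   per-cell pixel areas.

A first-class **synthetic-data module** generates every input with exact
ground truth — plates with planted actives, SMILES libraries with a
grafted pharmacophore, dose-response tables, and two-channel 16-bit cell
images — so the full cascade is testable offline with no external data.

The audience is screening-informatics and chemical-biology groups who
want the numerical core of such a campaign (normalization, enrichment,
curve fitting, segmentation) reproducible and benchmarked against ground
truth, rather than buried in one-off scripts.

## Worked example

Simulate a 10-plate, 384-well screen with ±30% row/column gradients, 20%
edge depression, 10% well noise and 2% spiked actives at +8 robust units,
then normalize and triage:

```r
library(DimerScreen)

spec <- plateEffectSpec(grandMean = 1e6, rowGradient = 0.3,
                        colGradient = -0.3, edgeDepression = 0.2,
                        noiseCv = 0.1, spikeRate = 0.02, spikeEffect = 8,
                        seed = 1L)
screen <- simulateScreen(spec, nPlates = 10L)
screen$plates[[1]]
#> PlateGrid 'plate001': 16 x 24 wells (352 sample, 16 pos, 16 neg)

top <- selectTopHits(scoreScreen(screen$plates), n = 80L)
head(top, 3)
#>      compound_id plate_id row col  b_score
#> 754    CMP000754 plate003   1   4 11.61839
#> 3074   CMP003074 plate009   1  17 11.40689
#> 399    CMP000399 plate002  14   3 11.39801

spiked <- screen$truth$compound_id[screen$truth$active]
mean(spiked %in% top$compound_id)
#> [1] 0.9756098
```

The top B-scores are ~11: the spikes were planted at 8 robust units and
the polish concentrates them in the residuals. 97.6% of the planted
actives of this screen land in the top 80. The confirmation threshold is
the plain control rule:

```r
confirmationThreshold(c(90000, 110000, 95000, 105000))
#> [1] 127386.1
```

Fit a dose-response curve simulated from an EF-1-like agonist
(EC50 10.5 µM, Emax 27.9% of the reference ligand, 5% CV noise, n = 4)
over the 2-fold 0.0625–32 µM series:

```r
drc <- simulateDoseResponse(c(bottom = 0, top = 27.9, ec50 = 1.05e-5,
                              hill = 1), nReps = 4L, noiseCv = 0.05,
                            seed = 2L)
fit4PL(normalizeToReference(drc))
#> FourPLFit (agonist): bottom 0.261, top 24.9, EC50 8.34e-06 M,
#>   hill 1.07, converged = TRUE
```

The recovered EC50 (8.3 µM) sits within the sampling error of the true
10.5 µM at this noise level; the noise-free fit recovers all four
parameters to better than 1e-6 relative error.

Segment a synthetic two-channel image and report per-cell CSA:

```r
img <- renderCellImage(cellImageSpec(imageShape = c(512L, 512L),
                                     nCells = 8L,
                                     cellAreaRange = c(2000, 8000),
                                     seed = 5L))
res <- quantifyCSA(img$image)
res
#> SegmentationResult: 8 cells, CSA 2786-7784 px
#>   stages: initial=8, area_removed=0, overlap_removed=0, retained=8,
#>   watershed_labels=8, border_removed=0, eroded_away=0, reported=8
head(csaTable(res), 3)
#>   label csa_pixels seed_nucleus
#> 1     1       6357            1
#> 2     2       5403            2
#> 3     3       3383            3
```

All eight planted cells are recovered; against the rasterized ground
truth the median per-cell relative area error of this pipeline is ~3%.

## Package layout

- `R/` — S4 classes (`PlateGrid`, `MedianPolishDecomposition`,
  `BScorePlate`, `CompoundLibrary`, `MCSPatternSet`, `MCSClusterSet`,
  `FingerprintMatrix`, `ActivityModel`, `FourPLFit`,
  `SegmentationResult`, and the generator specs) plus the exported
  camelCase functions per stage.
- `src/` — the seeded compact-watershed flood (Rcpp).
- `vignettes/dimer-screen-cascade.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (RDKit via the preinstalled Python, hand-coded
  set-operation morphology, `stats::medpolish`).
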