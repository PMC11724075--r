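---
title: "The DimerScreen cascade: models, parameters and design decisions"
author: "DimerScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DimerScreen cascade: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DimerScreen)
```

DimerScreen reimplements the computational cascade behind a
dimerization-assay screening campaign for small-molecule receptor
agonists (the ERBB4/NRG1 assay class): plate normalization and hit
calling, substructure-based pharmacophore discovery and enrichment,
random-forest hit expansion, four-parameter logistic pharmacology, and an
automated cardiomyocyte cross-sectional-area (CSA) readout. This vignette
is the package's own account of the underlying models, the parameters
that matter, the numerical decisions taken where the procedure left
choices open, and what the synthetic benchmarks do and do not
demonstrate.

## 1. Plate statistics

**Model.** A screening plate is a rectangular grid of luminescence
signals contaminated by smooth spatial artifacts — row and column
gradients from dispensing and incubation, depressed outer wells from
evaporation. Median polish decomposes the plate additively,

$$y_{ij} = \mu + R_i + C_j + r_{ij},$$

by alternating row-then-column median sweeps. The B-score of a sample
well is its residual divided by the robust scale of the plate's sample
residuals, $1.4826 \cdot \mathrm{MAD}(r)$, which makes scores comparable
across plates regardless of per-plate signal level (the inter-plate
normalization step).

**Parameters.**

* `maxSweeps = 10`, `tol = 1e-6 ×` the absolute plate median. Median
  polish on real plates converges geometrically; ten sweeps are ample for
  16 × 24 grids, and the tolerance is scale-free. The decomposition
  identity `values = overall + row + col + residuals` holds *exactly* at
  any iteration count, so an unconverged polish is still a valid
  decomposition (flagged via `converged`).
* Controls are masked to `NA` before polishing and never receive scores:
  control columns would otherwise drag the column medians.
* MAD scaling 1.4826 makes the robust scale consistent for Gaussian
  noise, the standard B-score convention.
* The confirmation threshold is `mean(neg) + 3 × sd(neg)` with the
  sample (n−1) SD — the denominator is a declared choice, as is the
  *strict* `>` reading of "above threshold".
* Triage ties are broken by compound id ascending so the top-N set is
  reproducible byte for byte.

**Degenerate inputs.** A plate whose sample residuals are identical has
robust scale zero and raises a degenerate-plate error rather than
emitting infinite scores; matrices smaller than 2 × 2 or containing
non-finite values are rejected.

## 2. Synthetic screens

`simulateScreen()` draws sample wells as

$$y_{ij} = \bar\mu\,(1 + \rho_i)(1 + \gamma_j)(1 - e_{ij})\,\varepsilon_{ij},$$

with centred linear row/column gradients (total span `rowGradient`,
`colGradient`), a fractional `edgeDepression` on outermost wells,
and unit-mean log-normal noise of CV `noiseCv`. A Bernoulli fraction
`spikeRate` of sample wells are true actives, raised **additively** by
`spikeEffect` robust residual scales computed per plate before spiking —
sizing the effect in robust-scale units makes B-score recovery targets
scale-free. Controls occupy two dedicated edge-adjacent columns (columns
2 and 23 of a 384-well plate by default; the layout is configurable
because real campaigns differ and the underlying study does not state
its layout) and are subject to the same artifacts.

Defaults (`grandMean = 1e6` counts, gradients ±0.3 span, 20% edge loss,
10% CV, 2% actives at +8 robust units) are the artifact magnitudes a
screening facility would call a bad-but-usable plate set, and they are
exactly the conditions of the spike-recovery benchmark. Note that the
generator is multiplicative while the polish is additive: the residual
row × column interaction (up to ~2% of the signal at ±15% half-span
gradients) is deliberately left for the polish to cope with, emulating
the model mismatch present in real data.

## 3. Compound libraries and the pharmacophore

`generateLibrary()` assembles molecules from a fixed fragment grammar —
benzene, pyridine, cyclopentane/cyclohexane, short alkyl chains, and
polar decorations (hydroxyl, amine, thioether, ether, acetyl, aliphatic
amide) joined at free valences — so every emitted SMILES is valid by
construction. A fraction `activeFraction` of compounds *carry* the
pharmacophore (default `c1ccccc1C(=O)N`, an aryl amide) grafted as a
fragment. Carrier status is then **verified by an actual substructure
match** (OpenBabel), and non-carrier draws that accidentally contain the
pattern are resampled; the ground truth is therefore exact by
definition, not by intent. Observed activity labels are the carrier
flags with `labelNoise` random flips.

Aromaticity is handled explicitly: the internal molecular graph marks
alternating 5/6-rings of C/N/O/S as aromatic after parsing kekulized
connection tables, and the SMILES/SMARTS writer emits lowercase aromatic
atoms, so OpenBabel and RDKit agree exactly on every pattern the grammar
can produce. Fused aromatic systems are outside the grammar and may be
perceived ring-by-ring — a documented limitation for exotic user input,
not for anything the package generates.

What the generator does *not* emulate: stereochemistry, charges,
tautomers, molecular-weight/logP distributions of vendor libraries, and
the structural redundancy of combinatorial series. Passing benchmarks on
this grammar therefore demonstrates correctness of the counting,
matching and learning machinery — not virtual-screening performance on
real chemistry.

## 4. MCS mining, clustering and enrichment

**MCS definition.** For each unordered pair of hits the package finds
the maximum common *connected induced* substructure under exact atom
(element + aromaticity) and bond (order, aromatic) matching, via a
branch-and-bound search: the lowest-indexed frontier atom of the first
molecule is either mapped to each compatible atom of the second or
permanently excluded, with an optimistic size bound for pruning.
Induced matching plus ring-aware labels is the package's reading of
"MCS with ring-bond matching on"; a per-pair deadline (2 s) skips
pathological pairs with a logged count, since a missing pair only costs
support. Fragments below 4 heavy atoms are discarded — trivial fragments
would otherwise dominate the unique-pattern count.

**Uniqueness.** Patterns are deduplicated by exact colored-graph
isomorphism (VF2 via igraph) behind a cheap invariant hash; the first
representative's SMARTS is kept, which makes the pattern set
deterministic given input order.

**Clustering.** Each fragment is embedded as a 1024-bit, radius-2
circular fingerprint and clustered by k-means (Euclidean on 0/1 vectors,
10 restarts under a fixed seed); the default `k = 10` follows the
campaign this emulates, and the medoid of a cluster is the member
nearest its centroid (ties to the lowest index). Duplicate fingerprints
are collapsed before k-means; `k` equal to the number of *distinct*
fingerprints degenerates to one cluster per fingerprint (base R's
`kmeans` refuses `k = n`, so that case is assigned directly). Cluster
results are reported both as the medoid's enrichment and as per-member
enrichments, since "the cluster's enrichment" is ambiguous in the
source procedure.

**Enrichment.** For a pattern, `fold = (h/H)/(r/R)` where `h`/`r` count
*compounds* containing the pattern (not embeddings) in the hit list and
reference library. A zero reference count yields a flagged infinity by
default; a 0.5 pseudocount on `r` is available behind a flag.
Unparsable structures are excluded from the denominators with a logged
count, never silently dropped.

## 5. Fingerprints and the random forest

No installed R package provides Morgan/ECFP fingerprints, so the package
implements folded circular fingerprints on its own molecular graph: the
initial atom invariant is (element, heavy degree, implicit-H count,
aromaticity); each radius hashes the previous invariant with the sorted
(bond type, neighbour hash) list; all radii 0–2 fold into 2048 bits.
Atom numbering cannot affect the result, so different writings of one
structure map to identical rows.

The classifier is a `ranger` probability forest: 500 trees, class
weights inverse to class frequency, single-threaded with a fixed seed so
training and prediction are exactly reproducible. Stratified k-fold
cross-validation (default 5) reports AUROC/precision/recall against the
*observed* (possibly noisy) labels; the benchmarks additionally score
predictions against the planted ground truth. Predictions exclude
training compounds, are sorted by probability with id tie-breaks, and
use a 0.5 default threshold — the underlying campaign's decision rule is
unstated, so the threshold is exposed.

## 6. Dose-response pharmacology

Responses are normalized to the reference-ligand window:
`100 × (x − mean(neg)) / (mean(pos) − mean(neg))`, anchoring vehicle at
0% and the reference ligand (e.g. 0.1 µM NRG1) at 100%. "Relative to
the reference signal" could also mean a plain ratio; both are
implemented (`method = "ratio"`), subtractive is the default because it
makes bottom ≈ 0 meaningful. Equal control means raise a
degenerate-controls error.

The model is the variable-slope 4PL on log10 concentration, fitted by
Levenberg–Marquardt (`minpack.lm::nlsLM`, up to 200 iterations, default
tolerances — on noise-free data these already recover parameters to
better than 1e-6 relative). Initialization is from data quantiles
(bottom/top from the 5%/95% response quantiles, the midpoint from the
concentration whose mean response is nearest half-range, hill ±1); the
hill slope is constrained positive for agonist fits and negative for
inhibition fits, and the midpoint is fitted on the log scale with a ±4
decade box around the tested range. The convergence flag is honest:
optimizer failure, a fitted span smaller than twice the residual scale
(a flat curve), or a midpoint more than three decades outside the tested
range all clear it. EC50 standard errors are delta-method transforms of
the log-scale SE.

Potentiation is defined on **fitted tops**:
`100 × (top_mod − top_base)/top_base` per modulator concentration. The
source description ("potentiated … by 299.5%") does not say whether it
means the fitted maximum, the response at one ligand concentration, or
an AUC change; fitted tops are the implemented reading, and the
alternatives would be one-line variants on the returned fits. The
potentiation benchmark simulates modulated *reference-ligand* curves
with a 1 µM midpoint so the tested 0.0625–32 µM series saturates — as
the emulated assay does. With a 10 µM midpoint the top of this series is
an extrapolation and no faithful fitter can pin a 4× top change to
±50%; that regime is deliberately not what the benchmark measures.

Replicates enter as individual points (no weighting); the simulated
noise is multiplicative Gaussian, `4PL(conc) × (1 + N(0, cv))`, with
noisy controls included so normalization is exercised.

## 7. CSA segmentation

The pipeline follows the published automated algorithm with all printed
constants as defaults (`segmentationParams()`):

1. **Nuclei**: binary threshold at `mode + SD` of the nuclear channel
   (the mode over the integer histogram of nonzero values, ties to the
   lowest value; SD over all pixels — only the mode excludes zeros,
   mirroring the algorithm's explicit scoping); 4-connected components;
   drop components `< 500 px`; drop nuclei whose mean cell-channel
   intensity is below `median_A + 0.5 SD_A` (nuclei not on a cell).
2. **Cell mask**: threshold at `mode_A + 0.5 SD_A`, one binary erosion
   and two dilations with the 4-connected cross element, then removal of
   all pixels below `mode_A − 0.5 SD_A` (the sign is read as minus; a
   plus would duplicate the threshold already applied).
3. **Gradient**: 3 × 3 gray erosion, Gaussian blur σ = 3 px, Scharr
   gradient magnitude, linear min–max rescale to 8-bit (a constant image
   maps to zeros; a `1e-6` range guard also absorbs FFT round-off from
   the convolution), 5 × 5 gray dilation.
4. **Compact watershed**: priority flood of the gradient from the
   nucleus seeds, confined to the mask, with energy
   `gradient + 0.1 × squared distance to the seed centroid`; FIFO tie
   breaks make the labeling deterministic. Seeds outside the mask are
   clipped and logged; zero seeds yield a valid empty labeling.
5. **Post-processing**: per label — remove it if any pixel touches the
   image border; fill internal holes; 3 erosions then 3 dilations to
   remove protrusions; report the remaining pixel count as the CSA.
   Labels emptied by the erosions are dropped and counted. Stage
   removal counts are additive: initial nuclei minus all removals equals
   reported cells.

"1-connected neighbourhood" is read as 4-connectivity throughout,
including component labeling. Binary morphology treats outside-of-image
as background and gray morphology replicates edges — the conventions of
the ndimage-style tools this algorithm class is built on (EBImage's
built-in erosion ignores out-of-image kernel pixels instead, so the
binary and gray passes are implemented in-package by shifted set
operations and verified against brute-force windowed oracles). Multiple
nuclei inside one true cell produce multiple labels; the algorithm does
not merge them. No micron calibration is attempted: CSA is reported in
pixels, as the readout is relative across treatment groups.

**Synthetic images.** `renderCellImage()` packs near-disk star-convex
cells (two random radial harmonics, amplitude ≤ 0.1, radius corrected
for the harmonic area factor so the rasterized area matches the target)
with one nuclear disk each into a 16-bit two-channel canvas, largest
first, with additive Gaussian noise clipped to the bit depth. The truth
table records each cell's exact rasterized pixel count. Border-crossing
cells can be requested (`allowBorder`) to exercise border removal; their
centres are placed just inside the edge so the body crosses but the
nucleus survives the 500-px filter. The images emulate well-separated,
roughly convex cultured cardiomyocytes with uniform staining; they do
not emulate touching cells, intensity gradients within cells,
out-of-focus light, or multinucleation, so the area benchmark validates
the geometric pipeline, not performance on confluent cultures.

## 8. Benchmark sizes and determinism

The acceptance suite (`tests/testthat/test-acceptance.R`) runs the
stage-level benchmarks at their full sizes: 100 exactly-additive plates;
20 screens of 10 × 384 wells with 2% spikes; 1,000 random confirmation
screens against the brute-force threshold oracle; a 2,000-compound
reference with 20 planted patterns checked pattern-by-pattern against an
independent RDKit count; a 5,000-compound learning benchmark (10%
carriers, 10% label noise) with a permuted-label null; 100 noisy EC50
recoveries and 200 potentiation simulations; and 30 segmentation images
(10–40 cells each, areas 2,000–20,000 px, 1536 × 1536 canvas — chosen so
that 40 non-overlapping cells occupy about a quarter of the frame).
`scripts/acceptance.R` reruns the cascade at reduced sizes (10 screens,
a 2,000-compound learning library, 6 images) and writes its quantities
as JSON; every random draw in the package flows through a seed argument
and a restore-on-exit RNG guard, and the fixture writer's checksum
manifest makes end-to-end byte determinism a one-line check.

## 9. Known limitations

* Substructure matching shells out to `obabel`; compound ids must be
  whitespace-free and throughput is per-pattern process calls —
  appropriate for thousands, not millions, of compounds.
* The MCS search is exact but exponential in the worst case; the
  deadline-and-skip policy trades completeness of *pair support* for
  bounded runtime on adversarial inputs.
* The molecular graph covers C/N/O/S/P heavy atoms without charges,
  stereochemistry or explicit hydrogens; exotic atoms in user input are
  dropped from the graph (matching still sees them through OpenBabel).
* Median polish is not unique on non-additive data; B-scores are exactly
  location-invariant but only asymptotically equivariant to row/column
  offsets at a finite sweep tolerance.
* The 4PL fitter reports, not repairs, ill-posed curves (flat responses,
  out-of-range midpoints); downstream code must respect `converged`.
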