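## One-call emission of every synthetic input kind with a checksum
## manifest, for pipeline demos and byte-identity (determinism) checks.

#' Write a complete set of synthetic fixtures
#'
#' Generates plates, a compound library, a dose-response table and
#' two-channel cell images from the given specs and writes them under
#' \code{outdir} together with a JSON ground-truth manifest listing every
#' file with its MD5 checksum. Rerunning with the same seeds reproduces
#' identical checksums.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; the per-generator seeds derive from it.
#' @param plateSpec,libSpec,imageSpec optional spec objects overriding the
#'   defaults.
#' @param nPlates,nImages counts of plates / images to emit.
#' @return invisibly, the manifest data.frame (\code{file}, \code{kind},
#'   \code{md5}).
#' @export
writeFixtures <- function(outdir, seed = 1L, plateSpec = NULL, libSpec = NULL,
                          imageSpec = NULL, nPlates = 2L, nImages = 2L) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    stop("cannot create output directory ", outdir, call. = FALSE)
  probe <- file.path(outdir, ".write_probe")
  if (inherits(try(writeLines("x", probe), silent = TRUE), "try-error"))
    stop("output directory is not writable: ", outdir, call. = FALSE)
  unlink(probe)
  seed <- as.integer(seed)
  if (is.null(plateSpec)) plateSpec <- plateEffectSpec(seed = seed)
  if (is.null(libSpec))
    libSpec <- librarySpec(nCompounds = 200L, seed = seed + 1L)
  if (is.null(imageSpec))
    imageSpec <- cellImageSpec(imageShape = c(512L, 512L), nCells = 8L,
                               cellAreaRange = c(2000, 8000),
                               seed = seed + 2L)

  files <- character(0); kinds <- character(0)
  addFile <- function(f, kind) {
    files <<- c(files, f); kinds <<- c(kinds, kind)
  }

  scr <- simulateScreen(plateSpec, nPlates = nPlates)
  plateFile <- file.path(outdir, "plates.csv")
  writePlateCsv(scr$plates, plateFile)
  addFile(plateFile, "plates")

  lib <- generateLibrary(libSpec)
  smiFile <- file.path(outdir, "library.smi")
  writeSmi(lib$library, smiFile)
  addFile(smiFile, "library")

  drc <- simulateDoseResponse(c(bottom = 0, top = 30, ec50 = 1e-5, hill = 1),
                              seed = seed + 3L)
  drcFile <- file.path(outdir, "drc.csv")
  write.csv(drc, drcFile, row.names = FALSE, quote = FALSE)
  addFile(drcFile, "drc")

  imgTruth <- list()
  for (i in seq_len(nImages)) {
    sp <- imageSpec
    sp@seed <- imageSpec@seed + i - 1L
    img <- renderCellImage(sp)
    f <- file.path(outdir, sprintf("cells%02d.tif", i))
    writeCellTiff(img$image, f)
    addFile(f, "image")
    fl <- file.path(outdir, sprintf("cells%02d_labels.tif", i))
    writeCellTiff(array(img$truthLabels, c(1L, dim(img$truthLabels))), fl)
    addFile(fl, "image_truth")
    imgTruth[[i]] <- img$truth
  }

  manifest <- list(
    seed = seed,
    truth = list(
      plate_wells = scr$truth,
      library = lib$truth,
      images = imgTruth),
    files = data.frame(file = basename(files), kind = kinds,
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest$files)
}
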