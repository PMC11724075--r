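## Bridge to the OpenBabel command line (`obabel`) for the two standard
## cheminformatics primitives the package does not author itself: SMARTS
## substructure matching and SMILES canonicalization.

.obabelPath <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      p <- Sys.which("obabel")
      if (!nzchar(p))
        stop("OpenBabel ('obabel') is required on the PATH for substructure ",
             "matching", call. = FALSE)
      cached <<- unname(p)
    }
    cached
  }
})

## Run obabel over a set of SMILES, returning the ids that survive the given
## extra arguments (e.g. a -s SMARTS filter).  Ids must be whitespace-free.
.obabelSelect <- function(smiles, ids, extraArgs = character()) {
  stopifnot(length(smiles) == length(ids), !anyNA(ids))
  if (any(grepl("[[:space:]]", ids)))
    stop("compound ids must not contain whitespace", call. = FALSE)
  inFile <- tempfile(fileext = ".smi")
  outFile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(inFile, outFile)), add = TRUE)
  writeLines(paste(smiles, ids, sep = "\t"), inFile)
  args <- c(shQuote(inFile), "-osmi", "-O", shQuote(outFile), extraArgs)
  status <- suppressWarnings(
    system2(.obabelPath(), args, stdout = FALSE, stderr = FALSE))
  if (status != 0L)
    stop("obabel failed (exit status ", status, ")", call. = FALSE)
  if (!file.exists(outFile)) return(character())
  out <- readLines(outFile, warn = FALSE)
  out <- out[nzchar(out)]
  vapply(strsplit(out, "[\t ]+"), function(f) f[length(f)], character(1))
}

#' Substructure matching via SMARTS
#'
#' Tests every compound for containment of a SMARTS pattern using OpenBabel.
#' Structures that OpenBabel cannot parse are reported as \code{NA} and
#' counted in a message (skip-and-log policy).
#'
#' @param x a \linkS4class{CompoundLibrary} or a character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @param quiet suppress the skipped-structure message.
#' @return logical vector, one element per compound (\code{NA} = unparsable).
#' @export
matchesSubstructure <- function(x, smarts, quiet = FALSE) {
  smiles <- if (is(x, "CompoundLibrary")) x@smiles else as.character(x)
  stopifnot(is.character(smarts), length(smarts) == 1L)
  if (!isValidSmarts(smarts)) stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
  ids <- sprintf("m%06d", seq_along(smiles))
  parseable <- ids %in% .obabelSelect(smiles, ids)
  hit <- ids %in% .obabelSelect(smiles, ids, c("-s", shQuote(smarts)))
  res <- hit
  res[!parseable] <- NA
  if (!quiet && any(!parseable))
    message(sum(!parseable), " structure(s) could not be parsed and were skipped")
  res
}

#' Canonical SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @return canonical SMILES (\code{NA} where unparsable).
#' @export
canonicalSmiles <- function(smiles) {
  ids <- sprintf("m%06d", seq_along(smiles))
  inFile <- tempfile(fileext = ".smi")
  outFile <- tempfile(fileext = ".can")
  on.exit(unlink(c(inFile, outFile)), add = TRUE)
  writeLines(paste(smiles, ids, sep = "\t"), inFile)
  status <- suppressWarnings(system2(.obabelPath(),
    c(shQuote(inFile), "-ocan", "-O", shQuote(outFile)),
    stdout = FALSE, stderr = FALSE))
  if (status != 0L) stop("obabel failed", call. = FALSE)
  out <- readLines(outFile, warn = FALSE)
  out <- out[nzchar(out)]
  parts <- strsplit(out, "[\t ]+")
  got <- vapply(parts, function(f) f[length(f)], character(1))
  can <- vapply(parts, function(f) f[1L], character(1))
  can[match(ids, got)]
}

#' Validate a SMARTS pattern
#'
#' A pattern is considered valid when OpenBabel accepts it as a filter.
#'
#' @param smarts single pattern string.
#' @return TRUE/FALSE.
#' @export
isValidSmarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || !nzchar(smarts))
    return(FALSE)
  inFile <- tempfile(fileext = ".smi")
  on.exit(unlink(inFile), add = TRUE)
  writeLines("C\tprobe", inFile)
  ## obabel exits 0 even for malformed patterns; detect via its stderr
  err <- suppressWarnings(system2(.obabelPath(),
    c(shQuote(inFile), "-osmi", "-s", shQuote(smarts)),
    stdout = FALSE, stderr = TRUE))
  !any(grepl("SMARTS Error", err, fixed = TRUE))
}
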