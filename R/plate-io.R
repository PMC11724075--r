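## Long-format plate CSV input/output.
## Schema: plate_id,row,col,role,value with 0-based row/col indices and
## role in {sample,pos,neg,empty}.  Compound identifiers are not part of
## the schema; on reading they are synthesized deterministically from the
## plate coordinates.

#' Write plates to a long-format CSV
#'
#' @param plates list of \linkS4class{PlateGrid} (or a single one).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePlateCsv <- function(plates, path) {
  if (is(plates, "PlateGrid")) plates <- list(plates)
  rows <- lapply(plates, function(pl) {
    d <- dim(pl@values)
    idx <- arrayInd(seq_along(pl@values), d)
    data.frame(plate_id = pl@plateId, row = idx[, 1L] - 1L,
               col = idx[, 2L] - 1L, role = as.vector(pl@roles),
               value = as.vector(pl@values))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$plate_id, df$row, df$col), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plates from a long-format CSV
#'
#' @param path CSV path with columns \code{plate_id,row,col,role,value}.
#' @return list of \linkS4class{PlateGrid}; sample-well compound ids are
#'   synthesized as \code{<plate>_r<row>c<col>}.
#' @export
readPlateCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "role", "value")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(split(df, df$plate_id), function(d) {
    nr <- max(d$row) + 1L; nc <- max(d$col) + 1L
    if (nrow(d) != nr * nc)
      stop("plate ", d$plate_id[1L], " is not a full rectangular layout",
           call. = FALSE)
    values <- matrix(NA_real_, nr, nc)
    roles <- matrix("empty", nr, nc)
    values[cbind(d$row + 1L, d$col + 1L)] <- d$value
    roles[cbind(d$row + 1L, d$col + 1L)] <- d$role
    cids <- matrix("", nr, nc)
    s <- which(roles == "sample")
    rc <- arrayInd(s, c(nr, nc))
    cids[s] <- sprintf("%s_r%02dc%02d", d$plate_id[1L], rc[, 1L] - 1L,
                       rc[, 2L] - 1L)
    new("PlateGrid", plateId = as.character(d$plate_id[1L]), values = values,
        roles = roles, compoundIds = cids)
  })
}

#' Write B-scores / hit calls as CSV
#'
#' \code{writeScoreCsv} writes the \code{\link{scoreScreen}} table;
#' \code{writeHitCsv} writes hit calls with the threshold recorded in a
#' \code{#}-prefixed header comment line.
#'
#' @param scores,hits the corresponding tables.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScoreCsv <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScoreCsv
#' @export
writeHitCsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%.10g", hits$threshold[1L]), con)
  write.csv(hits, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
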