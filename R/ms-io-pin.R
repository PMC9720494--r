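## Percolator pin export (and re-import for round-trip checks and for
## accepting scores computed by an external rescoring engine).

#' Write a FeatureTable as a Percolator pin file
#'
#' Tab-separated with columns SpecId, Label (1/-1), ScanNr, the feature
#' columns, Peptide (flanked \code{-.SEQ.-}) and Proteins. Values are printed
#' with enough precision that re-reading reproduces the feature matrix.
#'
#' @param table A [FeatureTable-class] with at least one row.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePin <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  meta <- psmMeta(table)
  feats <- featureMatrix(table)
  if (nrow(meta) < 1L) {
    stop("cannot write an empty pin file")
  }
  bad <- which(!is.finite(feats), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite feature value for PSM '", meta$specId[bad[1, 1]],
         "', feature '", colnames(feats)[bad[1, 2]], "'")
  }
  header <- c("SpecId", "Label", "ScanNr", colnames(feats), "Peptide",
              "Proteins")
  body <- cbind(
    meta$specId,
    as.character(meta$label),
    as.character(meta$scanNumber),
    matrix(sprintf("%.10g", feats), nrow = nrow(feats)),
    paste0("-.", meta$peptide, ".-"),
    meta$proteins
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a Percolator pin file back into a FeatureTable
#'
#' @param path Path to a pin file written by [writePin()].
#' @return A [FeatureTable-class].
#' @export
readPin <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  featCols <- setdiff(names(tab),
                      c("SpecId", "Label", "ScanNr", "Peptide", "Proteins"))
  meta <- data.frame(
    specId = as.character(tab$SpecId),
    label = as.integer(tab$Label),
    scanNumber = as.integer(tab$ScanNr),
    sourceFile = NA_character_,
    peptide = sub("^-\\.", "", sub("\\.-$", "", tab$Peptide)),
    proteins = as.character(tab$Proteins),
    stringsAsFactors = FALSE
  )
  FeatureTable(meta, as.matrix(tab[, featCols, drop = FALSE]))
}
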