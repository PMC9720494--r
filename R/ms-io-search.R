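## Search-engine result readers.
##
## Three tabular dialects are supported:
##  * maxquant: msms.txt-like TSV with columns Raw file, Scan number,
##    Sequence, Modified sequence, Charge, Retention time, Score, Proteins,
##    Reverse ("+" flags a decoy).
##  * peaks: simplified TSV with columns Source File, Scan, Peptide, z,
##    -10lgP, RT, Accession; decoys carry a configurable protein-accession
##    prefix (default "DECOY_").
##  * mascot: flattened CSV export with columns Source File, Scan, Sequence,
##    Charge, Score, Proteins, Decoy (TRUE/FALSE decoy-database flag).
##
## The delimiter is sniffed from the header line; a header containing both
## tabs and the other dialect's delimiter pattern is rejected rather than
## guessed. Rows are never silently dropped: the number of input rows always
## equals the number of returned PSMs plus the number of rejected rows
## reported in the "rejected" attribute.

.ENGINE_COLUMNS <- list(
  maxquant = c("Raw file", "Scan number", "Sequence", "Modified sequence",
               "Charge", "Retention time", "Score", "Proteins", "Reverse"),
  peaks = c("Source File", "Scan", "Peptide", "z", "-10lgP", "RT",
            "Accession"),
  mascot = c("Source File", "Scan", "Sequence", "Charge", "Score",
             "Proteins", "RT", "Decoy")
)

#' @noRd
.sniffDelimiter <- function(path) {
  header <- readLines(path, n = 1L)
  hasTab <- grepl("\t", header, fixed = TRUE)
  hasComma <- grepl(",", header, fixed = TRUE)
  if (hasTab && hasComma) {
    stop("ambiguous delimiter in ", path,
         ": header contains both tabs and commas; refusing to guess")
  }
  if (hasTab) "\t" else if (hasComma) "," else
    stop("cannot determine delimiter of ", path)
}

#' Read search-engine results into a PSM table
#'
#' @param path Path to a tab- or comma-separated search-result table.
#' @param engine One of \code{"maxquant"}, \code{"peaks"}, \code{"mascot"}.
#' @param decoyPrefix Protein-accession prefix flagging decoys in the PEAKS
#'   dialect (ignored for the other engines).
#' @return A data.frame of PSMs with columns \code{sourceFile},
#'   \code{scanNumber}, \code{peptide} (bracketed modification notation),
#'   \code{charge}, \code{engineScore}, \code{label} (+1 target, -1 decoy),
#'   \code{proteins}, \code{retentionTime}. Multiple rows may share one scan
#'   (chimeric spectra are retained). The attribute \code{"rejected"} holds a
#'   data.frame of rejected rows with reasons (empty unless rows were
#'   unparseable).
#' @export
readSearchResults <- function(path, engine = c("maxquant", "peaks", "mascot"),
                              decoyPrefix = "DECOY_") {
  engine <- match.arg(engine)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  sep <- .sniffDelimiter(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  need <- .ENGINE_COLUMNS[[engine]]
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing required ", engine, " columns: ",
         paste(missing, collapse = ", "))
  }
  rejected <- data.frame(row = integer(0), reason = character(0))
  if (nrow(tab) == 0L) {
    out <- data.frame(sourceFile = character(0), scanNumber = integer(0),
                      peptide = character(0), charge = integer(0),
                      engineScore = numeric(0), label = integer(0),
                      proteins = character(0), retentionTime = numeric(0))
    attr(out, "rejected") <- rejected
    return(out)
  }
  if (engine == "maxquant") {
    peptide <- tab[["Modified sequence"]]
    peptide[!nzchar(peptide)] <- tab[["Sequence"]][!nzchar(peptide)]
    out <- data.frame(
      sourceFile = as.character(tab[["Raw file"]]),
      scanNumber = as.integer(tab[["Scan number"]]),
      peptide = peptide,
      charge = as.integer(tab[["Charge"]]),
      engineScore = as.numeric(tab[["Score"]]),
      label = ifelse(trimws(as.character(tab[["Reverse"]])) == "+", -1L, 1L),
      proteins = as.character(tab[["Proteins"]]),
      retentionTime = as.numeric(tab[["Retention time"]]),
      stringsAsFactors = FALSE
    )
  } else if (engine == "peaks") {
    out <- data.frame(
      sourceFile = as.character(tab[["Source File"]]),
      scanNumber = as.integer(tab[["Scan"]]),
      peptide = as.character(tab[["Peptide"]]),
      charge = as.integer(tab[["z"]]),
      engineScore = as.numeric(tab[["-10lgP"]]),
      label = ifelse(startsWith(as.character(tab[["Accession"]]),
                                decoyPrefix), -1L, 1L),
      proteins = as.character(tab[["Accession"]]),
      retentionTime = as.numeric(tab[["RT"]]),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      sourceFile = as.character(tab[["Source File"]]),
      scanNumber = as.integer(tab[["Scan"]]),
      peptide = as.character(tab[["Sequence"]]),
      charge = as.integer(tab[["Charge"]]),
      engineScore = as.numeric(tab[["Score"]]),
      label = ifelse(as.logical(tab[["Decoy"]]), -1L, 1L),
      proteins = as.character(tab[["Proteins"]]),
      retentionTime = as.numeric(tab[["RT"]]),
      stringsAsFactors = FALSE
    )
  }
  ## validate peptides row by row; unparseable modification tokens are an
  ## error naming the row, per the dialect contract
  for (i in seq_len(nrow(out))) {
    ok <- tryCatch({ parsePeptide(out$peptide[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop("row ", i, " of ", path, ": ", ok)
    }
  }
  if (any(!nzchar(out$peptide))) {
    stop("empty peptide in ", path)
  }
  attr(out, "rejected") <- rejected
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
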