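## MHC binding %Rank tables (as produced by affinity predictors, flattened
## to TSV with columns peptide, allele, percent_rank).

#' Read a %Rank table
#'
#' @param path Tab-separated file with columns \code{peptide}, \code{allele},
#'   \code{percent_rank}.
#' @return A data.frame of class \code{"rankTable"} with those columns.
#'   Any \code{percent_rank} outside [0, 100] is an error. Peptides absent
#'   from the table are reported as explicitly missing (NA) by
#'   [queryPercentRank()], never as zero.
#' @export
readRankTable <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "percent_rank")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing rank-table columns: ", paste(missing, collapse = ", "))
  }
  tab$percent_rank <- as.numeric(tab$percent_rank)
  if (any(tab$percent_rank < 0 | tab$percent_rank > 100)) {
    stop("percent_rank outside [0, 100] in ", path)
  }
  class(tab) <- c("rankTable", "data.frame")
  tab
}

#' Query %Rank values for peptides
#'
#' For multi-allele tables the minimum %Rank across alleles is returned per
#' peptide (a peptide binds if it binds any allele of the sample).
#'
#' @param rankTable A rank table from [readRankTable()] (or a data.frame with
#'   the same columns).
#' @param peptides Character vector of plain peptide sequences.
#' @return Numeric vector of minimum %Rank per peptide; NA for peptides
#'   absent from the table (explicit missing marker, never zero).
#' @export
queryPercentRank <- function(rankTable, peptides) {
  best <- tapply(rankTable$percent_rank, rankTable$peptide, min)
  out <- as.numeric(best[peptides])
  names(out) <- peptides
  out
}
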