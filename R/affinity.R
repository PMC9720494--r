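## MHC binding-strength classification from %Rank values.
##
## %Rank is an allele-normalised rank of predicted binding strength
## (lower = stronger). The conventional thresholds are strict:
## < 0.5 -> strong binder, < 2 -> binder, otherwise nonbinder.

#' Classify binding strength from %Rank
#'
#' For multi-allele samples, pass the minimum %Rank across alleles (see
#' [queryPercentRank()]).
#'
#' @param percentRank Numeric vector of %Rank values (>= 0).
#' @return Character vector with values \code{"strong"}, \code{"binder"},
#'   \code{"nonbinder"}. Thresholds are strict: 2.0 is a nonbinder.
#' @examples
#' classifyBinder(c(0.3, 1.5, 2.0))
#' @export
classifyBinder <- function(percentRank) {
  if (any(percentRank < 0, na.rm = TRUE)) {
    stop("negative %Rank")
  }
  out <- ifelse(percentRank < 0.5, "strong",
                ifelse(percentRank < 2, "binder", "nonbinder"))
  out[is.na(percentRank)] <- NA_character_
  out
}

#' Percentage of predicted binders among identified peptides
#'
#' Validation metric: among identified peptides within the length window
#' (default 8..14 residues, the window the binding predictor supports), the
#' percentages predicted as binders (strong or weak) and as strong binders.
#'
#' @param peptides Character vector of identified plain peptide sequences.
#' @param rankTable A rank table (see [readRankTable()]); it must cover all
#'   in-window peptides (a missing one is an error listing the peptides).
#' @param lengthWindow Integer vector \code{c(min, max)} (default
#'   \code{c(8, 14)}).
#' @return List with \code{percentBinders}, \code{percentStrong} (both on
#'   the 0..100 scale) and \code{n}, the in-window denominator.
#' @export
percentPredictedBinders <- function(peptides, rankTable,
                                    lengthWindow = c(8L, 14L)) {
  peptides <- unique(peptides)
  len <- nchar(peptides)
  inWindow <- peptides[len >= lengthWindow[1] & len <= lengthWindow[2]]
  if (!length(inWindow)) {
    stop("no identified peptides within the length window")
  }
  ranks <- queryPercentRank(rankTable, inWindow)
  if (any(is.na(ranks))) {
    stop("peptides missing from the rank table: ",
         paste(utils::head(inWindow[is.na(ranks)], 10), collapse = ", "))
  }
  call <- classifyBinder(ranks)
  list(
    percentBinders = 100 * mean(call %in% c("strong", "binder")),
    percentStrong = 100 * mean(call == "strong"),
    n = length(inWindow)
  )
}
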