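## Peptide notation.
##
## Peptides travel through the pipeline as strings in a bracketed notation:
## plain one-letter residues with optional modification tokens directly after
## the modified residue, e.g. "AC(cam)M(ox)K". Only oxidation of Met ("ox")
## and carbamidomethylation of Cys ("cam") are supported. parsePeptide()
## converts the string into the internal form (plain sequence + a table of
## (position, name) modifications); peptideString() is its inverse.

#' Parse a peptide string in bracketed modification notation
#'
#' @param x A single peptide string, e.g. \code{"AC(cam)M(ox)K"}.
#' @return A list with \code{sequence} (unmodified one-letter string),
#'   \code{length}, and \code{mods}, a data.frame with columns
#'   \code{position} (1-based) and \code{name} (\code{"ox"} or \code{"cam"}).
#' @examples
#' parsePeptide("AC(cam)M(ox)K")
#' @export
parsePeptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (!nzchar(x)) {
    stop("empty peptide sequence")
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  mods_pos <- integer(0)
  mods_name <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- which(chars == ")" & seq_len(n) > i)
      if (length(close) == 0L) {
        stop("unclosed modification token in peptide '", x, "'")
      }
      close <- close[1]
      token <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!token %in% names(MODIFICATION_MASSES)) {
        stop("unknown modification token '", token, "' in peptide '", x, "'")
      }
      if (length(seq_chars) == 0L) {
        stop("modification token before any residue in peptide '", x, "'")
      }
      pos <- length(seq_chars)
      res <- seq_chars[pos]
      if (token == "ox" && res != "M") {
        stop("oxidation on residue '", res, "' (only M) in peptide '", x, "'")
      }
      if (token == "cam" && res != "C") {
        stop("carbamidomethyl on residue '", res,
             "' (only C) in peptide '", x, "'")
      }
      mods_pos <- c(mods_pos, pos)
      mods_name <- c(mods_name, token)
      i <- close + 1L
    } else {
      if (!ch %in% names(RESIDUE_MASSES)) {
        stop("unknown residue letter '", ch, "' in peptide '", x, "'")
      }
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  if (length(seq_chars) == 0L) {
    stop("empty peptide sequence")
  }
  if (anyDuplicated(mods_pos)) {
    stop("duplicate modification position in peptide '", x, "'")
  }
  list(
    sequence = paste(seq_chars, collapse = ""),
    length = length(seq_chars),
    mods = data.frame(position = mods_pos, name = mods_name,
                      stringsAsFactors = FALSE)
  )
}

#' Rebuild a peptide string from its parsed form
#'
#' @param p A parsed peptide, as returned by [parsePeptide()].
#' @return The bracketed-notation peptide string.
#' @export
peptideString <- function(p) {
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  if (nrow(p$mods)) {
    for (k in seq_len(nrow(p$mods))) {
      pos <- p$mods$position[k]
      chars[pos] <- paste0(chars[pos], "(", p$mods$name[k], ")")
    }
  }
  paste(chars, collapse = "")
}

#' Strip modification tokens from peptide strings
#'
#' @param x Character vector of peptide strings in bracketed notation.
#' @return Character vector of plain sequences.
#' @examples
#' stripModifications(c("AC(cam)K", "PEPTIDE"))
#' @export
stripModifications <- function(x) {
  gsub("\\([a-z]+\\)", "", x)
}

#' @noRd
isUnmodified <- function(x) {
  !grepl("(", x, fixed = TRUE)
}
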