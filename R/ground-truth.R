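## Ground-truth benchmark construction and precision-recall evaluation.
##
## A set of peptides with known spectra is split: two-thirds are embedded
## into a reference database ("discoverable"), the remaining third is kept
## out ("undiscoverable") so that any assignment of them by a search is
## necessarily wrong. Fragments of the removed peptides are appended so the
## database composition is not biased against them.

#' Build a constructed reference database with known answers
#'
#' A fraction of the ground-truth peptides (default 2/3) is embedded into
#' randomly chosen database entries at random positions, replacing a span of
#' equal length; the remainder is excluded. After embedding, every excluded
#' peptide is checked against the whole database: accidental substring
#' occurrences are re-labelled discoverable (and logged). For each
#' undiscoverable peptide, two non-overlapping fragments (random split point
#' in [3, L-3]) are appended as padding entries.
#'
#' @param gtPeptides Character vector of unique plain peptides (length >= 7).
#' @param referenceDb An [Biostrings::AAStringSet] (or named character
#'   vector) of reference protein entries.
#' @param discoverableFraction Fraction embedded (default 2/3), in (0, 1).
#' @param seed Integer seed; the construction is deterministic under it.
#' @return A [GroundTruthBenchmark-class] (truth map empty; filled by the
#'   dataset generator or the caller).
#' @export
buildConstructedDatabase <- function(gtPeptides, referenceDb,
                                     discoverableFraction = 2 / 3,
                                     seed = 1L) {
  if (anyDuplicated(gtPeptides)) {
    stop("ground-truth peptides must be unique")
  }
  if (any(nchar(gtPeptides) < 7L)) {
    stop("ground-truth peptides must be at least 7 residues long")
  }
  if (discoverableFraction <= 0 || discoverableFraction >= 1) {
    stop("discoverableFraction must be in (0, 1)")
  }
  if (is(referenceDb, "AAStringSet")) {
    entries <- as.character(referenceDb)
  } else {
    entries <- as.character(referenceDb)
  }
  if (!length(entries)) {
    stop("reference database is empty")
  }
  if (is.null(names(entries))) {
    names(entries) <- paste0("entry", seq_along(entries))
  }
  rng <- .restoreSeed(seed)
  on.exit(rng())
  n <- length(gtPeptides)
  nDisc <- round(discoverableFraction * n)
  discIdx <- sample(n, nDisc)
  discoverable <- gtPeptides[sort(discIdx)]
  undiscoverable <- gtPeptides[setdiff(seq_len(n), discIdx)]
  ## embed each discoverable peptide into a random entry at a random
  ## position, replacing a same-length span; spans never overlap so one
  ## embedding cannot destroy another
  occupied <- vector("list", length(entries))
  for (pep in discoverable) {
    L <- nchar(pep)
    placed <- FALSE
    for (try in seq_len(200L)) {
      e <- sample(length(entries), 1L)
      maxStart <- nchar(entries[e]) - L + 1L
      if (maxStart < 1L) next
      start <- if (maxStart == 1L) 1L else sample(maxStart, 1L)
      span <- c(start, start + L - 1L)
      clash <- any(vapply(occupied[[e]], function(s) {
        span[1] <= s[2] && s[1] <= span[2]
      }, logical(1)))
      if (!clash) {
        substr(entries[e], span[1], span[2]) <- pep
        occupied[[e]] <- c(occupied[[e]], list(span))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not embed '", pep,
           "' without overlap; provide a larger reference database")
    }
  }
  ## collision check: an excluded peptide occurring by chance is relabelled
  relabelled <- character(0)
  for (pep in undiscoverable) {
    if (any(grepl(pep, entries, fixed = TRUE))) {
      relabelled <- c(relabelled, pep)
    }
  }
  if (length(relabelled)) {
    message(length(relabelled),
            " excluded peptide(s) occurred by chance and were relabelled ",
            "discoverable: ", paste(relabelled, collapse = ", "))
    discoverable <- c(discoverable, relabelled)
    undiscoverable <- setdiff(undiscoverable, relabelled)
  }
  ## padding fragments of the removed peptides (each >= 3 residues)
  padEntries <- character(0)
  for (pep in undiscoverable) {
    L <- nchar(pep)
    split <- if (L - 3L == 3L) 3L else sample(seq(3L, L - 3L), 1L)
    padEntries <- c(padEntries,
                    substr(pep, 1L, split),
                    substr(pep, split + 1L, L))
  }
  if (length(padEntries)) {
    names(padEntries) <- paste0("PAD_", seq_along(padEntries))
    entries <- c(entries, padEntries)
  }
  ## exhaustive invariant verification after every build
  for (pep in discoverable) {
    if (!any(grepl(pep, entries, fixed = TRUE))) {
      stop("internal error: discoverable peptide '", pep, "' not embedded")
    }
  }
  stillThere <- vapply(undiscoverable, function(pep) {
    any(grepl(pep, entries, fixed = TRUE))
  }, logical(1))
  if (any(stillThere)) {
    stop("internal error: undiscoverable peptide present after build")
  }
  labels <- rbind(
    data.frame(peptide = discoverable, label = "discoverable",
               stringsAsFactors = FALSE),
    data.frame(peptide = undiscoverable, label = "undiscoverable",
               stringsAsFactors = FALSE)
  )
  labels <- labels[order(labels$peptide), , drop = FALSE]
  rownames(labels) <- NULL
  new("GroundTruthBenchmark",
      database = Biostrings::AAStringSet(entries),
      truthMap = data.frame(sourceFile = character(0),
                            scanNumber = integer(0),
                            peptide = character(0),
                            stringsAsFactors = FALSE),
      labels = labels)
}

#' Precision-recall curve of rescored assignments against ground truth
#'
#' Sweeps a cutoff over the distinct final scores of the target PSMs. At
#' each cutoff, precision is the number of correctly assigned PSMs above the
#' cutoff divided by the total PSMs above it, and recall is the number of
#' correctly assigned PSMs divided by the number of discoverable peptides in
#' the constructed database. Correctness is an exact residue match between
#' the assigned peptide (modifications stripped) and the truth; I and L are
#' NOT collapsed.
#'
#' @param assignments A q-value table from [semiSupervisedRescore()] (needs
#'   \code{score}, \code{label}, \code{peptide}, \code{sourceFile},
#'   \code{scanNumber}).
#' @param benchmark A [GroundTruthBenchmark-class] with a populated truth
#'   map. A target PSM whose scan is absent from the truth map is an error
#'   (such scans must be filtered before rescoring).
#' @return data.frame with columns \code{cutoff}, \code{precision},
#'   \code{recall}, ordered by decreasing cutoff.
#' @export
prCurve <- function(assignments, benchmark) {
  tm <- truthMap(benchmark)
  lab <- peptideLabels(benchmark)
  nDiscoverable <- sum(lab$label == "discoverable")
  tgt <- assignments[assignments$label == 1L, , drop = FALSE]
  key <- paste(tgt$sourceFile, tgt$scanNumber, sep = "/")
  tmKey <- paste(tm$sourceFile, tm$scanNumber, sep = "/")
  idx <- match(key, tmKey)
  if (any(is.na(idx))) {
    stop("scan(s) absent from truth map: ",
         paste(utils::head(key[is.na(idx)], 5), collapse = ", "))
  }
  correct <- stripModifications(tgt$peptide) == tm$peptide[idx]
  ord <- order(tgt$score, decreasing = TRUE)
  correctOrd <- correct[ord]
  scoreOrd <- tgt$score[ord]
  cumCorrect <- cumsum(correctOrd)
  cumTotal <- seq_along(correctOrd)
  ## one point per distinct score (block ends)
  isEnd <- c(scoreOrd[-1] != scoreOrd[-length(scoreOrd)], TRUE)
  data.frame(
    cutoff = scoreOrd[isEnd],
    precision = (cumCorrect / cumTotal)[isEnd],
    recall = (cumCorrect / nDiscoverable)[isEnd]
  )
}

#' Maximum recall at a precision floor
#'
#' @param curve A PR curve from [prCurve()].
#' @param precisionFloor Minimum acceptable precision in [0, 1]
#'   (default 0.99); 0 imposes no constraint (global maximum recall).
#' @return The maximum recall among cutoffs with precision >= the floor;
#'   0 when no cutoff qualifies.
#' @export
recallAtPrecision <- function(curve, precisionFloor = 0.99) {
  if (!nrow(curve)) {
    stop("empty precision-recall curve")
  }
  if (precisionFloor < 0 || precisionFloor > 1) {
    stop("precisionFloor must be in [0, 1]")
  }
  ok <- curve$precision >= precisionFloor
  if (!any(ok)) {
    return(0)
  }
  max(curve$recall[ok])
}
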