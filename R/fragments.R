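## Peptide chemistry: monoisotopic masses, theoretical b/y fragment m/z and
## tolerance-based peak matching.

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of monoisotopic residue masses plus water, plus the mass deltas of any
#' modifications (oxidation +15.994915 Da, carbamidomethyl +57.021464 Da).
#'
#' @param peptide Peptide string in bracketed notation (see [parsePeptide()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideNeutralMass("G")           # 75.03203
#' peptideNeutralMass("M(ox)") - peptideNeutralMass("M")  # 15.994915
#' @export
peptideNeutralMass <- function(peptide) {
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  residues <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(RESIDUE_MASSES[residues]) + WATER_MASS
  if (nrow(p$mods)) {
    m <- m + sum(MODIFICATION_MASSES[p$mods$name])
  }
  unname(m)
}

#' Theoretical b/y fragment m/z table
#'
#' Computes the m/z of all b and y backbone fragments of a peptide. The b_i
#' neutral mass is the sum of residues 1..i (plus their modifications); the
#' y_j neutral mass is the sum of the last j residues plus water. Fragment
#' charges 1..min(3, precursorCharge) are emitted;
#' mz = (neutral + z * 1.007276) / z.
#'
#' @param peptide Peptide string (bracketed notation), length 7..30.
#' @param precursorCharge Precursor charge (>= 1); caps the fragment charge.
#' @return data.frame with columns \code{series}, \code{ordinal},
#'   \code{charge}, \code{mz}.
#' @examples
#' head(fragmentMzTable("AGPEPTIDE", 2L))
#' @export
fragmentMzTable <- function(peptide, precursorCharge) {
  if (precursorCharge < 1L) {
    stop("precursorCharge must be >= 1")
  }
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  L <- p$length
  residues <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  resMass <- unname(RESIDUE_MASSES[residues])
  if (nrow(p$mods)) {
    resMass[p$mods$position] <- resMass[p$mods$position] +
      unname(MODIFICATION_MASSES[p$mods$name])
  }
  bNeutral <- cumsum(resMass)[-L]                 # b_1 .. b_{L-1}
  yNeutral <- rev(cumsum(rev(resMass)))[-1] + WATER_MASS  # y_{L-1} .. y_1
  ordinalB <- seq_len(L - 1L)
  ordinalY <- rev(ordinalB)
  zmax <- min(3L, as.integer(precursorCharge))
  out <- do.call(rbind, lapply(seq_len(zmax), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      ordinal = c(ordinalB, ordinalY),
      charge = z,
      mz = (c(bNeutral, yNeutral) + z * PROTON_MASS) / z,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Match theoretical fragments to spectrum peaks within a tolerance
#'
#' Each fragment is matched to at most one peak with absolute m/z difference
#' within \code{tolerance}; among candidates the nearest peak wins, with
#' equidistant ties broken to the lower m/z. One peak may serve several
#' fragments. The signed m/z error is observed minus theoretical.
#'
#' @param spectrum A [Spectrum-class] (peaks sorted ascending by m/z).
#' @param fragments A fragment table from [fragmentMzTable()].
#' @param tolerance Matching tolerance in Th (default 0.02).
#' @return The fragment table with added columns \code{matched} (logical),
#'   \code{peakMz}, \code{peakIntensity}, \code{mzError} (NA when unmatched).
#' @examples
#' sp <- Spectrum("f", 1L, 400, 2L, 10,
#'                cbind(mz = c(200.01, 350.5), intensity = c(5, 2)))
#' fr <- data.frame(series = "b", ordinal = 2L, charge = 1L, mz = 200.0)
#' matchPeaks(sp, fr)
#' @export
matchPeaks <- function(spectrum, fragments, tolerance = 0.02) {
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0")
  }
  pk <- if (is(spectrum, "Spectrum")) peaks(spectrum) else as.matrix(spectrum)
  fr <- fragments
  n <- nrow(fr)
  fr$matched <- logical(n)
  fr$peakMz <- rep(NA_real_, n)
  fr$peakIntensity <- rep(NA_real_, n)
  fr$mzError <- rep(NA_real_, n)
  if (nrow(pk) == 0L || n == 0L) {
    return(fr)
  }
  mzP <- pk[, 1L]
  idx <- findInterval(fr$mz, mzP)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mzP))
  dLo <- abs(fr$mz - mzP[lo])
  dHi <- abs(fr$mz - mzP[hi])
  ## nearest peak; exact ties go to the lower m/z (dLo wins on <=)
  useLo <- dLo <= dHi
  best <- ifelse(useLo, lo, hi)
  dBest <- ifelse(useLo, dLo, dHi)
  ok <- dBest <= tolerance
  fr$matched <- ok
  fr$peakMz[ok] <- mzP[best[ok]]
  fr$peakIntensity[ok] <- pk[best[ok], 2L]
  fr$mzError[ok] <- fr$peakMz[ok] - fr$mz[ok]
  fr
}
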