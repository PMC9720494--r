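## Collision-energy calibration: spectral predictors are trained at discrete
## normalised collision energies and their output shape depends on it, so
## the setting must be matched to the instrument before prediction features
## are meaningful.

#' Calibrate the collision-energy setting
#'
#' Takes the \code{topN} highest engine-score unmodified target PSMs,
#' computes the mean spectral angle between their experimental spectra and
#' predictions at every collision energy from 20 to 40 (inclusive), and
#' selects the CE with the highest mean (ties broken to the lowest CE).
#'
#' @param psms PSM data.frame (compatibility-filtered).
#' @param spectra Named list of [Spectrum-class]
#'   (\code{"<sourceFile>/<scanNumber>"}).
#' @param predictor Function \code{(peptide, charge, ce) ->}
#'   [PredictedSpectrum-class].
#' @param topN Number of top-scoring PSMs to use (default 1000).
#' @param tolerance Peak-matching tolerance in Th.
#' @return A [CalibrationResult-class].
#' @export
calibrateCollisionEnergy <- function(psms, spectra, predictor,
                                     topN = 1000L, tolerance = 0.02) {
  sel <- psms[psms$label == 1L & isUnmodified(psms$peptide), , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no unmodified target PSMs available for calibration")
  }
  if (nrow(sel) < 10L) {
    stop("calibration needs >= 10 unmodified target PSMs (got ",
         nrow(sel), ")")
  }
  sel <- sel[order(sel$engineScore, decreasing = TRUE), , drop = FALSE]
  sel <- utils::head(sel, topN)
  ## sort for order-invariance of the (deterministic) mean
  sel <- sel[order(sel$sourceFile, sel$scanNumber, sel$peptide), ,
             drop = FALSE]
  grid <- 20:40
  specKey <- paste(sel$sourceFile, sel$scanNumber, sep = "/")
  ## matches are CE-independent; compute once per PSM
  matchList <- lapply(seq_len(nrow(sel)), function(i) {
    matchPeaks(spectra[[specKey[i]]],
               fragmentMzTable(sel$peptide[i], sel$charge[i]), tolerance)
  })
  meanSa <- vapply(grid, function(ce) {
    sas <- vapply(seq_len(nrow(sel)), function(i) {
      pred <- predictor(sel$peptide[i], sel$charge[i], ce)
      al <- .alignedIntensities(pred, matchList[[i]])
      spectralAngle(al$predicted, al$observed)
    }, numeric(1))
    mean(sas)
  }, numeric(1))
  selectedCe <- grid[which.max(meanSa)]  # which.max takes the first = lowest CE
  new("CalibrationResult",
      grid = as.integer(grid),
      meanSa = meanSa,
      selectedCe = as.integer(selectedCe),
      nPsmsUsed = nrow(sel))
}
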