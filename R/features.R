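## Per-PSM feature computation: spectral angle, ion-series coverage, m/z
## error, retention-time error, compatibility filtering and assembly of the
## full rescoring feature table.

## Predicted intensities below this fraction of the base peak are treated as
## absent when counting "possible" fragments of a series; spectral
## predictors emit near-zero noise intensities for most positions.
.COVERAGE_THRESHOLD <- 0.01

#' Normalised spectral contrast angle
#'
#' \code{SA = 1 - (2/pi) * arccos(<p, e> / (||p|| ||e||))} over intensity
#' vectors indexed by the same fragment set. 1 means a perfect match, 0
#' orthogonal spectra. When the observed vector is all zero (nothing
#' matched), 0 is returned by convention.
#'
#' @param predicted,observed Nonnegative intensity vectors over an identical
#'   fragment index set.
#' @return Spectral angle in [0, 1].
#' @examples
#' spectralAngle(c(1, 0), c(1, 1))  # 0.5
#' @export
spectralAngle <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("intensity vectors must be over the identical fragment index set")
  }
  if (any(predicted < 0) || any(observed < 0)) {
    stop("negative intensity")
  }
  np <- sqrt(sum(predicted^2))
  ne <- sqrt(sum(observed^2))
  if (ne == 0 || np == 0) {
    return(0)
  }
  cosine <- sum(predicted * observed) / (np * ne)
  cosine <- min(1, max(-1, cosine))
  1 - (2 / pi) * acos(cosine)
}

#' @noRd
## Align a prediction with peak matches on the union of predicted fragment
## positions: returns predicted and observed intensity vectors plus
## bookkeeping shared by several feature blocks.
.alignedIntensities <- function(prediction, matches) {
  fr <- prediction@fragments
  keyPred <- paste(fr$series, fr$ordinal, fr$charge)
  keyMatch <- paste(matches$series, matches$ordinal, matches$charge)
  idx <- match(keyPred, keyMatch)
  obs <- ifelse(!is.na(idx) & matches$matched[idx],
                matches$peakIntensity[idx], 0)
  obs[is.na(obs)] <- 0
  list(predicted = fr$intensity, observed = obs,
       matched = !is.na(idx) & matches$matched[idx] %in% TRUE,
       fragments = fr)
}

#' Ion-series coverage features
#'
#' Per series (b, y): predicted coverage is the fraction of possible ordinals
#' (1..L-1) carrying predicted intensity above 1% of the base peak; matched
#' coverage is the fraction of those predicted fragments matched to an
#' experimental peak. The dominant series is the one with the greater
#' predicted coverage (ties go to y, the usual HCD dominant series).
#'
#' @param prediction A [PredictedSpectrum-class].
#' @param matches Match table from [matchPeaks()] on the same fragment set.
#' @return Named numeric vector: \code{dominantCoverage},
#'   \code{lesserCoverage}, \code{dominantMatched}, \code{lesserMatched},
#'   \code{ms2Coverage}.
#' @export
seriesCoverageFeatures <- function(prediction, matches) {
  fr <- prediction@fragments
  L <- parsePeptide(prediction@peptide)$length
  al <- .alignedIntensities(prediction, matches)
  thr <- .COVERAGE_THRESHOLD * max(fr$intensity)
  stats <- lapply(c(b = "b", y = "y"), function(s) {
    sel <- fr$series == s & fr$intensity > thr
    ordinals <- unique(fr$ordinal[sel])
    predCov <- length(ordinals) / (L - 1L)
    matchCov <- if (any(sel)) mean(al$matched[sel]) else 0
    c(predCov = predCov, matchCov = matchCov)
  })
  predAll <- fr$intensity > thr
  ms2 <- if (any(predAll)) mean(al$matched[predAll]) else 0
  dominant <- if (stats$b["predCov"] > stats$y["predCov"]) "b" else "y"
  lesser <- setdiff(c("b", "y"), dominant)
  c(
    dominantCoverage = unname(stats[[dominant]]["predCov"]),
    lesserCoverage = unname(stats[[lesser]]["predCov"]),
    dominantMatched = unname(stats[[dominant]]["matchCov"]),
    lesserMatched = unname(stats[[lesser]]["matchCov"]),
    ms2Coverage = ms2
  )
}

#' Fragment m/z error features
#'
#' @param matches Match table from [matchPeaks()].
#' @return Named numeric vector: \code{medianAbsMzError},
#'   \code{maxAbsMzError}, \code{meanMzError} (signed), \code{nMatched}.
#'   All error features are 0 when nothing matched; \code{nMatched}
#'   disambiguates that convention.
#' @export
mzErrorFeatures <- function(matches) {
  err <- matches$mzError[matches$matched]
  if (!length(err)) {
    return(c(medianAbsMzError = 0, maxAbsMzError = 0, meanMzError = 0,
             nMatched = 0))
  }
  c(
    medianAbsMzError = stats::median(abs(err)),
    maxAbsMzError = max(abs(err)),
    meanMzError = mean(err),
    nMatched = length(err)
  )
}

#' Fit the retention-time alignment
#'
#' Least-squares line mapping the predicted retention index (iRT) to observed
#' minutes, fitted on a high-confidence PSM subset.
#'
#' @param observedRt Observed retention times (minutes).
#' @param irt Predicted retention indices, same length, not all equal.
#' @return An [RtAlignment-class].
#' @export
fitRtAlignment <- function(observedRt, irt) {
  if (length(observedRt) != length(irt)) {
    stop("observedRt and irt lengths differ")
  }
  if (length(irt) < 10L) {
    stop("retention-time alignment requires >= 10 (PSM, iRT) pairs")
  }
  if (stats::sd(irt) == 0) {
    stop("degenerate retention-time alignment: iRT values are constant")
  }
  fit <- stats::lm.fit(cbind(1, irt), observedRt)
  res <- fit$residuals
  new("RtAlignment",
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      residualSd = stats::sd(res),
      n = length(irt))
}

#' Retention-time error of PSMs under an alignment
#'
#' @param alignment An [RtAlignment-class].
#' @param observedRt Observed retention times (minutes).
#' @param irt Predicted retention indices.
#' @return Absolute deviation |observed - fitted| in minutes.
#' @export
rtError <- function(alignment, observedRt, irt) {
  abs(observedRt - (alignment@slope * irt + alignment@intercept))
}

#' Filter PSMs for spectral-predictor compatibility
#'
#' Keeps PSMs whose peptide length is 7..30 (inclusive), with no unmodified
#' cysteine (the spectral predictor assumes carbamidomethylation of Cys) and
#' no modification outside oxidation-M / carbamidomethyl-C. Idempotent.
#'
#' @param psms PSM data.frame from [readSearchResults()].
#' @return List with \code{kept} (PSM data.frame) and \code{rejected}
#'   (data.frame with the rejected rows and a \code{reason} column).
#' @export
filterCompatible <- function(psms) {
  n <- nrow(psms)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- tryCatch(parsePeptide(psms$peptide[i]), error = function(e) NULL)
    if (is.null(p)) {
      reason[i] <- "unparseable peptide"
      next
    }
    if (p$length < 7L) {
      reason[i] <- "peptide shorter than 7 residues"
    } else if (p$length > 30L) {
      reason[i] <- "peptide longer than 30 residues"
    } else {
      cysPos <- which(strsplit(p$sequence, "")[[1]] == "C")
      camPos <- p$mods$position[p$mods$name == "cam"]
      if (length(setdiff(cysPos, camPos))) {
        reason[i] <- "unmodified cysteine"
      }
    }
  }
  keep <- is.na(reason)
  rejected <- psms[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!keep]
  } else {
    rejected$reason <- character(0)
  }
  list(kept = psms[keep, , drop = FALSE], rejected = rejected)
}

#' @noRd
## The canonical base feature list (printed in reports so runs are
## self-describing). Order is fixed per run.
.baseFeatureNames <- function() {
  c("engineScore", "spectralAngle", "pearsonCorr",
    "dominantCoverage", "lesserCoverage", "dominantMatched",
    "lesserMatched", "ms2Coverage",
    "medianAbsMzError", "maxAbsMzError", "meanMzError", "nMatched",
    "fracPredictedMatched", "fracObservedExplained",
    "rtError", "peptideLength",
    paste0("charge", 1:6))
}

.DELTA_FEATURE_NAMES <- c("deltaMin", "deltaMax", "deltaMedian", "deltaQ1",
                          "deltaQ3", "deltaFracAboveM01", "deltaFracAbove0")

#' Build the per-PSM rescoring feature table
#'
#' Assembles the fixed feature vector for every PSM: the search-engine score,
#' spectral-match features against the predicted spectrum (spectral angle,
#' Pearson correlation, dominant/lesser ion-series coverage, m/z error
#' block, fractions of predicted intensity matched and of observed intensity
#' explained), the retention-time error under the fitted alignment, peptide
#' length and a precursor-charge one-hot (1..6). Optional blocks: the 7
#' adjacent-swap delta summary features and, in affinity mode, the binding
#' %Rank and its negative log. PSMs missing a %Rank receive the worst rank
#' observed in the table (no missing values are ever emitted).
#'
#' @param psms PSM data.frame (already passed through [filterCompatible()]).
#' @param spectra Named list of [Spectrum-class]; names
#'   \code{"<sourceFile>/<scanNumber>"}.
#' @param predictions Named list of [PredictedSpectrum-class]; names
#'   \code{"<peptide>/<charge>"} at the calibrated collision energy.
#' @param rtAlignment An [RtAlignment-class].
#' @param deltaSummaries Optional data.frame of 7 delta summary columns (one
#'   row per PSM, same order), as produced by [deltaSummary()] rows.
#' @param rankTable Optional rank table (affinity mode): adds
#'   \code{percentRank} and \code{negLogRank} columns.
#' @param tolerance Peak-matching tolerance in Th.
#' @return A [FeatureTable-class].
#' @export
buildFeatureTable <- function(psms, spectra, predictions, rtAlignment,
                              deltaSummaries = NULL, rankTable = NULL,
                              tolerance = 0.02) {
  n <- nrow(psms)
  predKey <- paste(psms$peptide, psms$charge, sep = "/")
  missingPred <- setdiff(unique(predKey), names(predictions))
  if (length(missingPred)) {
    stop("PSMs without a spectral prediction: ",
         paste(utils::head(missingPred, 5), collapse = ", "),
         if (length(missingPred) > 5) " ...")
  }
  specKey <- paste(psms$sourceFile, psms$scanNumber, sep = "/")
  missingSpec <- setdiff(unique(specKey), names(spectra))
  if (length(missingSpec)) {
    stop("PSMs without a spectrum: ",
         paste(utils::head(missingSpec, 5), collapse = ", "))
  }
  featNames <- .baseFeatureNames()
  if (!is.null(deltaSummaries)) {
    featNames <- c(featNames, .DELTA_FEATURE_NAMES)
  }
  if (!is.null(rankTable)) {
    featNames <- c(featNames, "percentRank", "negLogRank")
  }
  feats <- matrix(0, nrow = n, ncol = length(featNames),
                  dimnames = list(NULL, featNames))
  if (!is.null(rankTable)) {
    ranks <- queryPercentRank(rankTable, stripModifications(psms$peptide))
    worst <- max(rankTable$percent_rank)
    ranks[is.na(ranks)] <- worst
  }
  for (i in seq_len(n)) {
    pred <- predictions[[predKey[i]]]
    sp <- spectra[[specKey[i]]]
    L <- parsePeptide(psms$peptide[i])$length
    fragTab <- fragmentMzTable(psms$peptide[i], psms$charge[i])
    matches <- matchPeaks(sp, fragTab, tolerance)
    al <- .alignedIntensities(pred, matches)
    sa <- spectralAngle(al$predicted, al$observed)
    pearson <- if (stats::sd(al$predicted) > 0 && stats::sd(al$observed) > 0) {
      stats::cor(al$predicted, al$observed)
    } else 0
    cov <- seriesCoverageFeatures(pred, matches)
    mzf <- mzErrorFeatures(matches)
    fracPredMatched <- if (sum(al$predicted) > 0) {
      sum(al$predicted[al$matched]) / sum(al$predicted)
    } else 0
    pkAll <- peaks(sp)
    totObs <- sum(pkAll[, 2L])
    matchedMz <- unique(matches$peakMz[matches$matched])
    explained <- sum(pkAll[pkAll[, 1L] %in% matchedMz, 2L])
    fracObsExplained <- if (totObs > 0) explained / totObs else 0
    rte <- rtError(rtAlignment, psms$retentionTime[i], pred@irt)
    chargeOneHot <- as.numeric(seq_len(6L) == min(psms$charge[i], 6L))
    row <- c(psms$engineScore[i], sa, pearson, cov, mzf,
             fracPredMatched, fracObsExplained, rte, L, chargeOneHot)
    if (!is.null(deltaSummaries)) {
      row <- c(row, as.numeric(deltaSummaries[i, .DELTA_FEATURE_NAMES]))
    }
    if (!is.null(rankTable)) {
      r <- unname(ranks[i])
      row <- c(row, r, -log10(max(r, 1e-3)))
    }
    feats[i, ] <- row
  }
  meta <- data.frame(
    specId = paste(psms$sourceFile, psms$scanNumber, psms$peptide,
                   sep = "_"),
    label = psms$label,
    scanNumber = psms$scanNumber,
    sourceFile = psms$sourceFile,
    peptide = psms$peptide,
    proteins = psms$proteins,
    stringsAsFactors = FALSE
  )
  FeatureTable(meta, feats)
}

#' Drop feature columns from a FeatureTable
#'
#' @param table A [FeatureTable-class].
#' @param exclude Character vector of feature names to remove (must be a
#'   subset of the table's features).
#' @return A [FeatureTable-class] without the excluded columns.
#' @export
excludeFeatures <- function(table, exclude) {
  unknown <- setdiff(exclude, featureNames(table))
  if (length(unknown)) {
    stop("unknown features: ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(featureNames(table), exclude)
  FeatureTable(psmMeta(table),
               featureMatrix(table)[, keep, drop = FALSE])
}
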