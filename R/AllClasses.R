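## S4 classes for the central data objects of the rescoring pipeline.

#' @import methods
NULL

#' Spectrum: one experimental MS2 scan
#'
#' Holds the peak list, precursor information and provenance of a single MS2
#' scan. Peaks are kept sorted by ascending m/z; several PSMs may reference
#' one scan (chimeric spectra are first-class citizens and are never dropped).
#'
#' @slot sourceFile character scalar, the originating file.
#' @slot scanNumber integer scalar, scan index within the source file.
#' @slot precursorMz numeric scalar (Th).
#' @slot precursorCharge integer scalar, >= 1.
#' @slot retentionTime numeric scalar, minutes.
#' @slot peaks two-column numeric matrix (\code{mz}, \code{intensity}),
#'   sorted ascending by m/z, intensities >= 0.
#'
#' @exportClass Spectrum
setClass("Spectrum", representation(
  sourceFile = "character",
  scanNumber = "integer",
  precursorMz = "numeric",
  precursorCharge = "integer",
  retentionTime = "numeric",
  peaks = "matrix"
))

setValidity("Spectrum", function(object) {
  msg <- character(0)
  if (length(object@scanNumber) != 1L || object@scanNumber < 1L)
    msg <- c(msg, "scanNumber must be a single positive integer")
  if (length(object@precursorCharge) != 1L || object@precursorCharge < 1L)
    msg <- c(msg, "precursorCharge must be >= 1")
  pk <- object@peaks
  if (ncol(pk) != 2L)
    msg <- c(msg, "peaks must have two columns (mz, intensity)")
  else {
    if (nrow(pk) > 1L && is.unsorted(pk[, 1L]))
      msg <- c(msg, "peaks must be sorted ascending by m/z")
    if (nrow(pk) > 0L && any(pk[, 2L] < 0))
      msg <- c(msg, "peak intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param sourceFile Originating file name.
#' @param scanNumber Scan index (positive integer).
#' @param precursorMz Precursor m/z in Th.
#' @param precursorCharge Precursor charge (>= 1).
#' @param retentionTime Retention time in minutes.
#' @param peaks Two-column matrix or data.frame of (mz, intensity); sorted on
#'   construction.
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum("run1.mgf", 7L, 500.3, 2L, 35.2,
#'          cbind(mz = c(200, 300), intensity = c(1, 2)))
#' @export
Spectrum <- function(sourceFile, scanNumber, precursorMz, precursorCharge,
                     retentionTime, peaks) {
  peaks <- as.matrix(peaks)
  if (!nrow(peaks)) {
    peaks <- matrix(numeric(0), ncol = 2)
  }
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  new("Spectrum",
      sourceFile = as.character(sourceFile),
      scanNumber = as.integer(scanNumber),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      retentionTime = as.numeric(retentionTime),
      peaks = peaks)
}

#' PredictedSpectrum: predictor output for one (peptide, charge, CE)
#'
#' Fragment-level intensity predictions for a peptide at a given precursor
#' charge and collision energy, plus the predicted retention index (iRT
#' scale). Intensities are relative, normalised so the base peak is 1.
#'
#' @slot peptide character scalar in bracketed modification notation.
#' @slot charge integer scalar, precursor charge.
#' @slot collisionEnergy integer scalar.
#' @slot fragments data.frame with columns \code{series} ("b"/"y"),
#'   \code{ordinal}, \code{charge}, \code{intensity} in [0, 1].
#' @slot irt numeric scalar, predicted retention index (dimensionless).
#'
#' @exportClass PredictedSpectrum
setClass("PredictedSpectrum", representation(
  peptide = "character",
  charge = "integer",
  collisionEnergy = "integer",
  fragments = "data.frame",
  irt = "numeric"
))

setValidity("PredictedSpectrum", function(object) {
  fr <- object@fragments
  msg <- character(0)
  need <- c("series", "ordinal", "charge", "intensity")
  if (!all(need %in% names(fr)))
    msg <- c(msg, "fragments must have series/ordinal/charge/intensity")
  else {
    if (any(!fr$series %in% c("b", "y")))
      msg <- c(msg, "fragment series must be 'b' or 'y'")
    if (any(fr$intensity < 0) || any(fr$intensity > 1 + 1e-9))
      msg <- c(msg, "fragment intensities must lie in [0, 1]")
    if (nrow(fr) && max(fr$intensity) <= 0)
      msg <- c(msg, "at least one fragment must have intensity > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PredictedSpectrum-class
#' @param peptide,charge,collisionEnergy,fragments,irt see slots.
#' @return A [PredictedSpectrum-class] object.
#' @export
PredictedSpectrum <- function(peptide, charge, collisionEnergy, fragments,
                              irt = NA_real_) {
  new("PredictedSpectrum",
      peptide = as.character(peptide),
      charge = as.integer(charge),
      collisionEnergy = as.integer(collisionEnergy),
      fragments = as.data.frame(fragments),
      irt = as.numeric(irt))
}

#' FeatureTable: per-PSM feature vectors in rescoring-input layout
#'
#' One row per PSM. The feature matrix holds only finite numeric features; the
#' metadata block carries identifiers, the target/decoy label, the peptide and
#' its proteins. The feature-name list is fixed per run so exports are
#' self-describing and bit-exact round-trippable.
#'
#' @slot meta data.frame with columns \code{specId}, \code{label} (+1/-1),
#'   \code{scanNumber}, \code{sourceFile}, \code{peptide}, \code{proteins}.
#' @slot features numeric matrix, one column per feature.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", representation(
  meta = "data.frame",
  features = "matrix"
))

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  need <- c("specId", "label", "scanNumber", "sourceFile", "peptide",
            "proteins")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@meta) != nrow(object@features))
    msg <- c(msg, "meta and features must have the same number of rows")
  if (is.null(colnames(object@features)))
    msg <- c(msg, "feature columns must be named")
  if (nrow(object@features) && any(!is.finite(object@features)))
    msg <- c(msg, "all feature values must be finite (no missing values)")
  if (!all(object@meta$label %in% c(1L, -1L)))
    msg <- c(msg, "labels must be +1 (target) or -1 (decoy)")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureTable-class
#' @param meta,features see slots.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(meta, features) {
  new("FeatureTable", meta = as.data.frame(meta), features = as.matrix(features))
}

#' RtAlignment: linear map from predicted retention index to minutes
#'
#' @slot slope,intercept numeric scalars of the least-squares line
#'   observed_minutes = slope * iRT + intercept.
#' @slot residualSd numeric scalar, standard deviation of fit residuals.
#' @slot n integer, number of (PSM, iRT) pairs used.
#' @exportClass RtAlignment
setClass("RtAlignment", representation(
  slope = "numeric", intercept = "numeric", residualSd = "numeric",
  n = "integer"
))

setValidity("RtAlignment", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  if (object@n < 10L)
    return("retention-time alignment requires >= 10 PSMs")
  TRUE
})

#' CalibrationResult: collision-energy calibration outcome
#'
#' @slot grid integer vector of the CE settings evaluated (20..40).
#' @slot meanSa numeric vector, mean spectral angle at each grid point.
#' @slot selectedCe integer, the argmax (ties broken to the lowest CE).
#' @slot nPsmsUsed integer, number of PSMs the calibration used.
#' @exportClass CalibrationResult
setClass("CalibrationResult", representation(
  grid = "integer", meanSa = "numeric", selectedCe = "integer",
  nPsmsUsed = "integer"
))

setValidity("CalibrationResult", function(object) {
  msg <- character(0)
  if (length(object@grid) != length(object@meanSa))
    msg <- c(msg, "grid and meanSa lengths differ")
  if (!object@selectedCe %in% object@grid)
    msg <- c(msg, "selectedCe must be on the grid")
  if (any(!is.finite(object@meanSa)))
    msg <- c(msg, "meanSa must be finite at every grid point")
  if (length(msg)) msg else TRUE
})

#' GroundTruthBenchmark: constructed database with known answers
#'
#' @slot database An [Biostrings::AAStringSet] of the constructed reference
#'   entries (embedded peptides plus padding fragments).
#' @slot truthMap data.frame mapping scans to their true peptide:
#'   columns \code{sourceFile}, \code{scanNumber}, \code{peptide}. May be
#'   empty when the benchmark was built from peptides alone.
#' @slot labels data.frame with columns \code{peptide} and \code{label}
#'   ("discoverable" or "undiscoverable").
#' @exportClass GroundTruthBenchmark
setClass("GroundTruthBenchmark", representation(
  database = "AAStringSet",
  truthMap = "data.frame",
  labels = "data.frame"
))

setValidity("GroundTruthBenchmark", function(object) {
  lab <- object@labels
  if (!all(c("peptide", "label") %in% names(lab)))
    return("labels must have columns peptide, label")
  if (!all(lab$label %in% c("discoverable", "undiscoverable")))
    return("labels must be 'discoverable' or 'undiscoverable'")
  TRUE
})

#' DeltaModel: trained adjacent-swap sensitivity predictor
#'
#' Wraps an xgboost booster together with the feature-schema version it was
#' trained under; loading or predicting under a different schema is refused.
#'
#' @slot booster the fitted xgboost model (as a raw serialized blob).
#' @slot schemaVersion character scalar.
#' @slot featureNames character vector, the training feature layout.
#' @slot evaluation list with held-out evaluation results (r2, n).
#' @exportClass DeltaModel
setClass("DeltaModel", representation(
  booster = "raw",
  schemaVersion = "character",
  featureNames = "character",
  evaluation = "list"
))

## ---- accessors ----

#' @describeIn Spectrum-class peak matrix accessor
#' @param object A Spectrum.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname Spectrum-class
#' @export
setMethod("peaks", "Spectrum", function(object) object@peaks)

#' @describeIn Spectrum-class scan number accessor
#' @export
setGeneric("scanNumber", function(object) standardGeneric("scanNumber"))
#' @rdname Spectrum-class
#' @export
setMethod("scanNumber", "Spectrum", function(object) object@scanNumber)

#' @describeIn FeatureTable-class feature matrix accessor
#' @param object A FeatureTable.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname FeatureTable-class
#' @export
setMethod("featureMatrix", "FeatureTable", function(object) object@features)

#' @describeIn FeatureTable-class metadata accessor
#' @export
setGeneric("psmMeta", function(object) standardGeneric("psmMeta"))
#' @rdname FeatureTable-class
#' @export
setMethod("psmMeta", "FeatureTable", function(object) object@meta)

#' @describeIn FeatureTable-class feature name accessor
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname FeatureTable-class
#' @export
setMethod("featureNames", "FeatureTable",
          function(object) colnames(object@features))

#' @describeIn CalibrationResult-class selected collision energy
#' @param object A CalibrationResult.
#' @export
setGeneric("selectedCe", function(object) standardGeneric("selectedCe"))
#' @rdname CalibrationResult-class
#' @export
setMethod("selectedCe", "CalibrationResult", function(object) object@selectedCe)

#' @describeIn CalibrationResult-class calibration grid as a data.frame
#' @export
setGeneric("calibrationGrid", function(object) standardGeneric("calibrationGrid"))
#' @rdname CalibrationResult-class
#' @export
setMethod("calibrationGrid", "CalibrationResult", function(object) {
  data.frame(ce = object@grid, meanSpectralAngle = object@meanSa)
})

#' @describeIn GroundTruthBenchmark-class constructed database accessor
#' @param object A GroundTruthBenchmark.
#' @export
setGeneric("benchmarkDatabase", function(object) standardGeneric("benchmarkDatabase"))
#' @rdname GroundTruthBenchmark-class
#' @export
setMethod("benchmarkDatabase", "GroundTruthBenchmark",
          function(object) object@database)

#' @describeIn GroundTruthBenchmark-class truth map accessor
#' @export
setGeneric("truthMap", function(object) standardGeneric("truthMap"))
#' @rdname GroundTruthBenchmark-class
#' @export
setMethod("truthMap", "GroundTruthBenchmark", function(object) object@truthMap)

#' @describeIn GroundTruthBenchmark-class peptide label accessor
#' @export
setGeneric("peptideLabels", function(object) standardGeneric("peptideLabels"))
#' @rdname GroundTruthBenchmark-class
#' @export
setMethod("peptideLabels", "GroundTruthBenchmark", function(object) object@labels)

## ---- show methods ----

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum: scan", object@scanNumber, "from", object@sourceFile, "\n")
  cat("  precursor m/z", format(object@precursorMz, digits = 8),
      "charge", object@precursorCharge,
      "RT", format(object@retentionTime, digits = 5), "min\n")
  cat("  ", nrow(object@peaks), "peaks\n")
})

setMethod("show", "PredictedSpectrum", function(object) {
  cat("PredictedSpectrum:", object@peptide, "/", object@charge,
      "at CE", object@collisionEnergy, "\n")
  cat("  ", nrow(object@fragments), "fragments; iRT",
      format(object@irt, digits = 5), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@meta), "PSMs x",
      ncol(object@features), "features\n")
  cat("  targets:", sum(object@meta$label == 1L),
      " decoys:", sum(object@meta$label == -1L), "\n")
  cat("  features:", paste(utils::head(colnames(object@features), 8),
                           collapse = ", "),
      if (ncol(object@features) > 8) "...", "\n")
})

setMethod("show", "RtAlignment", function(object) {
  cat("RtAlignment: minutes =", format(object@slope, digits = 6), "* iRT +",
      format(object@intercept, digits = 6), "\n")
  cat("  residual sd", format(object@residualSd, digits = 4),
      "on", object@n, "PSMs\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult: selected CE", object@selectedCe,
      "(grid", min(object@grid), "..", max(object@grid), ")\n")
  cat("  mean spectral angle at optimum:",
      format(object@meanSa[match(object@selectedCe, object@grid)],
             digits = 5),
      "on", object@nPsmsUsed, "PSMs\n")
})

setMethod("show", "GroundTruthBenchmark", function(object) {
  lab <- object@labels$label
  cat("GroundTruthBenchmark:", length(object@database), "database entries\n")
  cat("  ", sum(lab == "discoverable"), "discoverable /",
      sum(lab == "undiscoverable"), "undiscoverable peptides;",
      nrow(object@truthMap), "mapped scans\n")
})

setMethod("show", "DeltaModel", function(object) {
  cat("DeltaModel: schema", object@schemaVersion, "with",
      length(object@featureNames), "features\n")
  if (!is.null(object@evaluation$r2))
    cat("  held-out r2:", format(object@evaluation$r2, digits = 4),
        "on", object@evaluation$n, "samples\n")
})
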