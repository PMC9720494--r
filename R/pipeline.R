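## End-to-end orchestration: ingest -> filter -> calibrate -> features ->
## rescore -> report.

#' Assemble a run configuration
#'
#' @param searchFiles Character vector of search-result paths.
#' @param engine Search engine dialect (\code{"maxquant"}, \code{"peaks"},
#'   \code{"mascot"}).
#' @param spectrumFiles Character vector of MGF paths.
#' @param predictions Either \code{"toy"} (use the built-in toy predictor)
#'   or a path to an MSP spectral library.
#' @param collisionEnergy Integer CE, or \code{"calibrate"} to select it on
#'   the data.
#' @param deltaMode \code{"off"}, \code{"oracle"} (brute-force deltas via
#'   the predictor) or \code{"model"} (requires \code{deltaModelPath}).
#' @param deltaModelPath Path to a saved delta model (for
#'   \code{deltaMode = "model"}).
#' @param affinityMode \code{"off"}, \code{"asValidation"} (binder
#'   percentages in the report only) or \code{"asFeature"} (adds the two
#'   %Rank feature columns).
#' @param rankTablePath Path to a %Rank table (required unless
#'   \code{affinityMode = "off"}).
#' @param fdrThreshold Reporting FDR threshold (default 0.01).
#' @param excludeFeatures Character vector of feature names to drop before
#'   rescoring.
#' @param truthFiles Optional list with \code{truth} and \code{labels}
#'   sidecar paths for precision-recall analysis.
#' @param tolerance Peak-matching tolerance in Th.
#' @param seed Integer seed.
#' @param outputDir Output directory for the report bundle.
#' @return A list of class \code{"runConfig"}.
#' @export
runConfig <- function(searchFiles, engine, spectrumFiles,
                      predictions = "toy",
                      collisionEnergy = "calibrate",
                      deltaMode = c("off", "oracle", "model"),
                      deltaModelPath = NULL,
                      affinityMode = c("off", "asValidation", "asFeature"),
                      rankTablePath = NULL,
                      fdrThreshold = 0.01,
                      excludeFeatures = character(0),
                      truthFiles = NULL,
                      tolerance = 0.02,
                      seed = 1L,
                      outputDir = tempfile("run")) {
  deltaMode <- match.arg(deltaMode)
  affinityMode <- match.arg(affinityMode)
  stopifnot(all(file.exists(searchFiles)), all(file.exists(spectrumFiles)))
  if (fdrThreshold <= 0 || fdrThreshold > 1) {
    stop("fdrThreshold must be in (0, 1]")
  }
  if (affinityMode != "off" && is.null(rankTablePath)) {
    stop("affinityMode '", affinityMode, "' requires rankTablePath")
  }
  if (deltaMode == "model" && is.null(deltaModelPath)) {
    stop("deltaMode 'model' requires deltaModelPath")
  }
  structure(list(
    searchFiles = searchFiles, engine = engine,
    spectrumFiles = spectrumFiles, predictions = predictions,
    collisionEnergy = collisionEnergy, deltaMode = deltaMode,
    deltaModelPath = deltaModelPath, affinityMode = affinityMode,
    rankTablePath = rankTablePath, fdrThreshold = fdrThreshold,
    excludeFeatures = excludeFeatures, truthFiles = truthFiles,
    tolerance = tolerance, seed = as.integer(seed), outputDir = outputDir
  ), class = c("runConfig", "list"))
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [runConfig()].
#' @return A run configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the core rescoring pipeline
#'
#' Executes ingestion, compatibility filtering, collision-energy calibration
#' (if requested), feature building (with delta and affinity blocks per
#' mode), semi-supervised rescoring, and identification counting; writes a
#' report bundle (CSV tables plus an HTML summary) to the output directory.
#' Rescoring is also run on the non-spectral baseline feature set
#' (engine score, peptide length, charge) so the spectral gain is always
#' quantified. Deterministic under the configured seed.
#'
#' @param config A [runConfig()] (or the path of a YAML file for
#'   [readRunConfig()]).
#' @return A list (report bundle): \code{psms}, \code{featureTable},
#'   \code{rescored}, \code{baselineRescored}, \code{identifications},
#'   \code{baselineIdentifications}, \code{calibration}, \code{featureList},
#'   \code{featureImportance}, \code{binderPercentages} (affinity modes),
#'   \code{prCurve}/\code{recallAt99Precision} (when truth sidecars are
#'   given), \code{outputDir}.
#' @export
runCore <- function(config) {
  if (is.character(config)) {
    config <- readRunConfig(config)
  }
  cfg <- config
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)

  psms <- .stage("ingest-search", {
    do.call(rbind, lapply(cfg$searchFiles, readSearchResults,
                          engine = cfg$engine))
  })
  spectra <- .stage("ingest-spectra", {
    sp <- unlist(lapply(cfg$spectrumFiles, readMgf), recursive = FALSE)
    names(sp) <- .spectrumKey(sp)
    sp
  })
  filt <- .stage("filter", filterCompatible(psms))
  kept <- filt$kept
  if (nrow(kept) == 0L) {
    stop("stage 'filter': no compatible PSMs left")
  }

  predictor <- NULL
  mspLibrary <- NULL
  if (identical(cfg$predictions, "toy")) {
    predictor <- toyPredictSpectrum
  } else {
    mspLibrary <- .stage("ingest-predictions", readMsp(cfg$predictions))
  }

  calibration <- NULL
  ce <- cfg$collisionEnergy
  if (identical(ce, "calibrate")) {
    if (is.null(predictor)) {
      stop("stage 'calibrate': CE calibration needs a predictor; ",
           "give a fixed collisionEnergy with an MSP library")
    }
    calibration <- .stage("calibrate", {
      calibrateCollisionEnergy(kept, spectra, predictor,
                               tolerance = cfg$tolerance)
    })
    ce <- selectedCe(calibration)
  }
  ce <- as.integer(ce)

  predictions <- .stage("predict", {
    keys <- unique(paste(kept$peptide, kept$charge, sep = "/"))
    if (!is.null(predictor)) {
      out <- lapply(keys, function(k) {
        parts <- strsplit(k, "/", fixed = TRUE)[[1]]
        predictor(parts[1], as.integer(parts[2]), ce)
      })
      names(out) <- keys
      out
    } else {
      wanted <- paste0(keys, "/", ce)
      found <- mspLibrary[intersect(wanted, names(mspLibrary))]
      names(found) <- sub("/[0-9]+$", "", names(found))
      found
    }
  })

  rtAlignment <- .stage("rt-align", {
    hi <- kept[kept$label == 1L, , drop = FALSE]
    hi <- utils::head(hi[order(hi$engineScore, decreasing = TRUE), ],
                      max(10L, min(100L, nrow(hi))))
    irt <- vapply(paste(hi$peptide, hi$charge, sep = "/"),
                  function(k) predictions[[k]]@irt, numeric(1))
    fitRtAlignment(hi$retentionTime, irt)
  })

  deltaSummaries <- NULL
  if (cfg$deltaMode != "off") {
    deltaSummaries <- .stage("delta", {
      specKey <- paste(kept$sourceFile, kept$scanNumber, sep = "/")
      model <- if (cfg$deltaMode == "model") {
        loadDeltaModel(cfg$deltaModelPath)
      } else NULL
      rows <- lapply(seq_len(nrow(kept)), function(i) {
        deltas <- if (cfg$deltaMode == "oracle") {
          deltaOracle(kept[i, , drop = FALSE], spectra[[specKey[i]]],
                      predictor, ce, cfg$tolerance)$delta
        } else {
          predictDeltas(model, kept$peptide[i], kept$charge[i], ce)$delta
        }
        deltaSummary(deltas)
      })
      as.data.frame(do.call(rbind, rows))
    })
  }

  rankTable <- NULL
  if (cfg$affinityMode != "off") {
    rankTable <- .stage("rank-table", readRankTable(cfg$rankTablePath))
  }

  featureTable <- .stage("features", {
    buildFeatureTable(kept, spectra, predictions, rtAlignment,
                      deltaSummaries = deltaSummaries,
                      rankTable = if (cfg$affinityMode == "asFeature")
                        rankTable else NULL,
                      tolerance = cfg$tolerance)
  })
  if (length(cfg$excludeFeatures)) {
    featureTable <- .stage("exclude-features", {
      excludeFeatures(featureTable, cfg$excludeFeatures)
    })
  }

  rescored <- .stage("rescore", {
    semiSupervisedRescore(featureTable, seed = cfg$seed)
  })
  ids <- identificationsAtFdr(rescored, cfg$fdrThreshold)

  ## non-spectral baseline on the same PSMs
  baselineFeatures <- intersect(
    c("engineScore", "peptideLength", paste0("charge", 1:6)),
    featureNames(featureTable))
  baseline <- .stage("rescore-baseline", {
    ft <- FeatureTable(psmMeta(featureTable),
                       featureMatrix(featureTable)[, baselineFeatures,
                                                   drop = FALSE])
    semiSupervisedRescore(ft, seed = cfg$seed)
  })
  baselineIds <- identificationsAtFdr(baseline, cfg$fdrThreshold)

  weights <- attr(rescored, "featureWeights")
  importance <- sort(colMeans(abs(weights)), decreasing = TRUE)

  bundle <- list(
    psms = kept, rejected = filt$rejected,
    featureTable = featureTable,
    rescored = rescored, baselineRescored = baseline,
    identifications = ids, baselineIdentifications = baselineIds,
    calibration = calibration, collisionEnergy = ce,
    featureList = featureNames(featureTable),
    featureImportance = importance,
    outputDir = cfg$outputDir
  )

  if (cfg$affinityMode != "off") {
    bundle$binderPercentages <- .stage("binder-validation", {
      idPeps <- stripModifications(
        rescored$peptide[rescored$label == 1L &
                           rescored$qValue <= cfg$fdrThreshold])
      percentPredictedBinders(idPeps, rankTable)
    })
  }

  if (!is.null(cfg$truthFiles)) {
    bundle <- c(bundle, .stage("pr-analysis", {
      truth <- utils::read.table(cfg$truthFiles$truth, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
      names(truth) <- c("sourceFile", "scanNumber", "peptide")
      labels <- utils::read.table(cfg$truthFiles$labels, sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
      benchmark <- new("GroundTruthBenchmark",
                       database = Biostrings::AAStringSet(character(0)),
                       truthMap = truth, labels = labels)
      curve <- prCurve(rescored, benchmark)
      baseCurve <- prCurve(baseline, benchmark)
      list(prCurve = curve,
           baselinePrCurve = baseCurve,
           recallAt99Precision = recallAtPrecision(curve, 0.99),
           baselineRecallAt99Precision = recallAtPrecision(baseCurve, 0.99))
    }))
  }

  .writeReportBundle(bundle, cfg)
  bundle
}

#' @noRd
.df2html <- function(df, maxRows = 25L) {
  df <- utils::head(df, maxRows)
  cells <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table border='1'><tr>",
         paste0("<th>", names(df), "</th>", collapse = ""),
         "</tr>", paste(cells, collapse = "\n"), "</table>")
}

#' @noRd
## Every table in the report has a machine-readable CSV twin.
.writeReportBundle <- function(bundle, cfg) {
  out <- cfg$outputDir
  utils::write.csv(bundle$rescored, file.path(out, "rescored_psms.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$baselineRescored,
                   file.path(out, "baseline_psms.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(feature = names(bundle$featureImportance),
               meanAbsWeight = as.numeric(bundle$featureImportance)),
    file.path(out, "feature_importance.csv"), row.names = FALSE)
  writeLines(bundle$featureList, file.path(out, "feature_list.txt"))
  if (!is.null(bundle$calibration)) {
    utils::write.csv(calibrationGrid(bundle$calibration),
                     file.path(out, "calibration.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$prCurve)) {
    utils::write.csv(bundle$prCurve, file.path(out, "pr_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$baselinePrCurve,
                     file.path(out, "pr_curve_baseline.csv"),
                     row.names = FALSE)
  }
  summaryTab <- data.frame(
    metric = c("psms_at_fdr", "peptides_at_fdr",
               "baseline_psms_at_fdr", "collision_energy"),
    value = c(bundle$identifications$psms,
              bundle$identifications$peptides,
              bundle$baselineIdentifications$psms,
              bundle$collisionEnergy)
  )
  if (!is.null(bundle$binderPercentages)) {
    summaryTab <- rbind(summaryTab, data.frame(
      metric = c("percent_binders", "percent_strong_binders"),
      value = c(bundle$binderPercentages$percentBinders,
                bundle$binderPercentages$percentStrong)))
  }
  if (!is.null(bundle$recallAt99Precision)) {
    summaryTab <- rbind(summaryTab, data.frame(
      metric = c("recall_at_99_precision", "baseline_recall_at_99_precision"),
      value = c(bundle$recallAt99Precision,
                bundle$baselineRecallAt99Precision)))
  }
  utils::write.csv(summaryTab, file.path(out, "summary.csv"),
                   row.names = FALSE)
  html <- paste0(
    "<html><head><title>Rescoring report</title></head><body>",
    "<h1>Rescoring report</h1>",
    "<h2>Summary</h2>", .df2html(summaryTab),
    "<h2>Feature importance (mean |discriminant weight|)</h2>",
    .df2html(data.frame(feature = names(bundle$featureImportance),
                        weight = sprintf("%.4f",
                                         bundle$featureImportance))),
    "<h2>Feature list</h2><pre>",
    paste(bundle$featureList, collapse = "\n"),
    "</pre></body></html>")
  writeLines(html, file.path(out, "report.html"))
  invisible(out)
}

#' Export mirrored spectra for pair plots
#'
#' For selected PSMs, exports the experimental peak list (up), the predicted
#' fragment peaks (down), matched-fragment annotations and the spectral
#' angle, as a JSON file per PSM; rendering is left to external tools.
#' Selection is by (source file, scan number) pairs, as in a
#' peptides-of-interest CSV.
#'
#' @param selection data.frame with columns \code{sourceFile},
#'   \code{scanNumber}.
#' @param psms PSM data.frame.
#' @param spectra Named spectrum list.
#' @param predictions Named prediction list (\code{"<peptide>/<charge>"}).
#' @param dir Output directory.
#' @param tolerance Peak-matching tolerance in Th.
#' @return Invisibly, the list of exported structures (one per PSM).
#' @export
exportPairplotData <- function(selection, psms, spectra, predictions,
                               dir = tempfile("pairplot"),
                               tolerance = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!nrow(selection)) {
    return(invisible(list()))
  }
  selKey <- paste(selection$sourceFile, selection$scanNumber, sep = "/")
  psmKey <- paste(psms$sourceFile, psms$scanNumber, sep = "/")
  out <- list()
  for (k in selKey) {
    rows <- which(psmKey == k)
    if (!length(rows)) {
      stop("unknown PSM selection: ", k)
    }
    for (i in rows) {
      pep <- psms$peptide[i]
      pred <- predictions[[paste(pep, psms$charge[i], sep = "/")]]
      sp <- spectra[[k]]
      fragTab <- fragmentMzTable(pep, psms$charge[i])
      matches <- matchPeaks(sp, fragTab, tolerance)
      al <- .alignedIntensities(pred, matches)
      fr <- pred@fragments
      key <- paste(fragTab$series, fragTab$ordinal, fragTab$charge)
      fr$mz <- fragTab$mz[match(paste(fr$series, fr$ordinal, fr$charge),
                                key)]
      obj <- list(
        peptide = pep,
        charge = psms$charge[i],
        spectralAngle = spectralAngle(al$predicted, al$observed),
        experimental = as.data.frame(peaks(sp)),
        predicted = fr[, c("series", "ordinal", "charge", "mz",
                           "intensity")],
        matched = matches[matches$matched,
                          c("series", "ordinal", "charge", "mz",
                            "peakMz", "mzError")]
      )
      fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", k), "_",
                                  gsub("[^A-Za-z0-9]", "_", pep), ".json"))
      jsonlite::write_json(obj, fn, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      out[[length(out) + 1L]] <- obj
    }
  }
  invisible(out)
}
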