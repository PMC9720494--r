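## Adjacent-residue-swap sensitivity ("delta").
##
## The delta of a fragmentation site is the change in spectral angle against
## the experimental spectrum when the two residues flanking that site are
## exchanged: delta = SA(predict(swapped), spectrum) - SA(predict(original),
## spectrum). Sites where the spectral predictor cannot discriminate residue
## order have delta near 0; such peptides are easy to misassign and should be
## identified with less confidence. A gradient-boosted regressor predicts
## deltas cheaply from local sequence features so that no extra spectral
## predictions are needed at rescoring time.

.DELTA_SCHEMA_VERSION <- "delta-features-1"
.PAD_TOKEN <- "-"

#' Swap two adjacent residues of a peptide
#'
#' Residues at positions \code{site} and \code{site + 1} are exchanged;
#' modifications travel with their residues.
#'
#' @param peptide Peptide string in bracketed notation.
#' @param site 1-based fragmentation site, 1..L-1.
#' @return The swapped peptide string.
#' @examples
#' swapAdjacent("MATYGWNLVK", 2)  # "MTAYGWNLVK"
#' @export
swapAdjacent <- function(peptide, site) {
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  if (site < 1L || site > p$length - 1L) {
    stop("site ", site, " out of range 1..", p$length - 1L)
  }
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  chars[c(site, site + 1L)] <- chars[c(site + 1L, site)]
  mods <- p$mods
  if (nrow(mods)) {
    atSite <- mods$position == site
    atNext <- mods$position == site + 1L
    mods$position[atSite] <- site + 1L
    mods$position[atNext] <- site
  }
  peptideString(list(sequence = paste(chars, collapse = ""),
                     length = p$length, mods = mods))
}

#' Brute-force deltas for every fragmentation site of a PSM
#'
#' Calls the spectral predictor for the original and every swapped sequence
#' and scores each against the experimental spectrum.
#'
#' @param psm One-row PSM data.frame (columns \code{peptide}, \code{charge}).
#' @param spectrum The experimental [Spectrum-class].
#' @param predictor Function \code{(peptide, charge, ce) ->}
#'   [PredictedSpectrum-class].
#' @param ce Collision energy passed to the predictor.
#' @param tolerance Peak-matching tolerance in Th.
#' @param sites Optional integer vector restricting the evaluated sites
#'   (default: every site 1..L-1).
#' @return data.frame with columns \code{site} and \code{delta}. Sites whose
#'   swapped sequence the predictor rejects are skipped (with a message).
#' @export
deltaOracle <- function(psm, spectrum, predictor, ce, tolerance = 0.02,
                        sites = NULL) {
  peptide <- psm$peptide[1]
  charge <- psm$charge[1]
  L <- parsePeptide(peptide)$length
  saOf <- function(pep) {
    pred <- predictor(pep, charge, ce)
    matches <- matchPeaks(spectrum, fragmentMzTable(pep, charge), tolerance)
    al <- .alignedIntensities(pred, matches)
    spectralAngle(al$predicted, al$observed)
  }
  saOrig <- saOf(peptide)
  if (is.null(sites)) {
    sites <- seq_len(L - 1L)
  }
  out <- data.frame(site = integer(0), delta = numeric(0))
  for (s in sites) {
    swapped <- swapAdjacent(peptide, s)
    if (swapped == peptide) {
      out <- rbind(out, data.frame(site = s, delta = 0))
      next
    }
    d <- tryCatch(saOf(swapped) - saOrig, error = function(e) {
      message("site ", s, " of ", peptide, " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(d)) {
      out <- rbind(out, data.frame(site = s, delta = d))
    }
  }
  out
}

#' @noRd
## One-hot / numeric feature vector for a (peptide, site, charge, ce) swap.
## Local window residues at site-1..site+2 (padding token at the termini),
## site index from both termini, peptide length, precursor charge, collision
## energy, the monoisotopic masses of the swapped pair, their absolute mass
## difference and an identical-pair indicator.
.deltaFeatureRow <- function(peptide, site, charge, ce) {
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  L <- p$length
  window <- vapply(site + (-1L:2L), function(j) {
    if (j < 1L || j > L) .PAD_TOKEN else chars[j]
  }, character(1))
  alphabet <- c(names(RESIDUE_MASSES), .PAD_TOKEN)
  onehot <- unlist(lapply(seq_along(window), function(w) {
    v <- as.numeric(alphabet == window[w])
    names(v) <- paste0("w", w, "_", alphabet)
    v
  }))
  m1 <- unname(RESIDUE_MASSES[chars[site]])
  m2 <- unname(RESIDUE_MASSES[chars[site + 1L]])
  c(onehot,
    siteFromN = site,
    siteFromC = L - site,
    peptideLength = L,
    precursorCharge = charge,
    collisionEnergy = ce,
    massLeft = m1,
    massRight = m2,
    absMassDiff = abs(m1 - m2),
    pairIdentical = as.numeric(chars[site] == chars[site + 1L]))
}

#' @noRd
.deltaFeatureNames <- function() {
  names(.deltaFeatureRow("PEPTIDEK", 1L, 2L, 30L))
}

#' Sample delta training points from PSMs
#'
#' For each PSM, \code{nSites} distinct fragmentation sites are drawn
#' uniformly without replacement (all sites when the peptide has fewer), and
#' the oracle delta is computed for each, yielding one training sample per
#' site.
#'
#' @param psms PSM data.frame (compatibility-filtered).
#' @param spectra Named list of [Spectrum-class]
#'   (\code{"<sourceFile>/<scanNumber>"}).
#' @param predictor Spectral predictor function.
#' @param ce Collision energy.
#' @param nSites Sites sampled per PSM (default 5).
#' @param seed Integer seed; sampling is reproducible.
#' @return List with \code{features} (matrix), \code{delta} (numeric),
#'   \code{peptide} (character, for peptide-disjoint splitting) and
#'   \code{site}.
#' @export
sampleTrainingPoints <- function(psms, spectra, predictor, ce,
                                 nSites = 5L, seed = 1L) {
  rng <- .restoreSeed(seed)
  on.exit(rng())
  featRows <- list()
  deltas <- numeric(0)
  peps <- character(0)
  siteIdx <- integer(0)
  specKey <- paste(psms$sourceFile, psms$scanNumber, sep = "/")
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    L <- parsePeptide(pep)$length
    sites <- seq_len(L - 1L)
    if (length(sites) > nSites) {
      sites <- sort(sample(sites, nSites))
    }
    oracle <- deltaOracle(psms[i, , drop = FALSE], spectra[[specKey[i]]],
                          predictor, ce, sites = sites)
    for (k in seq_len(nrow(oracle))) {
      featRows[[length(featRows) + 1L]] <-
        .deltaFeatureRow(pep, oracle$site[k], psms$charge[i], ce)
    }
    deltas <- c(deltas, oracle$delta)
    peps <- c(peps, rep(pep, nrow(oracle)))
    siteIdx <- c(siteIdx, oracle$site)
  }
  list(features = do.call(rbind, featRows), delta = deltas,
       peptide = peps, site = siteIdx)
}

#' Train the delta predictor
#'
#' Gradient-boosted tree regression (xgboost) of oracle deltas on local swap
#' features. Defaults are the tuned hyperparameters: maximum tree depth 16,
#' minimum child weight 2, learning rate 0.15, gamma 0.1, column subsample
#' 0.9. The train/test split must be peptide-disjoint; overlap is an error.
#'
#' @param samples Output of [sampleTrainingPoints()] (>= 1000 samples).
#' @param testFraction Fraction of peptides held out for evaluation.
#' @param nrounds Number of boosting rounds.
#' @param maxDepth,minChildWeight,eta,gamma,colsampleBytree xgboost
#'   hyperparameters.
#' @param seed Integer seed.
#' @return A [DeltaModel-class] with a held-out r2 in its evaluation slot.
#' @export
trainDeltaModel <- function(samples, testFraction = 0.2, nrounds = 150L,
                            maxDepth = 16L, minChildWeight = 2,
                            eta = 0.15, gamma = 0.1, colsampleBytree = 0.9,
                            seed = 1L) {
  n <- length(samples$delta)
  if (n < 1000L) {
    stop("need >= 1000 delta samples to train (got ", n, ")")
  }
  rng <- .restoreSeed(seed)
  on.exit(rng())
  peps <- unique(samples$peptide)
  testPeps <- sample(peps, max(1L, round(testFraction * length(peps))))
  isTest <- samples$peptide %in% testPeps
  if (any(samples$peptide[isTest] %in% samples$peptide[!isTest])) {
    stop("peptide overlap between train and test split")
  }
  X <- samples$features
  y <- samples$delta
  dtrain <- xgboost::xgb.DMatrix(X[!isTest, , drop = FALSE],
                                 label = y[!isTest])
  booster <- xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror",
      max_depth = maxDepth,
      min_child_weight = minChildWeight,
      eta = eta,
      gamma = gamma,
      colsample_bytree = colsampleBytree,
      nthread = 1
    ),
    data = dtrain,
    nrounds = nrounds,
    verbose = 0
  )
  predTest <- stats::predict(booster,
                             xgboost::xgb.DMatrix(X[isTest, , drop = FALSE]))
  yTest <- y[isTest]
  r2 <- 1 - sum((yTest - predTest)^2) / sum((yTest - mean(yTest))^2)
  new("DeltaModel",
      booster = xgboost::xgb.save.raw(booster),
      schemaVersion = .DELTA_SCHEMA_VERSION,
      featureNames = colnames(X),
      evaluation = list(r2 = r2, n = sum(isTest)))
}

#' Predict deltas for every fragmentation site of a peptide
#'
#' Uses the trained lightweight model; no spectral predictions are made.
#'
#' @param model A [DeltaModel-class].
#' @param peptide Peptide string.
#' @param charge Precursor charge.
#' @param ce Collision energy.
#' @return data.frame with columns \code{site}, \code{delta} (one row per
#'   site 1..L-1).
#' @export
predictDeltas <- function(model, peptide, charge, ce) {
  if (!is(model, "DeltaModel") || length(model@booster) == 0L) {
    stop("untrained delta model")
  }
  if (model@schemaVersion != .DELTA_SCHEMA_VERSION) {
    stop("delta model schema mismatch: model has '", model@schemaVersion,
         "', this package expects '", .DELTA_SCHEMA_VERSION, "'")
  }
  L <- parsePeptide(peptide)$length
  sites <- seq_len(L - 1L)
  X <- do.call(rbind, lapply(sites, function(s) {
    .deltaFeatureRow(peptide, s, charge, ce)
  }))
  booster <- xgboost::xgb.load.raw(model@booster)
  data.frame(site = sites,
             delta = stats::predict(booster, xgboost::xgb.DMatrix(X)))
}

#' Save / load a delta model
#'
#' The model is serialised to a single file embedding the feature-schema
#' version; [loadDeltaModel()] refuses a file with a mismatching schema.
#'
#' @param model A [DeltaModel-class].
#' @param path File path.
#' @return \code{path} (save) or the [DeltaModel-class] (load).
#' @export
saveDeltaModel <- function(model, path) {
  obj <- list(booster = model@booster,
              schemaVersion = model@schemaVersion,
              featureNames = model@featureNames,
              evaluation = model@evaluation)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveDeltaModel
#' @export
loadDeltaModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schemaVersion, .DELTA_SCHEMA_VERSION)) {
    stop("delta model schema mismatch: file has '", obj$schemaVersion,
         "', this package expects '", .DELTA_SCHEMA_VERSION, "'")
  }
  new("DeltaModel", booster = obj$booster,
      schemaVersion = obj$schemaVersion,
      featureNames = obj$featureNames,
      evaluation = obj$evaluation)
}

#' Summarise a site-wise delta profile into the 7 rescoring features
#'
#' Order statistics of the deltas (minimum, maximum, median, first and third
#' quartile with linear-interpolation quantiles) plus the fractions of
#' deltas strictly above -0.1 and strictly above 0.
#'
#' @param deltas Numeric vector of deltas (>= 1 value).
#' @return Named numeric vector: \code{deltaMin}, \code{deltaMax},
#'   \code{deltaMedian}, \code{deltaQ1}, \code{deltaQ3},
#'   \code{deltaFracAboveM01}, \code{deltaFracAbove0}.
#' @examples
#' deltaSummary(c(-0.3, -0.05, 0.01))
#' @export
deltaSummary <- function(deltas) {
  if (!length(deltas)) {
    stop("empty delta list")
  }
  q <- stats::quantile(deltas, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(deltaMin = min(deltas),
    deltaMax = max(deltas),
    deltaMedian = q[2],
    deltaQ1 = q[1],
    deltaQ3 = q[3],
    deltaFracAboveM01 = mean(deltas > -0.1),
    deltaFracAbove0 = mean(deltas > 0))
}
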