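## Target-decoy q-values and the self-contained semi-supervised rescorer.

#' Target-decoy competition q-values
#'
#' At each target score s the estimated FDR is
#' \code{(1 + #decoys >= s) / max(1, #targets >= s)} (the +1 decoy correction
#' keeps small sets conservative); q-values are the running minimum of the
#' estimate from the worst score to the best, capped at 1.
#'
#' @param scores Numeric vector of final PSM scores (higher = better).
#' @param labels Integer vector, +1 target / -1 decoy.
#' @return data.frame with columns \code{score}, \code{label},
#'   \code{qValue}, in the input order.
#' @export
tdcQValues <- function(scores, labels) {
  if (!length(scores)) {
    stop("empty input")
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ")
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite")
  }
  if (!any(labels == 1L)) {
    stop("need at least one target PSM")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  nDecoyAbove <- cumsum(lab == -1L)
  nTargetAbove <- cumsum(lab == 1L)
  ## scores tie-safe: at equal scores, all share the counts at the tie block
  ## end (every member of the block is ">= s")
  s <- scores[ord]
  runs <- rle(s)
  blockEnd <- rep(cumsum(runs$lengths), runs$lengths)
  fdr <- (1 + nDecoyAbove[blockEnd]) / pmax(1, nTargetAbove[blockEnd])
  fdr <- pmin(fdr, 1)
  ## monotonize from worst to best
  q <- rev(cummin(rev(fdr)))
  out <- data.frame(score = scores, label = labels,
                    qValue = NA_real_)
  out$qValue[ord] <- q
  out
}

#' Count identifications below an FDR threshold
#'
#' @param qtab A q-value table (data.frame with \code{qValue}, \code{label},
#'   and optionally \code{peptide}).
#' @param threshold FDR threshold in (0, 1] (default 0.01).
#' @return List with \code{psms} (target PSM count at q <= threshold) and
#'   \code{peptides} (unique target peptide count; NA when the table has no
#'   peptide column).
#' @export
identificationsAtFdr <- function(qtab, threshold = 0.01) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  pass <- qtab$label == 1L & qtab$qValue <= threshold
  peptides <- if ("peptide" %in% names(qtab)) {
    length(unique(stripModifications(qtab$peptide[pass])))
  } else {
    NA_integer_
  }
  list(psms = sum(pass), peptides = peptides)
}

#' @noRd
## Identifications at a q threshold from raw (score, label) vectors.
.idsAt <- function(scores, labels, threshold) {
  q <- tdcQValues(scores, labels)
  sum(q$label == 1L & q$qValue <= threshold)
}

#' @noRd
## Ridge logistic discriminant on standardized features. Returns a scoring
## function plus the weight vector (on the standardized scale).
.fitLinearScorer <- function(X, y, lambda) {
  if (ncol(X) == 1L) {
    ## glmnet needs >= 2 columns; a single-feature scorer is a plain
    ## logistic fit (orientation is all that matters in 1D)
    fit1 <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    w <- fit1$coefficients[2]
    b <- fit1$coefficients[1]
    if (!is.finite(w)) w <- 0
    if (!is.finite(b)) b <- 0
    return(list(weights = unname(w), intercept = unname(b),
                score = function(Z) as.numeric(Z * w + b)))
  }
  ## small positive sets in early iterations trigger glmnet's class-size
  ## warning; the iteration recovers, so keep the log clean
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE))
  w <- as.numeric(fit$beta)
  b <- as.numeric(fit$a0)
  list(weights = w, intercept = b,
       score = function(Z) as.numeric(Z %*% w + b))
}

#' Semi-supervised cross-validated rescoring
#'
#' PSMs are split into folds by scan (all PSMs of one scan share a fold, so
#' chimeric matches never straddle folds). For each fold, a linear
#' discriminant (L2-regularised logistic scorer) is trained iteratively on
#' the other folds: positives are targets at \code{q <= trainFdr} under the
#' current score, negatives are all decoys; after each iteration the score
#' is the discriminant output. The held-out fold is then scored with the
#' best-performing weights; per-fold scores are normalised (decoy median to
#' 0, the score at the q = trainFdr threshold to 1) before merging, and
#' final q-values are computed by [tdcQValues()]. No training-set subsetting
#' is ever applied.
#'
#' @param table A [FeatureTable-class] (must contain an \code{engineScore}
#'   feature, the initial direction).
#' @param folds Number of cross-validation folds (default 3).
#' @param trainFdr Training FDR threshold for selecting positives
#'   (default 0.01).
#' @param iterations Training iterations per fold (default 10).
#' @param seed Integer seed; the procedure is deterministic under it.
#' @return data.frame with columns \code{specId}, \code{scanNumber},
#'   \code{sourceFile}, \code{peptide}, \code{proteins}, \code{score},
#'   \code{label}, \code{qValue}, \code{fold}. Attribute
#'   \code{"featureWeights"}: matrix of per-fold discriminant weights
#'   (standardized scale).
#' @export
semiSupervisedRescore <- function(table, folds = 3L, trainFdr = 0.01,
                                  iterations = 10L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  meta <- psmMeta(table)
  X <- featureMatrix(table)
  n <- nrow(X)
  if (n < folds * 20L) {
    stop("too few PSMs (", n, ") for ", folds, "-fold rescoring")
  }
  if (!"engineScore" %in% colnames(X)) {
    stop("feature table must contain engineScore")
  }
  labels <- meta$label
  ## fold assignment by scan-key hash (deterministic, scan-coherent)
  scanKey <- paste(meta$sourceFile, meta$scanNumber, sep = "/")
  foldOf <- vapply(scanKey, function(k) {
    .stableHashInt(paste0(k, "#", seed), folds) + 1
  }, numeric(1))
  for (k in seq_len(folds)) {
    if (!any(labels[foldOf == k] == -1L)) {
      stop("fold ", k, " contains no decoys; use fewer folds")
    }
  }
  finalScore <- numeric(n)
  weightList <- list()
  for (k in seq_len(folds)) {
    trainIdx <- which(foldOf != k)
    testIdx <- which(foldOf == k)
    Xtr <- X[trainIdx, , drop = FALSE]
    ytr <- labels[trainIdx]
    ## per-fold standardization from training statistics only
    mu <- colMeans(Xtr)
    sdev <- apply(Xtr, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    Ztr <- scale(Xtr, center = mu, scale = sdev)
    currentScore <- Ztr[, "engineScore"]
    ## lambda chosen once per fold on a nested scan-level split
    innerKey <- scanKey[trainIdx]
    innerHalf <- vapply(innerKey, function(kk) {
      .stableHashInt(paste0(kk, "@inner", seed), 2L)
    }, numeric(1))
    lambdaGrid <- c(0.01, 0.1, 1)
    lambda <- .chooseLambda(Ztr, ytr, currentScore, innerHalf, lambdaGrid,
                            trainFdr)
    best <- list(ids = -1L, fit = NULL)
    for (it in seq_len(iterations)) {
      pos <- which(ytr == 1L &
                     tdcQValues(currentScore, ytr)$qValue <= trainFdr)
      if (length(pos) < 5L) {
        ## too few confident positives at this threshold: fall back to the
        ## highest-scoring targets so training can bootstrap
        tIdx <- which(ytr == 1L)
        pos <- tIdx[order(currentScore[tIdx], decreasing = TRUE)][
          seq_len(min(10L, length(tIdx)))]
      }
      neg <- which(ytr == -1L)
      sel <- c(pos, neg)
      ysel <- c(rep(1, length(pos)), rep(0, length(neg)))
      fit <- .fitLinearScorer(Ztr[sel, , drop = FALSE], ysel, lambda)
      currentScore <- fit$score(Ztr)
      ids <- .idsAt(currentScore, ytr, trainFdr)
      if (ids > best$ids) {
        best <- list(ids = ids, fit = fit)
      }
    }
    Zte <- scale(X[testIdx, , drop = FALSE], center = mu, scale = sdev)
    sTest <- best$fit$score(Zte)
    ## per-fold normalization: decoy median -> 0, q = trainFdr score -> 1
    dMed <- stats::median(sTest[labels[testIdx] == -1L])
    qTest <- tdcQValues(sTest, labels[testIdx])
    passing <- sTest[labels[testIdx] == 1L & qTest$qValue <= trainFdr]
    tScore <- if (length(passing)) min(passing) else max(sTest)
    denom <- tScore - dMed
    if (!is.finite(denom) || abs(denom) < 1e-12) {
      denom <- 1
    }
    finalScore[testIdx] <- (sTest - dMed) / denom
    w <- best$fit$weights
    names(w) <- colnames(X)
    weightList[[k]] <- w
  }
  q <- tdcQValues(finalScore, labels)
  out <- data.frame(
    specId = meta$specId,
    scanNumber = meta$scanNumber,
    sourceFile = meta$sourceFile,
    peptide = meta$peptide,
    proteins = meta$proteins,
    score = finalScore,
    label = labels,
    qValue = q$qValue,
    fold = foldOf,
    stringsAsFactors = FALSE
  )
  attr(out, "featureWeights") <- do.call(rbind, weightList)
  out
}

#' @noRd
## Nested lambda selection: train on inner half 0, count identifications at
## trainFdr on inner half 1; ties to the largest lambda (most regularised).
.chooseLambda <- function(Z, y, initScore, innerHalf, lambdaGrid, trainFdr) {
  trIdx <- which(innerHalf == 0)
  teIdx <- which(innerHalf == 1)
  if (length(teIdx) < 10L || !any(y[teIdx] == -1L) ||
      !any(y[trIdx] == -1L) || sum(y[trIdx] == 1L) < 10L) {
    return(lambdaGrid[2])
  }
  pos <- trIdx[y[trIdx] == 1L &
                 tdcQValues(initScore[trIdx], y[trIdx])$qValue <= trainFdr]
  if (length(pos) < 5L) {
    tIdx <- trIdx[y[trIdx] == 1L]
    pos <- tIdx[order(initScore[tIdx], decreasing = TRUE)][
      seq_len(min(10L, length(tIdx)))]
  }
  neg <- trIdx[y[trIdx] == -1L]
  sel <- c(pos, neg)
  ysel <- c(rep(1, length(pos)), rep(0, length(neg)))
  idsPer <- vapply(lambdaGrid, function(lam) {
    fit <- .fitLinearScorer(Z[sel, , drop = FALSE], ysel, lam)
    .idsAt(fit$score(Z[teIdx, , drop = FALSE]), y[teIdx], trainFdr)
  }, numeric(1))
  lambdaGrid[max(which(idsPer == max(idsPer)))]
}

#' Rescore from externally computed scores
#'
#' Compatibility path for an external rescoring engine: given a
#' tab-separated score file with columns \code{specId} and \code{score},
#' joins the scores onto a feature table's PSMs and computes target-decoy
#' q-values only.
#'
#' @param table A [FeatureTable-class] (provides labels and identities).
#' @param scoreFile Tab-separated file with columns \code{specId},
#'   \code{score}.
#' @return A q-value table as from [semiSupervisedRescore()] (without fold
#'   or weight information).
#' @export
rescoreFromExternalScores <- function(table, scoreFile) {
  meta <- psmMeta(table)
  sc <- utils::read.table(scoreFile, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  idx <- match(meta$specId, sc$specId)
  if (any(is.na(idx))) {
    stop("external score file misses ", sum(is.na(idx)), " PSMs")
  }
  scores <- sc$score[idx]
  q <- tdcQValues(scores, meta$label)
  data.frame(specId = meta$specId, scanNumber = meta$scanNumber,
             sourceFile = meta$sourceFile, peptide = meta$peptide,
             proteins = meta$proteins, score = scores, label = meta$label,
             qValue = q$qValue, stringsAsFactors = FALSE)
}
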