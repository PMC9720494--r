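## Deterministic toy spectral predictor.
##
## A stand-in satisfying the spectral-predictor contract so that every part
## of the pipeline (calibration, features, delta sensitivity, benchmarks)
## is testable without an external deep-learning predictor. Fragment
## intensities are derived from a version-pinned mixing hash of the local
## residue pair (with a smaller position-dependent component), so
## predictions are stable across platforms, change whenever swapped
## residues differ, and are learnable from local sequence features. The
## collision-energy response is per fragment: each fragment's intensity is
## scaled by a Gaussian in (ce - optimum) where the optimum carries a
## fragment-specific offset around the peptide-level optimum; this makes
## spectral *shape* (not just scale) depend on CE, so the spectral angle
## against a spectrum acquired at some CE peaks at that CE.

## Cache of the CE-independent base table per sequence: the hashes are pure
## functions of the sequence, so caching only saves recomputation (results
## are identical with or without it). Bounded by clearing when large.
.toyCache <- new.env(parent = emptyenv())

#' @noRd
.toyBaseTable <- function(sequence) {
  hit <- .toyCache[[sequence]]
  if (!is.null(hit)) {
    return(hit)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  ceOpt <- 26 + .stableHashInt(sequence, 5)
  sites <- seq_len(L - 1L)
  series <- rep(c("b", "y"), each = L - 1L)
  siteIdx <- c(sites, sites)
  pair <- paste0(chars[siteIdx], chars[siteIdx + 1L])
  base <- numeric(2L * (L - 1L))
  ceOff <- numeric(2L * (L - 1L))
  for (k in seq_along(base)) {
    ## intensity mostly from the residue pair, partly from its position
    base[k] <- 0.7 * stableHash(pair[k], series[k]) +
      0.3 * stableHash(pair[k], series[k], siteIdx[k])
    ## per-fragment CE optimum within +/-4 of the peptide optimum
    ceOff[k] <- .stableHashInt(paste(pair[k], series[k], siteIdx[k], "ce"),
                               9) - 4
  }
  base[series == "y"] <- base[series == "y"] * 1.2
  ordinal <- ifelse(series == "b", siteIdx, L - siteIdx)
  ord <- order(series, ordinal)
  tab <- list(
    series = series[ord],
    ordinal = ordinal[ord],
    base = base[ord],
    ceTarget = (ceOpt + ceOff)[ord]
  )
  count <- get0("..n", envir = .toyCache, ifnotfound = 0L)
  if (count > 20000L) {
    rm(list = ls(.toyCache), envir = .toyCache)
    count <- 0L
  }
  assign("..n", count + 1L, envir = .toyCache)
  .toyCache[[sequence]] <- tab
  tab
}

#' Toy MS2 spectrum prediction
#'
#' @param peptide Peptide string (bracketed notation), length 7..30.
#' @param charge Precursor charge.
#' @param ce Collision energy (integer-valued).
#' @return A [PredictedSpectrum-class] with singly charged b/y fragments at
#'   every site, intensities normalised to base peak 1, and the composition
#'   iRT from [toyRtIndex()].
#' @examples
#' toyPredictSpectrum("PEPTIDEK", 2L, 28)
#' @export
toyPredictSpectrum <- function(peptide, charge, ce) {
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  L <- p$length
  if (L < 7L || L > 30L) {
    stop("toy predictor supports peptide lengths 7..30 (got ", L, ")")
  }
  tab <- .toyBaseTable(p$sequence)
  intensity <- tab$base * exp(-(ce - tab$ceTarget)^2 / 72)
  fr <- data.frame(series = tab$series, ordinal = tab$ordinal,
                   charge = 1L, intensity = intensity / max(intensity),
                   stringsAsFactors = FALSE)
  PredictedSpectrum(peptideString(p), charge, round(ce), fr,
                    irt = toyRtIndex(p))
}

#' Toy retention index
#'
#' Composition-only retention model: the sum of fixed per-residue hydropathy
#' coefficients. Additive over sequence concatenation and invariant to
#' residue order (a documented limitation: adequate for exercising the
#' alignment and feature plumbing, not for order-sensitive chromatography).
#'
#' @param peptide Peptide string.
#' @return Dimensionless retention index.
#' @examples
#' toyRtIndex("PEPTIDEK")
#' @export
toyRtIndex <- function(peptide) {
  p <- if (is.list(peptide)) peptide else parsePeptide(peptide)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sum(HYDROPATHY[chars])
}
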