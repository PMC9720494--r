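## Synthetic benchmark dataset generator.
##
## Emulates a ground-truth benchmark measurement: true PSMs whose spectra
## are noisy realisations of the toy prediction, wrong PSMs whose spectra
## come from peptides deliberately excluded from the constructed database,
## and reversed-sequence decoys. All outputs are written in the package's
## standard formats and parse back through the ms I/O readers.

#' Fixture configuration
#'
#' Study conditions of the synthetic benchmark. Defaults describe a
#' moderate-size immunopeptidome-like experiment: 2,000 PSMs split
#' 1100/350/550 (true/wrong/decoy; decoys ~27% of the total), peptide
#' lengths 8..14, charges 1..3 dominated by 2+, instrument collision-energy
#' optimum 28, lognormal intensity noise (sigma 0.3), 10% peak dropout,
#' 0.005 Th m/z jitter, 10 uniform noise peaks per spectrum, and engine
#' scores Normal(25, 5) for correct vs Normal(15, 5) for incorrect
#' assignments (partial overlap: the engine alone identifies a minority).
#'
#' @param nTruePsms,nWrongPsms,nDecoys PSM counts per class.
#' @param lengthRange Integer \code{c(min, max)} peptide length.
#' @param chargeProbs Probabilities of precursor charges 1..3.
#' @param ceOptimum Instrument collision-energy optimum, in 20..40.
#' @param intensitySigma Lognormal sigma of the peak intensity multiplier.
#' @param dropProb Probability that a fragment peak is dropped.
#' @param mzJitterSigma Gaussian m/z jitter sd in Th.
#' @param nNoisePeaks Uniform random noise peaks added per spectrum.
#' @param scoreMeanCorrect,scoreMeanWrong,scoreSd Engine-score model.
#' @param seed Integer seed.
#' @return A list of class \code{"fixtureConfig"}.
#' @export
fixtureConfig <- function(nTruePsms = 1100L, nWrongPsms = 350L,
                          nDecoys = 550L, lengthRange = c(8L, 14L),
                          chargeProbs = c(0.15, 0.6, 0.25),
                          ceOptimum = 28L, intensitySigma = 0.3,
                          dropProb = 0.1, mzJitterSigma = 0.005,
                          nNoisePeaks = 10L, scoreMeanCorrect = 25,
                          scoreMeanWrong = 15, scoreSd = 5, seed = 1L) {
  cfg <- list(nTruePsms = as.integer(nTruePsms),
              nWrongPsms = as.integer(nWrongPsms),
              nDecoys = as.integer(nDecoys),
              lengthRange = as.integer(lengthRange),
              chargeProbs = chargeProbs,
              ceOptimum = as.integer(ceOptimum),
              intensitySigma = intensitySigma,
              dropProb = dropProb,
              mzJitterSigma = mzJitterSigma,
              nNoisePeaks = as.integer(nNoisePeaks),
              scoreMeanCorrect = scoreMeanCorrect,
              scoreMeanWrong = scoreMeanWrong,
              scoreSd = scoreSd,
              seed = as.integer(seed))
  if (any(c(cfg$nTruePsms, cfg$nWrongPsms, cfg$nDecoys) < 0L)) {
    stop("PSM counts must be >= 0")
  }
  if (cfg$nTruePsms + cfg$nWrongPsms + cfg$nDecoys == 0L) {
    stop("contradictory configuration: zero PSMs requested")
  }
  if (cfg$ceOptimum < 20L || cfg$ceOptimum > 40L) {
    stop("ceOptimum must lie in [20, 40]")
  }
  if (cfg$dropProb < 0 || cfg$dropProb > 1) {
    stop("dropProb must lie in [0, 1]")
  }
  class(cfg) <- c("fixtureConfig", "list")
  cfg
}

## Peptide alphabet for generated ground-truth peptides: no Cys (the
## compatibility filter would otherwise discard true PSMs carrying
## unmodified cysteine, which is a property of real searches we exercise
## with dedicated fixtures instead).
.GT_ALPHABET <- setdiff(names(RESIDUE_MASSES), "C")

#' @noRd
.randomPeptides <- function(n, lengthRange) {
  out <- character(0)
  while (length(out) < n) {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), n, replace = TRUE)
    peps <- vapply(lens, function(L) {
      paste(sample(.GT_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, peps))
  }
  out[seq_len(n)]
}

#' @noRd
## Reverse a sequence keeping the C-terminal residue fixed (the usual decoy
## construction for tryptic-like score distributions).
.reverseDecoy <- function(pep) {
  L <- nchar(pep)
  if (L <= 2L) return(pep)
  chars <- strsplit(pep, "", fixed = TRUE)[[1]]
  paste(c(rev(chars[seq_len(L - 1L)]), chars[L]), collapse = "")
}

#' @noRd
## Noisy experimental spectrum realised from a toy prediction.
.noisySpectrum <- function(peptide, charge, cfg, sourceFile, scan, rt) {
  pred <- toyPredictSpectrum(peptide, charge, cfg$ceOptimum)
  fr <- pred@fragments
  tab <- fragmentMzTable(peptide, charge)
  key <- paste(tab$series, tab$ordinal, tab$charge)
  fr$mz <- tab$mz[match(paste(fr$series, fr$ordinal, fr$charge), key)]
  keep <- stats::runif(nrow(fr)) > cfg$dropProb
  fr <- fr[keep & fr$intensity > 1e-4, , drop = FALSE]
  intensity <- fr$intensity *
    exp(stats::rnorm(nrow(fr), 0, cfg$intensitySigma))
  mz <- fr$mz + stats::rnorm(nrow(fr), 0, cfg$mzJitterSigma)
  precursorMz <- (peptideNeutralMass(peptide) + charge * PROTON_MASS) /
    charge
  if (cfg$nNoisePeaks > 0L) {
    noiseMz <- stats::runif(cfg$nNoisePeaks, 100, precursorMz * charge)
    noiseInt <- stats::runif(cfg$nNoisePeaks, 0, 0.05)
    mz <- c(mz, noiseMz)
    intensity <- c(intensity, noiseInt)
  }
  Spectrum(sourceFile, scan, precursorMz, charge, rt,
           cbind(mz = mz, intensity = pmax(intensity, 0)))
}

## Retention-time model of the fixture: minutes = 60 + 0.8 * iRT + noise.
.RT_INTERCEPT <- 60
.RT_SLOPE <- 0.8
.RT_NOISE_SD <- 0.25

#' Generate a complete synthetic benchmark dataset
#'
#' Builds the constructed database (two-thirds of the ground-truth peptides
#' embedded, one-third excluded with padding fragments), realises noisy
#' spectra, assembles the search-result table (true assignments scored
#' Normal(mu_correct, sd); wrong assignments pair a spectrum generated from
#' an excluded peptide with a same-length discoverable peptide, scored
#' Normal(mu_wrong, sd); decoys are reversed sequences referencing existing
#' scans), and writes everything to \code{dir}: \code{spectra.mgf},
#' \code{search.tsv} (MaxQuant dialect), \code{constructed_db.fasta},
#' \code{truth.tsv}, \code{labels.tsv}, \code{ranks.tsv} (synthetic binding
#' %Rank table covering every assigned peptide). Byte-identical under a
#' fixed seed.
#'
#' @param config A [fixtureConfig()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the file paths, the
#'   [GroundTruthBenchmark-class], and the in-memory PSM/spectrum objects.
#' @export
generateBenchmarkDataset <- function(config = fixtureConfig(),
                                     dir = tempfile("fixture")) {
  cfg <- config
  rng <- .restoreSeed(cfg$seed)
  on.exit(rng())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## source-file name must match the MGF basename so spectrum keys line up
  src <- "spectra.mgf"

  ## ground-truth peptide pool: enough that the discoverable two-thirds
  ## covers one peptide per true PSM
  nGt <- max(3L, ceiling(cfg$nTruePsms * 3 / 2))
  gtPeptides <- .randomPeptides(nGt, cfg$lengthRange)
  ## reference sized ~3x the total embedded length so non-overlapping
  ## placement succeeds comfortably
  nRef <- max(40L, ceiling(nGt * max(cfg$lengthRange) * 3 / 400))
  reference <- vapply(seq_len(nRef), function(i) {
    paste(sample(names(RESIDUE_MASSES), 400, replace = TRUE),
          collapse = "")
  }, character(1))
  names(reference) <- paste0("REF_", seq_along(reference))
  benchmark <- buildConstructedDatabase(gtPeptides, reference,
                                        discoverableFraction = 2 / 3,
                                        seed = cfg$seed + 1L)
  lab <- peptideLabels(benchmark)
  discoverable <- lab$peptide[lab$label == "discoverable"]
  undiscoverable <- lab$peptide[lab$label == "undiscoverable"]

  drawCharge <- function(n) {
    sample(1:3, n, replace = TRUE, prob = cfg$chargeProbs)
  }

  ## true PSMs: one spectrum per sampled discoverable peptide
  nTrue <- min(cfg$nTruePsms, length(discoverable))
  truePeps <- if (nTrue) sample(discoverable, nTrue) else character(0)
  ## wrong PSMs: spectra from excluded peptides, assigned a same-length
  ## discoverable peptide (what a search engine does when the real answer
  ## is not in its database)
  nWrong <- cfg$nWrongPsms
  wrongGen <- if (nWrong) {
    sample(undiscoverable, nWrong, replace = TRUE)
  } else character(0)

  scans <- integer(0)
  spectra <- list()
  psmRows <- list()
  truthRows <- list()
  scan <- 0L
  addPsm <- function(scan, peptide, charge, score, label, proteins, rt) {
    psmRows[[length(psmRows) + 1L]] <<- data.frame(
      sourceFile = src, scanNumber = scan, peptide = peptide,
      charge = charge, engineScore = score, label = label,
      proteins = proteins, retentionTime = rt, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nTrue)) {
    scan <- scan + 1L
    pep <- truePeps[i]
    z <- drawCharge(1L)
    rt <- .RT_INTERCEPT + .RT_SLOPE * toyRtIndex(pep) +
      stats::rnorm(1, 0, .RT_NOISE_SD)
    spectra[[length(spectra) + 1L]] <-
      .noisySpectrum(pep, z, cfg, src, scan, rt)
    addPsm(scan, pep, z, stats::rnorm(1, cfg$scoreMeanCorrect, cfg$scoreSd),
           1L, "GT_PROT", rt)
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      sourceFile = src, scanNumber = scan, peptide = pep,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nWrong)) {
    scan <- scan + 1L
    gen <- wrongGen[i]
    z <- drawCharge(1L)
    rt <- .RT_INTERCEPT + .RT_SLOPE * toyRtIndex(gen) +
      stats::rnorm(1, 0, .RT_NOISE_SD)
    spectra[[length(spectra) + 1L]] <-
      .noisySpectrum(gen, z, cfg, src, scan, rt)
    sameLen <- discoverable[nchar(discoverable) == nchar(gen)]
    assigned <- if (length(sameLen)) sample(sameLen, 1L) else
      sample(discoverable, 1L)
    addPsm(scan, assigned, z,
           stats::rnorm(1, cfg$scoreMeanWrong, cfg$scoreSd), 1L,
           "GT_PROT", rt)
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      sourceFile = src, scanNumber = scan, peptide = gen,
      stringsAsFactors = FALSE)
  }
  ## decoys reference existing scans (a second candidate for the same
  ## spectrum: chimeric-style competition, never dropped)
  nScans <- scan
  for (i in seq_len(cfg$nDecoys)) {
    ref <- if (nScans) sample(nScans, 1L) else stop("no scans for decoys")
    refSpec <- spectra[[ref]]
    dec <- .reverseDecoy(sample(discoverable, 1L))
    addPsm(refSpec@scanNumber, dec, refSpec@precursorCharge,
           stats::rnorm(1, cfg$scoreMeanWrong, cfg$scoreSd), -1L,
           "REV_GT_PROT", refSpec@retentionTime)
  }
  psms <- do.call(rbind, psmRows)
  truth <- do.call(rbind, truthRows)
  benchmark@truthMap <- truth

  ## synthetic binding %Rank table over every peptide that can be queried:
  ## ground-truth peptides behave like eluted ligands (mostly binders),
  ## decoy sequences like random peptides
  allPeps <- unique(c(stripModifications(psms$peptide), gtPeptides))
  isLigand <- allPeps %in% gtPeptides
  ranks <- ifelse(isLigand,
                  10^stats::runif(length(allPeps), -2, 0.7),
                  stats::runif(length(allPeps), 0, 100))
  rankTab <- data.frame(peptide = allPeps, allele = "HLA-A*02:01",
                        percent_rank = round(ranks, 4))

  paths <- list(
    mgf = file.path(dir, "spectra.mgf"),
    search = file.path(dir, "search.tsv"),
    fasta = file.path(dir, "constructed_db.fasta"),
    truth = file.path(dir, "truth.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ranks = file.path(dir, "ranks.tsv")
  )
  writeMgf(spectra, paths$mgf)
  searchTab <- data.frame(
    "Raw file" = psms$sourceFile,
    "Scan number" = psms$scanNumber,
    "Sequence" = stripModifications(psms$peptide),
    "Modified sequence" = psms$peptide,
    "Charge" = psms$charge,
    "Retention time" = sprintf("%.4f", psms$retentionTime),
    "Score" = sprintf("%.4f", psms$engineScore),
    "Proteins" = psms$proteins,
    "Reverse" = ifelse(psms$label == -1L, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(searchTab, paths$search, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Biostrings::writeXStringSet(benchmarkDatabase(benchmark), paths$fasta)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(peptideLabels(benchmark), paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rankTab, paths$ranks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, benchmark = benchmark, psms = psms,
                 spectra = spectra, config = cfg))
}
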