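# Shared fixture builders. Everything is generated in code at test time;
# no binary or stored data.

# random unmodified peptides over the 20-letter alphabet (seeded by caller)
randomPeptides <- function(n, lengths = 8:14, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- names(psmRescore::massConstants()$residues)
  }
  vapply(sample(lengths, n, replace = TRUE), function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# a tiny MaxQuant-dialect search table on disk
writeMaxquantFixture <- function(path, rows) {
  tab <- data.frame(
    "Raw file" = rows$sourceFile,
    "Scan number" = rows$scanNumber,
    "Sequence" = psmRescore::stripModifications(rows$peptide),
    "Modified sequence" = rows$peptide,
    "Charge" = rows$charge,
    "Retention time" = rows$retentionTime,
    "Score" = rows$engineScore,
    "Proteins" = rows$proteins,
    "Reverse" = ifelse(rows$label == -1L, "+", ""),
    check.names = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force nearest-within-tolerance matcher (O(n*m));
# the oracle against which matchPeaks is checked
bruteForceMatch <- function(peakMz, fragMz, tolerance) {
  vapply(fragMz, function(f) {
    d <- abs(peakMz - f)
    best <- which(d == min(d))[1]  # ties: first = lower m/z (sorted input)
    if (d[best] <= tolerance) best else NA_integer_
  }, integer(1))
}

# independent O(n^2) q-value computation straight from the FDR formula
bruteForceQValues <- function(scores, labels) {
  vapply(seq_along(scores), function(i) {
    fdrAt <- function(s) {
      d <- sum(labels == -1L & scores >= s)
      t <- sum(labels == 1L & scores >= s)
      min(1, (1 + d) / max(1, t))
    }
    # q = min FDR over all thresholds at or below this score
    min(vapply(unique(scores[scores <= scores[i]]), fdrAt, numeric(1)))
  }, numeric(1))
}

# independent spectral-angle implementation for delta-oracle equivalence
independentSA <- function(p, e) {
  if (all(e == 0) || all(p == 0)) return(0)
  1 - 2 / pi * acos(min(1, max(-1, sum(p * e) / sqrt(sum(p^2) * sum(e^2)))))
}

# SA of a peptide's toy prediction against a spectrum, built from scratch
# (no use of the package's alignment helper)
independentToySA <- function(peptide, charge, ce, spectrum,
                             tolerance = 0.02) {
  pred <- psmRescore::toyPredictSpectrum(peptide, charge, ce)
  fr <- pred@fragments
  tab <- psmRescore::fragmentMzTable(peptide, charge)
  key <- paste(tab$series, tab$ordinal, tab$charge)
  fr$mz <- tab$mz[match(paste(fr$series, fr$ordinal, fr$charge), key)]
  pk <- psmRescore::peaks(spectrum)
  obs <- vapply(fr$mz, function(m) {
    if (!nrow(pk)) return(0)
    d <- abs(pk[, 1] - m)
    j <- which(d == min(d))[1]
    if (d[j] <= tolerance) pk[j, 2] else 0
  }, numeric(1))
  independentSA(fr$intensity, obs)
}

# small in-memory benchmark dataset shared by several test files
smallFixture <- function(nTrue = 60L, nWrong = 20L, nDecoys = 30L,
                         seed = 7L) {
  psmRescore::generateBenchmarkDataset(
    psmRescore::fixtureConfig(nTruePsms = nTrue, nWrongPsms = nWrong,
                              nDecoys = nDecoys, seed = seed),
    dir = tempfile("smallfix"))
}

namedSpectra <- function(spectra) {
  names(spectra) <- vapply(spectra, function(s) {
    paste(s@sourceFile, s@scanNumber, sep = "/")
  }, character(1))
  spectra
}
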