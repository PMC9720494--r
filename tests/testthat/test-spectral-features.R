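# Spectral angle, coverage, m/z error, retention-time alignment,
# compatibility filter and feature-table assembly.

test_that("spectral angle hits its analytic anchor points", {
  expect_equal(spectralAngle(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(spectralAngle(c(1, 0, 0), c(0, 1, 0)), 0.0)
  # arccos(1/sqrt(2)) = pi/4 => 1 - (2/pi)(pi/4) = 1/2
  expect_equal(spectralAngle(c(1, 0), c(1, 1)), 0.5, tolerance = 1e-12)
  # all-zero observed vector: 0 by convention
  expect_equal(spectralAngle(c(1, 1), c(0, 0)), 0)
  expect_error(spectralAngle(c(1, -1), c(1, 1)), "negative")
  expect_error(spectralAngle(c(1, 2), c(1, 2, 3)), "identical fragment")
})

test_that("spectral angle is symmetric and scale-invariant", {
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(20)
    e <- runif(20)
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 10)
    expect_equal(spectralAngle(p, e), spectralAngle(e, p))
    expect_equal(spectralAngle(a * p, b * e), spectralAngle(p, e),
                 tolerance = 1e-12)
    sa <- spectralAngle(p, e)
    expect_gte(sa, 0)
    expect_lte(sa, 1)
  }
})

test_that("series coverage distinguishes dominant and lesser series", {
  pred <- PredictedSpectrum("PEPTIDEK", 2L, 28, data.frame(
    series = c("b", "b", "y", "y", "y", "y"),
    ordinal = c(1, 2, 1, 2, 3, 4),
    charge = 1L,
    intensity = c(0.5, 0.4, 1, 0.9, 0.8, 0.7)
  ))
  # L = 8 => 7 possible ordinals; y covers 4/7, b covers 2/7 => y dominant
  allMatched <- data.frame(
    series = c("b", "b", "y", "y", "y", "y"),
    ordinal = c(1, 2, 1, 2, 3, 4), charge = 1L,
    mz = 1:6, matched = TRUE, peakMz = 1:6,
    peakIntensity = 1, mzError = 0.001
  )
  f <- seriesCoverageFeatures(pred, allMatched)
  expect_equal(unname(f["dominantCoverage"]), 4 / 7)
  expect_equal(unname(f["lesserCoverage"]), 2 / 7)
  expect_equal(unname(f["dominantMatched"]), 1)
  expect_equal(unname(f["lesserMatched"]), 1)
  expect_equal(unname(f["ms2Coverage"]), 1)

  # nothing matched: matched-coverage features all zero
  none <- allMatched
  none$matched <- FALSE
  f0 <- seriesCoverageFeatures(pred, none)
  expect_equal(unname(f0[c("dominantMatched", "lesserMatched",
                           "ms2Coverage")]), c(0, 0, 0))
})

test_that("m/z error features follow their conventions", {
  m <- data.frame(series = "b", ordinal = 1:2, charge = 1L, mz = 1:2,
                  matched = TRUE, peakMz = 1:2, peakIntensity = 1,
                  mzError = c(0.01, -0.01))
  f <- mzErrorFeatures(m)
  expect_equal(unname(f["meanMzError"]), 0)
  expect_equal(unname(f["medianAbsMzError"]), 0.01)
  expect_equal(unname(f["nMatched"]), 2)

  single <- m[1, ]
  single$mzError <- -0.015
  expect_equal(unname(mzErrorFeatures(single)["maxAbsMzError"]), 0.015)

  m$matched <- FALSE
  expect_equal(unname(mzErrorFeatures(m)),
               c(0, 0, 0, 0))
})

test_that("retention-time alignment recovers exact and noisy lines", {
  irt <- seq(-20, 30, length.out = 40)
  rt <- 2 * irt + 5
  al <- fitRtAlignment(rt, irt)
  expect_equal(al@slope, 2, tolerance = 1e-9)
  expect_equal(al@intercept, 5, tolerance = 1e-9)
  expect_equal(rtError(al, rt[3], irt[3]), 0, tolerance = 1e-9)

  # noisy fit: slope within 3 closed-form standard errors of truth
  set.seed(41)
  noise <- rnorm(40, 0, 0.1)
  alN <- fitRtAlignment(rt + noise, irt)
  se <- sqrt(sum(alN@residualSd^2) / sum((irt - mean(irt))^2))
  expect_lt(abs(alN@slope - 2), 3 * se)

  expect_error(fitRtAlignment(rt[1:5], irt[1:5]), ">= 10")
  expect_error(fitRtAlignment(rt, rep(1, 40)), "degenerate")
})

test_that("compatibility filter enforces length and cysteine rules", {
  psms <- data.frame(
    sourceFile = "r", scanNumber = 1:5,
    peptide = c("SHRTAK",                       # length 6: too short
                paste(rep("A", 30), collapse = ""),  # length 30: kept
                paste(rep("A", 31), collapse = ""),  # length 31: too long
                "ACDEFGHIK",                    # unmodified C
                "AC(cam)DEFGHIK"),              # modified C: kept
    charge = 2L, engineScore = 1, label = 1L, proteins = "P",
    retentionTime = 1
  )
  res <- filterCompatible(psms)
  expect_equal(res$kept$scanNumber, c(2L, 5L))
  expect_match(res$rejected$reason[1], "shorter")
  expect_match(res$rejected$reason[2], "longer")
  expect_match(res$rejected$reason[3], "unmodified cysteine")
  # idempotence
  again <- filterCompatible(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$rejected), 0L)
})

test_that("feature table has a fixed schema and detects perfect PSMs", {
  pep <- "MATYGWNLVK"
  pred <- toyPredictSpectrum(pep, 2L, 28)
  tab <- fragmentMzTable(pep, 2L)
  key <- paste(tab$series, tab$ordinal, tab$charge)
  fr <- pred@fragments
  mz <- tab$mz[match(paste(fr$series, fr$ordinal, fr$charge), key)]
  sp <- Spectrum("r.mgf", 1L, 500, 2L, 60 + 0.8 * toyRtIndex(pep),
                 cbind(mz = mz, intensity = fr$intensity))
  psms <- data.frame(sourceFile = "r.mgf", scanNumber = 1L, peptide = pep,
                     charge = 2L, engineScore = 40, label = 1L,
                     proteins = "P",
                     retentionTime = 60 + 0.8 * toyRtIndex(pep))
  al <- fitRtAlignment(60 + 0.8 * seq(-20, 20, 2), seq(-20, 20, 2))
  ft <- buildFeatureTable(psms, setNames(list(sp), "r.mgf/1"),
                          setNames(list(pred), paste0(pep, "/2")), al)
  feats <- featureMatrix(ft)
  expect_equal(ncol(feats), 22L)  # base schema: no optional blocks
  expect_equal(unname(feats[1, "spectralAngle"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(feats[1, "fracPredictedMatched"]), 1.0)
  expect_equal(unname(feats[1, "charge2"]), 1)
  expect_equal(unname(feats[1, "peptideLength"]), 10)

  # affinity mode adds exactly two columns
  rk <- data.frame(peptide = pep, allele = "A0201", percent_rank = 0.3)
  ft2 <- buildFeatureTable(psms, setNames(list(sp), "r.mgf/1"),
                           setNames(list(pred), paste0(pep, "/2")), al,
                           rankTable = rk)
  expect_equal(ncol(featureMatrix(ft2)), 24L)
  expect_equal(unname(featureMatrix(ft2)[1, "percentRank"]), 0.3)

  # missing prediction is an upstream error
  expect_error(
    buildFeatureTable(psms, setNames(list(sp), "r.mgf/1"),
                      list(), al),
    "without a spectral prediction")
})

test_that("missing %Rank values impute to the worst observed rank", {
  pep1 <- "MATYGWNLVK"; pep2 <- "AIKVLRGFKK"
  preds <- setNames(list(toyPredictSpectrum(pep1, 2L, 28),
                         toyPredictSpectrum(pep2, 2L, 28)),
                    paste0(c(pep1, pep2), "/2"))
  sp <- Spectrum("r.mgf", 1L, 500, 2L, 50, cbind(mz = 500, intensity = 1))
  spectra <- setNames(list(sp, sp), c("r.mgf/1", "r.mgf/2"))
  psms <- data.frame(sourceFile = "r.mgf", scanNumber = 1:2,
                     peptide = c(pep1, pep2), charge = 2L,
                     engineScore = 1, label = 1L, proteins = "P",
                     retentionTime = 50)
  al <- fitRtAlignment(60 + 0.8 * seq(-20, 20, 2), seq(-20, 20, 2))
  rk <- data.frame(peptide = pep1, allele = "A", percent_rank = c(7.5))
  ft <- buildFeatureTable(psms, spectra, preds, al, rankTable = rk)
  # pep2 absent from the table: takes the worst rank present (7.5)
  expect_equal(unname(featureMatrix(ft)[2, "percentRank"]), 7.5)
})

test_that("correct PSMs dominate incorrect ones in spectral angle", {
  # Mann-Whitney separation on the synthetic fixture, n = 200 per class
  fx <- generateBenchmarkDataset(
    fixtureConfig(nTruePsms = 200L, nWrongPsms = 200L, nDecoys = 10L,
                  seed = 5L), dir = tempfile())
  psms <- fx$psms
  spectra <- namedSpectra(fx$spectra)
  key <- paste(psms$sourceFile, psms$scanNumber, sep = "/")
  tm <- truthMap(fx$benchmark)
  tkey <- paste(tm$sourceFile, tm$scanNumber, sep = "/")
  isTrue <- psms$label == 1L &
    psms$peptide == tm$peptide[match(key, tkey)]
  sa <- vapply(which(psms$label == 1L), function(i) {
    independentToySA(psms$peptide[i], psms$charge[i], 28,
                     spectra[[key[i]]])
  }, numeric(1))
  cls <- isTrue[psms$label == 1L]
  wt <- wilcox.test(sa[cls], sa[!cls], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("excludeFeatures drops only the named columns", {
  meta <- data.frame(specId = "x", label = 1L, scanNumber = 1L,
                     sourceFile = "r", peptide = "PEPTIDEK",
                     proteins = "P")
  ft <- FeatureTable(meta, matrix(1:3, 1, dimnames = list(NULL,
                                                          c("a", "b", "c"))))
  out <- excludeFeatures(ft, "b")
  expect_equal(featureNames(out), c("a", "c"))
  expect_error(excludeFeatures(ft, "zz"), "unknown")
})
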