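# Adjacent-swap sensitivity: swaps, oracle deltas, summaries, and the
# lightweight predictor.

test_that("adjacent swaps exchange residues and carry modifications", {
  expect_equal(swapAdjacent("MATYGWNLVK", 2), "MTAYGWNLVK")
  expect_equal(swapAdjacent("AIKVLRGFKK", 8), "AIKVLRGKFK")
  # identical adjacent residues: sequence unchanged
  expect_equal(swapAdjacent("AAPEPTIDE", 1), "AAPEPTIDE")
  # modifications travel with their residue
  expect_equal(swapAdjacent("AM(ox)PEPTIDE", 1), "M(ox)APEPTIDE")
  expect_equal(swapAdjacent("AM(ox)PEPTIDE", 2), "APM(ox)EPTIDE")
  expect_error(swapAdjacent("PEPTIDE", 7), "out of range")
  expect_error(swapAdjacent("PEPTIDE", 0), "out of range")
})

test_that("oracle deltas agree with an independent SA implementation", {
  pep <- "MATYGWNLVK"
  pred <- toyPredictSpectrum(pep, 2L, 28)
  tab <- fragmentMzTable(pep, 2L)
  key <- paste(tab$series, tab$ordinal, tab$charge)
  fr <- pred@fragments
  mz <- tab$mz[match(paste(fr$series, fr$ordinal, fr$charge), key)]
  sp <- Spectrum("r", 1L, 500, 2L, 30,
                 cbind(mz = mz, intensity = fr$intensity))
  psm <- data.frame(peptide = pep, charge = 2L)
  got <- deltaOracle(psm, sp, toyPredictSpectrum, 28)
  expect_equal(nrow(got), nchar(pep) - 1L)
  saOrig <- independentToySA(pep, 2L, 28, sp)
  for (k in seq_len(nrow(got))) {
    swapped <- swapAdjacent(pep, got$site[k])
    want <- independentToySA(swapped, 2L, 28, sp) - saOrig
    expect_equal(got$delta[k], want, tolerance = 1e-12)
  }
  # deltas are bounded and mostly negative for a self-match spectrum
  expect_true(all(got$delta >= -1 & got$delta <= 1))
  expect_lt(median(got$delta), 0)
})

test_that("identical-residue swap sites have delta exactly zero", {
  pep <- "AAPEPTIDE"
  sp <- Spectrum("r", 1L, 500, 2L, 30, cbind(mz = 500, intensity = 1))
  got <- deltaOracle(data.frame(peptide = pep, charge = 2L), sp,
                     toyPredictSpectrum, 28)
  expect_identical(got$delta[got$site == 1], 0)
})

test_that("delta summaries compute order statistics and strict fractions", {
  s <- deltaSummary(c(-0.3, -0.05, 0.01))
  expect_equal(unname(s["deltaMin"]), -0.3)
  expect_equal(unname(s["deltaMax"]), 0.01)
  expect_equal(unname(s["deltaMedian"]), -0.05)
  expect_equal(unname(s["deltaFracAboveM01"]), 2 / 3)
  expect_equal(unname(s["deltaFracAbove0"]), 1 / 3)

  # strict inequality: zeros are NOT above 0 but ARE above -0.1
  z <- deltaSummary(rep(0, 5))
  expect_equal(unname(z["deltaFracAboveM01"]), 1)
  expect_equal(unname(z["deltaFracAbove0"]), 0)

  expect_error(deltaSummary(numeric(0)), "empty")
})

test_that("delta summaries are order-invariant and internally ordered", {
  set.seed(13)
  for (rep in 1:30) {
    x <- runif(sample(3:15, 1), -1, 1)
    a <- deltaSummary(x)
    b <- deltaSummary(sample(x))
    expect_equal(a, b)
    expect_lte(a["deltaMin"], a["deltaQ1"])
    expect_lte(a["deltaQ1"], a["deltaMedian"])
    expect_lte(a["deltaMedian"], a["deltaQ3"])
    expect_lte(a["deltaQ3"], a["deltaMax"])
    expect_lte(a["deltaFracAbove0"], a["deltaFracAboveM01"])
  }
})

test_that("training-point sampling is seeded and counts sites correctly", {
  fx <- smallFixture(nTrue = 20L, nWrong = 0L, nDecoys = 5L, seed = 3L)
  psms <- fx$psms[fx$psms$label == 1L, ][1:10, ]
  spectra <- namedSpectra(fx$spectra)
  s1 <- sampleTrainingPoints(psms, spectra, toyPredictSpectrum, 28,
                             seed = 2L)
  s2 <- sampleTrainingPoints(psms, spectra, toyPredictSpectrum, 28,
                             seed = 2L)
  # 5 sites per PSM by default
  expect_equal(length(s1$delta), 50L)
  expect_identical(s1$site, s2$site)
  expect_identical(s1$delta, s2$delta)
  # peptides with fewer than 5 sites contribute all their sites
  short <- psms[1, ]
  short$peptide <- "PEPTIDE"  # 6 sites > 5; use a 7-mer for the cap
  s3 <- sampleTrainingPoints(short, setNames(
    list(fx$spectra[[1]]), paste(short$sourceFile, short$scanNumber,
                                 sep = "/")),
    toyPredictSpectrum, 28, nSites = 10L, seed = 1L)
  expect_equal(length(s3$delta), 6L)
})

test_that("a model trained on constant targets predicts constants", {
  set.seed(17)
  peps <- randomPeptides(300, 9:11,
                         alphabet = setdiff(names(massConstants()$residues),
                                            "C"))
  feats <- do.call(rbind, lapply(peps, function(p) {
    psmRescore:::.deltaFeatureRow(p, 3L, 2L, 28L)
  }))
  samples <- list(features = feats[rep(1:300, 4), ],
                  delta = rep(0.25, 1200),
                  peptide = rep(peps, 4), site = rep(3L, 1200))
  model <- trainDeltaModel(samples, nrounds = 10L, seed = 1L)
  pred <- predictDeltas(model, peps[1], 2L, 28L)
  expect_equal(nrow(pred), nchar(peps[1]) - 1L)
  expect_true(all(abs(pred$delta - 0.25) < 0.02))
  # determinism
  pred2 <- predictDeltas(model, peps[1], 2L, 28L)
  expect_identical(pred$delta, pred2$delta)
})

test_that("the model refuses schema mismatches and untrained state", {
  expect_error(predictDeltas(new("DeltaModel", booster = raw(0),
                                 schemaVersion = "x",
                                 featureNames = character(0),
                                 evaluation = list()),
                             "PEPTIDEK", 2L, 28L),
               "untrained")
  f <- tempfile(fileext = ".rds")
  saveRDS(list(booster = as.raw(1:4), schemaVersion = "other",
               featureNames = "a", evaluation = list()), f)
  expect_error(loadDeltaModel(f), "schema mismatch")
})

test_that("training requires enough samples and disjoint peptides", {
  feats <- matrix(runif(50), nrow = 10)
  colnames(feats) <- paste0("f", 1:5)
  expect_error(trainDeltaModel(list(features = feats, delta = runif(10),
                                    peptide = letters[1:10],
                                    site = rep(1L, 10))),
               ">= 1000")
})
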