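# Readers and writers: MGF, MSP, search results, pin, %Rank tables.
# Every pair is checked by write-then-read round trips on generated
# fixtures.

test_that("MGF round-trips and normalises records", {
  f <- tempfile(fileext = ".mgf")
  sp <- list(
    Spectrum("a.mgf", 11L, 500.25, 2L, 30.5,
             cbind(mz = c(300.1, 200.2, 450.9),
                   intensity = c(1, 2, 3))),
    Spectrum("a.mgf", 12L, 602.33, 3L, 31.0,
             cbind(mz = c(150.5, 700.1), intensity = c(4, 5)))
  )
  writeMgf(sp, f)
  got <- readMgf(f)
  expect_length(got, 2L)
  expect_setequal(vapply(got, scanNumber, integer(1)), c(11L, 12L))
  # peaks sorted ascending even though input was unsorted
  expect_false(is.unsorted(peaks(got[[1]])[, 1]))
  # RT survived the seconds/minutes conversion
  expect_equal(got[[1]]@retentionTime, 30.5, tolerance = 1e-6)
  expect_equal(peaks(got[[1]])[, "intensity"], c(2, 1, 3),
               ignore_attr = TRUE)
})

test_that("empty MGF gives an empty list; malformed records are named", {
  f <- tempfile(fileext = ".mgf")
  writeLines(character(0), f)
  expect_length(readMgf(f), 0L)

  writeLines(c("BEGIN IONS", "TITLE=no scan digits here x",
               "PEPMASS=500.0", "100.0 1.0", "END IONS"), f)
  expect_error(readMgf(f), "record 1")

  writeLines(c("BEGIN IONS", "SCANS=5", "100.0 1.0", "END IONS"), f)
  expect_error(readMgf(f), "PEPMASS")
})

test_that("MGF scan numbers fall back to the TITLE integer", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=run1.raw scan 341", "PEPMASS=432.1",
               "CHARGE=2+", "RTINSECONDS=120", "100.5 1.0", "END IONS"), f)
  got <- readMgf(f)
  expect_equal(scanNumber(got[[1]]), 341L)
  expect_equal(got[[1]]@retentionTime, 2)
})

test_that("MSP round-trips toy predictions to printed precision", {
  preds <- list(
    toyPredictSpectrum("PEPTIDEK", 2L, 28),
    toyPredictSpectrum("MATYGWNLVK", 2L, 30)
  )
  f <- tempfile(fileext = ".msp")
  writeMsp(preds, f)
  got <- readMsp(f)
  expect_named(got, c("PEPTIDEK/2/28", "MATYGWNLVK/2/30"),
               ignore.order = TRUE)
  p1 <- got[["PEPTIDEK/2/28"]]
  expect_equal(nrow(p1@fragments), nrow(preds[[1]]@fragments))
  ord <- function(fr) fr[order(fr$series, fr$ordinal), ]
  expect_equal(ord(p1@fragments)$intensity,
               ord(preds[[1]]@fragments)$intensity, tolerance = 1e-6)
  expect_equal(p1@irt, preds[[1]]@irt, tolerance = 1e-6)
})

test_that("MSP rejects duplicates and bad annotation tokens", {
  pred <- toyPredictSpectrum("PEPTIDEK", 2L, 28)
  f <- tempfile(fileext = ".msp")
  writeMsp(list(pred, pred), f)
  expect_error(readMsp(f), "duplicate")

  writeLines(c("Name: PEPTIDEK/2", "Comment: CollisionEnergy=28 iRT=1.0",
               "Num peaks: 1", '100.0 0.5 "a3"'), f)
  expect_error(readMsp(f), "a3")
})

test_that("MaxQuant search results parse with decoy flags and chimera", {
  rows <- data.frame(
    sourceFile = "r.mgf", scanNumber = c(1L, 2L, 7L, 7L),
    peptide = c("PEPTIDEK", "MAGICPEPK", "WHYNTNSWK", "WHYNTNSKW"),
    charge = 2L, engineScore = c(50, 40, 30, 20),
    label = c(1L, -1L, 1L, 1L), proteins = "P1",
    retentionTime = c(10, 11, 12, 12)
  )
  f <- writeMaxquantFixture(tempfile(fileext = ".tsv"), rows)
  got <- readSearchResults(f, "maxquant")
  expect_equal(nrow(got), 4L)
  expect_equal(sum(got$label == -1L), 1L)
  # both PSMs of scan 7 retained (chimeric spectra are first-class)
  expect_equal(sum(got$scanNumber == 7L), 2L)
  expect_equal(nrow(attr(got, "rejected")), 0L)
})

test_that("header-only tables give empty PSM lists", {
  rows <- data.frame(sourceFile = character(0), scanNumber = integer(0),
                     peptide = character(0), charge = integer(0),
                     engineScore = numeric(0), label = integer(0),
                     proteins = character(0), retentionTime = numeric(0))
  f <- writeMaxquantFixture(tempfile(fileext = ".tsv"), rows)
  expect_equal(nrow(readSearchResults(f, "maxquant")), 0L)
})

test_that("missing columns and bad modification tokens are errors", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame("Raw file" = "a", Score = 1, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSearchResults(f, "maxquant"), "Scan number")

  rows <- data.frame(sourceFile = "r", scanNumber = 1L,
                     peptide = "PE(zz)PTIDEK", charge = 2L,
                     engineScore = 1, label = 1L, proteins = "P",
                     retentionTime = 5)
  f2 <- writeMaxquantFixture(tempfile(fileext = ".tsv"), rows)
  expect_error(readSearchResults(f2, "maxquant"), "row 1")
})

test_that("PEAKS and Mascot dialects parse with their decoy conventions", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(
    "Source File" = "r.mgf", Scan = c(1L, 2L), Peptide = c("PEPTIDEK",
                                                           "KEDITPEP"),
    z = 2L, "-10lgP" = c(35.2, 12.1), RT = c(20.1, 20.5),
    Accession = c("sp|P1", "DECOY_P1"), check.names = FALSE
  ), f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readSearchResults(f, "peaks")
  expect_equal(got$label, c(1L, -1L))

  fm <- tempfile(fileext = ".csv")
  write.table(data.frame(
    "Source File" = "r.mgf", Scan = 3L, Sequence = "MAGICPEPK",
    Charge = 2L, Score = 55, Proteins = "P2", RT = 31.5, Decoy = FALSE,
    check.names = FALSE
  ), fm, sep = ",", quote = FALSE, row.names = FALSE)
  gotm <- readSearchResults(fm, "mascot")
  expect_equal(gotm$label, 1L)
  expect_equal(gotm$retentionTime, 31.5)
})

test_that("ambiguous delimiters are rejected, not guessed", {
  f <- tempfile()
  writeLines("Source File\tScan,Peptide\tz", f)
  expect_error(readSearchResults(f, "peaks"), "ambiguous")
})

test_that("pin files round-trip the feature matrix bit-exactly", {
  meta <- data.frame(
    specId = c("a_1", "a_2"), label = c(1L, -1L), scanNumber = c(1L, 2L),
    sourceFile = "a", peptide = c("PEPTIDEK", "KEDITPEP"),
    proteins = c("P1", "DECOY_P1")
  )
  feats <- matrix(c(1.23456789, -2.5, 0.001, 42, 1e-7, 3.25),
                  nrow = 2, dimnames = list(NULL, c("f1", "f2", "f3")))
  ft <- FeatureTable(meta, feats)
  f <- tempfile(fileext = ".pin")
  writePin(ft, f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + 2 rows
  # decoy encoded as -1
  expect_match(lines[3], "\t-1\t")
  back <- readPin(f)
  expect_equal(featureMatrix(back), featureMatrix(ft))
  expect_equal(psmMeta(back)$peptide, meta$peptide)

  feats[1, 2] <- NaN
  expect_error(writePin(FeatureTable(meta, feats), f), "finite")
})

test_that("rank tables round-trip and flag absences explicitly", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(peptide = c("AAAWWWKK", "CCCDDDRR", "AAAWWWKK"),
                         allele = c("A0201", "A0201", "B0702"),
                         percent_rank = c(0.4, 3.2, 1.1)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readRankTable(f)
  expect_equal(nrow(rt), 3L)
  # multi-allele query returns the minimum rank
  got <- queryPercentRank(rt, c("AAAWWWKK", "NOTINTABLE"))
  expect_equal(unname(got[1]), 0.4)
  expect_true(is.na(got[2]))  # explicit missing, never zero

  write.table(data.frame(peptide = "A", allele = "x", percent_rank = -1),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRankTable(f), "\\[0, 100\\]")
})
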