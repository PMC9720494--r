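# Target-decoy q-values and the semi-supervised rescorer.

test_that("q-values follow the +1-corrected FDR formula on tiny sets", {
  # hand evaluation: targets {3, 2}, decoy {2.5}
  # FDR(3) = (1+0)/1 = 1; FDR(2.5) = (1+1)/1 = 2 -> 1; FDR(2) = (1+1)/2 = 1
  q <- tdcQValues(c(3, 2, 2.5), c(1L, 1L, -1L))
  expect_equal(q$qValue, c(1, 1, 1))

  # no decoys: FDR(s) = 1 / #targets >= s, monotonized
  q2 <- tdcQValues(c(5, 4, 3), c(1L, 1L, 1L))
  expect_equal(q2$qValue, c(1 / 3, 1 / 3, 1 / 3))

  # clean separation: best targets pass at low q
  q3 <- tdcQValues(c(10, 9, 8, 1), c(1L, 1L, 1L, -1L))
  expect_equal(q3$qValue[1:3], rep(1 / 3, 3))

  expect_error(tdcQValues(numeric(0), integer(0)), "empty")
  expect_error(tdcQValues(c(1, NA), c(1L, -1L)), "finite")
  expect_error(tdcQValues(c(1, 2), c(-1L, -1L)), "target")
})

test_that("q-values equal the O(n^2) brute force on random scores", {
  set.seed(101)
  n <- 1000
  scores <- c(rnorm(600, 1), rnorm(400, 0))
  labels <- c(rep(1L, 600), rep(-1L, 400))
  # inject exact ties to exercise the tie handling
  scores[1:10] <- scores[11:20]
  got <- tdcQValues(scores, labels)$qValue
  want <- bruteForceQValues(scores, labels)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("q-values are monotone in score", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 200
    scores <- rnorm(n)
    labels <- sample(c(1L, -1L), n, replace = TRUE, prob = c(0.7, 0.3))
    if (!any(labels == 1L)) next
    q <- tdcQValues(scores, labels)
    ord <- order(q$score, decreasing = TRUE)
    expect_true(all(diff(q$qValue[ord]) >= -1e-12))
    expect_true(all(q$qValue >= 0 & q$qValue <= 1))
  }
})

test_that("identification counting respects thresholds and peptides", {
  q <- data.frame(score = c(3, 2.5, 2, 1), label = c(1L, 1L, 1L, -1L),
                  qValue = c(0.005, 0.005, 0.5, 1),
                  peptide = c("PEPA", "PEPA", "PEPB", "PEPX"))
  ids <- identificationsAtFdr(q, 0.01)
  expect_equal(ids$psms, 2L)
  expect_equal(ids$peptides, 1L)  # two PSMs of one peptide
  all <- identificationsAtFdr(q, 1.0)
  expect_equal(all$psms, 3L)
  none <- identificationsAtFdr(transform(q, qValue = 1), 0.01)
  expect_equal(none$psms, 0L)
  expect_equal(none$peptides, 0L)
  expect_error(identificationsAtFdr(q, 0), "threshold")
  expect_error(identificationsAtFdr(q, 1.5), "threshold")
})

# a feature table where one feature carries signal strength `sep` and the
# rest are noise
syntheticFeatureTable <- function(n = 300, sep = 3, seed = 1,
                                  nNoise = 3) {
  set.seed(seed)
  label <- rep(c(1L, -1L), length.out = n)
  isGood <- label == 1L & runif(n) < 0.7
  signal <- rnorm(n) + sep * isGood
  feats <- cbind(engineScore = signal,
                 matrix(rnorm(n * nNoise), n,
                        dimnames = list(NULL, paste0("noise", 1:nNoise))))
  meta <- data.frame(
    specId = paste0("s", 1:n), label = label, scanNumber = 1:n,
    sourceFile = "r", peptide = paste0("PEPTID", LETTERS[1 + (1:n) %% 26],
                                       "K"),
    proteins = "P")
  FeatureTable(meta, feats)
}

test_that("a perfectly separating feature yields full separation", {
  n <- 200
  label <- rep(c(1L, -1L), each = n / 2)
  feats <- cbind(engineScore = as.numeric(label == 1L),
                 other = rnorm(n))
  meta <- data.frame(specId = paste0("s", 1:n), label = label,
                     scanNumber = 1:n, sourceFile = "r",
                     peptide = "PEPTIDEK", proteins = "P")
  ft <- FeatureTable(meta, feats)
  out <- semiSupervisedRescore(ft, seed = 1L)
  expect_gt(min(out$score[out$label == 1L]),
            max(out$score[out$label == -1L]))
})

test_that("no PSM is scored by a model trained on its own fold", {
  ft <- syntheticFeatureTable(n = 240, seed = 3)
  out <- semiSupervisedRescore(ft, folds = 3L, seed = 2L)
  # fold bookkeeping: every PSM has a fold, all PSMs of one scan share it
  expect_true(all(out$fold %in% 1:3))
  byScan <- tapply(out$fold, paste(out$sourceFile, out$scanNumber),
                   function(x) length(unique(x)))
  expect_true(all(byScan == 1L))
  # determinism under seed
  out2 <- semiSupervisedRescore(ft, folds = 3L, seed = 2L)
  expect_identical(out$score, out2$score)
  expect_identical(out$qValue, out2$qValue)
})

test_that("chimeric PSMs of one scan never straddle folds", {
  ft <- syntheticFeatureTable(n = 240, seed = 4)
  meta <- psmMeta(ft)
  meta$scanNumber <- rep(1:60, each = 4)  # 4 PSMs per scan
  ft2 <- FeatureTable(meta, featureMatrix(ft))
  out <- semiSupervisedRescore(ft2, seed = 1L)
  byScan <- tapply(out$fold, out$scanNumber,
                   function(x) length(unique(x)))
  expect_true(all(byScan == 1L))
})

test_that("pure-noise features cannot inflate identifications", {
  # null-feature control: engine score plus noise must not beat the engine
  # score alone by more than 20% at q <= 0.01
  ftNoise <- syntheticFeatureTable(n = 600, sep = 4, seed = 11,
                                   nNoise = 5)
  ftEngine <- FeatureTable(
    psmMeta(ftNoise),
    featureMatrix(ftNoise)[, "engineScore", drop = FALSE])
  idsNoise <- identificationsAtFdr(
    semiSupervisedRescore(ftNoise, seed = 5L))$psms
  idsEngine <- identificationsAtFdr(
    semiSupervisedRescore(ftEngine, seed = 5L))$psms
  expect_gt(idsEngine, 0L)
  expect_lte(idsNoise, ceiling(1.2 * idsEngine))
})

test_that("rescoring fails cleanly on degenerate inputs", {
  ft <- syntheticFeatureTable(n = 30)
  expect_error(semiSupervisedRescore(ft, folds = 3L), "too few")
  ftBig <- syntheticFeatureTable(n = 240)
  meta <- psmMeta(ftBig)
  meta$label <- 1L
  meta$label[1] <- -1L
  expect_error(
    semiSupervisedRescore(FeatureTable(meta, featureMatrix(ftBig))),
    "no decoys")
})

test_that("external scores re-import through the pin compatibility path", {
  ft <- syntheticFeatureTable(n = 100)
  f <- tempfile()
  write.table(data.frame(specId = psmMeta(ft)$specId,
                         score = featureMatrix(ft)[, "engineScore"]),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- rescoreFromExternalScores(ft, f)
  expect_equal(nrow(out), 100L)
  expect_true(all(c("score", "qValue") %in% names(out)))
  write.table(data.frame(specId = "nope", score = 1), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(rescoreFromExternalScores(ft, f), "misses")
})
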