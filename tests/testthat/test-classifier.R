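test_that("log-odds differ only where the training classes differ", {
  base <- strrep("A", 29)
  other <- paste0(strrep("A", 14), "G", strrep("A", 14))  # column 15 differs
  tr <- data.frame(
    record_id = sprintf("s%02d", 1:12),
    class = rep(c("X", "Y"), each = 6),
    seq = c(rep(base, 6), rep(other, 6)))
  models <- trainProfiles(tr)
  lo <- logOdds(models)
  diffs <- which(colSums(abs(lo$X - lo$Y)) > 1e-12)
  expect_equal(unname(diffs), 15L)
})

test_that("a huge pseudocount flattens all log-odds toward zero", {
  tr <- simulateTrainingAlignment(nPerClass = 10, noise = 0.1, seed = 4)
  models <- trainProfiles(tr, pseudocount = 1e7)
  for (m in logOdds(models)) expect_lt(max(abs(m)), 1e-4)
})

test_that("trained profiles recover the generator consensus per column", {
  tr <- simulateTrainingAlignment(nPerClass = 100, noise = 0.05, seed = 12)
  models <- trainProfiles(tr)
  for (cl in modelClasses(models)) {
    cons <- trnacca:::.classConsensus(cl)
    lo <- logOdds(models)[[cl]]
    top <- rownames(lo)[apply(lo, 2, which.max)]
    expect_identical(unname(top), unname(cons))
  }
})

test_that("training is invariant to sequence order and validates inputs", {
  tr <- simulateTrainingAlignment(nPerClass = 20, noise = 0.05, seed = 5)
  m1 <- trainProfiles(tr)
  set.seed(1)
  m2 <- trainProfiles(tr[sample(nrow(tr)), ])
  expect_identical(logOdds(m1), logOdds(m2))

  bad <- tr
  bad$seq[1] <- substr(bad$seq[1], 1, 10)
  expect_error(trainProfiles(bad), "same length")
  few <- tr[c(1:20, 21:24, 41:60), ]  # Met has 4 sequences
  expect_error(trainProfiles(few), "Met")
  expect_error(trainProfiles(tr[tr$class == "Ini", ]), "two classes")
})

test_that("scores behave: own consensus wins, all-gap gets the gap score", {
  tr <- simulateTrainingAlignment(nPerClass = 50, noise = 0.05, seed = 6)
  models <- trainProfiles(tr)
  consSet <- data.frame(
    record_id = c("cIni", "cMet", "ckIle"),
    seq = vapply(c("Ini", "Met", "kIle"),
                 function(cl) paste(trnacca:::.classConsensus(cl),
                                    collapse = ""), character(1)))
  sc <- scoreSequences(models, consSet)
  expect_equal(colnames(sc)[apply(sc, 1, which.max)],
               c("Ini", "Met", "kIle"))

  gaps <- data.frame(record_id = "g", seq = strrep("-", 29))
  scg <- scoreSequences(models, gaps)
  for (cl in colnames(scg))
    expect_equal(scg[1, cl], sum(logOdds(models)[[cl]]["-", ]))

  short <- data.frame(record_id = "s", seq = "ACGU")
  expect_error(scoreSequences(models, short), "frame")
})

test_that("classification flags ambiguity and margins are non-negative", {
  tr <- simulateTrainingAlignment(nPerClass = 50, noise = 0.05, seed = 8)
  models <- trainProfiles(tr)
  te <- simulateTrainingAlignment(nPerClass = 20, noise = 0.05, seed = 9)
  res <- classifySequences(models, te, backgroundShuffles = 0)
  expect_true(all(res$margin >= 0))
  expect_equal(mean(res$best_class == res$prior_class), 1)

  ## identical consensus for two classes -> margin ~ 0, flagged ambiguous
  cons <- list(Ini = trnacca:::.classConsensus("Ini"),
               Met = trnacca:::.classConsensus("Ini"))
  trSame <- simulateTrainingAlignment(nPerClass = 30, noise = 0.05,
                                      seed = 10, classes = c("Ini", "Met"),
                                      consensus = cons)
  mSame <- trainProfiles(trSame)
  teSame <- simulateTrainingAlignment(nPerClass = 10, noise = 0,
                                      seed = 11, classes = c("Ini"),
                                      consensus = cons["Ini"])
  resSame <- classifySequences(mSame, teSame, backgroundShuffles = 0)
  expect_lt(max(resSame$margin), 1)
  expect_true(all(resSame$ambiguous))
})

test_that("background z separates real sequences from shuffles", {
  tr <- simulateTrainingAlignment(nPerClass = 50, noise = 0.05, seed = 13)
  models <- trainProfiles(tr)
  te <- simulateTrainingAlignment(nPerClass = 10, noise = 0.05, seed = 14)
  bg <- backgroundDistribution(models, te, nShuffle = 200, seed = 15)
  expect_true(all(is.finite(bg$mean)) && all(is.finite(bg$sd)))
  res <- classifySequences(models, te, backgroundShuffles = 200, seed = 15)
  expect_true(all(res$background_z > 3))
})

test_that("missing-initiator detection follows the z threshold", {
  tr <- simulateTrainingAlignment(nPerClass = 50, noise = 0.05, seed = 16)
  models <- trainProfiles(tr)
  ## genome with its initiator deleted: only Met/kIle genes remain
  noIni <- simulateTrainingAlignment(nPerClass = 5, noise = 0.05, seed = 17,
                                     classes = c("Met", "kIle"))
  resNo <- classifySequences(models, noIni, backgroundShuffles = 100,
                             seed = 18)
  expect_true(detectMissingInitiator(resNo))
  ## genome with a planted initiator consensus gene
  withIni <- simulateTrainingAlignment(nPerClass = 2, noise = 0, seed = 19)
  resWith <- classifySequences(models, withIni, backgroundShuffles = 100,
                               seed = 20)
  expect_false(detectMissingInitiator(resWith))
  expect_warning(empty <- detectMissingInitiator(resWith[0, ]), "empty")
  expect_true(empty)
})

test_that("prior non-CAU labels pass through; initiator overwrite warns", {
  prior <- c("Tyr", "Sec", "Unspecified", "Met", "Ini")
  calls <- c("Ini", "Ini", "kIle", "Met", "Ini")
  out <- reconcileAnnotations(prior, calls)
  expect_identical(out, c("Tyr", "Sec", "kIle", "Met", "Ini"))
  expect_warning(reconcileAnnotations("Ini", "Met"), "initiator")
})
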