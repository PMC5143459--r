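test_that("pair scores follow the Watson-Crick/wobble pair set", {
  expect_equal(pairScore("G", "C"), 4)
  expect_equal(pairScore("C", "G"), 4)
  expect_equal(pairScore("G", "U"), 4)  # wobble counts as pairing
  expect_equal(pairScore("U", "G"), 4)
  expect_equal(pairScore("A", "C"), 1)
  expect_equal(pairScore("A", "A"), 1)
  expect_equal(pairScore("t", "a"), 4)  # T/U and case-insensitive
  expect_error(pairScore("N", "A"), "A, C, G, U")
})

test_that("a perfectly paired heptamer scores 28, or 35 with full bonus", {
  x <- c("G", "C", "G", "G", "A", "U", "U")
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  seg <- unname(comp[x])                 # elementwise partner
  y <- c(seg, randomBaseVec(10))
  set.seed(5)
  aln <- bestAlignment(buildAlignmentMatrix(x, y))
  expect_equal(aln$score, 28)
  expect_equal(nrow(aln$pairs), 7L)
  expect_equal(aln$pairs[, "j"], 1:7)

  mask <- matrix(FALSE, 7, length(y))
  mask[cbind(1:7, 1:7)] <- TRUE
  alnB <- bestAlignment(buildAlignmentMatrix(x, y, bonusMask = mask))
  expect_equal(alnB$score, 35)
})

test_that("equally scoring placements resolve toward the 5'-most (smallest j)", {
  x <- c("G", "C", "G", "G", "A", "U", "U")
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  seg <- unname(comp[x])
  y <- c(seg, seg, c("A", "A", "A"))    # two perfect placements
  aln <- bestAlignment(buildAlignmentMatrix(x, y))
  expect_equal(aln$score, 28)
  expect_equal(aln$jEnd, 7L)            # not 14
})

test_that("DP optimum equals brute-force enumeration on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    m <- sample(2:5, 1); n <- sample(3:7, 1)
    x <- randomBaseVec(m); y <- randomBaseVec(n)
    mask <- matrix(runif(m * n) < 0.2, m, n)
    sch <- ScoringScheme()
    got <- bestAlignment(buildAlignmentMatrix(x, y, sch, mask))$score
    want <- oracleBestScore(x, y, bonus = 1, bonusMask = mask)
    expect_equal(got, want)
  }
})

test_that("annotation bonus never decreases the optimal score", {
  set.seed(33)
  for (rep in 1:25) {
    x <- randomBaseVec(7); y <- randomBaseVec(17)
    mask <- matrix(runif(7 * 17) < 0.15, 7, 17)
    s0 <- bestAlignment(buildAlignmentMatrix(
      x, y, ScoringScheme(annotationBonus = 0), mask))$score
    s1 <- bestAlignment(buildAlignmentMatrix(
      x, y, ScoringScheme(annotationBonus = 1), mask))$score
    expect_gte(s1, s0)
    expect_gte(s0, 0)   # boundary of the final row is always reachable
  }
})

test_that("Sprinzl 66-76 assignment places the discriminator and 74-76", {
  ## CCA templated inside the gene: ...stem3, disc A, CCA
  rec <- makeRecord(makeStemGene("ACCA"))
  ann <- assignSprinzl3prime(rec)
  expect_equal(annotationStatus(ann), "ok")
  expect_equal(sprinzlBase(ann, 73), "A")
  expect_equal(c(sprinzlBase(ann, 74), sprinzlBase(ann, 75),
                 sprinzlBase(ann, 76)), c("C", "C", "A"))
  cd <- sprinzlCoords(ann)
  expect_true(all(cd$source[cd$sprinzl >= 73] == "gene"))
  expect_true(templatesCCA(ann))

  ## CCA only in the trailer
  rec2 <- makeRecord(makeStemGene("A"), downstream = "CCAUGAUGCA")
  ann2 <- assignSprinzl3prime(rec2)
  expect_equal(c(sprinzlBase(ann2, 74), sprinzlBase(ann2, 75),
                 sprinzlBase(ann2, 76)), c("C", "C", "A"))
  cd2 <- sprinzlCoords(ann2)
  expect_true(all(cd2$source[cd2$sprinzl %in% 74:76] == "trailer"))
  expect_true(templatesCCA(ann2))

  ## non-CCA 3' end
  rec3 <- makeRecord(makeStemGene("AUGC"))
  ann3 <- assignSprinzl3prime(rec3)
  expect_equal(c(sprinzlBase(ann3, 74), sprinzlBase(ann3, 75),
                 sprinzlBase(ann3, 76)), c("U", "G", "C"))
  expect_false(templatesCCA(ann3))
})

test_that("stem coordinates map to strictly increasing y indices and runs are idempotent", {
  sim <- simulateGenomes(syntheticConfig(), seed = 3)
  for (k in c(1, 10, 25)) {
    a1 <- assignSprinzl3prime(sim$records[k, ])
    yi <- sprinzlCoords(a1)$yIndex
    yi <- yi[!is.na(yi)]
    expect_false(is.unsorted(yi, strictly = TRUE))
    a2 <- assignSprinzl3prime(sim$records[k, ])
    expect_identical(sprinzlCoords(a1), sprinzlCoords(a2))
  }
})

test_that("an empty bonus mask reproduces the bonus-off run", {
  sim <- simulateGenomes(syntheticConfig(pAcc3Missing = 1), seed = 9)
  rec <- sim$records[1, ]
  expect_identical(rec$acc3_pos, ".")
  aOn <- assignSprinzl3prime(rec, useBonus = TRUE)
  aOff <- assignSprinzl3prime(rec, useBonus = FALSE)
  expect_identical(alignmentScore(aOn), alignmentScore(aOff))
  expect_identical(sprinzlCoords(aOn), sprinzlCoords(aOff))
  expect_false(aOn@usedBonus)
})

test_that("templating call requires all of 74-76 to be assigned", {
  coords <- data.frame(sprinzl = 66:76, base = "-",
                       source = "absent", yIndex = NA_integer_)
  coords$base[coords$sprinzl %in% 66:74] <- "A"
  coords$source[coords$sprinzl %in% 66:74] <- "gene"
  coords$yIndex[coords$sprinzl %in% 66:74] <- 1:9
  ann <- new("SprinzlAnnotation", recordId = "r", coords = coords,
             pairs = matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("i", "j"))),
             score = 0, usedBonus = FALSE, status = "truncated")
  expect_false(templatesCCA(ann))
})
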