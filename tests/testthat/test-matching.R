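test_that("consensus-to-PWM conversion follows the pseudo-mass rule", {
  expect_equal(unname(consensusToPwm("A", pseudo = 0)[, 1]),
               c(1, 0, 0, 0))
  expect_equal(unname(consensusToPwm("N")[, 1]), rep(0.25, 4))
  expect_equal(unname(consensusToPwm("W", pseudo = 0.01)[, 1]),
               c(0.49, 0.01, 0.01, 0.49))
  pwm <- consensusToPwm("ACGTRYSWKMBDHVN")
  expect_true(all(colSums(pwm) == 1))
  expect_error(consensusToPwm("AXG"), "invalid IUPAC")
  expect_error(consensusToPwm("A", pseudo = 0.3), "pseudo")
})

test_that("self-alignment and reverse-complement self-alignment score 0", {
  q <- consensusToPwm("ACGGTA")
  s <- pwmAlignScore(q, q)
  expect_equal(s$score, 0)
  expect_identical(s$offset, 0L)
  expect_identical(s$orientation, "+")
  s2 <- pwmAlignScore(q, revcompPwm(q))
  expect_equal(s2$score, 0)
  expect_identical(s2$orientation, "-")
})

test_that("alignment equals the exhaustive enumeration oracle", {
  set.seed(77)
  for (trial in 1:40) {
    q <- randomPwm(sample(4:10, 1))
    t <- randomPwm(sample(4:10, 1))
    got <- pwmAlignScore(q, t)
    tab <- bruteAlignTable(q, t)
    expect_equal(got$score, min(tab$score), tolerance = 1e-12)
    ## the reported alignment achieves the reported score in the oracle
    hit <- tab[tab$offset == got$offset &
                 tab$orientation == got$orientation, ]
    expect_equal(hit$score, got$score, tolerance = 1e-12)
  }
})

test_that("alignment is invariant to reverse-complementing both PWMs", {
  set.seed(9)
  for (trial in 1:10) {
    q <- randomPwm(6); t <- randomPwm(8)
    a <- pwmAlignScore(q, t)
    b <- pwmAlignScore(revcompPwm(q), revcompPwm(t))
    expect_equal(a$score, b$score, tolerance = 1e-12)
  }
})

test_that("minimum-overlap rule bounds the alignable offsets", {
  ## a width-3 query may overlap at most 3 columns (min(4, 3)), so
  ## every reported alignment covers the full query
  s <- pwmAlignScore(consensusToPwm("ACG"), consensusToPwm("TTTTTTT"))
  expect_identical(s$overlap, 3L)
  ## wider pairs never report overlaps below 4 columns
  set.seed(12)
  for (trial in 1:10) {
    got <- pwmAlignScore(randomPwm(5), randomPwm(6))
    expect_gte(got$overlap, 4L)
  }
  s2 <- pwmAlignScore(consensusToPwm("ACG"), consensusToPwm("ACG"))
  expect_equal(s2$score, 0)
})

test_that("empirical E-values are seeded, bounded and monotone", {
  set.seed(31)
  ## a generic sharp target: distinct columns, so column shuffles almost
  ## never recreate a zero-score alignment
  sharp <- randomPwm(8)
  db <- list(SHARP = sharp, OTHER = consensusToPwm("TTGGCCAA"))
  q <- sharp
  e1 <- empiricalEvalue(q, db, nShuffles = 200, seed = 5)
  e2 <- empiricalEvalue(q, db, nShuffles = 200, seed = 5)
  expect_identical(e1, e2)
  ## a perfect match against it attains (or nearly attains) the floor:
  ## only the identity permutation can tie
  iS <- which(e1$target == "SHARP")
  expect_equal(e1$score[iS], 0)
  expect_lte(e1$evalue[iS], 2 * 2 / 201)
  ## E-values never exceed the database size and are positive
  expect_true(all(e1$evalue > 0 & e1$evalue <= 2))
  expect_error(empiricalEvalue(q, list(), 200, 1), "empty")
  expect_error(empiricalEvalue(q, db, nShuffles = 50), ">= 100")
})

test_that("a uniform query is blind to column shuffling", {
  db <- list(TGT = consensusToPwm("TTGACTCA"))
  q <- consensusToPwm(strrep("N", 6))
  e <- empiricalEvalue(q, db, nShuffles = 150, seed = 3)
  ## distance is unchanged by any column permutation => all null scores
  ## tie the observed one => evalue == dbSize
  expect_equal(e$evalue, 1)
})

test_that("match reports rank a planted database motif first", {
  db <- list(MBP1 = consensusToPwm("ACGCGT"),
             DECOY1 = consensusToPwm("TTATWTAA"),
             DECOY2 = consensusToPwm("GGCCSGG"))
  occ <- data.frame(gene = "g1", distance = 10L, strand = "+",
                    stringsAsFactors = FALSE)
  rep <- new("MotifReport", consensus = "ACGCGT", count = 1L,
             sig = 5, coverage = 0.85, occurrences = list(occ),
             nGenes = 1L, regionLength = 800L, nCandidates = 1)
  m <- matchReport(rep, db, maxEvalue = 3, nShuffles = 150, seed = 2)
  expect_identical(m$target[1], "MBP1")
  expect_equal(m$coverage, rep(0.85, nrow(m)))  # pass-through
  empty <- new("MotifReport", consensus = character(0),
               count = integer(0), sig = numeric(0),
               coverage = numeric(0), occurrences = list(),
               nGenes = 1L, regionLength = 800L, nCandidates = 1)
  expect_identical(nrow(matchReport(empty, db, nShuffles = 150)), 0L)
})
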