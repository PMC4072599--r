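test_that("gamma priors peak exactly at their centers", {
  for (a in c(2, 5, 10, 50)) {
    cfg <- priorConfig(lengthShape = a, contigShape = a)
    grid <- seq_len(20000L)
    lp <- vapply(grid, function(x) logPrior(x, 1L, cfg), numeric(1L))
    expect_equal(grid[which.max(lp)], 5386L)
    nGrid <- seq_len(50L)
    lpn <- vapply(nGrid, function(n) logPrior(5386, n, cfg), numeric(1L))
    expect_equal(nGrid[which.max(lpn)], 1L)
    ## mode identity (alpha - 1) * theta = center holds exactly
    expect_equal((a - 1) * (5386 / (a - 1)), 5386)
  }
  expect_equal(logPrior(123, 7, priorConfig(mode = "flat")), 0)
  expect_error(gammaPrior(1, 5386), "shape")
  expect_error(gammaPrior(2, -1), "center")
  ## impossible assemblies are floored, not NaN
  expect_true(is.finite(logPrior(0, 0, priorConfig())))
  expect_lt(logPrior(0, 1, priorConfig()), logPrior(5386, 1, priorConfig()))
})

test_that("placement log probability counts matches and mismatches", {
  m0 <- readModel(errorRate = 0)
  expect_equal(placementLogProb("ACGT", "TTACGTTT", 3L, "+", m0), 0)
  expect_equal(placementLogProb("ACGT", "TTACGTTT", 1L, "+", m0), -Inf)
  m <- readModel(errorRate = 0.01)
  expect_equal(placementLogProb("AT", "AA", 1L, "+", m),
               log(0.99) + log(0.01 / 3))
  ## strand '-' compares the reverse complement
  expect_equal(placementLogProb("AACGT", "ACGTT", 1L, "-", m0), 0)
  expect_error(placementLogProb("ACGT", "ACG", 1L), "range")
})

test_that("read probability equals the brute-force placement sum", {
  m <- readModel(errorRate = 0.01)
  ## exact single forward placement: log(1/2)
  expect_equal(readLogProb("AACGT", "AACGT", readModel(errorRate = 0)),
               log(1 / 2))
  ## absent read with no error tolerance hits the (-Inf) floor
  expect_equal(readLogProb("AAAAA", "CCCCCCCCCC", readModel(errorRate = 0)),
               -Inf)
  ## with a positive error rate the floor is the worst-case placement
  expect_equal(readLogProb("AAAAA", "CCCC", readModel(errorRate = 0.01)),
               5 * log(0.01 / 3) - log(2 * 4))
  ## random instances against the independent enumeration oracle
  set.seed(41)
  for (i in 1:120) {
    nc <- sample(1:3, 1L)
    contigs <- vapply(seq_len(nc), function(j) randSeq(sample(8:50, 1L)),
                      character(1L))
    read <- randSeq(sample(3:10, 1L))
    expect_equal(readLogProb(read, contigs, m),
                 bruteReadLogProb(read, contigs, 0.01), tolerance = 1e-12)
  }
  ## doubling the contig: verified against brute force
  ct <- randSeq(30L); rd <- substr(ct, 11L, 18L)
  expect_equal(readLogProb(rd, paste0(ct, ct), m),
               bruteReadLogProb(rd, paste0(ct, ct), 0.01), tolerance = 1e-12)
})

test_that("seed search agrees with exhaustive enumeration on close
           placements", {
  set.seed(17)
  gen <- simulateGenome(400L, 0L)
  pairs <- simulatePairedReads(gen$genome, NULL, 60L, readLength = 80L,
                               insertMean = 120, insertSd = 10,
                               errorRate = 0.01)
  reads <- as.character(orientedReads(pairs))
  m <- readModel(errorRate = 0.01)
  ctg <- gen$genome
  attr(ctg, "circular") <- TRUE
  expect_equal(logLikelihood(ctg, reads, m, method = "seed"),
               logLikelihood(ctg, reads, m, method = "exhaustive"),
               tolerance = 1e-6)
})

test_that("likelihood basics: N = 1, prior-only, empty contigs", {
  m <- readModel(errorRate = 0.01)
  rd <- "ACGTACGTAA"
  ct <- "TTACGTACGTAATT"
  expect_equal(logLikelihood(ct, rd, m), readLogProb(rd, ct, m))
  expect_equal(logLikelihood(ct, rd, m, average = TRUE),
               readLogProb(rd, ct, m))
  ## prior_only zeroes the likelihood inside the posterior
  toy <- toy2()
  s <- randomState(toy$g, seed = 3L)
  po <- logPosterior(s, toy$g, "ACGT",
                     priorConfig(mode = "prior_only"))
  expect_equal(po, logPrior(totalLength(s), nContigs(s), priorConfig()))
  ## no contigs: every read floored
  expect_true(is.finite(logLikelihood(character(0L), rd,
                                      readModel(errorRate = 0.01))))
})

test_that("the true genome outranks substituted genomes", {
  set.seed(29)
  wins <- 0L
  for (trial in 1:20) {
    gen <- simulateGenome(200L, 0L)
    pairs <- simulatePairedReads(gen$genome, NULL, 40L, readLength = 50L,
                                 insertMean = 80, insertSd = 8,
                                 errorRate = 0)
    reads <- as.character(orientedReads(pairs))
    m <- readModel(errorRate = 0.01)
    ctg <- gen$genome; attr(ctg, "circular") <- TRUE
    llTrue <- logLikelihood(ctg, reads, m)
    ok <- TRUE
    for (j in 1:5) {
      p <- sample.int(200L, 1L)
      mut <- gen$genome
      alts <- setdiff(c("A", "C", "G", "T"), substr(mut, p, p))
      substr(mut, p, p) <- alts[sample.int(3L, 1L)]
      attr(mut, "circular") <- TRUE
      if (logLikelihood(mut, reads, m) >= llTrue) ok <- FALSE
    }
    if (ok) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("posterior prefers the supported bubble branch", {
  toy <- toyBubble(1L, seed = 31L)
  g <- toy$g
  et <- edgeTable(g)
  branches <- which(tabulate(et$from, nbins = nNodes(g)) == 1L)
  cycleVia <- function(b) {
    act <- rep(FALSE, nEdges(g))
    act[et$from == b | et$to == b] <- TRUE
    assemblyState(g, act)
  }
  sA <- cycleVia(branches[1L]); sB <- cycleVia(branches[2L])
  ## reads from one haplotype only (the reference allele)
  set.seed(6)
  pure <- simulatePairedReads(toy$genome, NULL, 150L, readLength = 60L,
                              insertMean = 80, insertSd = 5, errorRate = 0)
  reads <- orientedReads(pure)
  m <- readModel(errorRate = 0.002)
  lpA <- logPosterior(sA, g, reads, model = m)
  lpB <- logPosterior(sB, g, reads, model = m)
  refState <- if (canonicalRotation(spellPath(g, which(activeEdges(sA)))) ==
                  canonicalRotation(toy$genome)) "A" else "B"
  if (refState == "A") expect_gt(lpA, lpB) else expect_gt(lpB, lpA)
})

test_that("paired scoring favors the correct insert size", {
  set.seed(51)
  gen <- simulateGenome(150L, 0L)
  m <- readModel(errorRate = 0.01, insertMean = 60, insertSd = 5)
  fwd <- substr(gen$genome, 11L, 40L)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gen$genome, 41L, 70L))))
  good <- readPairLogProb(fwd, rev, gen$genome, m)
  ## same mates scored under a wildly wrong insert model
  mBad <- readModel(errorRate = 0.01, insertMean = 400, insertSd = 5)
  bad <- readPairLogProb(fwd, rev, gen$genome, mBad)
  expect_gt(good, bad)
  expect_equal(pairedLogLikelihood(gen$genome,
                                   makePairs(fwd, rev), m), good)
})

test_that("analysis config files round-trip prior and model settings", {
  f <- withr::local_tempfile()
  writeLines(c("# benchmark settings", "prior.length.center=300",
               "prior.length.shape=10", "prior.mode=flat",
               "model.error_rate=0.01", "model.paired=true"), f)
  conf <- readAnalysisConfig(f)
  expect_equal(conf$cfg@lengthPrior@center, 300)
  expect_equal(conf$cfg@lengthPrior@shape, 10)
  expect_equal(conf$cfg@mode, "flat")
  expect_equal(conf$model@errorRate, 0.01)
  expect_true(conf$model@paired)
  ## defaults survive for unspecified keys
  expect_equal(conf$cfg@contigPrior@center, 1)
  writeLines("bogus.key=1", f)
  expect_error(readAnalysisConfig(f), "unknown config key")
})
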