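test_that("cross-chain SD is zero for identical chains and known for
           frozen complementary chains", {
  g <- toy2()$g
  stub <- function(act) 0.3 * sum(act)
  t1 <- runChain(g, stub, 400L, seed = 2L)
  expect_equal(crossChainSD(list(t1, t1)), rep(0, 400L))
  expect_error(crossChainSD(list(t1)), "2 chains")
  ## chains frozen at complementary single-edge states: per differing edge
  ## the two cumulative frequencies are {0, 1}, sd = sqrt(1/2) with n-1
  mk <- function(e) {
    st <- matrix(FALSE, 100L, nEdges(g)); st[, e] <- TRUE
    new("ChainTrace", iteration = 1:100, accepted = rep(TRUE, 100L),
        logPosterior = numeric(100L), states = st, proposals = 100L,
        acceptances = 100L, seed = 1L, recordMode = "all")
  }
  sdSeries <- crossChainSD(list(mk(1L), mk(2L)))
  twoPoint <- stats::sd(c(0, 1))          # sqrt(1/2)
  expect_equal(sdSeries, rep(2 * twoPoint / nEdges(g), 100L))
})

test_that("frequency agreement pairs chains and reports max deviation", {
  g <- toy2()$g
  stub <- function(act) 0.3 * sum(act)
  t1 <- runChain(g, stub, 400L, seed = 2L)
  self <- frequencyAgreement(t1, t1, g)
  expect_equal(self$maxDeviation, 0)
  expect_equal(self$pairs$freqA, self$pairs$freqB)
  ## frozen disjoint chains deviate by exactly 1 on differing edges
  mk <- function(e) {
    st <- matrix(FALSE, 50L, nEdges(g)); st[, e] <- TRUE
    new("ChainTrace", iteration = 1:50, accepted = rep(TRUE, 50L),
        logPosterior = numeric(50L), states = st, proposals = 50L,
        acceptances = 50L, seed = 1L, recordMode = "all")
  }
  dis <- frequencyAgreement(mk(1L), mk(2L))
  expect_equal(dis$maxDeviation, 1.0)
})

test_that("majority consensus includes supra-threshold edges and resolves
           conflicts by frequency", {
  g <- toy2()$g
  et <- edgeTable(g)
  states <- enumerateValidStates(g)
  cyc <- states[[which(vapply(states, sum, integer(1L)) == 4L)[1L]]]
  ## a point-mass posterior reproduces the state's contigs exactly
  freqs <- as.numeric(cyc)
  cons <- majorityConsensus(freqs, g)
  expect_identical(activeEdges(cons@state), cyc)
  expect_equal(cons@contigs$sequence,
               as.character(activeContigs(assemblyState(g, cyc), g)))
  expect_equal(cons@contigs$posterior, 1)
  ## bubble with branch frequencies 0.8 / 0.2: only the strong branch
  fork <- et$from[duplicated(et$from)][1L]
  branchEdges <- which(et$from == fork)
  freqs2 <- freqs
  freqs2[branchEdges] <- c(0.8, 0.2)
  cons2 <- majorityConsensus(freqs2, g)
  expect_true(activeEdges(cons2@state)[branchEdges[1L]])
  expect_false(activeEdges(cons2@state)[branchEdges[2L]])
  ## exact tie at threshold: both qualify, lower index kept, other flagged
  freqs3 <- freqs
  freqs3[branchEdges] <- 0.5
  cons3 <- majorityConsensus(freqs3, g)
  expect_true(activeEdges(cons3@state)[branchEdges[1L]])
  expect_true(branchEdges[2L] %in% cons3@dropped)
  expect_true(validateState(g, cons3@state))
  ## contig posterior is the minimum along the path
  expect_equal(min(cons2@contigs$posterior), 0.8)
})

test_that("external assemblies are annotated by exact matching on either
           strand", {
  g <- toy2()$g
  freqs <- rep(0.9, nEdges(g))
  states <- enumerateValidStates(g)
  cyc <- states[[which(vapply(states, sum, integer(1L)) == 4L)[1L]]]
  ## open the cycle into a path: a linearized circular contig would split
  ## the node annotation straddling the rotation cut
  path <- cyc
  path[which(path)[1L]] <- FALSE
  consensusSeq <- activeContigs(assemblyState(g, path), g)
  ann <- annotateExternal(g, list(self = as.character(consensusSeq)),
                          freqs)
  onPath <- unique(c(edgeTable(g)$from[path], edgeTable(g)$to[path]))
  nodeRows <- ann[ann$type == "node", ]
  expect_true(all(nodeRows$matched_self[onPath]))
  edgeRows <- ann[ann$type == "edge", ]
  expect_true(all(edgeRows$matched_self[path]))
  ## reverse complement of a node matches too
  rcExt <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(nodeSeqs(g)[1L])))
  annRC <- annotateExternal(g, list(rc = rcExt), freqs)
  expect_true(annRC$matched_rc[annRC$type == "node"][1L])
  ## unrelated sequence matches nothing
  set.seed(12)
  annNo <- annotateExternal(g, list(bogus = randSeq(500L)), freqs)
  expect_false(any(annNo$matched_bogus))
  expect_error(annotateExternal(g, list(empty = character(0L)), freqs),
               "nonempty")
})

test_that("matches for a sub-assembly are a subset of self-matches", {
  g <- toy2()$g
  states <- enumerateValidStates(g)
  cyc <- states[[which(vapply(states, sum, integer(1L)) == 4L)[1L]]]
  full <- as.character(activeContigs(assemblyState(g, cyc), g))
  part <- substr(full, 10L, nchar(full) - 10L)
  ann <- annotateExternal(g, list(full = full, part = part),
                          rep(1, nEdges(g)))
  expect_true(all(!ann$matched_part | ann$matched_full))
})

test_that("outputs round-trip and carry posterior annotations", {
  g <- toy2()$g
  states <- enumerateValidStates(g)
  cyc <- states[[which(vapply(states, sum, integer(1L)) == 4L)[1L]]]
  freqs <- ifelse(cyc, 1, 0.25)
  cons <- majorityConsensus(freqs, g)
  dir <- withr::local_tempdir()
  writeOutputs(cons, freqs, g, dir,
               nodeFreqs = rep(0.5, nNodes(g)),
               diagnostics = list(acceptance = 0.2))
  fa <- readLines(file.path(dir, "consensus.fasta"))
  expect_true(grepl("posterior=1.000", fa[1L], fixed = TRUE))
  expect_true(grepl("circular=true", fa[1L], fixed = TRUE))
  feat <- readFeatureTable(file.path(dir, "features.tsv"))
  expect_equal(feat$posterior[feat$type == "edge"], freqs)
  back <- readGFA(file.path(dir, "graph.gfa"))
  expect_equal(nodeSeqs(back), nodeSeqs(g))
  js <- jsonlite::fromJSON(file.path(dir, "diagnostics.json"))
  expect_equal(js$acceptance, 0.2)
  ## empty consensus still writes, with a warning
  expect_warning(writeOutputs(majorityConsensus(rep(0, nEdges(g)), g),
                              rep(0, nEdges(g)), g,
                              withr::local_tempdir()), "empty")
})
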