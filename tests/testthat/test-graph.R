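test_that("de Bruijn construction records k-mers and adjacencies", {
  g <- buildDeBruijn("ACGT", k = 3L)
  expect_equal(nodeSeqs(g), c("ACG", "CGT"))
  expect_equal(edgeTable(g), data.frame(from = 1L, to = 2L))
  g2 <- buildDeBruijn("AAAA", k = 3L)
  expect_equal(nodeSeqs(g2), "AAA")
  expect_equal(edgeTable(g2), data.frame(from = 1L, to = 1L))
  ## k-mers containing N are skipped, not fatal
  g3 <- buildDeBruijn(c("ACGNT", "ACGTA"), k = 3L)
  expect_false(any(grepl("N", nodeSeqs(g3))))
  expect_error(buildDeBruijn("ACG", k = 5L), "no read")
  expect_error(buildDeBruijn("ACGT", k = 4L))  # k must be odd
})

test_that("min.count drops rare k-mers", {
  g <- buildDeBruijn(c("ACGTA", "ACGTA", "ACGGG"), k = 3L, min.count = 2L)
  expect_setequal(nodeSeqs(g), c("ACG", "CGT", "GTA"))
})

test_that("tip trimming removes dead-end chains recursively", {
  ## 4-cycle plus a single dangling node
  g <- buildDeBruijn(c("ACGTACG", "TACGG"), k = 3L)
  expect_true("CGG" %in% nodeSeqs(g))
  t <- trimTips(g)
  expect_setequal(nodeSeqs(t), c("ACG", "CGT", "GTA", "TAC"))
  ## already tipless graph is unchanged (idempotence)
  expect_equal(nodeSeqs(trimTips(t)), nodeSeqs(t))
  expect_equal(edgeTable(trimTips(t)), edgeTable(t))
  ## a chain hanging off the cycle disappears over several rounds
  g2 <- buildDeBruijn(c("ACGTACG", "TACGGCCAT"), k = 3L)
  t2 <- trimTips(g2)
  expect_setequal(nodeSeqs(t2), c("ACG", "CGT", "GTA", "TAC"))
  ## oracle: iterate single-round removal to fixpoint by hand
  byHand <- g2
  repeat {
    et <- edgeTable(byHand)
    indeg <- tabulate(et$to, nbins = nNodes(byHand))
    outdeg <- tabulate(et$from, nbins = nNodes(byHand))
    bad <- indeg == 0L | outdeg == 0L
    if (!any(bad)) break
    byHand <- AssemblySampler:::subsetGraph(byHand, which(!bad))
  }
  expect_equal(nodeSeqs(t2), nodeSeqs(byHand))
})

test_that("linear mode only trims tips shorter than 2k", {
  ## path graph from a single long read: its ends are legitimate dead ends
  g <- buildDeBruijn(strrep("ACGTT", 8L), k = 5L)
  t <- trimTips(g, mode = "linear")
  expect_gt(nNodes(t), 0L)
  ## a short spur off the path is removed
  spur <- paste0(substr(strrep("ACGTT", 8L), 5L, 12L), "GG")
  g2 <- buildDeBruijn(c(strrep("ACGTT", 8L), spur), k = 5L)
  t2 <- trimTips(g2, mode = "linear")
  expect_false(any(grepl("GG$", nodeSeqs(t2))))
})

test_that("unambiguous chains merge with one nucleotide per merged node", {
  g <- buildDeBruijn("ACGTA", k = 3L)   # chain ACG -> CGT -> GTA
  m <- mergeUnambiguousPaths(g)
  expect_equal(nodeSeqs(m), "ACGTA")
  expect_equal(nEdges(m), 0L)
  ## merging twice changes nothing
  m2 <- mergeUnambiguousPaths(m)
  expect_equal(nodeSeqs(m2), nodeSeqs(m))
})

test_that("bubbles are preserved by merging; pure cycles collapse", {
  toy <- toy2()
  expect_equal(countBubbles(toy$g), 2L)
  expect_equal(nNodes(toy$g), 6L)
  expect_equal(nEdges(toy$g), 8L)
  ## forks/joins not merged across branch points
  et <- edgeTable(toy$g)
  outdeg <- tabulate(et$from, nbins = nNodes(toy$g))
  expect_equal(sum(outdeg >= 2L), 2L)
  ## pure cycle collapses to one node with one self-edge
  cyc <- mergeUnambiguousPaths(trimTips(buildDeBruijn("ACGTACG", k = 3L)))
  expect_equal(nNodes(cyc), 1L)
  expect_equal(edgeTable(cyc), data.frame(from = 1L, to = 1L))
  expect_equal(nchar(nodeSeqs(cyc)), 4L + 2L)  # cycle length + k - 1
})

test_that("sequence is conserved through merging", {
  ## spell the chain before merging and compare to the merged annotation
  g <- buildDeBruijn("ACGTAACC", k = 3L)
  path <- seq_len(nEdges(g))
  ## reorder edge indices into a contiguous chain
  et <- edgeTable(g)
  start <- setdiff(et$from, et$to)
  ord <- integer(0L); cur <- start
  while (length(ord) < nEdges(g)) {
    e <- which(et$from == cur)
    ord <- c(ord, e); cur <- et$to[e]
  }
  spelled <- spellPath(g, ord)
  merged <- mergeUnambiguousPaths(g)
  expect_equal(spelled, "ACGTAACC")
  expect_equal(nodeSeqs(merged), "ACGTAACC")
})

test_that("largest weak component is chosen by annotation length with
           lexicographic tie-break", {
  g <- buildDeBruijn(c("AAACCCAAG", "GGGTTT"), k = 3L)
  big <- largestWeakComponent(g)
  expect_true(all(grepl("^[ACG]+$", nodeSeqs(big))))
  expect_false(any(grepl("T", nodeSeqs(big))))
  ## constructed tie: equal total lengths, component containing the
  ## lexicographically smallest annotation wins
  g2 <- buildDeBruijn(c("AAACCC", "GGGTTT"), k = 3L)
  tie <- largestWeakComponent(g2)
  expect_true("AAA" %in% nodeSeqs(tie))
  ## single component: identity
  g3 <- buildDeBruijn("ACGTA", k = 3L)
  expect_equal(nodeSeqs(largestWeakComponent(g3)), nodeSeqs(g3))
})

test_that("spellPath removes overlaps, trims and rotates cycles", {
  toy <- toy2()
  g <- toy$g
  ## a single node with no edges spells its annotation
  expect_equal(spellPath(g, integer(0L), node = 1L), nodeSeqs(g)[1L])
  expect_error(spellPath(g, integer(0L)), "empty path")
  ## two-node overlap removal by hand (k = 3)
  h <- buildDeBruijn("ACGTAC", k = 3L)
  et <- edgeTable(h)
  e1 <- which(et$from == match("ACG", nodeSeqs(h)) &
              et$to == match("CGT", nodeSeqs(h)))
  expect_equal(spellPath(h, e1), "ACGT")
  expect_error(spellPath(h, c(e1, e1)), "repeats")
  ## cycle spelling conserves the simulated genome length exactly
  tiling <- vapply(0:9, function(i)
    substr(strrep(toy$genome, 2L), i * 30L + 1L, i * 30L + 330L),
    character(1L))
  circle <- reduceGraph(buildDeBruijn(tiling, k = 15L))
  expect_equal(nchar(spellPath(circle, 1L)), 300L)
  expect_equal(spellPath(circle, 1L), canonicalRotation(toy$genome))
})

test_that("circular genome without repeats collapses to one self-edge and
           spells the genome rotation", {
  set.seed(5)
  gen <- simulateGenome(200L, 0L)
  reads <- vapply(seq_len(40L), function(i) {
    s <- sample.int(200L, 1L)
    substr(strrep(gen$genome, 2L), s, s + 49L)
  }, character(1L))
  g <- reduceGraph(buildDeBruijn(reads, k = 15L))
  expect_equal(nNodes(g), 1L)
  expect_equal(nEdges(g), 1L)
  expect_equal(spellPath(g, 1L), canonicalRotation(gen$genome))
})

test_that("variant sites yield exactly that many bubbles", {
  for (v in 1:2) {
    toy <- toyBubble(v, seed = 20L + v)
    expect_equal(countBubbles(toy$g), v)
    ## direct k-mer oracle: branch nodes beyond the backbone
    expect_equal(nNodes(toy$g), 2L * v + v * 2L - v)  # v segments + 2v branches
  }
})

test_that("GFA round-trips the graph; DOT is written", {
  g <- toy2()$g
  gfa <- withr::local_tempfile(fileext = ".gfa")
  writeGFA(g, gfa)
  back <- readGFA(gfa)
  expect_equal(nodeSeqs(back), nodeSeqs(g))
  expect_equal(edgeTable(back), edgeTable(g))
  expect_equal(kSize(back), kSize(g))
  dot <- withr::local_tempfile(fileext = ".dot")
  writeDOT(g, dot, edgePosterior = rep(0.5, nEdges(g)))
  txt <- readLines(dot)
  expect_true(any(grepl("digraph", txt)))
  expect_equal(sum(grepl("->", txt)), nEdges(g))
})
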