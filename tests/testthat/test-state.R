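test_that("state construction caches totals and rejects invalid vectors", {
  g <- toy2()$g
  states <- enumerateValidStates(g)
  expect_length(states, 81L)
  ## cached totals equal recomputation from spelled contigs
  set.seed(3)
  for (act in states[sample.int(81L, 15L)]) {
    s <- assemblyState(g, act)
    ctg <- activeContigs(s, g)
    expect_equal(s@totalLength, sum(nchar(ctg)))
    expect_equal(nContigs(s), length(ctg))
    expect_true(validateState(g, s))
  }
  ## both branches of a bubble active is invalid
  et <- edgeTable(g)
  fork <- et$from[duplicated(et$from)][1L]
  both <- rep(FALSE, nEdges(g))
  both[which(et$from == fork)] <- TRUE
  expect_false(validateState(g, both))
  expect_error(assemblyState(g, both), "constraint")
  ## all-inactive is valid and spells nothing
  none <- assemblyState(g, rep(FALSE, nEdges(g)))
  expect_equal(nContigs(none), 0L)
  expect_length(activeContigs(none, g), 0L)
})

test_that("random states are reproducible and always valid", {
  g <- toy2()$g
  s1 <- randomState(g, seed = 5L)
  s2 <- randomState(g, seed = 5L)
  expect_identical(activeEdges(s1), activeEdges(s2))
  set.seed(1)
  for (i in 1:200) expect_true(validateState(g, randomState(g)))
  ## single self-edge graph: both settings of the edge are valid
  cyc <- mergeUnambiguousPaths(trimTips(buildDeBruijn("ACGTACG", k = 3L)))
  expect_true(validateState(cyc, TRUE))
  expect_true(validateState(cyc, FALSE))
})

test_that("deactivating an edge splits its path and changes nothing else", {
  g <- toy2()$g
  ## force a state with a full cycle (4 edges)
  states <- enumerateValidStates(g)
  nact <- vapply(states, sum, integer(1L))
  cyc <- states[[which(nact == 4L)[1L]]]
  s <- assemblyState(g, cyc)
  set.seed(7)
  sawSplit <- FALSE
  for (i in 1:50) {
    p <- perturb(s, g)
    d <- which(activeEdges(s) != activeEdges(p))
    if (length(d) == 1L && !activeEdges(p)[d]) {
      sawSplit <- TRUE
      ## a cycle opened into a path: contig count stays >= 1
      expect_true(validateState(g, p))
    }
  }
  expect_true(sawSplit)
})

test_that("activating a bubble edge switches the whole branch", {
  ## two-bubble graph: forks and joins are distinct nodes, so activating an
  ## edge of the inactive branch displaces the whole active branch
  g <- toy2()$g
  et <- edgeTable(g)
  forks <- sort(unique(et$from[duplicated(et$from)]))
  branchesOf <- function(f) sort(et$to[et$from == f])
  cycleVia <- function(b1, b2) {
    act <- rep(FALSE, nEdges(g))
    for (b in c(b1, b2)) act[et$from == b | et$to == b] <- TRUE
    act
  }
  bs1 <- branchesOf(forks[1L]); bs2 <- branchesOf(forks[2L])
  a <- assemblyState(g, cycleVia(bs1[1L], bs2[1L]))
  target <- stateKeyOf(cycleVia(bs1[2L], bs2[1L]))
  set.seed(9)
  outcomes <- character(0L)
  for (i in 1:300) {
    p <- perturb(a, g)
    expect_true(validateState(g, p))
    outcomes <- c(outcomes, stateKeyOf(activeEdges(p)))
  }
  ## the complete branch swap is reachable in ONE move: the entire
  ## alternate branch activates and the displaced branch deactivates
  expect_true(target %in% outcomes)
})

test_that("propose composes perturbations deterministically", {
  g <- toy2()$g
  s <- randomState(g, seed = 4L)
  set.seed(11); p1 <- propose(s, g, nPerturbations = 3L)
  set.seed(11); p2 <- propose(s, g, nPerturbations = 3L)
  expect_identical(activeEdges(p1), activeEdges(p2))
  set.seed(12); q1 <- propose(s, g, nPerturbations = 1L)
  set.seed(12); q2 <- perturb(s, g)
  expect_identical(activeEdges(q1), activeEdges(q2))
  ## Hamming distance bounded by the edge count
  set.seed(13)
  for (i in 1:100) {
    p <- propose(s, g)
    expect_lte(sum(activeEdges(p) != activeEdges(s)), nEdges(g))
    expect_true(validateState(g, p))
  }
})

test_that("plain perturbation closure stays within valid states", {
  g <- toy2()$g
  gi <- AssemblySampler:::graphIndex(g)
  act <- rep(FALSE, nEdges(g))
  set.seed(21)
  seen <- new.env(parent = emptyenv())
  for (i in 1:20000) {
    act <- AssemblySampler:::perturbActive(gi, act)
    expect_true(AssemblySampler:::validActive(gi, act))
    seen[[stateKeyOf(act)]] <- TRUE
  }
  expect_gt(length(ls(seen)), 40L)
})

test_that("the exact toggle+walk sampler visits every valid state", {
  g <- toy2()$g
  states <- enumerateValidStates(g)
  tr <- runChainHastings(g, function(a) 0, 30000L, seed = 8L)
  visited <- unique(apply(tr@states, 1L, stateKeyOf))
  expect_setequal(visited, vapply(states, stateKeyOf, character(1L)))
})

test_that("states serialize to a 0/1 line plus JSON summary", {
  g <- toy2()$g
  s <- randomState(g, seed = 6L)
  f <- withr::local_tempfile()
  writeState(s, f)
  lines <- readLines(f)
  expect_equal(lines[1L], stateKeyOf(activeEdges(s)))
  js <- jsonlite::fromJSON(lines[2L])
  expect_equal(js$totalLength, totalLength(s))
  expect_equal(js$nContigs, nContigs(s))
})
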