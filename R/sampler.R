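#' Memoized log-posterior closure for a fixed graph and read set
#'
#' Builds the read bank once and returns a function mapping a logical
#' active-edge vector to its unnormalized log posterior. Results are cached
#' by state, so the sampler pays the likelihood cost only once per distinct
#' assembly hypothesis; the cache may be shared between independent chains
#' (the posterior depends only on the state).
#'
#' @param g an [AssemblyGraph-class].
#' @param reads the read set (character vector or `DNAStringSet`); ignored
#'   in `"prior_only"` mode.
#' @param cfg a [PriorConfig-class].
#' @param model a [ReadModel-class].
#' @param method placement search passed to the scorer (`"seed"` default:
#'   the sampler evaluates many states on full read sets).
#' @param cache environment used for memoization (share to share work).
#' @return a function `f(activeLogicalVector) -> numeric`.
#' @export
makeLogPosterior <- function(g, reads, cfg = priorConfig(),
                             model = readModel(), method = "seed",
                             cache = new.env(parent = emptyenv())) {
  bank <- if (cfg@mode == "prior_only") NULL else
    newReadBank(as.character(reads), model)
  function(act) {
    key <- stateKey(act)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- assemblyState(g, act)
    ll <- 0
    if (!is.null(bank)) {
      ctg <- activeContigs(s, g)
      ll <- scoreReadBank(bank, ctg, model,
                          circular = attr(ctg, "circular"),
                          method = method)$sum
    }
    lp <- ll + logPrior(s@totalLength, s@nContigs, cfg)
    cache[[key]] <- lp
    lp
  }
}

#' One Metropolis step
#'
#' Proposes a new state ([propose()]), computes the log odds ratio
#' `logR = logpost(new) - logpost(current)`, and accepts automatically if
#' `logR > 0`, otherwise with probability `exp(logR)`. Equal posteriors
#' (`R = 1`) are always accepted. On rejection the current state is
#' returned unchanged. No Hastings correction is applied: the acceptance
#' rule is the plain posterior odds ratio.
#'
#' @param current a valid [AssemblyState-class].
#' @param logpostCurrent its log posterior.
#' @param g the [AssemblyGraph-class].
#' @param logpostFun function from a logical active vector to a log
#'   posterior (e.g. from [makeLogPosterior()]).
#' @param nPerturbations perturbations per proposal.
#' @return a list with `state`, `logpost`, `accepted`.
#' @export
metropolisStep <- function(current, logpostCurrent, g, logpostFun,
                           nPerturbations = 3L) {
  gi <- graphIndex(g)
  act <- current@active
  for (i in seq_len(nPerturbations)) act <- perturbActive(gi, act)
  lpNew <- logpostFun(act)
  logR <- lpNew - logpostCurrent
  if (is.nan(logR)) logR <- 0         # -Inf vs -Inf: equal posteriors
  accepted <- logR >= 0 || runif(1L) < exp(logR)
  if (accepted)
    list(state = assemblyState(g, act), logpost = lpNew, accepted = TRUE)
  else
    list(state = current, logpost = logpostCurrent, accepted = FALSE)
}

#' Run one Metropolis chain over assembly states
#'
#' Initializes from a random state (seeded, reproducible) and iterates
#' [metropolisStep()]. With `recordMode = "all"` every iteration is
#' recorded (a rejection re-records the current state); with
#' `"accepted_only"` only accepted proposals are recorded, matching
#' summaries quoted in terms of accepted samples.
#'
#' @param g a nonempty [AssemblyGraph-class].
#' @param logpostFun log-posterior function over active vectors (see
#'   [makeLogPosterior()]).
#' @param nIterations number of Metropolis steps (>= 1).
#' @param nPerturbations perturbations per proposal (default 3).
#' @param seed integer RNG seed; the trace is deterministic given the seed.
#' @param recordMode `"all"` or `"accepted_only"`.
#' @param init optional initial [AssemblyState-class] (default: random).
#' @return a [ChainTrace-class].
#' @export
runChain <- function(g, logpostFun, nIterations, nPerturbations = 3L,
                     seed = 1L, recordMode = c("all", "accepted_only"),
                     init = NULL) {
  stopifnot(nIterations >= 1L)
  recordMode <- match.arg(recordMode)
  set.seed(seed)
  gi <- graphIndex(g)
  if (gi$E == 0L) stop("graph has no edges")
  if (is.null(init)) {
    act <- rep(FALSE, gi$E)
    for (i in seq_len(gi$E)) act <- perturbActive(gi, act)
  } else act <- init@active
  lp <- logpostFun(act)
  states <- matrix(FALSE, nrow = nIterations, ncol = gi$E)
  lps <- numeric(nIterations)
  accs <- logical(nIterations)
  iter <- integer(nIterations)
  nrec <- 0L
  nacc <- 0L
  for (it in seq_len(nIterations)) {
    actNew <- act
    for (i in seq_len(nPerturbations)) actNew <- perturbActive(gi, actNew)
    lpNew <- logpostFun(actNew)
    logR <- lpNew - lp
    if (is.nan(logR)) logR <- 0
    accepted <- logR >= 0 || runif(1L) < exp(logR)
    if (accepted) { act <- actNew; lp <- lpNew; nacc <- nacc + 1L }
    if (recordMode == "all" || accepted) {
      nrec <- nrec + 1L
      states[nrec, ] <- act
      lps[nrec] <- lp
      accs[nrec] <- accepted
      iter[nrec] <- it
    }
  }
  new("ChainTrace",
      iteration = iter[seq_len(nrec)], accepted = accs[seq_len(nrec)],
      logPosterior = lps[seq_len(nrec)],
      states = states[seq_len(nrec), , drop = FALSE],
      proposals = as.integer(nIterations), acceptances = nacc,
      seed = as.integer(seed), recordMode = recordMode)
}

#' Run several independent chains
#'
#' Chains differ only in their RNG seed (`seed`, `seed + 1`, ...); the
#' posterior cache is shared across chains since the target is identical.
#'
#' @inheritParams runChain
#' @param nChains number of independent chains (default 3).
#' @return a list of [ChainTrace-class] objects.
#' @export
runChains <- function(g, logpostFun, nIterations, nChains = 3L,
                      nPerturbations = 3L, seed = 1L,
                      recordMode = c("all", "accepted_only")) {
  recordMode <- match.arg(recordMode)
  lapply(seq_len(nChains), function(i)
    runChain(g, logpostFun, nIterations, nPerturbations,
             seed = seed + i - 1L, recordMode = recordMode))
}

setMethod("show", "ChainTrace", function(object) {
  cat("ChainTrace:", length(object@iteration), "records (",
      object@recordMode, ") |", object@acceptances, "/",
      object@proposals, "accepted (",
      sprintf("%.1f%%", 100 * object@acceptances / object@proposals),
      ") | seed", object@seed, "\n")
})

#' Acceptance rate of a chain
#'
#' @param trace a [ChainTrace-class].
#' @return `acceptances / proposals`, in `[0, 1]`.
#' @export
acceptanceRate <- function(trace) {
  stopifnot(trace@proposals >= 1L)
  trace@acceptances / trace@proposals
}

#' Posterior edge frequencies of a chain
#'
#' Fraction of post-burn-in records in which each edge is active -- the
#' cumulative frequency at the end of the chain, the quantity whose
#' stabilization indicates mixing.
#'
#' @param trace a [ChainTrace-class].
#' @param burnIn number of initial records to discard (default 0; the
#'   headline summaries use cumulative frequencies from the start).
#' @return numeric vector of length `nEdges`.
#' @export
edgeFrequencies <- function(trace, burnIn = 0L) {
  nr <- nrow(trace@states)
  stopifnot(burnIn < nr)
  colMeans(trace@states[(burnIn + 1L):nr, , drop = FALSE])
}

#' Posterior node frequencies of a chain
#'
#' Fraction of post-burn-in records in which at least one edge incident to
#' the node is active.
#'
#' @inheritParams edgeFrequencies
#' @param g the [AssemblyGraph-class] the chain ran on.
#' @return numeric vector of length `nNodes`.
#' @export
nodeFrequencies <- function(trace, g, burnIn = 0L) {
  nr <- nrow(trace@states)
  stopifnot(burnIn < nr)
  rows <- (burnIn + 1L):nr
  n <- length(g@nodes)
  freq <- numeric(n)
  for (v in seq_len(n)) {
    inc <- c(which(g@edges[, 1L] == v), which(g@edges[, 2L] == v))
    if (length(inc) > 0L)
      freq[v] <- mean(rowSums(trace@states[rows, inc, drop = FALSE]) > 0L)
  }
  freq
}

## Cumulative edge-frequency matrix of a chain (records x edges).
cumulativeFrequencies <- function(trace) {
  m <- trace@states
  apply(m, 2L, cumsum) / seq_len(nrow(m))
}
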