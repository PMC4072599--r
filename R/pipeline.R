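#' Full Bayesian assembly pipeline
#'
#' Convenience driver tying the modules together: quality filtering, de
#' Bruijn construction, graph reduction, multi-chain Metropolis sampling,
#' convergence diagnostics and majority-rule consensus extraction.
#'
#' @param pairs a [ReadPairs-class] (filtered with [filterPairs()] unless
#'   `filter = FALSE`).
#' @param k k-mer size (default 31).
#' @param min.count k-mer multiplicity cutoff passed to [buildDeBruijn()]
#'   (default 5 for error-containing reads; see the package vignette).
#' @param mode `"circular"` or `"linear"` tip trimming.
#' @param nChains,nIterations,nPerturbations sampler settings.
#' @param seed integer seed (chains use `seed`, `seed + 1`, ...).
#' @param cfg a [PriorConfig-class].
#' @param model a [ReadModel-class].
#' @param threshold majority-rule consensus threshold.
#' @param filter apply the mean-quality filter pipeline first.
#' @param minMeanQuality,nKeep filter settings (see [filterPairs()]).
#' @return a list with `graph` (reduced [AssemblyGraph-class]), `traces`
#'   (list of [ChainTrace-class]), `edgeFreqs`, `nodeFreqs` (averaged over
#'   chains), `consensus` ([ConsensusAssembly-class]) and `diagnostics`
#'   (named list: per-chain acceptance rates, final cross-chain SD, max
#'   pairwise frequency deviation).
#' @export
assemblePosterior <- function(pairs, k = 31L, min.count = 5L,
                              mode = c("circular", "linear"),
                              nChains = 3L, nIterations = 20000L,
                              nPerturbations = 3L, seed = 1L,
                              cfg = priorConfig(), model = readModel(),
                              threshold = 0.5, filter = TRUE,
                              minMeanQuality = 37, nKeep = Inf) {
  mode <- match.arg(mode)
  if (filter)
    pairs <- filterPairs(pairs, minMeanQuality = minMeanQuality, n = nKeep)
  reads <- orientedReads(pairs)
  g <- buildDeBruijn(reads, k = k, min.count = min.count)
  g <- reduceGraph(g, mode = mode)
  logpost <- makeLogPosterior(g, reads, cfg, model, method = "seed")
  traces <- runChains(g, logpost, nIterations, nChains = nChains,
                      nPerturbations = nPerturbations, seed = seed)
  edgeFreqs <- rowMeans(vapply(traces, edgeFrequencies,
                               numeric(nrow(g@edges))))
  nodeFreqs <- rowMeans(vapply(traces, nodeFrequencies,
                               numeric(length(g@nodes)), g = g))
  consensus <- majorityConsensus(edgeFreqs, g, threshold)
  sdSeries <- if (nChains >= 2L) crossChainSD(traces) else NA_real_
  maxDev <- if (nChains >= 2L) {
    combos <- utils::combn(nChains, 2L)
    max(apply(combos, 2L, function(ij)
      frequencyAgreement(traces[[ij[1L]]], traces[[ij[2L]]],
                         g)$maxDeviation))
  } else NA_real_
  diagnostics <- list(
    acceptanceRates = vapply(traces, acceptanceRate, numeric(1L)),
    finalCrossChainSD = sdSeries[length(sdSeries)],
    maxPairwiseFrequencyDeviation = maxDev,
    nBubbles = countBubbles(g),
    nNodes = length(g@nodes), nEdges = nrow(g@edges))
  list(graph = g, traces = traces, edgeFreqs = edgeFreqs,
       nodeFreqs = nodeFreqs, consensus = consensus,
       diagnostics = diagnostics)
}
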