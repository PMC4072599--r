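#' @importClassesFrom Biostrings QualityScaledDNAStringSet DNAStringSet
NULL

#' Paired-end read set
#'
#' Ordered collection of read pairs. Both mates are stored as
#' [Biostrings::QualityScaledDNAStringSet] objects of equal length, so every
#' pair has both mates present by construction.
#'
#' @slot forward forward mates (read 1).
#' @slot reverse reverse mates (read 2), same length as `forward`.
#' @slot provenance free-text description of where the pairs came from.
#' @export
setClass("ReadPairs",
  representation(
    forward = "QualityScaledDNAStringSet",
    reverse = "QualityScaledDNAStringSet",
    provenance = "character"
  )
)

setValidity("ReadPairs", function(object) {
  if (length(object@forward) != length(object@reverse))
    return("forward and reverse mates must have the same length")
  TRUE
})

#' Reduced assembly graph
#'
#' A directed graph whose nodes carry sequence annotations and whose edges
#' represent k-1 base overlaps (the suffix of the source equals the prefix of
#' the target). Freshly built de Bruijn graphs have one node per k-mer; after
#' reduction, nodes carry merged unitig sequences and the graph consists of
#' bubbles joined by unambiguous segments. Edges are kept in a deterministic
#' order (sorted by source then target annotation) and are addressed by their
#' 1-based position in that order; assembly states index this enumeration.
#'
#' @slot k k-mer size used to build the graph (overlap is `k - 1`).
#' @slot nodes character vector of node sequence annotations; the node id is
#'   the index into this vector.
#' @slot edges integer matrix with columns `from` and `to` (node ids), one
#'   row per edge, rows in canonical order.
#' @export
setClass("AssemblyGraph",
  representation(k = "integer", nodes = "character", edges = "matrix")
)

setValidity("AssemblyGraph", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 2L)
    return("k must be a single integer >= 2")
  e <- object@edges
  if (!is.integer(e) || ncol(e) != 2L)
    return("edges must be an integer matrix with columns from, to")
  n <- length(object@nodes)
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      return("edge endpoints must index existing nodes")
    src <- object@nodes[e[, 1L]]
    tgt <- object@nodes[e[, 2L]]
    ok <- substring(src, nchar(src) - k + 2L) == substring(tgt, 1L, k - 1L)
    if (!all(ok))
      return("every edge must overlap by exactly k-1 characters")
  }
  if (any(nchar(object@nodes) < k))
    return("node annotations must have length >= k")
  TRUE
})

#' Assembly hypothesis state
#'
#' One assembly hypothesis: a boolean vector over the graph's edge
#' enumeration. Active edges must form vertex-disjoint paths and cycles (no
#' node may have more than one active incoming or outgoing edge), so every
#' hypothesis spells a set of contiguous contigs. Path decomposition, total
#' length and contig count are cached at construction.
#'
#' @slot active logical vector, one entry per graph edge.
#' @slot paths list of integer vectors of edge indices, one per maximal
#'   active path or cycle.
#' @slot isCycle logical vector parallel to `paths`.
#' @slot totalLength total spelled length (bases) over all contigs.
#' @slot nContigs number of maximal active paths/cycles.
#' @export
setClass("AssemblyState",
  representation(
    active = "logical",
    paths = "list",
    isCycle = "logical",
    totalLength = "numeric",
    nContigs = "integer"
  )
)

#' Gamma prior with a fixed mode
#'
#' Gamma distribution parameterized by shape \eqn{\alpha > 1} and mode
#' \eqn{c}; the scale is derived as \eqn{\theta = c / (\alpha - 1)} so the
#' density's maximum stays at `center` for any shape. Centering the prior at
#' the known genome length (or at one contig) pins the maximum a priori
#' assembly while the shape controls how sharply deviations are penalized.
#'
#' @slot shape shape parameter, must exceed 1 for the mode to exist.
#' @slot center the distribution's mode (must be positive).
#' @export
setClass("GammaPrior", representation(shape = "numeric", center = "numeric"))

setValidity("GammaPrior", function(object) {
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 1)
    return("shape must be a single finite value > 1 (mode parameterization)")
  if (length(object@center) != 1L || !is.finite(object@center) ||
      object@center <= 0)
    return("center must be a single positive value")
  TRUE
})

#' Prior configuration
#'
#' Product of two gamma priors: one on the total assembly length (default
#' mode 5,386 bp, the phiX174 genome length) and one on the number of contigs
#' (default mode 1, a single circular chromosome). `mode` selects the
#' posterior variant: `"full"` (likelihood + priors), `"flat"` (likelihood
#' only; log prior identically 0) or `"prior_only"` (log likelihood
#' identically 0).
#'
#' @slot lengthPrior [GammaPrior-class] on total contig length.
#' @slot contigPrior [GammaPrior-class] on the contig count.
#' @slot mode one of `"full"`, `"flat"`, `"prior_only"`.
#' @export
setClass("PriorConfig",
  representation(
    lengthPrior = "GammaPrior",
    contigPrior = "GammaPrior",
    mode = "character"
  )
)

setValidity("PriorConfig", function(object) {
  if (!object@mode %in% c("full", "flat", "prior_only"))
    return("mode must be one of 'full', 'flat', 'prior_only'")
  TRUE
})

#' Read-generation model
#'
#' Parameters of the placement + substitution-error model under which the
#' probability that an assembly generated each read is computed. A read
#' placed at a given position contributes \eqn{(1-\epsilon)} per matching
#' base and \eqn{\epsilon/3} per mismatching base; the read probability
#' averages over all placements on both strands of all contigs. Reads with
#' no placement are floored at `minLogProb` (or, when `NA`, at the worst
#' possible placement log probability for that read).
#'
#' @slot errorRate per-base substitution probability \eqn{\epsilon \in
#'   [0, 3/4)}.
#' @slot minLogProb floor for unplaceable reads; `NA` derives the floor per
#'   read as `l*log(errorRate/3) - log(2*sum(contig lengths))`.
#' @slot seedLength exact-match seed length for the fast placement search.
#' @slot paired score mates jointly with an insert-size density.
#' @slot insertMean,insertSd normal insert-size model for paired scoring.
#' @export
setClass("ReadModel",
  representation(
    errorRate = "numeric",
    minLogProb = "numeric",
    seedLength = "integer",
    paired = "logical",
    insertMean = "numeric",
    insertSd = "numeric"
  )
)

setValidity("ReadModel", function(object) {
  if (object@errorRate < 0 || object@errorRate >= 0.75)
    return("errorRate must lie in [0, 3/4)")
  if (object@seedLength < 1L)
    return("seedLength must be >= 1")
  TRUE
})

#' MCMC chain trace
#'
#' Per-iteration record of a Metropolis chain over assembly states, plus
#' acceptance bookkeeping. With `recordMode = "all"` a rejected proposal
#' re-records the current state (standard MCMC); with `"accepted_only"` only
#' accepted proposals are recorded.
#'
#' @slot iteration iteration index of each record.
#' @slot accepted whether the proposal at that iteration was accepted.
#' @slot logPosterior unnormalized log posterior of the recorded state.
#' @slot states logical matrix, one row per record, one column per edge.
#' @slot proposals,acceptances totals over the whole run.
#' @slot seed RNG seed the chain was started from.
#' @slot recordMode `"all"` or `"accepted_only"`.
#' @export
setClass("ChainTrace",
  representation(
    iteration = "integer",
    accepted = "logical",
    logPosterior = "numeric",
    states = "matrix",
    proposals = "integer",
    acceptances = "integer",
    seed = "integer",
    recordMode = "character"
  )
)

setValidity("ChainTrace", function(object) {
  if (object@acceptances > object@proposals)
    return("acceptances cannot exceed proposals")
  TRUE
})

#' Majority-rule consensus assembly
#'
#' The assembly formed by edges whose posterior sampling frequency meets the
#' threshold, reduced to a valid state (greedy conflict resolution by
#' descending frequency) and spelled into contigs annotated with the minimum
#' edge posterior along each contig.
#'
#' @slot state the consensus [AssemblyState-class].
#' @slot contigs data.frame with columns `sequence`, `circular`, `length`,
#'   `posterior`.
#' @slot threshold the frequency threshold used.
#' @slot dropped edge indices that met the threshold but were dropped to
#'   keep the state valid (flagged decisions).
#' @export
setClass("ConsensusAssembly",
  representation(
    state = "AssemblyState",
    contigs = "data.frame",
    threshold = "numeric",
    dropped = "integer"
  )
)

#' Simulated ground truth
#'
#' A known circular genome with optional biallelic variant sites, the
#' paired-end reads simulated from it, and the parameters used, so recovery
#' can be checked exactly.
#'
#' @slot genome the circular reference sequence (character).
#' @slot variants data.frame with columns `pos`, `ref`, `alt`, `fraction`.
#' @slot pairs the simulated [ReadPairs-class].
#' @slot seed RNG seed.
#' @slot params named list of simulation parameters.
#' @export
setClass("SimulatedTruth",
  representation(
    genome = "character",
    variants = "data.frame",
    pairs = "ReadPairs",
    seed = "integer",
    params = "list"
  )
)
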