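#' Cross-chain convergence series
#'
#' At each record index, the standard deviation across chains of each
#' edge's cumulative frequency, averaged over edges. Independent chains
#' that converge to the same posterior drive this series toward zero.
#'
#' @param traces list of at least two [ChainTrace-class] objects with equal
#'   record counts.
#' @return numeric series, one value per record index.
#' @export
crossChainSD <- function(traces) {
  if (length(traces) < 2L) stop("need at least 2 chains")
  nr <- vapply(traces, function(t) nrow(t@states), integer(1L))
  if (length(unique(nr)) != 1L)
    stop("chains must have equal record counts")
  cums <- lapply(traces, cumulativeFrequencies)
  k <- length(cums)
  m1 <- Reduce(`+`, cums) / k
  m2 <- Reduce(`+`, lapply(cums, function(x) x * x)) / k
  v <- pmax(m2 - m1 * m1, 0) * k / (k - 1)
  rowMeans(sqrt(v))
}

#' Pairwise frequency agreement between two chains
#'
#' Final cumulative frequencies of each feature (edges, plus nodes when the
#' graph is supplied) in the two chains, paired, with the maximum absolute
#' deviation -- the numeric content of a bivariate chain-agreement plot.
#'
#' @param a,b [ChainTrace-class] objects from the same graph.
#' @param g optional [AssemblyGraph-class] to include node frequencies.
#' @return a list with `pairs` (data.frame `feature`, `type`, `freqA`,
#'   `freqB`) and `maxDeviation`.
#' @export
frequencyAgreement <- function(a, b, g = NULL) {
  fa <- edgeFrequencies(a); fb <- edgeFrequencies(b)
  if (length(fa) != length(fb))
    stop("chains ran on different graphs")
  pairs <- data.frame(feature = seq_along(fa), type = "edge",
                      freqA = fa, freqB = fb)
  if (!is.null(g)) {
    na <- nodeFrequencies(a, g); nb <- nodeFrequencies(b, g)
    pairs <- rbind(pairs, data.frame(feature = seq_along(na),
                                     type = "node", freqA = na, freqB = nb))
  }
  list(pairs = pairs, maxDeviation = max(abs(pairs$freqA - pairs$freqB)))
}

#' Majority-rule consensus assembly
#'
#' Activates every edge whose posterior frequency meets the threshold
#' (`>=`, so exact ties are kept). When supra-threshold edges jointly
#' violate the one-in/one-out validity constraint, edges are admitted
#' greedily by descending frequency (ties: lower edge index), and displaced
#' edges are reported in the `dropped` slot so the decision is auditable.
#' Each consensus contig is annotated with the minimum edge posterior along
#' its path (a conservative contig-level posterior).
#'
#' @param freqs numeric edge-frequency vector (length `nEdges(g)`), e.g.
#'   from [edgeFrequencies()] or averaged over chains.
#' @param g the [AssemblyGraph-class].
#' @param threshold inclusion threshold (default 0.5, majority rule).
#' @return a [ConsensusAssembly-class].
#' @export
majorityConsensus <- function(freqs, g, threshold = 0.5) {
  stopifnot(length(freqs) == nrow(g@edges))
  cand <- which(freqs >= threshold)
  cand <- cand[order(-freqs[cand], cand)]
  n <- length(g@nodes)
  outUsed <- logical(n); inUsed <- logical(n)
  act <- rep(FALSE, nrow(g@edges))
  dropped <- integer(0L)
  for (e in cand) {
    f <- g@edges[e, 1L]; t <- g@edges[e, 2L]
    if (outUsed[f] || inUsed[t]) {
      dropped <- c(dropped, e)
      next
    }
    act[e] <- TRUE; outUsed[f] <- TRUE; inUsed[t] <- TRUE
  }
  s <- assemblyState(g, act)
  post <- vapply(s@paths, function(p) min(freqs[p]), numeric(1L))
  ## match contig order (longest first, then lexicographic)
  raw <- vapply(s@paths, function(p) spellPath(g, p), character(1L))
  ord <- order(-nchar(raw), raw, method = "radix")
  contigs <- data.frame(
    sequence = raw[ord],
    circular = s@isCycle[ord],
    length = nchar(raw[ord]),
    posterior = post[ord],
    stringsAsFactors = FALSE)
  new("ConsensusAssembly", state = s, contigs = contigs,
      threshold = threshold, dropped = dropped)
}

setMethod("show", "ConsensusAssembly", function(object) {
  cat("ConsensusAssembly: threshold", object@threshold, "|",
      nrow(object@contigs), "contig(s),",
      sum(object@contigs$length), "bases")
  if (length(object@dropped) > 0L)
    cat(" |", length(object@dropped), "edge(s) dropped for validity")
  cat("\n")
})

## The k+1-length string spanning an edge junction (overlap-merged).
edgeJunction <- function(g, e) {
  src <- g@nodes[g@edges[e, 1L]]
  tgt <- g@nodes[g@edges[e, 2L]]
  k <- g@k
  paste0(substring(src, nchar(src) - k + 1L), substring(tgt, k, k))
}

#' Annotate external assemblies with posterior probabilities
#'
#' Identifies features of the sampling graph inside external assemblies by
#' exact matching: a node matches an assembly iff its annotation occurs as
#' an exact substring (either strand) of some contig; an edge matches iff
#' its junction string (the k+1 bases spanning the junction after overlap
#' merging) occurs exactly. Matched features carry their posterior
#' frequency, giving a unified statistical comparison of assemblies
#' produced by different tools.
#'
#' @param g the [AssemblyGraph-class].
#' @param external named list (or named character vector /
#'   `DNAStringSet`) of external assemblies; each element is the contig
#'   set of one assembly.
#' @param edgeFreqs numeric edge posterior frequencies.
#' @param nodeFreqs optional numeric node posterior frequencies.
#' @return a data.frame with one row per feature: `type` (`node`/`edge`),
#'   `id`, `posterior`, and one logical `matched_<name>` column per
#'   external assembly.
#' @export
annotateExternal <- function(g, external, edgeFreqs, nodeFreqs = NULL) {
  if (is(external, "XStringSet") || is.character(external))
    external <- list(assembly = as.character(external))
  external <- lapply(external, as.character)
  if (any(vapply(external, length, integer(1L)) == 0L))
    stop("external assemblies must be nonempty")
  if (is.null(names(external)) || any(names(external) == ""))
    names(external) <- paste0("assembly", seq_along(external))
  nNode <- length(g@nodes)
  nEdge <- nrow(g@edges)
  out <- data.frame(
    type = c(rep("node", nNode), rep("edge", nEdge)),
    id = c(seq_len(nNode), seq_len(nEdge)),
    posterior = c(if (is.null(nodeFreqs)) rep(NA_real_, nNode) else
      nodeFreqs, edgeFreqs),
    stringsAsFactors = FALSE)
  queries <- c(g@nodes, vapply(seq_len(nEdge), function(e)
    edgeJunction(g, e), character(1L)))
  rcq <- revComp(queries)
  for (nm in names(external)) {
    contigs <- external[[nm]]
    hit <- vapply(seq_along(queries), function(i)
      any(grepl(queries[i], contigs, fixed = TRUE)) ||
      any(grepl(rcq[i], contigs, fixed = TRUE)), logical(1L))
    out[[paste0("matched_", nm)]] <- hit
  }
  out
}

#' Write posterior-annotated outputs
#'
#' Writes, under `dir`: `consensus.fasta` (headers carry length,
#' circularity and the contig posterior), `features.tsv` (per-feature
#' posterior table), `graph.gfa`, `graph.dot` (posterior color ramp, grey
#' 0.0 to dark red 1.0) and `diagnostics.json`.
#'
#' @param consensus a [ConsensusAssembly-class].
#' @param freqs numeric edge posterior frequencies.
#' @param g the [AssemblyGraph-class].
#' @param dir output directory (created if needed).
#' @param nodeFreqs optional node posterior frequencies for the DOT ramp.
#' @param diagnostics named list written as JSON (e.g. acceptance rates,
#'   final cross-chain SD).
#' @return `dir`, invisibly.
#' @export
writeOutputs <- function(consensus, freqs, g, dir, nodeFreqs = NULL,
                         diagnostics = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctg <- consensus@contigs
  fa <- Biostrings::DNAStringSet(ctg$sequence)
  names(fa) <- sprintf("contig_%d length=%d circular=%s posterior=%.3f",
                       seq_len(nrow(ctg)), ctg$length,
                       tolower(ctg$circular), ctg$posterior)
  if (nrow(ctg) == 0L)
    warning("consensus is empty; writing empty FASTA")
  Biostrings::writeXStringSet(fa, file.path(dir, "consensus.fasta"))
  feat <- data.frame(
    type = c(rep("node", length(g@nodes)), rep("edge", nrow(g@edges))),
    id = c(seq_along(g@nodes), seq_len(nrow(g@edges))),
    posterior = c(if (is.null(nodeFreqs)) rep(NA_real_, length(g@nodes))
                  else nodeFreqs, freqs))
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeGFA(g, file.path(dir, "graph.gfa"))
  writeDOT(g, file.path(dir, "graph.dot"), nodePosterior = nodeFreqs,
           edgePosterior = freqs)
  jsonlite::write_json(diagnostics, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a feature table written by [writeOutputs()]
#'
#' @param file path to `features.tsv`.
#' @return the feature data.frame.
#' @export
readFeatureTable <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}
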