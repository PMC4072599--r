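## Canonical edge order: by source annotation, then target annotation.
## Edge indices are reproducible across runs because of this ordering.
orderEdges <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(edges)
  ord <- order(nodes[edges[, 1L]], nodes[edges[, 2L]], method = "radix")
  edges[ord, , drop = FALSE]
}

newAssemblyGraph <- function(k, nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  edges <- orderEdges(nodes, edges)
  new("AssemblyGraph", k = as.integer(k), nodes = unname(nodes),
      edges = edges)
}

#' Assembly graph accessors
#'
#' @param g an [AssemblyGraph-class].
#' @return `nNodes`/`nEdges` return counts; `nodeSeqs` the character vector
#'   of node annotations; `edgeTable` a data.frame with columns `from`,
#'   `to` (node ids) in canonical edge order; `kSize` the k-mer size.
#' @export
nNodes <- function(g) length(g@nodes)

#' @rdname nNodes
#' @export
nEdges <- function(g) nrow(g@edges)

#' @rdname nNodes
#' @export
nodeSeqs <- function(g) g@nodes

#' @rdname nNodes
#' @export
edgeTable <- function(g) {
  data.frame(from = as.vector(g@edges[, 1L]),
             to = as.vector(g@edges[, 2L]))
}

#' @rdname nNodes
#' @export
kSize <- function(g) g@k

setMethod("show", "AssemblyGraph", function(object) {
  cat("AssemblyGraph: k =", object@k, "|", length(object@nodes), "nodes,",
      nrow(object@edges), "edges |", sum(nchar(object@nodes)),
      "bases of annotation\n")
})

inDegree <- function(g) tabulate(g@edges[, 2L], nbins = length(g@nodes))
outDegree <- function(g) tabulate(g@edges[, 1L], nbins = length(g@nodes))

#' Build a de Bruijn graph from reads
#'
#' One node per distinct k-mer observed in the reads, one edge per observed
#' (k+1)-mer adjacency. k-mers containing non-ACGT characters (e.g. N) are
#' skipped. The graph is single-stranded: to place both mates of a pair on
#' one strand, pass the output of [orientedReads()] (or set
#' `canonical = TRUE` to also scan every read's reverse complement).
#'
#' @param reads a character vector, `DNAStringSet` or
#'   `QualityScaledDNAStringSet` of reads.
#' @param k k-mer size (odd, >= 3).
#' @param min.count drop k-mers observed fewer than this many times. The
#'   default (1) keeps everything; pipelines on error-containing reads use a
#'   small cutoff (see `vignette("assembly-mcmc")`) so that rare
#'   sequencing-error k-mers do not inflate the bubble space.
#' @param canonical also scan the reverse complement of every read, so both
#'   genome strands appear as complementary paths.
#' @return an [AssemblyGraph-class] whose node annotations all have length
#'   `k`.
#' @examples
#' g <- buildDeBruijn("ACGT", k = 3)
#' nodeSeqs(g)   # "ACG" "CGT"
#' edgeTable(g)  # one edge ACG -> CGT
#' @export
buildDeBruijn <- function(reads, k, min.count = 1L, canonical = FALSE) {
  stopifnot(k >= 3L, k %% 2L == 1L)
  reads <- as.character(reads)
  if (canonical) reads <- c(reads, revComp(reads))
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0L)
    stop("no read reaches length k = ", k, "; cannot build graph")
  kmerList <- lapply(reads, kmersOf, k = k)
  kmers <- unlist(kmerList, use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L)
    stop("no valid (ACGT-only) k-mers found")
  dt <- data.table::data.table(kmer = kmers)
  counts <- dt[, .N, by = "kmer"]
  kept <- counts$kmer[counts$N >= min.count]
  adj <- unlist(lapply(reads, kmersOf, k = k + 1L), use.names = FALSE)
  adj <- unique(adj[!grepl("[^ACGT]", adj)])
  nodes <- sort(kept, method = "radix")
  pre <- substring(adj, 1L, k)
  suf <- substring(adj, 2L, k + 1L)
  from <- match(pre, nodes)
  to <- match(suf, nodes)
  ok <- !is.na(from) & !is.na(to)
  newAssemblyGraph(k, nodes, cbind(from[ok], to[ok]))
}

## Restrict a graph to a subset of node ids.
subsetGraph <- function(g, keep) {
  keep <- sort(unique(keep))
  map <- integer(length(g@nodes))
  map[keep] <- seq_along(keep)
  e <- g@edges
  ok <- e[, 1L] %in% keep & e[, 2L] %in% keep
  newAssemblyGraph(g@k, g@nodes[keep],
                   cbind(map[e[ok, 1L]], map[e[ok, 2L]]))
}

#' Trim tips from an assembly graph
#'
#' A tip is a dead-end branch: a node of in-degree 0 or out-degree 0 and the
#' chain hanging off it, typically caused by read ends or sequencing errors.
#' In `"circular"` mode (the default; appropriate when the target genome is
#' circular, so the true graph has no dead ends at all) tips are removed
#' recursively and completely: removal is iterated to a fixpoint where no
#' node with in-degree 0 or out-degree 0 remains. In `"linear"` mode only
#' tip chains whose spelled length is below `2 * k` are removed (a softer
#' threshold, since a linear genome legitimately ends in two dead ends).
#'
#' @param g an [AssemblyGraph-class].
#' @param mode `"circular"` (trim to fixpoint) or `"linear"` (short tips
#'   only).
#' @return the trimmed graph (possibly empty).
#' @export
trimTips <- function(g, mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  if (mode == "circular") {
    repeat {
      if (length(g@nodes) == 0L) return(g)
      bad <- inDegree(g) == 0L | outDegree(g) == 0L
      if (!any(bad)) return(g)
      g <- subsetGraph(g, which(!bad))
    }
  }
  ## linear mode: remove maximal dead-end chains spelling < 2k bases
  repeat {
    if (length(g@nodes) == 0L) return(g)
    indeg <- inDegree(g); outdeg <- outDegree(g)
    drop <- integer(0L)
    for (dir in c("in", "out")) {
      seeds <- if (dir == "in") which(indeg == 0L) else which(outdeg == 0L)
      for (s in seeds) {
        chain <- s
        len <- nchar(g@nodes[s])
        cur <- s
        repeat {
          nxt <- if (dir == "in") g@edges[g@edges[, 1L] == cur, 2L]
                 else g@edges[g@edges[, 2L] == cur, 1L]
          if (length(nxt) != 1L) break
          ## stop at branching nodes: they belong to the trunk
          deg <- if (dir == "in") indeg[nxt] else outdeg[nxt]
          other <- if (dir == "in") outdeg[nxt] else indeg[nxt]
          if (deg > 1L || other > 1L) break
          chain <- c(chain, nxt)
          len <- len + nchar(g@nodes[nxt]) - (g@k - 1L)
          cur <- nxt
        }
        if (len < 2L * g@k) drop <- c(drop, chain)
      }
    }
    if (length(drop) == 0L) return(g)
    g <- subsetGraph(g, setdiff(seq_along(g@nodes), drop))
  }
}

#' Merge unambiguous paths into single nodes
#'
#' Contracts every edge `u -> v` where `u` has out-degree 1 and `v` has
#' in-degree 1 (and `u != v`), replacing each maximal unambiguous chain with
#' a single node whose annotation is the first node's annotation extended by
#' each subsequent node's annotation minus the shared k-1 overlap (for
#' k-mer nodes, one additional nucleotide per merged node). A fully
#' unambiguous cycle collapses to a single node carrying one self-edge (its
#' annotation starts at the cycle's lexicographically smallest node), so
#' every nonempty graph retains at least one edge.
#'
#' @param g an [AssemblyGraph-class].
#' @return the merged graph.
#' @export
mergeUnambiguousPaths <- function(g) {
  n <- length(g@nodes)
  if (n == 0L || nrow(g@edges) == 0L) return(g)
  indeg <- inDegree(g); outdeg <- outDegree(g)
  e <- g@edges
  mergeable <- outdeg[e[, 1L]] == 1L & indeg[e[, 2L]] == 1L &
               e[, 1L] != e[, 2L]
  nxt <- integer(n)                      # 0 = no mergeable out-edge
  nxt[e[mergeable, 1L]] <- e[mergeable, 2L]
  hasMergeIn <- logical(n)
  hasMergeIn[e[mergeable, 2L]] <- TRUE
  rep_of <- seq_len(n)                   # chain representative
  ann <- g@nodes
  visited <- logical(n)
  k <- g@k
  chainStarts <- which(nxt != 0L & !hasMergeIn)
  cycleSelf <- integer(0L)
  spellChain <- function(chain) {
    tails <- substring(ann[chain[-1L]], k)
    paste0(ann[chain[1L]], paste(tails, collapse = ""))
  }
  for (s in chainStarts) {
    chain <- s; cur <- s
    while (nxt[cur] != 0L) { cur <- nxt[cur]; chain <- c(chain, cur) }
    rep_of[chain] <- s
    ann[s] <- spellChain(chain)
    visited[chain] <- TRUE
  }
  ## remaining nodes with mergeable out-edges form pure cycles
  for (s in which(nxt != 0L & !visited)) {
    if (visited[s]) next
    chain <- s; cur <- nxt[s]
    while (cur != s) { chain <- c(chain, cur); cur <- nxt[cur] }
    start <- chain[order(ann[chain], method = "radix")[1L]]
    i <- match(start, chain)
    chain <- c(chain[i:length(chain)], chain[seq_len(i - 1L)])
    rep_of[chain] <- start
    ann[start] <- spellChain(chain)
    visited[chain] <- TRUE
    cycleSelf <- c(cycleSelf, start)
  }
  keep <- sort(unique(rep_of))
  map <- integer(n); map[keep] <- seq_along(keep)
  rest <- e[!mergeable, , drop = FALSE]
  newEdges <- cbind(map[rep_of[rest[, 1L]]], map[rep_of[rest[, 2L]]])
  if (length(cycleSelf) > 0L)
    newEdges <- rbind(newEdges, cbind(map[cycleSelf], map[cycleSelf]))
  newEdges <- unique(newEdges)
  newAssemblyGraph(k, ann[keep], newEdges)
}

#' Largest weakly connected component
#'
#' Splits the graph into weakly connected components and returns the one
#' with the greatest total annotation length. Ties are broken toward the
#' component containing the lexicographically smallest node annotation.
#'
#' @param g a nonempty [AssemblyGraph-class].
#' @return the induced subgraph.
#' @export
largestWeakComponent <- function(g) {
  if (length(g@nodes) == 0L) stop("empty graph has no components")
  ig <- igraph::make_empty_graph(n = length(g@nodes), directed = TRUE)
  if (nrow(g@edges) > 0L)
    ig <- igraph::add_edges(ig, t(g@edges))
  memb <- igraph::components(ig, mode = "weak")$membership
  tot <- tapply(nchar(g@nodes), memb, sum)
  best <- as.integer(names(tot)[tot == max(tot)])
  if (length(best) > 1L) {
    mins <- vapply(best, function(b) min(g@nodes[memb == b]), character(1L))
    best <- best[order(mins, method = "radix")[1L]]
  }
  subsetGraph(g, which(memb == best))
}

#' Full graph reduction pipeline
#'
#' Tip trimming, unambiguous-path merging and selection of the largest weak
#' component, in that order. The result is the minimal bubble-only
#' hypothesis space whose paths spell candidate assemblies.
#'
#' @inheritParams trimTips
#' @return the reduced [AssemblyGraph-class].
#' @export
reduceGraph <- function(g, mode = c("circular", "linear")) {
  g <- trimTips(g, mode)
  if (length(g@nodes) == 0L)
    stop("graph is empty after tip trimming")
  g <- mergeUnambiguousPaths(g)
  largestWeakComponent(g)
}

#' Spell the sequence of an edge path
#'
#' Concatenates node annotations along a contiguous path of edges, removing
#' the k-1 overlap at each junction. A closed cycle (the last edge returns
#' to the first node) is spelled with its final k-1 wrap characters trimmed
#' and the string rotated to its lexicographically minimal rotation, so a
#' collapsed circular genome of length L spells exactly L bases.
#'
#' @param g an [AssemblyGraph-class].
#' @param path integer vector of edge indices (1-based, in the graph's
#'   canonical edge order); must be contiguous and edge-disjoint. An empty
#'   path with `node` set spells that single node's annotation.
#' @param node single node id to spell when `path` is empty.
#' @return a single character string.
#' @export
spellPath <- function(g, path, node = NULL) {
  if (length(path) == 0L) {
    if (is.null(node)) stop("empty path: supply a node id to spell")
    return(g@nodes[node])
  }
  path <- as.integer(path)
  if (anyDuplicated(path)) stop("path repeats an edge")
  e <- g@edges
  from <- e[path, 1L]; to <- e[path, 2L]
  if (length(path) > 1L && any(to[-length(path)] != from[-1L]))
    stop("path is not contiguous")
  isCycle <- to[length(path)] == from[1L]
  nodesOnPath <- if (isCycle) from else c(from, to[length(to)])
  ann <- g@nodes[nodesOnPath]
  k <- g@k
  s <- if (length(ann) == 1L) ann else
    paste0(ann[1L], paste(substring(ann[-1L], k), collapse = ""))
  if (isCycle) {
    s <- substr(s, 1L, nchar(s) - (k - 1L))
    s <- canonicalRotation(s)
  }
  s
}

#' Count simple bubbles
#'
#' A bubble is a fork node whose out-neighbors are parallel branch nodes
#' that each lead, by their single outgoing edge, to one common join node.
#' On a reduced graph of a circular genome with v well-separated biallelic
#' variants this count is exactly v.
#'
#' @param g an [AssemblyGraph-class].
#' @return integer bubble count.
#' @export
countBubbles <- function(g) {
  if (nrow(g@edges) == 0L) return(0L)
  outdeg <- outDegree(g)
  forks <- which(outdeg >= 2L)
  n <- 0L
  for (f in forks) {
    branches <- g@edges[g@edges[, 1L] == f, 2L]
    joins <- vapply(branches, function(b) {
      outs <- g@edges[g@edges[, 1L] == b, 2L]
      if (length(outs) == 1L) outs else NA_integer_
    }, integer(1L))
    if (!anyNA(joins) && length(unique(joins)) == 1L) n <- n + 1L
  }
  n
}
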