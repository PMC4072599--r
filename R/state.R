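## Per-graph index used by the hot perturbation path: plain vectors and
## per-node incident edge lists.
graphIndex <- function(g) {
  n <- length(g@nodes)
  E <- nrow(g@edges)
  from <- g@edges[, 1L]
  to <- g@edges[, 2L]
  list(
    E = E, n = n, from = from, to = to,
    outE = split(seq_len(E), factor(from, levels = seq_len(n))),
    inE = split(seq_len(E), factor(to, levels = seq_len(n)))
  )
}

validActive <- function(gi, act) {
  idx <- which(act)
  !anyDuplicated(gi$from[idx]) && !anyDuplicated(gi$to[idx])
}

activeIncident <- function(gi, act, node) {
  any(act[gi$outE[[node]]]) || any(act[gi$inE[[node]]])
}

## Decompose an active vector into maximal paths and cycles.
## Returns NULL for an invalid vector.
decomposeActive <- function(g, act) {
  idx <- which(act)
  e <- g@edges
  from <- e[idx, 1L]; to <- e[idx, 2L]
  if (anyDuplicated(from) || anyDuplicated(to)) return(NULL)
  n <- length(g@nodes)
  outE <- integer(n); outE[from] <- idx
  inE <- integer(n); inE[to] <- idx
  visited <- logical(length(act))
  paths <- list(); isCycle <- logical(0L)
  startNodes <- from[inE[from] == 0L]
  for (s in startNodes) {
    p <- integer(0L); cur <- s
    while (outE[cur] != 0L) {
      ei <- outE[cur]
      p <- c(p, ei); visited[ei] <- TRUE
      cur <- e[ei, 2L]
    }
    paths[[length(paths) + 1L]] <- p
    isCycle <- c(isCycle, FALSE)
  }
  for (ei in idx) {
    if (visited[ei]) next
    p <- ei; visited[ei] <- TRUE
    cur <- e[ei, 2L]
    while (cur != e[ei, 1L]) {
      nx <- outE[cur]
      p <- c(p, nx); visited[nx] <- TRUE
      cur <- e[nx, 2L]
    }
    paths[[length(paths) + 1L]] <- p
    isCycle <- c(isCycle, TRUE)
  }
  k <- g@k
  lens <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    nodesOn <- if (isCycle[i]) e[p, 1L] else c(e[p, 1L], e[p[length(p)], 2L])
    sum(nchar(g@nodes[nodesOn])) - length(p) * (k - 1L)
  }, numeric(1L))
  list(paths = paths, isCycle = isCycle,
       totalLength = sum(lens), nContigs = length(paths))
}

#' Construct an assembly state from an active-edge vector
#'
#' @param g an [AssemblyGraph-class].
#' @param active logical vector over the graph's edges (edge order as in
#'   [edgeTable()]); must satisfy the path validity constraint.
#' @return an [AssemblyState-class].
#' @export
assemblyState <- function(g, active) {
  stopifnot(length(active) == nrow(g@edges))
  d <- decomposeActive(g, active)
  if (is.null(d))
    stop("active vector violates the one-in/one-out path constraint")
  new("AssemblyState", active = as.logical(active), paths = d$paths,
      isCycle = d$isCycle, totalLength = d$totalLength,
      nContigs = as.integer(d$nContigs))
}

#' Assembly state accessors
#'
#' @param s an [AssemblyState-class].
#' @return `activeEdges` the logical edge vector; `totalLength` the summed
#'   contig length in bases; `nContigs` the number of maximal active
#'   paths/cycles.
#' @export
activeEdges <- function(s) s@active

#' @rdname activeEdges
#' @export
totalLength <- function(s) s@totalLength

#' @rdname activeEdges
#' @export
nContigs <- function(s) s@nContigs

setMethod("show", "AssemblyState", function(object) {
  cat("AssemblyState:", sum(object@active), "of", length(object@active),
      "edges active |", object@nContigs, "contig(s),",
      object@totalLength, "bases\n")
})

#' Check the path-validity constraint
#'
#' A state is valid iff every node has at most one active incoming and at
#' most one active outgoing edge (an active path cannot take multiple
#' branches through the same bubble) -- the boolean representation itself
#' enforces that no edge is used twice.
#'
#' @param g an [AssemblyGraph-class].
#' @param active logical edge vector or an [AssemblyState-class].
#' @return `TRUE` or `FALSE`.
#' @export
validateState <- function(g, active) {
  if (is(active, "AssemblyState")) active <- active@active
  validActive(graphIndex(g), active)
}

## Attempt to activate edge e: extend with uniform random walks over
## inactive edges from both endpoints until each walk meets the existing
## assembly (a node with an active incident edge) or runs out of moves,
## then deactivate the displaced active branch between the two attachment
## nodes, if one exists. Returns the new vector or NULL if invalid.
tryActivate <- function(gi, act, e) {
  P <- e
  cur <- gi$from[e]; steps <- 0L
  while (!activeIncident(gi, act, cur) && steps < 2L * gi$E) {
    elig <- gi$inE[[cur]]
    elig <- elig[!act[elig] & !(elig %in% P)]
    if (length(elig) == 0L) break
    pick <- drawOne(elig)
    P <- c(pick, P); cur <- gi$from[pick]; steps <- steps + 1L
  }
  u <- cur
  cur <- gi$to[e]; steps <- 0L
  while (!activeIncident(gi, act, cur) && steps < 2L * gi$E) {
    elig <- gi$outE[[cur]]
    elig <- elig[!act[elig] & !(elig %in% P)]
    if (length(elig) == 0L) break
    pick <- drawOne(elig)
    P <- c(P, pick); cur <- gi$to[pick]; steps <- steps + 1L
  }
  v <- cur
  act2 <- act
  act2[P] <- TRUE
  if (u != v) {
    branch <- integer(0L); cur <- u; steps <- 0L
    repeat {
      oe <- gi$outE[[cur]]
      oe <- oe[act[oe]]
      if (length(oe) == 0L) { branch <- NULL; break }
      branch <- c(branch, oe[1L]); cur <- gi$to[oe[1L]]
      if (cur == v) break
      steps <- steps + 1L
      if (steps > gi$E) { branch <- NULL; break }
    }
    if (!is.null(branch)) act2[branch] <- FALSE
  }
  if (validActive(gi, act2)) act2 else NULL
}

## Single perturbation on a plain active vector (hot path).
perturbActive <- function(gi, act) {
  for (i in seq_len(gi$E)) {
    e <- sample.int(gi$E, 1L)
    if (act[e]) {
      act[e] <- FALSE
      return(act)
    }
    res <- tryActivate(gi, act, e)
    if (!is.null(res)) return(res)
  }
  act
}

#' Perturb an assembly state
#'
#' One elementary move of the sampler: an edge is chosen uniformly at
#' random. An active edge is simply deactivated (splitting its path). An
#' inactive edge is activated and extended from both endpoints by uniform
#' random walks over inactive edges until each walk meets the existing
#' assembly; the displaced branch of the pre-existing path between the two
#' attachment nodes (if any) is deactivated, so a whole alternate branch of
#' a bubble switches in a single move. A draw that cannot yield a valid
#' state is re-drawn; after `nEdges(g)` failed draws the state is returned
#' unchanged.
#'
#' @param s an [AssemblyState-class] (must be valid).
#' @param g the [AssemblyGraph-class] the state lives on.
#' @return a valid [AssemblyState-class].
#' @export
perturb <- function(s, g) {
  gi <- graphIndex(g)
  assemblyState(g, perturbActive(gi, s@active))
}

#' Propose a new assembly state
#'
#' Composition of `nPerturbations` elementary [perturb()] moves. Several
#' perturbations per proposal let the sampler take larger steps through the
#' combinatorial space of assemblies.
#'
#' @inheritParams perturb
#' @param nPerturbations number of perturbations to compose (default 3).
#' @return a valid [AssemblyState-class].
#' @export
propose <- function(s, g, nPerturbations = 3L) {
  stopifnot(nPerturbations >= 1L)
  gi <- graphIndex(g)
  act <- s@active
  for (i in seq_len(nPerturbations)) act <- perturbActive(gi, act)
  assemblyState(g, act)
}

#' Draw a random initial state
#'
#' Starts from the all-inactive vector and applies `nEdges(g)` random
#' perturbations, yielding a valid, typically well-connected starting
#' hypothesis.
#'
#' @param g a nonempty [AssemblyGraph-class].
#' @param seed optional integer seed for reproducibility.
#' @return a valid [AssemblyState-class].
#' @export
randomState <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gi <- graphIndex(g)
  if (gi$E == 0L) stop("graph has no edges")
  act <- rep(FALSE, gi$E)
  for (i in seq_len(gi$E)) act <- perturbActive(gi, act)
  assemblyState(g, act)
}

#' Spell the contigs of a state
#'
#' One string per maximal active path or cycle, in deterministic order
#' (longest first, ties broken lexicographically). Isolated nodes with no
#' active incident edge contribute no contig: an assembly is only what its
#' active paths spell. The returned vector carries a logical `circular`
#' attribute marking contigs spelled from cycles.
#'
#' @param s an [AssemblyState-class].
#' @param g the [AssemblyGraph-class].
#' @return a character vector with attribute `circular`.
#' @export
activeContigs <- function(s, g) {
  if (length(s@paths) == 0L) {
    out <- character(0L)
    attr(out, "circular") <- logical(0L)
    return(out)
  }
  seqs <- vapply(s@paths, function(p) spellPath(g, p), character(1L))
  ord <- order(-nchar(seqs), seqs, method = "radix")
  out <- seqs[ord]
  attr(out, "circular") <- s@isCycle[ord]
  out
}

#' Serialize a state to text
#'
#' Writes one line of 0/1 characters (one per edge index) followed by a
#' JSON summary line with `totalLength` and `nContigs`.
#'
#' @param s an [AssemblyState-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeState <- function(s, file) {
  writeLines(c(
    paste(as.integer(s@active), collapse = ""),
    jsonlite::toJSON(list(totalLength = s@totalLength,
                          nContigs = s@nContigs), auto_unbox = TRUE)
  ), file)
  invisible(file)
}
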