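#' Write an assembly graph as GFA1
#'
#' Segment (`S`) lines carry node annotations; link (`L`) lines carry the
#' k-1 overlap as a CIGAR (`<k-1>M`). Node ids are `n<index>`.
#'
#' @param g an [AssemblyGraph-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGFA <- function(g, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  if (length(g@nodes) > 0L)
    writeLines(paste0("S\tn", seq_along(g@nodes), "\t", g@nodes), con)
  if (nrow(g@edges) > 0L)
    writeLines(paste0("L\tn", g@edges[, 1L], "\t+\tn", g@edges[, 2L],
                      "\t+\t", g@k - 1L, "M"), con)
  invisible(file)
}

#' Read an assembly graph from GFA1
#'
#' Inverse of [writeGFA()]: expects `+/+` links with a uniform `<k-1>M`
#' overlap.
#'
#' @param file path to a GFA file.
#' @return an [AssemblyGraph-class].
#' @export
readGFA <- function(file) {
  lines <- readLines(file)
  sl <- strsplit(lines[startsWith(lines, "S\t")], "\t", fixed = TRUE)
  ll <- strsplit(lines[startsWith(lines, "L\t")], "\t", fixed = TRUE)
  ids <- vapply(sl, `[`, character(1L), 2L)
  nodes <- vapply(sl, `[`, character(1L), 3L)
  if (length(ll) == 0L) stop("GFA file has no links; k cannot be inferred")
  ov <- unique(vapply(ll, `[`, character(1L), 6L))
  ov <- unique(as.integer(sub("M$", "", ov)))
  if (length(ov) != 1L || is.na(ov))
    stop("expected a single uniform <k-1>M overlap in GFA links")
  from <- match(vapply(ll, `[`, character(1L), 2L), ids)
  to <- match(vapply(ll, `[`, character(1L), 4L), ids)
  if (anyNA(from) || anyNA(to)) stop("GFA link references unknown segment")
  newAssemblyGraph(ov + 1L, nodes, cbind(from, to))
}

## Map posteriors in [0,1] to a grey -> dark red ramp.
posteriorColor <- function(p) {
  ramp <- grDevices::colorRampPalette(c("grey80", "darkred"))(101L)
  ramp[pmin(100L, pmax(0L, round(p * 100))) + 1L]
}

#' Write an assembly graph in DOT format
#'
#' Node size is proportional to the log of the sequence length; optional
#' per-node and per-edge posteriors are drawn on a grey (0.0) to dark red
#' (1.0) color ramp.
#'
#' @param g an [AssemblyGraph-class].
#' @param file output path.
#' @param nodePosterior,edgePosterior optional numeric vectors in `[0, 1]`.
#' @return `file`, invisibly.
#' @export
writeDOT <- function(g, file, nodePosterior = NULL, edgePosterior = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("digraph assembly {", con)
  len <- nchar(g@nodes)
  w <- 0.3 + 0.25 * log10(pmax(len, 10L))
  ncol <- if (is.null(nodePosterior)) rep("grey80", length(len)) else
    posteriorColor(nodePosterior)
  if (length(g@nodes) > 0L)
    writeLines(sprintf(
      "  n%d [label=\"%d bp\", width=%.2f, style=filled, fillcolor=\"%s\", shape=circle];",
      seq_along(len), len, w, ncol), con)
  ecol <- if (is.null(edgePosterior)) rep("grey50", nrow(g@edges)) else
    posteriorColor(edgePosterior)
  if (nrow(g@edges) > 0L)
    writeLines(sprintf("  n%d -> n%d [color=\"%s\"];",
                       g@edges[, 1L], g@edges[, 2L], ecol), con)
  writeLines("}", con)
  invisible(file)
}
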