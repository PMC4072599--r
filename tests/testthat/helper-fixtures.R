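# Fixtures are built in code: small genomes, error-free read sets and the
# standard reduced toy graphs used across test files.

qsds <- function(seqs, quals = NULL, ids = NULL) {
  s <- Biostrings::DNAStringSet(seqs)
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n)
      strrep(rawToChar(as.raw(38L + 33L)), n), character(1L))
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  names(s) <- ids
  Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(quals))
}

makePairs <- function(fwdSeqs, revSeqs, fwdQuals = NULL, revQuals = NULL) {
  readPairs(qsds(fwdSeqs, fwdQuals), qsds(revSeqs, revQuals), "test")
}

## Reduced toy graph of a small circular genome with nVariants bubbles
## (50/50 haplotypes so both branches are well supported), error-free.
toyBubble <- function(nVariants = 2L, seed = 11L) {
  set.seed(seed)
  gen <- simulateGenome(300L, nVariants, minSpacing = 100L,
                        variantFraction = 0.5)
  pairs <- simulatePairedReads(gen$genome, gen$variants, nPairs = 300L,
                               readLength = 60L, insertMean = 80,
                               insertSd = 5, errorRate = 0)
  g <- reduceGraph(buildDeBruijn(orientedReads(pairs), k = 15L))
  list(g = g, genome = gen$genome, variants = gen$variants, pairs = pairs)
}

## Cache: building the toy graph is deterministic but not free.
.toy2 <- NULL
toy2 <- function() {
  if (is.null(.toy2)) .toy2 <<- toyBubble(2L, 11L)
  .toy2
}

stateKeyOf <- function(act) paste(as.integer(act), collapse = "")

## Empirical state frequencies of a list of traces over an enumerated
## state list.
stateFrequencies <- function(traces, states) {
  keys <- vapply(states, stateKeyOf, character(1L))
  ks <- unlist(lapply(traces, function(t)
    apply(t@states, 1L, stateKeyOf)))
  as.numeric(table(factor(ks, levels = keys))) / length(ks)
}

## Independent brute-force oracle for the average read probability:
## straight double loop over contigs, strands and starts.
bruteReadLogProb <- function(read, contigs, errorRate) {
  l <- nchar(read)
  tot <- 0
  npos <- 0
  for (contig in contigs) {
    L <- nchar(contig)
    if (L < l) next
    npos <- npos + (L - l + 1L)
    for (r in c(read, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read))))) {
      for (s in seq_len(L - l + 1L)) {
        m <- sum(strsplit(r, "")[[1L]] !=
                 strsplit(substr(contig, s, s + l - 1L), "")[[1L]])
        tot <- tot + (1 - errorRate)^(l - m) * (errorRate / 3)^m
      }
    }
  }
  if (npos == 0L || tot == 0)
    return(nchar(read) * log(errorRate / 3) -
           log(2 * max(sum(nchar(contigs)), 1)))
  log(tot / (2 * npos))
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
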