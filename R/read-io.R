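#' Parse a FASTQ file
#'
#' Reads 4-line FASTQ records (Phred-33 quality encoding) into a
#' [Biostrings::QualityScaledDNAStringSet]. Gzip-compressed files are read
#' transparently. Malformed records (missing `@`/`+` lines, or a quality
#' string whose length differs from the bases) raise an error.
#'
#' @param file path to a FASTQ file (optionally gzipped).
#' @return a `QualityScaledDNAStringSet`; quality character `c` decodes to
#'   integer `utf8ToInt(c) - 33`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "FFFF"), fq)
#' reads <- parseFastq(fq)
#' as(Biostrings::quality(reads), "IntegerList")[[1]]  # 37 37 37 37
#' @export
parseFastq <- function(file) {
  con <- gzfile(file, "r")         # transparent for plain text too
  on.exit(close(con))
  lines <- readLines(con)
  while (length(lines) > 0L && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0L))))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", file, ": line count not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@")) || !all(startsWith(plus, "+")))
    stop("malformed FASTQ in ", file, ": missing '@' or '+' line")
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ record with base/quality length mismatch in ", file)
  ds <- Biostrings::DNAStringSet(seqs)
  names(ds) <- sub("^@", "", sub("\\s.*$", "", ids))
  Biostrings::QualityScaledDNAStringSet(ds, Biostrings::PhredQuality(quals))
}

#' Write reads to FASTQ
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param file output path (`.gz` suffix compresses).
#' @return `file`, invisibly.
#' @export
writeFastq <- function(reads, file) {
  Biostrings::writeQualityScaledXStringSet(reads, file,
    compress = grepl("\\.gz$", file))
  invisible(file)
}

#' Construct a paired read set
#'
#' @param forward,reverse `QualityScaledDNAStringSet` mates of equal length.
#' @param provenance free-text origin.
#' @return a [ReadPairs-class] object.
#' @export
readPairs <- function(forward, reverse, provenance = "unknown") {
  new("ReadPairs", forward = forward, reverse = reverse,
      provenance = provenance)
}

#' Read a pair of FASTQ files
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files.
#' @param provenance free-text origin (defaults to the file names).
#' @return a [ReadPairs-class] object.
#' @export
readPairedFastq <- function(r1, r2,
                            provenance = paste(basename(r1), basename(r2))) {
  fwd <- parseFastq(r1)
  rev <- parseFastq(r2)
  if (length(fwd) != length(rev))
    stop("R1 and R2 contain different numbers of reads")
  readPairs(fwd, rev, provenance)
}

#' @describeIn readPairs number of pairs.
#' @param x,object a `ReadPairs` object.
#' @export
setMethod("length", "ReadPairs", function(x) length(x@forward))

#' @describeIn readPairs forward mates accessor.
#' @export
forwardReads <- function(x) x@forward

#' @describeIn readPairs reverse mates accessor.
#' @export
reverseReads <- function(x) x@reverse

setMethod("show", "ReadPairs", function(object) {
  cat("ReadPairs with", length(object), "pairs (",
      object@provenance, ")\n")
  if (length(object) > 0L)
    cat("  read length:", min(BiocGenerics::width(object@forward),
                              BiocGenerics::width(object@reverse)), "-",
        max(BiocGenerics::width(object@forward),
            BiocGenerics::width(object@reverse)), "bp\n")
})

subsetPairs <- function(pairs, idx) {
  new("ReadPairs", forward = pairs@forward[idx],
      reverse = pairs@reverse[idx], provenance = pairs@provenance)
}

## Per-read arithmetic mean Phred quality.
meanQuality <- function(reads) {
  if (length(reads) == 0L) return(numeric(0L))
  il <- as(Biostrings::quality(reads), "IntegerList")
  vapply(as.list(il), mean, numeric(1L), USE.NAMES = FALSE)
}

#' Filter pairs on mean base quality
#'
#' Retains a pair iff *both* mates have arithmetic mean Phred quality
#' strictly greater than `threshold` (a pair of all-Q37 mates is rejected at
#' the default threshold of 37). Order is preserved.
#'
#' @param pairs a [ReadPairs-class] object.
#' @param threshold minimum mean quality (exclusive), default 37.
#' @return the filtered `ReadPairs`.
#' @export
meanQualityFilter <- function(pairs, threshold = 37) {
  stopifnot(threshold >= 0)
  if (length(pairs) == 0L) return(pairs)
  keep <- meanQuality(pairs@forward) > threshold &
          meanQuality(pairs@reverse) > threshold
  subsetPairs(pairs, keep)
}

#' Drop pairs containing adapter sequence
#'
#' Optional screen that rejects a pair when either mate contains any of the
#' given adapter sequences as an exact substring. The default adapter list
#' is empty (no screening).
#'
#' @param pairs a [ReadPairs-class] object.
#' @param adapters character vector of adapter sequences.
#' @return the filtered `ReadPairs`.
#' @export
adapterFilter <- function(pairs, adapters = character(0L)) {
  if (length(pairs) == 0L || length(adapters) == 0L) return(pairs)
  fwd <- as.character(pairs@forward)
  rev <- as.character(pairs@reverse)
  hit <- rep(FALSE, length(pairs))
  for (a in adapters)
    hit <- hit | grepl(a, fwd, fixed = TRUE) | grepl(a, rev, fixed = TRUE)
  subsetPairs(pairs, !hit)
}

#' Keep the first n pairs
#'
#' @param pairs a [ReadPairs-class] object.
#' @param n number of pairs to keep (all pairs if fewer are present).
#' @return the truncated `ReadPairs`.
#' @export
takeFirst <- function(pairs, n) {
  stopifnot(n >= 0)
  subsetPairs(pairs, seq_len(min(n, length(pairs))))
}

#' Filter pipeline for paired reads
#'
#' Applies, in order: adapter screening, the mean-quality filter, and
#' truncation to the first `n` surviving pairs (filtering precedes
#' truncation, i.e. "the first n pairs that pass").
#'
#' @param pairs a [ReadPairs-class] object.
#' @param minMeanQuality mean-quality threshold (exclusive).
#' @param n number of pairs to keep after filtering (`Inf` keeps all).
#' @param adapters adapter sequences for exact-substring rejection.
#' @return the filtered `ReadPairs`.
#' @export
filterPairs <- function(pairs, minMeanQuality = 37, n = Inf,
                        adapters = character(0L)) {
  out <- adapterFilter(pairs, adapters)
  out <- meanQualityFilter(out, minMeanQuality)
  if (is.finite(n)) out <- takeFirst(out, n)
  out
}

#' Coverage statistics of a read set
#'
#' @param pairs a [ReadPairs-class] object.
#' @param genomeLength reference genome length in bases (> 0).
#' @return a list with `maxReadLength`, `totalBases` (over all mates) and
#'   `foldCoverage = totalBases / genomeLength`.
#' @export
coverageStats <- function(pairs, genomeLength) {
  stopifnot(genomeLength > 0)
  if (length(pairs) == 0L)
    return(list(maxReadLength = 0L, totalBases = 0L, foldCoverage = 0))
  w <- c(BiocGenerics::width(pairs@forward),
         BiocGenerics::width(pairs@reverse))
  list(maxReadLength = max(w), totalBases = sum(w),
       foldCoverage = sum(w) / genomeLength)
}

#' Reads oriented to a single strand
#'
#' Returns the forward mates as-is and the reverse mates
#' reverse-complemented, so both mates of a proper pair lie on the same
#' genome strand. This is the read collection the de Bruijn graph is built
#' from (a non-canonical, single-strand graph).
#'
#' @param pairs a [ReadPairs-class] object.
#' @return a [Biostrings::DNAStringSet].
#' @export
orientedReads <- function(pairs) {
  fwd <- Biostrings::DNAStringSet(pairs@forward)
  rev <- Biostrings::reverseComplement(Biostrings::DNAStringSet(pairs@reverse))
  names(fwd) <- paste0(names(pairs@forward), "/1")
  names(rev) <- paste0(names(pairs@reverse), "/2")
  c(fwd, rev)
}
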