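#' @import methods
#' @importFrom stats dgamma rbinom rnorm runif setNames
#' @importFrom utils head read.delim write.table
#' @importFrom data.table data.table
NULL

.datatable.aware <- TRUE

## Numerically stable log(sum(exp(x))); -Inf elements contribute 0.
logSumExp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Reverse complement for plain character vectors.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Lexicographically minimal rotation of a string
#'
#' Canonical representative of a circular sequence: the rotation that is
#' smallest in lexicographic order. Two strings are rotations of the same
#' circle iff their canonical rotations are identical, which is how circular
#' contigs are compared to a reference.
#'
#' @param x a character vector of sequences.
#' @return a character vector of the same length.
#' @export
canonicalRotation <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n <= 1L) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    starts <- which(chars == min(chars))
    if (length(starts) == 1L) {
      i <- starts
      return(paste0(substr(s, i, n), substr(s, 1L, i - 1L)))
    }
    s2 <- paste0(s, s)
    best <- NULL
    for (i in starts) {
      cand <- substr(s2, i, i + n - 1L)
      if (is.null(best) || cand < best) best <- cand
    }
    best
  }, character(1L), USE.NAMES = FALSE)
}

## Uniform draw from a vector (avoids sample()'s scalar surprise).
drawOne <- function(x) {
  n <- length(x)
  if (n == 0L) return(x)
  if (n == 1L) return(x[1L])
  x[sample.int(n, 1L)]
}

## All k-length substrings of a single string (character(0) if too short).
kmersOf <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0L))
  substring(s, seq_len(n - k + 1L), seq.int(k, n))
}

## Compact state key for memoization.
stateKey <- function(active) {
  rawToChar(as.raw(as.integer(active) + 48L))
}
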