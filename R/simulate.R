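#' Simulate a circular genome with biallelic variant sites
#'
#' Uniform random sequence plus `nVariants` substitution sites whose
#' positions are pairwise at least `minSpacing` apart (also across the
#' circular origin), so each variant later forms its own well-separated
#' bubble in a k-mer graph when `minSpacing > k`.
#'
#' @param length genome length in bases (>= 100).
#' @param nVariants number of variant sites.
#' @param minSpacing minimum pairwise distance between variant positions.
#' @param variantFraction haplotype fraction of each alternative allele.
#' @param seed optional integer seed.
#' @return a list with `genome` (character) and `variants` (data.frame
#'   with `pos`, `ref`, `alt`, `fraction`).
#' @export
simulateGenome <- function(length, nVariants = 0L, minSpacing = 200L,
                           variantFraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 100L)
  if (nVariants * minSpacing >= length)
    stop("infeasible variant spacing: nVariants * minSpacing >= length")
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, length, replace = TRUE), collapse = "")
  variants <- data.frame(pos = integer(0L), ref = character(0L),
                         alt = character(0L), fraction = numeric(0L))
  if (nVariants > 0L) {
    for (attempt in 1:1000) {
      pos <- sort(sample.int(length, nVariants))
      gaps <- if (nVariants > 1L) diff(pos) else integer(0L)
      wrap <- length - pos[nVariants] + pos[1L]
      if (all(gaps >= minSpacing) && (nVariants == 1L || wrap >= minSpacing))
        break
      if (attempt == 1000L) stop("could not place variants with spacing")
    }
    ref <- substring(genome, pos, pos)
    alt <- vapply(ref, function(b) drawOne(setdiff(bases, b)), character(1L),
                  USE.NAMES = FALSE)
    variants <- data.frame(pos = pos, ref = ref, alt = alt,
                           fraction = variantFraction)
  }
  list(genome = genome, variants = variants)
}

applyVariants <- function(genome, variants, which) {
  for (i in which(which)) {
    substr(genome, variants$pos[i], variants$pos[i]) <- variants$alt[i]
  }
  genome
}

#' Simulate paired-end reads from a circular genome
#'
#' Fragment starts are uniform on the circle; the insert length is drawn
#' from a normal law (clamped to at least `readLength`); the forward mate
#' is the fragment's first `readLength` bases and the reverse mate the
#' reverse complement of its last `readLength` bases. For each fragment,
#' each variant's alternative allele is applied independently with its
#' haplotype fraction. Substitution errors are i.i.d. at `errorRate` (the
#' erroneous base is uniform over the three alternatives); all base
#' qualities are constant Q38.
#'
#' @param genome circular reference sequence (character).
#' @param variants variant data.frame as from [simulateGenome()].
#' @param nPairs number of read pairs (>= 1).
#' @param readLength mate length in bases (<= genome length).
#' @param insertMean,insertSd normal insert-size model.
#' @param errorRate per-base substitution error probability.
#' @param seed optional integer seed; fixed seed gives identical reads.
#' @return a [ReadPairs-class].
#' @export
simulatePairedReads <- function(genome, variants = NULL, nPairs,
                                readLength = 251L, insertMean = 357,
                                insertSd = 40, errorRate = 0.002,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  stopifnot(readLength <= L, nPairs >= 1L)
  nv <- if (is.null(variants)) 0L else nrow(variants)
  if (nv > 16L) stop("more than 16 variant sites are not supported")
  ## precompute the 2^nv haplotype strings, doubled for circular substring
  combos <- if (nv == 0L) matrix(FALSE, 1L, 0L) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nv)))
  haplos <- vapply(seq_len(nrow(combos)), function(i) {
    h <- applyVariants(genome, variants, combos[i, ])
    paste0(h, h)
  }, character(1L))
  starts <- sample.int(L, nPairs, replace = TRUE)
  inserts <- pmax(round(rnorm(nPairs, insertMean, insertSd)), readLength)
  inserts <- pmin(inserts, L)
  comboIdx <- rep(1L, nPairs)
  if (nv > 0L) {
    picks <- matrix(runif(nPairs * nv) < rep(variants$fraction,
                                             each = nPairs), nPairs, nv)
    comboIdx <- 1L + as.integer(picks %*% 2L^(seq_len(nv) - 1L))
  }
  fwd <- substring(haplos[comboIdx], starts, starts + readLength - 1L)
  revWin <- substring(haplos[comboIdx], starts + inserts - readLength,
                      starts + inserts - 1L)
  rev <- revComp(revWin)
  if (errorRate > 0) {
    fwd <- injectErrors(fwd, errorRate)
    rev <- injectErrors(rev, errorRate)
  }
  q <- strrep(rawToChar(as.raw(38L + 33L)), readLength)
  mkset <- function(x) {
    s <- Biostrings::DNAStringSet(x)
    names(s) <- paste0("sim_", seq_along(x))
    Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(rep(q, length(x))))
  }
  readPairs(mkset(fwd), mkset(rev), provenance = "simulated")
}

## i.i.d. substitution errors on a character vector of reads.
injectErrors <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- drawOne(setdiff(bases, cur))
    }
  }
  reads
}

#' Simulate a complete benchmark dataset
#'
#' Generates a known circular genome plus paired-end reads with the
#' statistics of the phiX174 MiSeq benchmark subset: a 5,386 bp circle,
#' 2,000 pairs of 251 bp mates (mean insert 357 bp), low substitution
#' error, and two well-separated biallelic variant sites at a 90/10
#' haplotype ratio. All defaults can be overridden.
#'
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param length genome length.
#' @param nPairs,readLength,insertMean,insertSd,errorRate read simulation
#'   parameters (see [simulatePairedReads()]).
#' @param nVariants,variantFraction,minSpacing variant-site parameters
#'   (see [simulateGenome()]); `minSpacing = NULL` uses 500 bp, capped at
#'   `length / (2 * nVariants)` for short genomes.
#' @return a [SimulatedTruth-class].
#' @export
simulateDataset <- function(seed = 1L, length = 5386L, nPairs = 2000L,
                            readLength = 251L, insertMean = 357,
                            insertSd = 40, errorRate = 0.002,
                            nVariants = 2L, variantFraction = 0.1,
                            minSpacing = NULL) {
  if (is.null(minSpacing))
    minSpacing <- min(500L, length %/% (2L * max(nVariants, 1L)))
  set.seed(seed)
  gen <- simulateGenome(length, nVariants, minSpacing, variantFraction)
  pairs <- simulatePairedReads(gen$genome, gen$variants, nPairs,
                               readLength, insertMean, insertSd, errorRate)
  new("SimulatedTruth", genome = gen$genome, variants = gen$variants,
      pairs = pairs, seed = as.integer(seed),
      params = list(length = length, nPairs = nPairs,
                    readLength = readLength, insertMean = insertMean,
                    insertSd = insertSd, errorRate = errorRate,
                    nVariants = nVariants,
                    variantFraction = variantFraction,
                    minSpacing = minSpacing))
}

setMethod("show", "SimulatedTruth", function(object) {
  cat("SimulatedTruth:", nchar(object@genome), "bp circular genome,",
      nrow(object@variants), "variant site(s),",
      length(object@pairs), "read pairs (seed", object@seed, ")\n")
})

#' Write a simulated dataset to FASTQ (and the truth to JSON)
#'
#' @param truth a [SimulatedTruth-class].
#' @param r1,r2 output FASTQ paths for the two mates.
#' @param truthFile optional JSON path for the genome, variants and
#'   parameters.
#' @return invisibly, the output paths.
#' @export
writeSimulatedDataset <- function(truth, r1, r2, truthFile = NULL) {
  writeFastq(truth@pairs@forward, r1)
  writeFastq(truth@pairs@reverse, r2)
  if (!is.null(truthFile))
    jsonlite::write_json(
      list(genome = truth@genome, variants = truth@variants,
           seed = truth@seed, params = truth@params),
      truthFile, auto_unbox = TRUE, digits = NA)
  invisible(c(r1, r2, truthFile))
}
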