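## Precomputed per-read structures shared across likelihood evaluations:
## integer-encoded forward and reverse-complement sequences and exact-match
## seeds at up to three offsets per strand. Building the bank once and
## scoring many contig sets against it is what makes MCMC over states
## affordable: the sampler memoizes by state, and each new state costs one
## pass over the bank.
newReadBank <- function(reads, model = readModel()) {
  reads <- toupper(as.character(reads))
  n <- length(reads)
  lens <- nchar(reads)
  rcs <- if (n > 0L) revComp(reads) else character(0L)
  sl <- pmin(lens, model@seedLength)
  ints <- vector("list", n)
  sAcc <- vector("list", n)
  for (r in seq_len(n)) {
    ints[[r]] <- list(utf8ToInt(reads[r]), utf8ToInt(rcs[r]))
    l <- lens[r]; s <- sl[r]
    ## up to five evenly spaced seeds: a placement is missed only when
    ## every seed window contains an error
    nOff <- min(5L, max(1L, l %/% s))
    offs <- unique(as.integer(round(seq(1L, l - s + 1L,
                                        length.out = nOff))))
    no <- length(offs)
    sAcc[[r]] <- list(
      str = c(substring(reads[r], offs, offs + s - 1L),
              substring(rcs[r], offs, offs + s - 1L)),
      read = rep(r, 2L * no),
      strand = rep(1:2, each = no),
      off = rep(offs, 2L))
  }
  seedStr <- unlist(lapply(sAcc, `[[`, "str"), use.names = FALSE)
  seedRead <- unlist(lapply(sAcc, `[[`, "read"), use.names = FALSE)
  seedStrand <- unlist(lapply(sAcc, `[[`, "strand"), use.names = FALSE)
  seedOff <- unlist(lapply(sAcc, `[[`, "off"), use.names = FALSE)
  useeds <- unique(seedStr)
  uid <- match(seedStr, useeds)
  byRead <- vector("list", n)
  for (r in seq_len(n)) byRead[[r]] <- list(NULL, NULL)
  if (n > 0L) {
    grp <- split(seq_along(uid), list(seedRead, seedStrand), drop = TRUE)
    for (key in names(grp)) {
      i <- grp[[key]]
      r <- seedRead[i[1L]]; strand <- seedStrand[i[1L]]
      byRead[[r]][[strand]] <- list(uid = uid[i], off = seedOff[i])
    }
  }
  list(n = n, lens = lens, seedLens = sl, ints = ints,
       uniqueSeeds = useeds, byRead = byRead)
}

## Score every read in the bank against a contig set. Returns per-read log
## probabilities plus their sum and mean.
scoreReadBank <- function(bank, contigs, model = readModel(),
                          circular = FALSE,
                          method = c("exhaustive", "seed")) {
  method <- match.arg(method)
  contigs <- toupper(as.character(contigs))
  nc <- length(contigs)
  if (bank$n == 0L) return(list(perRead = numeric(0L), sum = 0, mean = 0))
  Lc <- nchar(contigs)
  circular <- rep_len(as.logical(circular), max(nc, 1L))
  totalLen <- sum(Lc)
  eps <- model@errorRate
  log1m <- log(1 - eps)
  logE3 <- if (eps > 0) log(eps / 3) else -Inf
  maxLen <- max(bank$lens)
  if (nc > 0L) {
    ext <- character(nc)
    for (ci in seq_len(nc)) {
      if (circular[ci]) {
        reps <- ceiling((Lc[ci] + maxLen - 1L) / Lc[ci])
        ext[ci] <- substr(strrep(contigs[ci], reps), 1L,
                          Lc[ci] + maxLen - 1L)
      } else ext[ci] <- contigs[ci]
    }
    extInt <- lapply(ext, utf8ToInt)
  }
  ## seed position lookup per contig, per distinct seed length
  seedPos <- NULL
  if (method == "seed" && nc > 0L) {
    seedPos <- vector("list", nc)
    for (ci in seq_len(nc)) seedPos[[ci]] <- list()
    for (s in unique(bank$seedLens)) {
      us <- which(nchar(bank$uniqueSeeds) == s)
      for (ci in seq_len(nc)) {
        n2 <- nchar(ext[ci])
        if (n2 < s) {
          seedPos[[ci]][[as.character(s)]] <-
            rep(list(integer(0L)), length(bank$uniqueSeeds))
          next
        }
        km <- substring(ext[ci], seq_len(n2 - s + 1L), seq.int(s, n2))
        posList <- split(seq_len(n2 - s + 1L), km)
        hit <- match(bank$uniqueSeeds[us], names(posList))
        tab <- rep(list(integer(0L)), length(bank$uniqueSeeds))
        found <- which(!is.na(hit))
        tab[us[found]] <- posList[hit[found]]
        seedPos[[ci]][[as.character(s)]] <- tab
      }
    }
  }
  perRead <- numeric(bank$n)
  for (r in seq_len(bank$n)) {
    l <- bank$lens[r]
    nPos <- if (nc > 0L) ifelse(circular, Lc, pmax(Lc - l + 1L, 0L)) else
      integer(0L)
    D <- 2 * sum(nPos)
    if (nc == 0L || D == 0L) {
      perRead[r] <- floorLogProb(model, l, totalLen)
      next
    }
    lps <- numeric(0L)
    for (ci in seq_len(nc)) {
      if (nPos[ci] == 0L) next
      for (strand in 1:2) {
        rInt <- bank$ints[[r]][[strand]]
        if (method == "exhaustive") {
          starts <- seq_len(nPos[ci])
        } else {
          sds <- bank$byRead[[r]][[strand]]
          tab <- seedPos[[ci]][[as.character(bank$seedLens[r])]]
          starts <- integer(0L)
          for (j in seq_along(sds$uid)) {
            p <- tab[[sds$uid[j]]]
            if (length(p) > 0L) starts <- c(starts, p - sds$off[j] + 1L)
          }
          starts <- unique(starts)
          starts <- starts[starts >= 1L & starts <= nPos[ci]]
          if (length(starts) == 0L) next
        }
        lps <- c(lps, placementVec(rInt, extInt[[ci]], starts, log1m, logE3))
      }
    }
    tot <- logSumExp(lps)
    perRead[r] <- if (is.finite(tot)) tot - log(D) else
      floorLogProb(model, l, totalLen)
  }
  list(perRead = perRead, sum = sum(perRead), mean = mean(perRead))
}

#' Joint log probability of a read pair
#'
#' Optional paired-end score: sums, over contigs and orientations, the
#' probability of placing the forward mate at `i` and the
#' reverse-complemented mate downstream at `j`, weighted by a normal density
#' on the implied insert size (`model@insertMean`, `model@insertSd`), then
#' normalizes by the single-end placement count of the forward mate.
#' Exhaustive enumeration; intended for small problems and model checking,
#' not the default sampler likelihood.
#'
#' @param fwd,rev the two mate sequences (character).
#' @param contigs character vector of contig sequences.
#' @param model a [ReadModel-class].
#' @return a single log probability.
#' @export
readPairLogProb <- function(fwd, rev, contigs, model = readModel()) {
  contigs <- toupper(as.character(contigs))
  l1 <- nchar(fwd); l2 <- nchar(rev)
  eps <- model@errorRate
  log1m <- log(1 - eps)
  logE3 <- if (eps > 0) log(eps / 3) else -Inf
  f <- list(utf8ToInt(fwd), utf8ToInt(revComp(fwd)))
  m <- list(utf8ToInt(rev), utf8ToInt(revComp(rev)))
  lps <- numeric(0L)
  D <- 0
  for (contig in contigs) {
    cInt <- utf8ToInt(contig)
    L <- length(cInt)
    n1 <- L - l1 + 1L; n2 <- L - l2 + 1L
    if (n1 < 1L || n2 < 1L) next
    D <- D + 2 * n1
    for (strand in 1:2) {
      ## forward mate on `strand`, mate reverse-complemented on the other
      lp1 <- placementVec(f[[strand]], cInt, seq_len(n1), log1m, logE3)
      lp2 <- placementVec(m[[3L - strand]], cInt, seq_len(n2), log1m, logE3)
      for (i in seq_len(n1)) {
        ins <- if (strand == 1L) (seq_len(n2) + l2 - 1L) - i + 1L else
          (i + l1 - 1L) - seq_len(n2) + 1L
        w <- stats::dnorm(ins, model@insertMean, model@insertSd, log = TRUE)
        lps <- c(lps, lp1[i] + logSumExp(lp2 + w))
      }
    }
  }
  tot <- logSumExp(lps)
  if (!is.finite(tot) || D == 0)
    return(floorLogProb(model, l1 + l2, sum(nchar(contigs))))
  tot - log(D)
}

#' Paired-end log likelihood
#'
#' Sum of [readPairLogProb()] over all pairs of a [ReadPairs-class] set.
#'
#' @param contigs character vector of contig sequences.
#' @param pairs a [ReadPairs-class].
#' @param model a [ReadModel-class] (used with `paired = TRUE` pipelines).
#' @return a single numeric value.
#' @export
pairedLogLikelihood <- function(contigs, pairs, model = readModel()) {
  fwd <- as.character(forwardReads(pairs))
  rev <- as.character(reverseReads(pairs))
  sum(vapply(seq_along(fwd), function(i)
    readPairLogProb(fwd[i], rev[i], contigs, model), numeric(1L)))
}
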