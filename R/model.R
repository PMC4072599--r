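## Finite stand-in for log(0) prior density at impossible assemblies
## (zero length / zero contigs), so log-posterior arithmetic stays finite.
PRIOR_FLOOR <- -1e6

#' Construct a mode-centered gamma prior
#'
#' @param shape shape \eqn{\alpha > 1}.
#' @param center the mode \eqn{c > 0}; the scale is
#'   \eqn{\theta = c/(\alpha-1)}, so \eqn{(\alpha-1)\theta = c} exactly.
#' @return a [GammaPrior-class].
#' @export
gammaPrior <- function(shape, center) {
  new("GammaPrior", shape = as.numeric(shape), center = as.numeric(center))
}

gammaLogDensity <- function(prior, x) {
  scale <- prior@center / (prior@shape - 1)
  ifelse(x > 0, dgamma(x, shape = prior@shape, scale = scale, log = TRUE),
         PRIOR_FLOOR)
}

#' Construct a prior configuration
#'
#' Defaults encode what is known about the phiX174 benchmark genome: total
#' length centered at 5,386 bp, contig count centered at 1 (a single
#' circular chromosome).
#'
#' @param lengthCenter,lengthShape mode and shape of the total-length prior.
#' @param contigCenter,contigShape mode and shape of the contig-count prior.
#' @param mode `"full"`, `"flat"` (log prior = 0) or `"prior_only"`
#'   (log likelihood = 0).
#' @return a [PriorConfig-class].
#' @export
priorConfig <- function(lengthCenter = 5386, lengthShape = 5,
                        contigCenter = 1, contigShape = 5,
                        mode = c("full", "flat", "prior_only")) {
  mode <- match.arg(mode)
  new("PriorConfig",
      lengthPrior = gammaPrior(lengthShape, lengthCenter),
      contigPrior = gammaPrior(contigShape, contigCenter),
      mode = mode)
}

#' Log prior of an assembly summary
#'
#' Sum of the two gamma log densities, evaluated at the total contig length
#' and the contig count. In `"flat"` mode the log prior is identically 0;
#' zero-length or zero-contig states receive a large negative floor (the
#' gamma density is 0 there).
#'
#' @param totalLength total contig length in bases (>= 0).
#' @param nContigs number of contigs (>= 0).
#' @param cfg a [PriorConfig-class].
#' @return a single numeric log density (unnormalized posterior component).
#' @export
logPrior <- function(totalLength, nContigs, cfg = priorConfig()) {
  stopifnot(totalLength >= 0, nContigs >= 0)
  if (cfg@mode == "flat") return(0)
  gammaLogDensity(cfg@lengthPrior, totalLength) +
    gammaLogDensity(cfg@contigPrior, nContigs)
}

#' Construct a read-generation model
#'
#' @param errorRate per-base substitution probability \eqn{\epsilon}.
#' @param minLogProb floor log probability for unplaceable reads; `NA`
#'   (default) derives the worst-possible-placement floor
#'   `l*log(errorRate/3) - log(2*sum(contig lengths))` per read.
#' @param seedLength exact seed length for the fast placement search
#'   (effective seed is `min(read length, seedLength)`).
#' @param paired score mates jointly with a normal insert-size density.
#' @param insertMean,insertSd insert-size model used when `paired = TRUE`.
#' @return a [ReadModel-class].
#' @export
readModel <- function(errorRate = 0.002, minLogProb = NA_real_,
                      seedLength = 16L, paired = FALSE,
                      insertMean = 357, insertSd = 40) {
  new("ReadModel", errorRate = errorRate, minLogProb = minLogProb,
      seedLength = as.integer(seedLength), paired = paired,
      insertMean = insertMean, insertSd = insertSd)
}

## Floor applied to a read with no (finite) placement.
floorLogProb <- function(model, readLen, totalContigLen) {
  if (!is.na(model@minLogProb)) return(model@minLogProb)
  eps <- model@errorRate
  readLen * log(eps / 3) - log(2 * max(totalContigLen, 1))
}

#' Log probability of one read placement
#'
#' Compares the read (reverse-complemented for `strand = "-"`) to the
#' contig window starting at `start`: each matching base contributes
#' \eqn{\log(1-\epsilon)}, each mismatch \eqn{\log(\epsilon/3)}. With
#' \eqn{\epsilon = 0} any mismatch yields `-Inf` (the placement contributes
#' probability 0).
#'
#' @param read,contig character strings.
#' @param start 1-based start of the placement window;
#'   `1 <= start <= nchar(contig) - nchar(read) + 1`.
#' @param strand `"+"` or `"-"`.
#' @param model a [ReadModel-class] (only `errorRate` is used).
#' @return a single log probability.
#' @export
placementLogProb <- function(read, contig, start, strand = "+",
                             model = readModel()) {
  l <- nchar(read)
  if (start < 1L || start > nchar(contig) - l + 1L)
    stop("placement start out of range")
  if (strand == "-") read <- revComp(read)
  rInt <- utf8ToInt(read)
  cInt <- utf8ToInt(substr(contig, start, start + l - 1L))
  m <- sum(rInt != cInt)
  eps <- model@errorRate
  mm <- if (m > 0L) m * log(eps / 3) else 0
  (l - m) * log(1 - eps) + mm
}

## Mismatch counts of `readInt` at each start in `starts` against the
## integer-encoded subject. Vectorized over starts.
mismatchCounts <- function(readInt, subjInt, starts) {
  l <- length(readInt)
  if (length(starts) == 0L) return(integer(0L))
  idx <- outer(seq_len(l) - 1L, starts, `+`)  # l x |starts|, starts 1-based
  .colSums(subjInt[idx] != readInt, l, length(starts))
}

## Placement log-probabilities for a read (already oriented) over all given
## starts of one subject.
placementVec <- function(readInt, subjInt, starts, log1m, logE3) {
  m <- mismatchCounts(readInt, subjInt, starts)
  lp <- (length(readInt) - m) * log1m
  has <- m > 0L
  lp[has] <- lp[has] + m[has] * logE3
  lp
}

#' Average read-generation probability of one read
#'
#' The probability that the contig set generated the read: the sum of
#' placement probabilities over all valid start positions, both strands and
#' all contigs, divided by the number of possible placements
#' `2 * sum(max(Lc - l + 1, 0))`. Returns the log. When the sum is zero or
#' no placement exists, the floor (`minLogProb`, or the derived worst-case
#' placement value) is returned.
#'
#' `method = "exhaustive"` enumerates every start (the default, exact);
#' `"seed"` enumerates only placements that share an exact seed
#' (`min(l, seedLength)` bases at up to five evenly spaced read offsets)
#' with the contig -- an approximation that misses a placement only when
#' every seed window contains an error, used by the sampler on full read
#' sets.
#'
#' @param read a character string.
#' @param contigs character vector of contig sequences.
#' @param model a [ReadModel-class].
#' @param method `"exhaustive"` or `"seed"`.
#' @param circular logical vector (recycled) marking contigs that represent
#'   circles; circular contigs are scored with a `l-1` wrap extension and
#'   contribute `Lc` placements per strand.
#' @return a single log probability.
#' @export
readLogProb <- function(read, contigs, model = readModel(),
                        method = c("exhaustive", "seed"),
                        circular = FALSE) {
  method <- match.arg(method)
  bank <- newReadBank(read, model)
  scoreReadBank(bank, contigs, model, circular = circular,
                method = method)$perRead
}

#' Log likelihood of a contig set
#'
#' Log probability that the assembly generated the whole read set under the
#' placement + substitution-error model: the sum over reads of
#' [readLogProb()] (the product-model likelihood). `average = TRUE` instead
#' returns the per-read mean -- the Log Average Probability (LAP) score
#' commonly used to compare assemblies (see also [lapScore()]).
#'
#' @param contigs character vector of contig sequences (may carry a
#'   `circular` attribute, as returned by [activeContigs()]).
#' @param reads character vector, `DNAStringSet` or
#'   `QualityScaledDNAStringSet`.
#' @param model a [ReadModel-class].
#' @param method placement search, as in [readLogProb()]; `"auto"` picks
#'   `"exhaustive"` for small problems and `"seed"` otherwise.
#' @param average return the per-read mean instead of the sum.
#' @return a single numeric value.
#' @export
logLikelihood <- function(contigs, reads, model = readModel(),
                          method = c("auto", "exhaustive", "seed"),
                          average = FALSE) {
  method <- match.arg(method)
  reads <- as.character(reads)
  circular <- attr(contigs, "circular")
  if (is.null(circular)) circular <- FALSE
  if (method == "auto") {
    work <- sum(nchar(reads)) * sum(nchar(contigs))
    method <- if (work <= 5e7) "exhaustive" else "seed"
  }
  bank <- newReadBank(reads, model)
  sc <- scoreReadBank(bank, as.character(contigs), model,
                      circular = circular, method = method)
  if (average) sc$mean else sc$sum
}

#' @rdname logLikelihood
#' @export
lapScore <- function(contigs, reads, model = readModel(),
                     method = c("auto", "exhaustive", "seed")) {
  logLikelihood(contigs, reads, model, method, average = TRUE)
}

#' Unnormalized log posterior of an assembly state
#'
#' `logLikelihood(activeContigs(s, g)) + logPrior(totalLength, nContigs)`.
#' `cfg@mode = "prior_only"` short-circuits the likelihood to 0;
#' `cfg@mode = "flat"` zeroes the prior.
#'
#' @param s a valid [AssemblyState-class].
#' @param g the [AssemblyGraph-class].
#' @param reads the read set (as in [logLikelihood()]).
#' @param cfg a [PriorConfig-class].
#' @param model a [ReadModel-class].
#' @param method placement search method.
#' @return a single numeric value.
#' @export
logPosterior <- function(s, g, reads, cfg = priorConfig(),
                         model = readModel(),
                         method = c("auto", "exhaustive", "seed")) {
  ll <- if (cfg@mode == "prior_only") 0 else
    logLikelihood(activeContigs(s, g), reads, model, method)
  ll + logPrior(s@totalLength, s@nContigs, cfg)
}

#' Read prior/model settings from a key-value config file
#'
#' Parses lines of the form `key=value` (blank lines and `#` comments
#' ignored). Recognized keys: `prior.length.center`, `prior.length.shape`,
#' `prior.contig.center`, `prior.contig.shape`, `prior.mode`
#' (`full`/`flat`/`prior_only`), `model.error_rate`, `model.paired`
#' (`true`/`false`), `model.insert_mean`, `model.insert_sd`. Unknown keys
#' are an error; missing keys keep their defaults.
#'
#' @param file path to the config file.
#' @return a list with `cfg` (a [PriorConfig-class]) and `model`
#'   (a [ReadModel-class]).
#' @export
readAnalysisConfig <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("config lines must have the form key=value")
  vals <- setNames(trimws(vapply(kv, `[`, character(1L), 2L)),
                   trimws(vapply(kv, `[`, character(1L), 1L)))
  known <- c("prior.length.center", "prior.length.shape",
             "prior.contig.center", "prior.contig.shape", "prior.mode",
             "model.error_rate", "model.paired", "model.insert_mean",
             "model.insert_sd")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  get <- function(key, default, f = as.numeric)
    if (key %in% names(vals)) f(vals[[key]]) else default
  cfg <- priorConfig(
    lengthCenter = get("prior.length.center", 5386),
    lengthShape = get("prior.length.shape", 5),
    contigCenter = get("prior.contig.center", 1),
    contigShape = get("prior.contig.shape", 5),
    mode = get("prior.mode", "full", as.character))
  model <- readModel(
    errorRate = get("model.error_rate", 0.002),
    paired = get("model.paired", FALSE,
                 function(x) tolower(x) == "true"),
    insertMean = get("model.insert_mean", 357),
    insertSd = get("model.insert_sd", 40))
  list(cfg = cfg, model = model)
}
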