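## Exact enumeration of the single-perturbation proposal kernel.
##
## The bubble-aware proposal is asymmetric: activating an edge can add a
## whole random-walk path while deactivating removes a single edge, so the
## plain posterior odds ratio does not target the posterior exactly. On
## small graphs the proposal probability q(s -> s') can be computed exactly
## by enumerating every random choice (edge draw, each walk step), which
## enables an exact Metropolis-Hastings acceptance rule. Cost grows with
## the walk tree, so this is intended for graphs of, say, <= 12 edges --
## model checking and small-problem inference, not the headline pipeline.

## Enumerate all outcomes of one perturbation draw from `act`.
## Returns list(outcomes = named prob vector keyed by stateKey, fail = prob
## mass of draws that cannot yield a valid state).
enumPerturbKernel <- function(gi, act) {
  E <- gi$E
  cap <- 2L * E
  outcomes <- new.env(parent = emptyenv())
  fail <- 0
  addOutcome <- function(a, p) {
    key <- stateKey(a)
    prev <- outcomes[[key]]
    outcomes[[key]] <- if (is.null(prev)) p else prev + p
  }
  for (e in seq_len(E)) {
    pe <- 1 / E
    if (act[e]) {
      a <- act; a[e] <- FALSE
      addOutcome(a, pe)
      next
    }
    ## recursive enumeration of the two walks, mirroring tryActivate()
    finish <- function(P, u, v, prob) {
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
          if (steps > E) { branch <- NULL; break }
        }
        if (!is.null(branch)) act2[branch] <- FALSE
      }
      if (validActive(gi, act2)) addOutcome(act2, prob)
      else fail <<- fail + prob
    }
    forwardWalk <- function(P, u, cur, steps, prob) {
      if (activeIncident(gi, act, cur) || steps >= cap) {
        finish(P, u, cur, prob)
        return()
      }
      elig <- gi$outE[[cur]]
      elig <- elig[!act[elig] & !(elig %in% P)]
      if (length(elig) == 0L) {
        finish(P, u, cur, prob)
        return()
      }
      for (pick in elig)
        forwardWalk(c(P, pick), u, gi$to[pick], steps + 1L,
                    prob / length(elig))
    }
    backwardWalk <- function(P, cur, steps, prob) {
      if (activeIncident(gi, act, cur) || steps >= cap) {
        forwardWalk(P, cur, gi$to[e], 0L, prob)
        return()
      }
      elig <- gi$inE[[cur]]
      elig <- elig[!act[elig] & !(elig %in% P)]
      if (length(elig) == 0L) {
        forwardWalk(P, cur, gi$to[e], 0L, prob)
        return()
      }
      for (pick in elig)
        backwardWalk(c(pick, P), gi$from[pick], steps + 1L,
                     prob / length(elig))
    }
    backwardWalk(e, gi$from[e], 0L, pe)
  }
  out <- as.list(outcomes)
  list(outcomes = unlist(out), fail = fail)
}

## Effective proposal probability q(s -> s'), accounting for the redraw
## policy (an invalid draw is re-drawn, up to E times).
effectiveProposalProb <- function(kernel, E, targetKey) {
  q1 <- kernel$outcomes[targetKey]
  if (is.na(q1)) return(0)
  f <- kernel$fail
  unname(q1) * if (f > 0) (1 - f^E) / (1 - f) else 1
}

## Memoized kernel lookup.
kernelFor <- function(gi, act, cache) {
  key <- paste0("K", stateKey(act))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- enumPerturbKernel(gi, act)
  cache[[key]] <- k
  k
}

## Mixture proposal probability q(s -> s') of the exact sampler: half the
## mass on the bubble-aware walk kernel (with redraws), half on a symmetric
## single-edge toggle (invalid toggles propose the current state).
mixtureProposalProb <- function(gi, actFrom, actTo, kernelFrom) {
  qWalk <- effectiveProposalProb(kernelFrom, gi$E, stateKey(actTo))
  qTog <- if (sum(actFrom != actTo) == 1L) 1 / gi$E else 0
  0.5 * qWalk + 0.5 * qTog
}

#' Run an exact Metropolis-Hastings chain over assembly states
#'
#' Variant of [runChain()] whose stationary distribution is exactly
#' `exp(logpost)`. The proposal is an equal mixture of the bubble-aware
#' walk perturbation and a symmetric single-edge toggle (an invalid toggle
#' proposes the current state), and the acceptance uses the exact
#' Metropolis-Hastings ratio
#' `min(1, exp(dlogpost) * q(new -> old) / q(old -> new))`, with the walk
#' kernel's proposal probabilities computed exactly by enumerating every
#' random choice of the move. The toggle component makes the mixture's
#' support reversible (a multi-edge walk activation alone cannot be undone
#' in one move). Kernel enumeration is memoized per state and is practical
#' on small graphs (roughly up to a dozen edges) -- model checking and
#' exact small-problem inference, not the headline pipeline.
#'
#' @inheritParams runChain
#' @return a [ChainTrace-class].
#' @export
runChainHastings <- function(g, logpostFun, nIterations, seed = 1L,
                             recordMode = c("all", "accepted_only"),
                             init = NULL) {
  stopifnot(nIterations >= 1L)
  recordMode <- match.arg(recordMode)
  set.seed(seed)
  gi <- graphIndex(g)
  if (gi$E == 0L) stop("graph has no edges")
  cache <- new.env(parent = emptyenv())
  if (is.null(init)) {
    act <- rep(FALSE, gi$E)
    for (i in seq_len(gi$E)) act <- perturbActive(gi, act)
  } else act <- init@active
  lp <- logpostFun(act)
  states <- matrix(FALSE, nrow = nIterations, ncol = gi$E)
  lps <- numeric(nIterations); accs <- logical(nIterations)
  iter <- integer(nIterations)
  nrec <- 0L; nacc <- 0L
  for (it in seq_len(nIterations)) {
    if (runif(1L) < 0.5) {
      actNew <- perturbActive(gi, act)
    } else {
      e <- sample.int(gi$E, 1L)
      actNew <- act
      actNew[e] <- !actNew[e]
      if (!validActive(gi, actNew)) actNew <- act
    }
    keyOld <- stateKey(act); keyNew <- stateKey(actNew)
    if (keyNew == keyOld) {
      accepted <- TRUE          # lazy self-move
      lpNew <- lp
    } else {
      lpNew <- logpostFun(actNew)
      qf <- mixtureProposalProb(gi, act, actNew,
                                kernelFor(gi, act, cache))
      qr <- mixtureProposalProb(gi, actNew, act,
                                kernelFor(gi, actNew, cache))
      if (qr == 0) {
        accepted <- FALSE
      } else {
        logR <- (lpNew - lp) + log(qr) - log(qf)
        if (is.nan(logR)) logR <- 0
        accepted <- logR >= 0 || runif(1L) < exp(logR)
      }
    }
    if (accepted) { act <- actNew; lp <- lpNew; nacc <- nacc + 1L }
    if (recordMode == "all" || accepted) {
      nrec <- nrec + 1L
      states[nrec, ] <- act
      lps[nrec] <- lp
      accs[nrec] <- accepted
      iter[nrec] <- it
    }
  }
  new("ChainTrace",
      iteration = iter[seq_len(nrec)], accepted = accs[seq_len(nrec)],
      logPosterior = lps[seq_len(nrec)],
      states = states[seq_len(nrec), , drop = FALSE],
      proposals = as.integer(nIterations), acceptances = nacc,
      seed = as.integer(seed), recordMode = recordMode)
}

#' Quantify the proposal asymmetry of the plain kernel
#'
#' For every valid state of a small graph, enumerates the exact
#' single-perturbation kernel and reports the forward/reverse proposal
#' probabilities of each move. A symmetric kernel would have ratio 1
#' everywhere; deviations measure the bias incurred by the plain
#' odds-ratio sampler.
#'
#' @param g a small [AssemblyGraph-class] (<= ~12 edges).
#' @return a data.frame with columns `from`, `to` (state keys), `qForward`,
#'   `qReverse`.
#' @export
hastingsCheck <- function(g) {
  gi <- graphIndex(g)
  states <- enumerateValidStates(g)
  keys <- vapply(states, stateKey, character(1L))
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (i in seq_along(states)) {
    kern <- kernelFor(gi, states[[i]], cache)
    for (key in names(kern$outcomes)) {
      j <- match(key, keys)
      if (is.na(j) || j == i) next
      qf <- effectiveProposalProb(kern, gi$E, key)
      qr <- effectiveProposalProb(kernelFor(gi, states[[j]], cache),
                                  gi$E, keys[i])
      rows[[length(rows) + 1L]] <- data.frame(
        from = keys[i], to = key, qForward = qf, qReverse = qr)
    }
  }
  do.call(rbind, rows)
}

#' Enumerate all valid states of a small graph
#'
#' Brute force over all `2^nEdges` boolean vectors, keeping those that
#' satisfy the path-validity constraint. Intended for oracle tests and
#' exact posterior summaries on toy graphs.
#'
#' @param g an [AssemblyGraph-class] with at most 20 edges.
#' @return a list of logical vectors.
#' @export
enumerateValidStates <- function(g) {
  E <- nrow(g@edges)
  stopifnot(E <= 20L)
  gi <- graphIndex(g)
  out <- list()
  for (m in 0:(2^E - 1)) {
    act <- bitwAnd(m, 2L^(seq_len(E) - 1L)) > 0L
    if (validActive(gi, act)) out[[length(out) + 1L]] <- act
  }
  out
}
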