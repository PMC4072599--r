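---
title: "Bayesian assembly by MCMC: model, sampler and design notes"
author: "AssemblySampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian assembly by MCMC: model, sampler and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Most assemblers report a single point-estimate genome. AssemblySampler
instead treats assembly as Bayesian inference: the hypothesis space is the
set of paths through a reduced de Bruijn graph, and a Metropolis sampler
draws assemblies from their posterior distribution, so that every node and
edge of the graph — and any feature of an external assembly that matches
the graph exactly — receives a posterior probability. This vignette
explains the model, the sampler, and the design decisions that were
genuinely open, in enough detail to judge what a passing test suite does
and does not establish.

## The hypothesis space

Reads (forward mates plus reverse-complemented reverse mates, so that a
proper pair lies on one strand) are decomposed into k-mers; nodes are
distinct k-mers, edges are observed (k+1)-mer adjacencies. Three
reductions shrink this graph to the minimal representation of the variants
supported by the data:

1. **Tip trimming** (`trimTips`): dead-end chains are removed recursively
   to a fixpoint, because the target genome is circular and the true graph
   therefore has no dead ends. A linear mode trims only tips shorter than
   `2k`, a softer threshold appropriate when genuine sequence ends exist.
2. **Unitig merging** (`mergeUnambiguousPaths`): every edge whose source
   has out-degree 1 and whose target has in-degree 1 is contracted; the
   merged annotation grows by one nucleotide per merged k-mer node. A
   fully unambiguous cycle collapses to one node with a self-edge, so a
   reduced graph always keeps at least one edge.
3. **Largest weak component** (`largestWeakComponent`), by total
   annotation length; ties go to the component containing the
   lexicographically smallest annotation so the choice is deterministic.

An assembly hypothesis (`AssemblyState`) is a boolean vector over the
graph's edge enumeration. Validity requires every node to have at most one
active incoming and one active outgoing edge; the active edges then
decompose uniquely into vertex-disjoint paths and cycles, each spelling
one contig by overlap-merged concatenation. Cycles are spelled with the
final k−1 wrap characters trimmed and rotated to the lexicographically
minimal rotation (`canonicalRotation`), which makes circular contigs
comparable across states and to a reference.

Edge enumeration is sorted by (source annotation, target annotation), so
edge indices — and therefore states, traces and frequencies — are
reproducible across runs. Indices are 1-based, following R convention.

## The posterior

**Likelihood.** A read is generated from a contig set by choosing a
placement uniformly among all `2 * sum(max(Lc - l + 1, 0))` (contig,
strand, start) combinations and copying the window with i.i.d.
substitution errors: each matching base contributes `1 - eps`, each
mismatch `eps/3`. The per-read probability is the average over all
placements; `readLogProb` computes its log, exhaustively or by
seed-and-extend (below). The assembly's log likelihood is the **sum** of
per-read log probabilities — the product-model likelihood that a
posterior odds ratio requires. The per-read *average* (the LAP score
commonly used to compare assemblies on the same reads) is available via
`lapScore()` and `average = TRUE`, but it is deliberately not what enters
the sampler: dividing by the read count compresses posterior differences
by a factor of N and would make the sampler almost indifferent between
supported and unsupported branches.

Reads with no placement are floored at the worst possible placement value,
`l*log(eps/3) - log(2*sum(Lc))`, so an unexplained read penalizes a state
heavily but finitely (with `eps = 0` the floor is `-Inf`, appropriate for
exact-match scoring). Contigs spelled from cycles are scored circularly:
the subject is extended by a `(max read length - 1)` wrap and each strand
contributes `Lc` placements, so reads spanning the origin place exactly
and the likelihood does not depend on where the canonical rotation happens
to cut the circle. The exported `readLogProb` keeps the plain linear
contract (no wrap) so its brute-force oracle is unambiguous.

**Seed-and-extend.** Enumerating every placement of 4,000 reads against a
5 kb contig set at every MCMC evaluation is wasteful: with a low error
rate, only near-exact placements contribute. The sampler's scorer
(`method = "seed"`) finds candidate placements through up to five evenly
spaced exact 16-mer seeds per read and strand, then counts mismatches at
the candidate starts only. A placement is missed only if *every* seed
window contains an error; with five seeds this is vanishingly rare at the
error rates the model targets (≤ 1%). The exhaustive mode remains the
default for `readLogProb`/`logLikelihood` on small inputs and is the
reference the seed mode is tested against.

**Priors.** The prior is a product of two gamma densities: one on total
contig length, one on the number of contigs. "Centered" is implemented as
the gamma **mode**: with shape α and scale θ = c/(α−1) the density peaks
at c exactly, for every α > 1, so the maximum a priori assembly keeps the
known genome length (5,386 bp) and chromosome count (1) while α tunes how
sharply deviations are penalized. The shape default is 5; it is
configuration, not a calibrated constant. `mode = "flat"` zeroes the log
prior, `mode = "prior_only"` zeroes the log likelihood, allowing
prior-sensitivity runs. Zero-length or zero-contig states take a large
finite floor instead of the gamma's `-Inf`, keeping arithmetic NaN-free.

## The sampler

The elementary move (`perturb`) picks an edge uniformly. An active edge is
simply deactivated, splitting its path — plain deactivation is the
minimal move that lets assemblies shrink. An inactive edge is activated and extended from both
endpoints by uniform random walks over inactive edges until each walk
meets a node with an active incident edge (or runs out of moves); the
pre-existing active branch between the two attachment nodes, if any, is
then deactivated. This is what lets one move switch an entire bubble
branch. A draw that cannot produce a valid state is re-drawn, up to E
times. Proposals compose three perturbations by default, taking larger
steps through the state space. Acceptance is the plain posterior odds
ratio: accept if `logR > 0`, else with probability `exp(logR)`.

Two properties of this kernel deserve honesty:

* **Asymmetry.** Activating an edge can add a whole walk path while the
  reverse move removes a single edge, so the proposal distribution is not
  symmetric and the plain odds-ratio acceptance does not target the
  posterior exactly. On sharply peaked posteriors (the realistic-coverage
  regime, where branch odds are hundreds of log units) this bias is
  irrelevant; on near-flat posteriors it is measurable.
* **Reducibility.** Exact enumeration of the kernel on a two-bubble toy
  graph shows that some valid states — those with a "dangling" branch
  out-edge whose feeding segment actively points to the other branch —
  can be left but never entered: activation walks overshoot them and
  every valid superset contains the same pattern.

Both are structural consequences of the bubble-aware walk, not bugs, and
both are quantifiable with `hastingsCheck()`, which enumerates every
random choice of a move and reports exact forward/reverse proposal
probabilities. For exact inference on small graphs the package provides
`runChainHastings()`: an equal mixture of the walk move and a symmetric
single-edge toggle (which restores irreducibility), accepted with the
exact Metropolis–Hastings ratio using the enumerated proposal
probabilities. Its stationary distribution provably equals the target,
and the sampler-correctness tests compare it against brute-force state
enumeration. The headline pipeline keeps the plain odds-ratio kernel —
the method's characteristic move set — while the exact variant is the
yardstick that shows what the plain kernel's bias does and does not
affect.

Chains are deterministic given their seed; `runChains` runs independent
chains at `seed, seed+1, ...` and shares the memoized posterior cache
(the posterior depends only on the state, and memoization is what makes
MCMC affordable: on a reduced graph the number of *distinct* valid states
is small, so each is scored once). By default every iteration is recorded
(a rejection re-records the current state); `accepted_only` matches
summaries quoted in accepted samples. No burn-in is discarded by default
— cumulative frequencies from the start are themselves the convergence
diagnostic.

## Summaries

Edge/node cumulative frequencies, their cross-chain standard deviation
(`crossChainSD`, averaged over edges) and pairwise final-frequency
agreement (`frequencyAgreement`) quantify mixing and convergence. The
majority-rule consensus activates edges at posterior frequency ≥ 0.5
(ties kept); should supra-threshold edges conflict, edges are admitted
greedily by descending frequency (ties: lower index) and displaced edges
are flagged in the output rather than silently dropped — the consensus is
always a valid, spellable state. Contig-level posteriors are the minimum
edge posterior along the path, a conservative choice. External assemblies
are annotated by exact substring matching on either strand: nodes by
their annotation, edges by the k+1-base junction string; exact matching
is conservative (a contig cut inside a node annotation will not match it,
e.g. the cut a linearized circular contig makes at its rotation anchor).

## The simulator and what passing tests mean

`simulateDataset` emulates the statistics of the phiX174 MiSeq benchmark
subset: a 5,386 bp uniform-random circle, 2,000 pairs of full-length
251 bp mates, normal insert (mean 357, sd 40 — only the benchmark's mean
insert size is known; 40 is a plausible library width), substitution errors
at 0.002, constant Q38 qualities (so simulated data pass the Q>37 mean
filter by construction), and two biallelic variant sites at least 500 bp
apart carried by 10% of fragments independently per site. Fragment starts
are uniform on the circle and wrap the origin; reads are emitted
linearized.

Note one bookkeeping subtlety: for full-length 2 × 251 bp pairs, total
base coverage is 2000·2·251/5386 ≈ 186×, while the benchmark's printed
"≈93×" corresponds to one mate per pair (2000·251/5386 ≈ 93.2).
`coverageStats` reports the total-bases figure; the acceptance script
reports both.

The simulator does **not** model indels, quality-score decay along the
read, adapter read-through, coverage biases, or repeats. Consequently,
recovery tests demonstrate that the graph machinery, likelihood and
sampler behave correctly under the generative model they assume — they do
not establish robustness to real-data artifacts outside that model, and
the de Bruijn stage has no indel-bubble handling at all (repeat-aware
multi-visit paths are explicitly out of scope).

The end-to-end study uses k = 31 and a k-mer multiplicity cutoff of 5.
The cutoff is the standard coverage filter of de Bruijn assemblers: at
~180× k-mer depth even the 10% haplotype's branch sits near 14×
(probability of falling below 5 is ~10⁻³), while error k-mers recur only
through independent reads making the same call at the same site — with
~2,000 errors over ~16,000 site/alternative combinations, triple
collisions occur a handful of times per dataset but five-fold collisions
have probability ~4·10⁻³. Without the cutoff, every interior read error
seeds its own bubble and the hypothesis space explodes.

Problem sizes in the test suite are the package's own choices: toy
two-bubble graphs of 8 edges (81 valid states, enumerable exactly),
3 chains × 50,000 iterations for sampler correctness, and the full
5,386 bp / 2,000-pair study with 3 chains × 20,000 iterations for
end-to-end recovery.

## Numerical and degenerate-input choices

* All probability arithmetic is in log space; sums of placement
  probabilities use a max-shifted log-sum-exp; the odds ratio is only
  exponentiated when `logR < 0`.
* `-Inf` vs `-Inf` posterior comparisons define `logR = 0` (equal), so
  chains cannot NaN even when every read is floored at `eps = 0`.
* Empty graphs error at reduction; an empty consensus writes an empty
  FASTA with a warning; an all-inactive state spells zero contigs
  (isolated nodes contribute nothing — an assembly is what its active
  paths spell).
* `parseFastq` validates 4-line record structure itself (the delegated
  C parser accepts base/quality length mismatches silently) and then
  stores reads in Biostrings containers.
* Random draws from length-1 vectors use `sample.int` to avoid R's
  scalar-sampling surprise; all stochastic entry points take explicit
  seeds.

## Limitations

Repeats (edges visited more than once) are out of scope, as is
Metropolis-coupled MCMC; both are natural extensions of the state vector
and sampler. The graph is single-stranded by construction from oriented
mates; data whose mates do not follow the forward/reverse-complement
convention would need canonicalization (`canonical = TRUE` in
`buildDeBruijn`). Paired-end likelihood (`readPairLogProb`, normal insert
density) is provided for model checking but is not the default sampler
likelihood. The exact Metropolis–Hastings sampler enumerates the walk
kernel and is therefore only practical on reduced graphs of roughly a
dozen edges.
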