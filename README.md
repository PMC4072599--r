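# AssemblySampler

Bayesian genome assembly by MCMC sampling of assembly-graph paths.

Most assemblers return one genome sequence — a point estimate — with no
statement of how strongly the data support it relative to the many
alternative assemblies consistent with the same reads. AssemblySampler
treats assembly as posterior inference: it samples whole assembly
hypotheses from their posterior distribution, so that every feature of the
assembly (each node and edge of the assembly graph, and any exactly
matching feature of an assembly produced by another tool) carries a
posterior probability. It is aimed at small genomes and at anyone who
wants calibrated uncertainty on assembly structure — which bubble branch
is real, which junctions are solid — rather than a single answer.

## Method

Reads are reduced to a de Bruijn graph (nodes = k-mers, edges = (k+1)-mer
adjacencies), tips are trimmed recursively (the target genome is
circular), unambiguous paths are merged into unitig nodes, and the
largest weakly connected component is kept. The result is a small graph
"of bubbles": parallel branches between forks and joins represent the
sequence variants the reads actually support.

An assembly hypothesis is a boolean vector **b** over the graph's E
edges whose active edges form vertex-disjoint paths and cycles, each
spelling a contig. The unnormalized log posterior of a state is

```
log P(b | reads)  ∝  Σ_r log p(r | contigs(b))  +  log Gamma(L(b); α, θ_L)
                                               +  log Gamma(C(b); α, θ_C)
```

where `p(r | contigs)` is the average over all placements (both strands,
all contigs) of an i.i.d. substitution-error model (match `1 − ε`,
mismatch `ε/3`), and the two gamma priors are parameterized by their mode:
total length L centered at 5,386 bp and contig count C centered at 1 for
the phiX174 benchmark. A Metropolis sampler explores states with a
bubble-aware proposal: toggling an inactive edge activates it, extends it
by random walks until it meets the existing assembly, and deactivates the
displaced branch — so one move can switch an entire bubble branch.
Acceptance follows the posterior odds ratio `R`: accept if `R > 1`, else
with probability `R`. Independent chains, cumulative node/edge
frequencies, cross-chain standard deviations and pairwise frequency
agreement provide convergence diagnostics; a majority-rule consensus
(edges at posterior ≥ 0.5) gives a point estimate with per-feature
posteriors attached. An exact Metropolis–Hastings variant
(`runChainHastings`) with enumerated proposal probabilities serves as the
correctness yardstick on small graphs.

A built-in simulator generates the benchmark conditions (5,386 bp
circular genome, 2,000 pairs of 251 bp mates, insert 357 ± 40 bp, 0.2%
substitution error, two variant sites at 90/10 haplotype fractions), so
the whole pipeline runs and is tested without downloading anything.

## Worked example

```r
library(AssemblySampler)

truth <- simulateDataset(seed = 42)     # known genome + reads
truth
#> SimulatedTruth: 5386 bp circular genome, 2 variant site(s), 2000 read pairs (seed 42 )

res <- assemblePosterior(truth@pairs, seed = 1)
res$graph
#> AssemblyGraph: k = 31 | 6 nodes, 8 edges | 5628 bases of annotation
res$diagnostics$nBubbles
#> [1] 2
res$consensus
#> ConsensusAssembly: threshold 0.5 | 1 contig(s), 5386 bases
round(res$edgeFreqs, 3)
#> [1] 1 0 1 0 0 1 0 1
signif(res$diagnostics$finalCrossChainSD, 3)
#> [1] 0.000237
identical(res$consensus@contigs$sequence[1],
          canonicalRotation(truth@genome))
#> [1] TRUE
```

Reading the output: graph reduction found exactly the two variant
bubbles (6 nodes, 8 edges); after 3 chains × 20,000 iterations the four
major-haplotype edges have posterior 1 and the minor branches 0; the
chains agree to within 2.4 × 10⁻⁴ in cumulative edge frequency; and the
majority-rule consensus is one circular contig of 5,386 bp whose
canonical rotation equals the true major haplotype exactly.

`writeOutputs()` exports the consensus FASTA (posteriors in headers), a
posterior-colored GFA/DOT graph, a per-feature TSV and a JSON diagnostics
file; `annotateExternal()` transfers posteriors onto assemblies produced
by other tools via exact feature matching. A thin command-line front end
with `simulate` / `filter` / `build` / `sample` / `consensus` /
`annotate` subcommands lives in `inst/scripts/assembly-sampler.R`.

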