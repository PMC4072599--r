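Package: AssemblySampler
Title: Bayesian Genome Assembly by MCMC Sampling of Assembly Graph Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Samples the posterior distribution over candidate genome
    assemblies instead of reporting a single point estimate. Reads are
    collapsed into a de Bruijn graph that is tip-trimmed and reduced to a
    bubble-only assembly graph; an assembly hypothesis is a boolean vector
    over the graph's edges whose active edges form vertex-disjoint paths. A
    bubble-aware Metropolis sampler explores this combinatorial space under
    a read-generation likelihood and gamma priors on total assembly length
    and contig count. Posterior edge and node frequencies are summarized as
    convergence diagnostics, a majority-rule consensus assembly, and
    posterior annotations of external assemblies. Includes a paired-end
    read simulator for small circular genomes so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
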