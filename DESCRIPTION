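Package: symbiocoal
Title: Recombination and Transmission-Mode Population Genetics for
    Bacterial Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference machinery for linking bacterial
    endosymbiont transmission mode to homologous recombination and genome
    evolution. Provides an exact ancestral-recombination-graph coalescent
    simulator with gene conversion, a forward Wright-Fisher model of
    host-structured symbiont inheritance (vertical bottlenecks plus
    horizontal host switching) with a closed-form expectation for pairwise
    differences, alignment summary statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, folded allele frequency spectra,
    distance-binned four-gamete profiles, Hudson's Fst with bootstrap
    confidence intervals), a random-forest regression approximate Bayesian
    computation estimator of theta and the per-site recombination rate
    rho*l with infinitesimal-jackknife confidence intervals, within-host
    variant calling from read pileups with coverage, indel-proximity and
    binomial sequencing-error filters, a read-backed-phasing four-gamete
    test, and generators for all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    vcfR,
    ranger,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
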