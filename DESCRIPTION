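Package: breedsim
Title: GWAS Power Simulation in Breed-Structured Dog Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates breed-structured dog genomes under a wolf to village
    dog to purebred demography with a fragment-based discrete-generation
    coalescent, ascertains SNP-array-like markers through a two-individual
    discovery panel, simulates liability-threshold case/control disease with
    fixed-effect causal loci, runs linear mixed model association with a
    genotype-derived kinship random effect and Wald tests, and evaluates
    detection power and false discovery rate across within-breed and
    across-breed cohort designs and array densities. Includes Weir-Cockerham
    FST and linkage-disequilibrium decay statistics used to validate the
    simulated populations, genotype quality-control filters with genotypic
    sex inference, and PLINK-format input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
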