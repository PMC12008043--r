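Package: gbspopgen
Title: Urban Population Genomics from Genotyping-by-Sequencing SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for reduced-representation (GBS)
    SNP data sampled along an urbanization gradient: genotype filtering and
    relatedness pruning, urban/rural classification from coordinates, genetic
    diversity statistics (nucleotide diversity, Watterson's theta, windowed
    Tajima's D, F_IS), differentiation (pairwise Hudson F_ST, hierarchical
    AMOVA, PERMANOVA, PERMDISP), spatial genetic structure (PCA, Mantel
    correlograms, Moran eigenvector maps), folded site-frequency-spectrum
    reconstruction of effective-population-size history by composite
    likelihood, and segmented (breakpoint) regression of ln(Ne) against time
    to delimit periods of constant exponential growth or decline. Includes a
    coalescent simulator for piecewise-constant population size and two-deme
    island models so every stage is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vcfR,
    vegan,
    geosphere,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
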