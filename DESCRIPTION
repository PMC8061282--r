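Package: bantamize
Title: Dissecting a Heterogeneous Dwarf Phenotype in Crossbred Chicken Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the genetic basis of the bantam (dwarf) phenotype
    in crossbred chicken populations. Implements a forward simulator of the
    bantamization crossbreeding design (founder breeds under Balding-Nichols
    drift, F1 cross, repeated backcrossing with selection at causal loci),
    variant quality control from VCF, identity-by-state relatedness, principal
    components and neighbor-joining trees, group-stratified linear mixed model
    association scans with Wald tests and genomic-control lambda, fixed-effects
    inverse-variance meta-analysis with Cochran heterogeneity, windowed
    Weir-Cockerham F_ST, relative identity-by-descent (rIBD) introgression
    mapping, lead-variant haplotype phylogenetics, and positional
    variant-to-gene annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR,
    jsonlite,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    metafor,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
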