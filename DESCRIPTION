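Package: dmiscreen
Title: Condition-Specific Genetic Incompatibility Screens in Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-wide screens of environment-dependent genetic
    incompatibility in Saccharomyces cerevisiae crosses. Simulates haploid x
    haploid crosses through meiosis into tetrads under configurable
    Dobzhansky-Muller incompatibility models, computes analytic tetrad
    viable-spore-class distributions and classifies observed segregation
    patterns, scores offspring viability across cross x condition screens with
    parental-viability exclusion, maps causal loci from bulk-segregant pooled
    allele frequencies (low-allele-frequency runs and marker deserts),
    annotates premature stop codons and tRNA anticodon nonsense suppressors,
    and quantifies fitness from microculture growth curves and colony-size
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    minpack.lm,
    car,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
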