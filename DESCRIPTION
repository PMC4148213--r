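Package: silkymap
Title: Mapping a Recessive Mendelian Trait to a Single Cis-Regulatory Variant
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the inference chain used to map a
    fully penetrant recessive Mendelian trait (silky-feather in chicken) to a
    single cis-regulatory SNP: F2 segregation-ratio testing, two-point linkage
    analysis (recombination-fraction maximum likelihood and LOD scores),
    identical-by-descent haplotype-sharing fine mapping with control exclusion
    and heterozygote boundary narrowing, causal-variant exclusion filtering and
    complete-association tabulation, pooled-sequencing fixation scanning, and
    expression statistics (2^-ddCt relative expression, allelic expression
    imbalance, luciferase reporter normalization). A synthetic-data module
    simulates every input the pipeline consumes: an F2 intercross between two
    inbred lines under Haldane recombination, breed panels carrying one shared
    ancestral haplotype eroded at its edges, pooled binomial read counts, and
    replicated expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
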