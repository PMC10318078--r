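Package: rohmap
Title: Runs of Homozygosity Mapping for SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Homozygosity mapping for dense SNP-array genotypes in the
    PLINK text PED/MAP dialect. Implements the classical pipeline used
    in dog and livestock population genetics: sample and marker quality
    control with method-of-moments relatedness (PI_HAT) screening,
    sliding-window detection of runs of homozygosity (ROH) with the
    Lencz/Purfield minimum-SNP rule, ROH length-class and genome-coverage
    summaries, ROH-based inbreeding coefficients (F_ROH), and extraction
    of extreme ROH islands shared across individuals. Ships a synthetic
    genotype simulator that plants autozygous tracts with known ground
    truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
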