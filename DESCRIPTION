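Package: pstrace
Title: Meiotic Crossover Detection from Pedigree SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls meiotic crossover sites from biallelic SNP genotypes of
    nuclear families using parent-sibling tracing (PST), which needs only
    two-generation pedigrees with two or more siblings, and a three-generation
    identity-by-descent (IBD) comparator. Includes a pedigree-genotype
    simulator with known truth crossovers, uninformative-region measurement
    and method comparison, fixed-width (1 Mb) sex-specific recombination maps,
    centromere-distance regressions per chromosome arm, conversion of genetic
    maps (cM) onto the bin grid, and correlation of per-bin crossover counts
    with repeat-element and tandem-repeat annotations. Reads PLINK-style
    PED/MAP text files and BED-like annotation intervals; writes BED6 events
    and TSV summaries. A thin command-line front-end is installed under exec/.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
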