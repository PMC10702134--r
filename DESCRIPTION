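Package: alphapgt
Title: Preimplantation Genetic Testing for SEA-Type Alpha-Thalassemia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comprehensive preimplantation genetic testing (PGT) analysis for
    SEA-type alpha-thalassemia carrier couples. Interprets fluorescent Gap-PCR
    peak data as deletion genotypes, selects informative SNPs in the region
    flanking the HBA1/HBA2 locus, phases parental risk and non-risk haplotypes
    from reference embryos (or from a pair of carrier embryos), calls each
    embryo's inherited haplotypes with recombination detection, screens
    chromosome-level aneuploidy from SNP-array B-allele frequencies and log R
    ratios (including trisomy parental origin and meiosis I/II staging), and
    reconciles discordant PCR and haplotype calls through a decision engine
    covering allele dropout, chromosome 16 trisomy/monosomy and poor
    amplification quality. A full synthetic family/embryo simulator (phased
    carrier parents, meioses with recombination, aneuploidy, whole-genome
    amplification noise) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
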