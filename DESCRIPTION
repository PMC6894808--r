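Package: lohsim
Title: Simulation and Mapping of Engineered Mitotic-Crossover Loss of
    Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromatid-level simulation and analysis of targeted
    loss-of-heterozygosity (LOH) engineering in diploid cells. Models the
    G2 (4N) allele-specific double-strand break, mitotic crossover,
    sister-chromatid segregation, Cre-invertible dual-resistance cassette
    and drug selection that underlie positive-selection LOH induction, and
    provides the matching inference stack: allele-specific CRISPR guide
    design through PAM-disrupting heterozygous SNPs, competitive-PCR
    screening logic, crossover-point mapping by the het/LOH midpoint rule,
    SNP-array B-allele-frequency and log-R-ratio simulation with
    copy-neutral LOH segmentation, and HLA-genotype propagation. All
    stages run on synthetic phased genomes so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
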