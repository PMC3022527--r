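Package: synthassoc
Title: Simulation and Power Analysis of Synthetic Associations from
    Rare-Variant Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study "synthetic associations": apparent association
    signals at common SNPs that are driven by clusters of low-frequency,
    highly penetrant causal variants residing on particular haplotype
    backgrounds. Provides closed-form single-locus genetics (Hardy-Weinberg
    genotype frequencies, penetrance calibration from odds-ratio targets,
    familial relative risks and affected-sib-pair IBD sharing probabilities
    in the Risch-Merikangas framework), an exact haplotype-pool simulator
    that places rare causal alleles on common-SNP backgrounds and samples
    ascertained case-control and affected-sib-pair cohorts, single-SNP
    association scans with and without conditioning on compound rare-variant
    carrier status, and analytic plus Monte-Carlo power comparisons of
    affected-sib-pair linkage versus case-control GWAS. Cohorts are exchanged
    as VCF plus tab-delimited phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
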