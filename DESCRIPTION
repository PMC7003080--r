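Package: pollcall
Title: Diplotype Calling for the Bovine POLLED Locus from Diagnostic SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Translates diagnostic SNP-panel genotypes at the bovine POLLED
    locus (BTA1, ARS-UCD1.2) into Celtic (P_C) and Friesian (P_F) poll
    diplotypes under the legacy 8-SNP rule set and an optimized 5-SNP rule
    set, with explicit No-Result budgets for missing and discordant markers.
    Includes readers for VCF and wide genotype tables, panel comparison and
    call-rate QC summaries, genotype-phenotype concordance tables with
    Fisher's exact comparison of heterozygote poll rates, and a seeded
    multi-breed simulator (Hardy-Weinberg haplotype draws, per-marker call
    rates, a probe-interference artifact, cis-recombination and penetrance)
    for end-to-end testing without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
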