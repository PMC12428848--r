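Package: SRNaseTyper
Title: S-RNase Allele Genotyping and Diversity Analysis for Apricot
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for S-RNase based S-genotyping of apricot (Prunus
    armeniaca) under gametophytic self-incompatibility: in-silico PCR with
    IUPAC-degenerate universal Prunus primers, second-intron annotation by
    the GT/AG rule against a coding reference, conserved-domain (C2, C3,
    RC4, C5) and hypervariable-region (RHV) detection, fragment-length plus
    sequence-based allele calling with novel-allele classification and
    naming, S_C versus S_8 haplotype resolution from SFB fragment sizes,
    allele-frequency and heterozygosity statistics stratified by geographic
    region, cross-(in)compatibility classification and parentage checks,
    and a Poisson-corrected neighbor-joining phylogeny with bootstrap
    supports. Ships a curated reference of 46 alleles and the S-genotypes
    of 168 cultivars, plus a synthetic-data generator that emulates the
    wet-lab steps so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
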