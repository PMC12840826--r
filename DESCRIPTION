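Package: kdrscreen
Title: Gene-Centric Screening of Insecticide-Resistance Variants in the
    Voltage-Gated Sodium Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-centric classification and population-frequency
    analysis of single-nucleotide variants in a voltage-gated sodium channel
    (VGSC) gene, as used for knockdown-resistance (kdr) and sodium-channel
    blocker insecticide (SCBI) resistance monitoring in insect pests such as
    the leafminer Liriomyza trifolii.  Assembles and translates a coding
    sequence from a gene model (FASTA plus exon intervals), classifies SNPs
    as intronic, synonymous or nonsynonymous by codon arithmetic, places
    protein positions on the channel's domain/segment/linker topology,
    converts native residue numbering to canonical (house-fly style)
    numbering to match a catalog of known resistance sites, computes
    per-population change frequencies from paired unchanged/changed counts,
    summarises presence across populations, the count-based dN/dS ratio and
    latitude-frequency rank correlations, and simulates gene models and
    binomially sampled population allele counts with known ground truth.  A
    packaged benchmark fixture of 37 VGSC variants observed in five Hainan
    populations is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
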