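Package: vpepop
Title: Gene-Level SNP Polymorphism and Diversity Analysis for Duplicated
    Vacuolar Processing Enzyme Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gene-level single-nucleotide polymorphism
    surveys in small structured cohorts, built around the three vacuolar
    processing enzyme (VPE) genes of Amborella trichopoda. Reads variants
    (VCF), gene models (GFF3) and a genomic reference (FASTA); applies
    minor-allele-frequency and missingness informativeness filters; annotates
    exonic SNPs as synonymous or non-synonymous with amino-acid polarity and
    catalytic-residue flags; computes per-individual and per-cluster diversity
    statistics (mean MAF, proportion polymorphic, proportion private) on
    intronic and exonic SNP sets independently; tests concordance of
    gene-level diversity with neutral microsatellite allelic richness by exact
    permutation of a Spearman rank statistic; and compares tandem-duplicated
    paralogs at the nucleotide and protein level, including in-silico tryptic
    digestion and peptide-to-proteome matching. A Balding-Nichols cohort
    simulator with exact ground-truth bookkeeping makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
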