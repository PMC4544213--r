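#!/usr/bin/env Rscript

# Sequence evidence across the gene family: pairwise similarity of the
# translated genes (global alignment percent identity at nucleotide and
# protein level) and in-silico tryptic peptide evidence - which peptides
# of each protein are unique and which are shared between paralogs, the
# situation that arises for near-identical tandem duplicates.

suppressPackageStartupMessages(library(vpepop))

inp <- "results/simulated_inputs"
models <- read_gene_models(file.path(inp, "genes.gff3"))
reference <- read_reference(file.path(inp, "reference.fa"))

cds <- vapply(models, function(m) vpepop:::spliced_cds(m, reference), "")
proteins <- vapply(cds, function(s)
  sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(s)))), "")
names(proteins) <- names(models)

nt <- similarity_matrix(cds, level = "nucleotide")
aa <- similarity_matrix(proteins, level = "protein")
sim <- rbind(nt, aa)
write.table(sim, "results/similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Pairwise global-alignment percent identity:\n")
print(transform(sim, percent_similarity = round(percent_similarity, 1)))
cat("\n(The three simulated genes are drawn independently, so these are\nbaseline identities for unrelated sequences of equal length, not the\nnear-identity of a real recent tandem duplication.)\n")

# tryptic digestion with one allowed missed cleavage; peptide-to-proteome
# matching flags paralog-shared peptides
peps <- tryptic_digest(proteins[[1]], max_missed_cleavages = 1L)
hits <- match_peptides(peps, proteins)
write.table(hits, "results/peptide_matches.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\n%s digests into %d peptides (<= 1 missed cleavage);\n%d peptide occurrences match the 3-protein proteome, %d from shared peptides\n",
            names(proteins)[1], length(peps), nrow(hits),
            sum(hits$shared)))
cat("\nWrote results/similarity.tsv and results/peptide_matches.tsv\n")
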