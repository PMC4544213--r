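#!/usr/bin/env Rscript

# Neutrality screen: does each gene's per-cluster diversity co-vary with
# the neutral SSR allelic richness of the same clusters? Quantified as a
# Spearman rank correlation with an exact permutation p-value (all 24
# orderings of the 4 clusters). A gene whose polymorphism gradient tracks
# the neutral background gives no evidence of selection.

suppressPackageStartupMessages(library(vpepop))

inp <- "results/simulated_inputs"
cht <- read_cluster_table(file.path(inp, "clusters.tsv"))
models <- read_gene_models(file.path(inp, "genes.gff3"))
reference <- read_reference(file.path(inp, "reference.fa"))
snps <- read_variants(file.path(inp, "variants.vcf"), cht)
richness <- read_neutral_richness(file.path(inp, "richness.tsv"))
annot <- annotate_snps(snps, models, reference)
sm <- summarize_diversity(snps, annot)

ct <- concordance_table(sm, richness)
write.table(ct, "results/concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Neutral SSR allelic richness per cluster:\n")
print(round(richness, 2))
cat("\nConcordance of prop_polymorphic with richness:\n")
print(transform(ct, rho = round(rho, 3), p_value = round(p_value, 4)))
cat(sprintf("\nNote: with 4 clusters the smallest attainable two-sided\npermutation p is 2/24 = %.3f, so a positive rho with an identical\ncluster ranking is also accepted as concordant.\n", 2 / 24))

# differentiation recovery on the same genotypes
est <- estimate_differentiation(snps)
cat(sprintf("\nWeir-style differentiation estimate: theta = %.3f +/- %.3f (jackknife SE, %d sites); configured Balding-Nichols F = 0.2\n",
            est$theta, est$se, est$n_sites))
cat("\nWrote results/concordance.tsv\n")
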