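# In-code fixtures shared across test files. Everything is generated
# programmatically; no binary data.

# A small hand-laid 3-exon gene on a 120-nt scaffold, fully coding,
# CDS = exons, 30 nt of CDS (10 codons). Exon chunks deliberately break
# codon boundaries so codons span splice junctions.
tiny_gene_fixture <- function(strand = "+") {
  # spliced CDS: ATG + 8 sense codons + TAA (30 nt)
  cds <- "ATGCTTGATCACTGTGGACCTAAAGCTTAA"
  chunks <- c(substr(cds, 1, 11), substr(cds, 12, 21), substr(cds, 22, 30))
  if (strand == "-") chunks_gen <- vapply(rev(chunks), function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  else chunks_gen <- chunks
  intron <- c("GTTTTTTTAG", "GTCCCCCCAG")
  flank5 <- paste(rep("A", 20), collapse = "")
  flank3 <- paste(rep("T", 50), collapse = "")
  body <- paste0(chunks_gen[1], intron[1], chunks_gen[2], intron[2],
                 chunks_gen[3])
  scaffold <- paste0(flank5, body, flank3)
  starts <- c(21,
              21 + nchar(chunks_gen[1]) + 10,
              21 + nchar(chunks_gen[1]) + 10 + nchar(chunks_gen[2]) + 10)
  ends <- starts + nchar(chunks_gen) - 1
  model <- gene_model("tiny", "scaf", strand,
                      exons = data.frame(start = starts, end = ends),
                      catalytic_codons = c(4L, 5L))  # CAC TGT = His Cys
  reference <- Biostrings::DNAStringSet(c(scaf = scaffold))
  list(model = model, reference = reference, cds = cds)
}

# Random SnpSet generator for round-trip and statistic properties.
random_snp_set <- function(n_snp, cht, seed) {
  set.seed(seed)
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, n_snp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), "")
  geno <- matrix(sample(c(0:2, NA), n_snp * length(cht$individuals),
                        replace = TRUE, prob = c(.3, .25, .25, .2)),
                 nrow = n_snp, dimnames = list(NULL, cht$individuals))
  # guarantee one called genotype per site
  for (i in which(rowSums(!is.na(geno)) == 0)) geno[i, 1] <- 1L
  snp_set(data.frame(scaffold_id = "scaf", pos = sort(sample(1e6, n_snp)),
                     ref = ref, alt = unname(alt),
                     gene_id = NA_character_),
          geno, cht)
}

demo_cohort <- function(n = 6) {
  cohort(paste0("ind", seq_len(n)),
         rep(c("A", "B", "C"), length.out = n))
}

# Gotoh global affine-gap aligner (score only), independent of Biostrings;
# oracle for percent_similarity on short strings.
gotoh_score <- function(a, b, match = 1, mismatch = -1,
                        gap_open = 5, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  # opening a gap of length k costs gap_open + k * gap_extend
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           Y[i + 1, j] - gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
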