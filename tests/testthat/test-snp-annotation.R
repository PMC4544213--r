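make_snp <- function(cht, geno_counts) {
  # geno_counts: vector of dosages/NA across cohort, at one site
  snp_set(data.frame(scaffold_id = "scaf", pos = 1L, ref = "A", alt = "G"),
          matrix(as.integer(geno_counts), nrow = 1,
                 dimnames = list(NULL, cht$individuals)), cht)
}

test_that("site MAF counts minor alleles over called genotypes only", {
  cht <- cohort(paste0("i", 1:12), rep("X", 12))
  expect_equal(site_maf(make_snp(cht, rep(0, 12))), 0)          # monomorphic
  expect_equal(site_maf(make_snp(cht, c(1, rep(0, 11)))), 1 / 24)
  g <- c(1, 1, 1, rep(0, 6), NA, NA, NA)                        # 3 alt / 18
  expect_equal(site_maf(make_snp(cht, g)), 3 / 18)
  expect_equal(site_missingness(make_snp(cht, g)), 3 / 12)
  # folded: 20 alt alleles of 24 called gives MAF of the REF allele
  g2 <- c(rep(2, 8), rep(1, 4))
  expect_equal(site_maf(make_snp(cht, g2)), 4 / 24)
  expect_identical(minor_allele(make_snp(cht, g2)), "A")
})

test_that("informativeness thresholds are strict, as printed", {
  expect_false(is_informative(1 / 24, 0))        # 0.0417 <= 0.08
  expect_true(is_informative(2 / 24, 0))         # 0.0833 > 0.08
  expect_true(is_informative(0.2, 5 / 12))       # 0.4167 < 0.42
  expect_false(is_informative(0.2, 6 / 12))      # 0.5 >= 0.42
  expect_false(is_informative(0.08, 0))          # boundary MAF excluded
  expect_false(is_informative(0.2, 0.42))        # boundary missingness
})

test_that("filter agrees with direct inequality evaluation for every
          (minor-count, missing-count) configuration of 12 diploids", {
  for (n_miss in 0:12) {
    called <- 12 - n_miss
    if (called == 0) next
    for (minor in 0:called) {  # minor allele count among 2*called alleles
      maf <- minor / (2 * called)
      if (maf > 0.5) next
      miss <- n_miss / 12
      expect_identical(is_informative(maf, miss),
                       (maf > 0.08) && (miss < 0.42))
    }
  }
  # monotone: raising the MAF threshold never adds informative sites
  set.seed(2)
  maf <- runif(200, 0, 0.5); miss <- runif(200)
  prev <- rep(TRUE, 200)
  for (t in c(0.01, 0.08, 0.2, 0.4)) {
    cur <- is_informative(maf, miss, maf_threshold = t)
    expect_true(all(prev | !cur))  # cur implies prev
    prev <- cur
  }
})

test_that("region classification matches a naive per-base lookup", {
  for (strand in c("+", "-")) {
    fx <- tiny_gene_fixture(strand)
    m <- fx$model
    span <- gene_span(m)
    # independent oracle: paint every base of the scaffold
    L <- Biostrings::width(fx$reference)[[1]]
    paint <- rep("intergenic", L)
    paint[span[1]:span[2]] <- "intronic"
    for (i in seq_len(nrow(m$exons)))
      paint[m$exons$start[i]:m$exons$end[i]] <- "exonic"
    for (pos in 1:L)
      expect_identical(classify_region(pos, m), paint[pos])
  }
})

test_that("boundary bases are classified inclusively", {
  fx <- tiny_gene_fixture("+")
  m <- fx$model
  expect_identical(classify_region(m$exons$start[1], m), "exonic")
  expect_identical(classify_region(m$exons$end[1], m), "exonic")
  expect_identical(classify_region(m$exons$end[1] + 1, m), "intronic")
  expect_identical(classify_region(m$exons$start[1] - 1, m), "intergenic")
})

test_that("known codon changes annotate as the genetic code dictates", {
  fx <- tiny_gene_fixture("+")
  m <- fx$model; ref <- fx$reference
  # codon 2 is CTT (Leu) at CDS 4-6: third position T>C is synonymous
  pos_ctt3 <- m$exons$start[1] + 5  # CDS offset 6, exon 1
  expect_identical(as.character(Biostrings::subseq(ref[[1]], pos_ctt3,
                                                   pos_ctt3)), "T")
  eff <- annotate_effect("scaf", pos_ctt3, "T", "C", m, ref)
  expect_identical(eff$effect, "synonymous")
  expect_identical(c(eff$ref_aa, eff$alt_aa), c("L", "L"))
  expect_false(eff$polarity_change)
  # codon 3 GAT (Asp): A>T at second position gives GTT (Val),
  # nonsynonymous with a polarity change (negative -> nonpolar)
  pos_gat2 <- m$exons$start[1] + 7  # CDS offset 8
  eff2 <- annotate_effect("scaf", pos_gat2, "A", "T", m, ref)
  expect_identical(eff2$effect, "nonsynonymous")
  expect_identical(c(eff2$ref_aa, eff2$alt_aa), c("D", "V"))
  expect_true(eff2$polarity_change)
  # catalytic codons are flagged (His codon 4, CDS 10-12, spans junction)
  pos_cat <- m$exons$start[1] + 9   # CDS offset 10, still exon 1
  eff3 <- annotate_effect("scaf", pos_cat, "C", "A", m, ref)
  expect_true(eff3$catalytic)
  # VCF/FASTA disagreement is a data-integrity error
  expect_error(annotate_effect("scaf", pos_ctt3, "G", "C", m, ref),
               "mismatch")
})

test_that("every CDS substitution matches whole-CDS re-translation, both
          strands", {
  code <- Biostrings::GENETIC_CODE
  for (strand in c("+", "-")) {
    fx <- tiny_gene_fixture(strand)
    m <- fx$model; ref <- fx$reference
    scaf <- fx$reference[[1]]
    cds_len <- nchar(fx$cds)
    ref_protein <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(fx$cds), no.init.codon = TRUE)), "")[[1]]
    mism <- 0L
    for (cds_pos in seq_len(cds_len)) {
      gpos <- vpepop:::cds_to_genomic(cds_pos, m)
      gref <- as.character(Biostrings::subseq(scaf, gpos, gpos))
      for (galt in setdiff(c("A", "C", "G", "T"), gref)) {
        eff <- annotate_effect("scaf", gpos, gref, galt, m, ref)
        # oracle: mutate the spliced CDS, translate it whole, diff proteins
        alt_cds_base <- if (strand == "-")
          chartr("ACGT", "TGCA", galt) else galt
        mut <- fx$cds
        substr(mut, cds_pos, cds_pos) <- alt_cds_base
        alt_protein <- strsplit(as.character(Biostrings::translate(
          Biostrings::DNAString(mut), if.fuzzy.codon = "solve",
          no.init.codon = TRUE)), "")[[1]]
        expected <- if (identical(ref_protein, alt_protein))
          "synonymous" else "nonsynonymous"
        codon_idx <- (cds_pos - 1L) %/% 3L + 1L
        if (!identical(eff$effect, expected)) mism <- mism + 1L
        if (!identical(eff$codon_index, codon_idx)) mism <- mism + 1L
        if (expected == "nonsynonymous" &&
            !identical(eff$alt_aa, alt_protein[codon_idx])) mism <- mism + 1L
      }
    }
    expect_identical(mism, 0L)
  }
})

test_that("effect annotation is strand-symmetric", {
  # mirror the + strand fixture: reverse-complement the scaffold, flip all
  # coordinates and the strand; every site must annotate identically
  fx <- tiny_gene_fixture("+")
  m <- fx$model
  L <- Biostrings::width(fx$reference)[[1]]
  rc_ref <- Biostrings::DNAStringSet(c(
    scaf = as.character(Biostrings::reverseComplement(fx$reference[[1]]))))
  flip <- function(x) L - x + 1
  m_rc <- gene_model(m$gene_id, "scaf", "-",
                     exons = data.frame(start = flip(m$exons$end),
                                        end = flip(m$exons$start)),
                     phase = m$phase,
                     catalytic_codons = m$catalytic_codons)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  set.seed(9)
  cds_positions <- sample(nchar(fx$cds), 12)
  for (cds_pos in cds_positions) {
    gpos <- vpepop:::cds_to_genomic(cds_pos, m)
    gref <- as.character(Biostrings::subseq(fx$reference[[1]], gpos, gpos))
    galt <- sample(setdiff(c("A", "C", "G", "T"), gref), 1)
    fwd <- annotate_effect("scaf", gpos, gref, galt, m, fx$reference)
    rev <- annotate_effect("scaf", flip(gpos), comp(gref), comp(galt),
                           m_rc, rc_ref)
    expect_identical(fwd[c("effect", "ref_aa", "alt_aa", "codon_index",
                           "polarity_change", "catalytic")],
                     rev[c("effect", "ref_aa", "alt_aa", "codon_index",
                           "polarity_change", "catalytic")])
  }
})

test_that("annotation table partitions sites and flags ambiguity", {
  cfg <- sim_config(seed = 21)
  truth <- simulate_cohort(cfg, withr::local_tempdir())
  snps <- read_variants(truth$paths[["vcf"]], truth$cohort)
  models <- read_gene_models(truth$paths[["gff3"]])
  ref <- read_reference(truth$paths[["reference"]])
  annot <- annotate_snps(snps, models, ref)
  # partition: every in-gene SNP is exactly one of exonic/intronic, and
  # synonymous + nonsynonymous = CDS-overlapping exonic SNPs
  in_gene <- !is.na(annot$gene)
  expect_true(all(annot$region[in_gene] %in% c("exonic", "intronic")))
  expect_equal(sum(annot$effect %in% c("synonymous", "nonsynonymous")),
               sum(annot$region == "exonic" & annot$effect != "not_applicable"))
  # writer produces a parseable TSV with the documented columns
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(annot, tsv)
  back <- read.delim(tsv)
  expect_identical(names(back), names(annot))
  expect_equal(nrow(back), nrow(annot))
})
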