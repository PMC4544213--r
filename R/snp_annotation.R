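# Informativeness filtering and effect annotation.
#
# A SNP is informative when its minor allele frequency exceeds the MAF
# threshold (default 0.08) AND its missingness rate is below the missingness
# threshold (default 0.42); both inequalities are strict. Exonic SNPs inside
# a CDS are classified synonymous/non-synonymous by mutating the spliced CDS
# and translating the affected codon under the standard genetic code.

#' Default amino-acid polarity classes
#'
#' Conventional biochemistry grouping used to flag whether a non-synonymous
#' substitution crosses a polarity class. A stop codon is its own class, so
#' any substitution creating or destroying a stop counts as a polarity
#' change.
#'
#' @return Named character vector mapping one-letter amino-acid codes to a
#'   class label.
#' @export
default_polarity_classes <- function() {
  c(G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
    I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
    W = "nonpolar", C = "nonpolar",
    S = "polar", T = "polar", Y = "polar", N = "polar", Q = "polar",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    "*" = "stop")
}

#' Per-site minor allele frequency
#'
#' Count of the less frequent allele divided by twice the number of called
#' individuals; missing genotypes are excluded from both numerator and
#' denominator. At exactly 0.5 the alternate allele is designated minor
#' (deterministic tie-break).
#'
#' @param snps A `SnpSet`.
#' @return Numeric vector in `[0, 0.5]`, one value per site.
#' @export
site_maf <- function(snps) {
  called <- rowSums(!is.na(snps$geno))
  if (any(called == 0L)) stop("site with all genotypes missing",
                              call. = FALSE)
  f_alt <- rowSums(snps$geno, na.rm = TRUE) / (2 * called)
  pmin(f_alt, 1 - f_alt)
}

#' Per-site minor allele
#'
#' @param snps A `SnpSet`.
#' @return Character vector: the cohort-wide minor allele at each site
#'   (`alt` when the alternate allele frequency is <= 0.5, else `ref`).
#' @export
minor_allele <- function(snps) {
  called <- rowSums(!is.na(snps$geno))
  f_alt <- rowSums(snps$geno, na.rm = TRUE) / (2 * called)
  ifelse(f_alt <= 0.5, snps$sites$alt, snps$sites$ref)
}

#' Per-site missingness rate
#'
#' Fraction of cohort individuals with no genotype call.
#'
#' @param snps A `SnpSet`.
#' @return Numeric vector in `[0, 1]`.
#' @export
site_missingness <- function(snps) {
  rowSums(is.na(snps$geno)) / ncol(snps$geno)
}

#' Informativeness filter
#'
#' A site is informative iff MAF is strictly greater than `maf_threshold`
#' and missingness is strictly less than `miss_threshold`.
#'
#' @param maf Numeric vector of minor allele frequencies.
#' @param missingness Numeric vector of missingness rates.
#' @param maf_threshold MAF cut-off, in `(0, 0.5]`; default 0.08.
#' @param miss_threshold Missingness cut-off, in `(0, 1]`; default 0.42.
#' @return Logical vector.
#' @export
is_informative <- function(maf, missingness,
                           maf_threshold = 0.08, miss_threshold = 0.42) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5,
            miss_threshold > 0, miss_threshold <= 1)
  maf > maf_threshold & missingness < miss_threshold
}

#' Assign each site to a gene by genomic span
#'
#' @param snps A `SnpSet`.
#' @param models List of `GeneModel`s.
#' @return The `SnpSet` with `sites$gene_id` filled (NA outside all genes).
#'   Errors if a site without a pre-assigned gene overlaps two gene spans.
#' @export
assign_genes <- function(snps, models) {
  s <- snps$sites
  for (i in seq_len(nrow(s))) {
    if (!is.na(s$gene_id[i])) next
    hits <- character(0)
    for (m in models) {
      if (m$scaffold_id != s$scaffold_id[i]) next
      sp <- gene_span(m)
      ho <- to_halfopen(sp[1L], sp[2L])
      if (pos_in_halfopen(s$pos[i], ho$start, ho$end))
        hits <- c(hits, m$gene_id)
    }
    if (length(hits) > 1L)
      stop("site ", s$scaffold_id[i], ":", s$pos[i],
           " overlaps multiple genes (", paste(hits, collapse = ", "),
           "); pre-assign a gene_id", call. = FALSE)
    if (length(hits) == 1L) s$gene_id[i] <- hits
  }
  snps$sites <- s
  snps
}

#' Region class of one position relative to a gene model
#'
#' Exonic if the position falls inside any exon; intronic if inside the gene
#' span but in no exon (splice-junction bases are intronic); intergenic
#' otherwise.
#'
#' @param pos 1-based genomic position.
#' @param model A `GeneModel` on the same scaffold.
#' @return `"exonic"`, `"intronic"` or `"intergenic"`.
#' @export
classify_region <- function(pos, model) {
  ex <- to_halfopen(model$exons$start, model$exons$end)
  if (any(pos_in_halfopen(pos, ex$start, ex$end))) return("exonic")
  sp <- gene_span(model)
  ho <- to_halfopen(sp[1L], sp[2L])
  if (pos_in_halfopen(pos, ho$start, ho$end)) return("intronic")
  "intergenic"
}

# ---------------------------------------------------------------------------
# Spliced CDS arithmetic

# Standard-genetic-code translation of an in-frame CDS given as a character
# scalar; plain table lookup, no object construction per call.
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# Concatenated CDS sequence in transcription order (reverse-complemented for
# minus-strand genes), as a character scalar.
spliced_cds <- function(model, reference) {
  scaf <- reference[[model$scaffold_id]]
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    as.character(Biostrings::subseq(scaf, model$cds$start[i],
                                    model$cds$end[i]))
  }, "")
  plus <- paste(pieces, collapse = "")
  if (model$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus)))
  else plus
}

# Map a 1-based genomic position to a 1-based offset in the spliced CDS
# (transcription order); NA if the position is not in any CDS interval.
genomic_to_cds <- function(pos, model) {
  cds <- model$cds
  ho <- to_halfopen(cds$start, cds$end)
  lens <- ho$end - ho$start
  hit <- which(pos_in_halfopen(pos, ho$start, ho$end))
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
  plus_off <- before + ((pos - 1L) - ho$start[hit]) + 1L
  if (model$strand == "+") as.integer(plus_off)
  else as.integer(sum(lens) - plus_off + 1L)
}

#' Annotate the coding effect of one SNP
#'
#' Splices the CDS, locates the variant's codon (strand- and phase-aware),
#' substitutes the alternate base and translates both codons under the
#' standard genetic code.
#'
#' @param scaffold_id,pos,ref,alt The variant (1-based, plus-strand alleles,
#'   as in a VCF).
#' @param model The `GeneModel` containing the site.
#' @param reference `DNAStringSet` with the scaffold sequence.
#' @param polarity Named amino-acid class map; see
#'   [default_polarity_classes()].
#' @param cds_seq Optional pre-spliced CDS sequence of the gene (as returned
#'   internally for the model); recomputed when `NULL`.
#' @return A list: `effect` (`"synonymous"`, `"nonsynonymous"` or
#'   `"not_applicable"` for exonic-but-non-coding positions), `ref_aa`,
#'   `alt_aa`, `codon_index` (1-based in the CDS), `polarity_change`,
#'   `catalytic`, `stop_involved`.
#' @export
annotate_effect <- function(scaffold_id, pos, ref, alt, model, reference,
                            polarity = default_polarity_classes(),
                            cds_seq = NULL) {
  if (model$scaffold_id != scaffold_id)
    stop("site and model on different scaffolds", call. = FALSE)
  scaf <- reference[[scaffold_id]]
  fasta_ref <- as.character(Biostrings::subseq(scaf, pos, pos))
  if (fasta_ref != ref)
    stop("reference mismatch at ", scaffold_id, ":", pos, " (VCF ref ", ref,
         ", FASTA ", fasta_ref, ")", call. = FALSE)
  na <- list(effect = "not_applicable", ref_aa = "", alt_aa = "",
             codon_index = NA_integer_, polarity_change = FALSE,
             catalytic = FALSE, stop_involved = FALSE)
  cds_pos <- genomic_to_cds(pos, model)
  if (is.na(cds_pos)) return(na)
  coding_pos <- cds_pos - model$phase
  if (coding_pos < 1L) return(na)
  if (is.null(cds_seq)) cds_seq <- spliced_cds(model, reference)
  codon_idx <- (coding_pos - 1L) %/% 3L + 1L
  codon_start <- model$phase + (codon_idx - 1L) * 3L + 1L
  if (codon_start + 2L > nchar(cds_seq)) return(na)  # trailing partial codon
  ref_codon <- substr(cds_seq, codon_start, codon_start + 2L)
  alt_base <- if (model$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  else alt
  within <- cds_pos - (codon_start - 1L) # 1..3 offset of site inside codon
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  stop_involved <- (ref_aa == "*") != (alt_aa == "*")
  list(effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
       ref_aa = ref_aa, alt_aa = alt_aa, codon_index = codon_idx,
       polarity_change = polarity[[ref_aa]] != polarity[[alt_aa]],
       catalytic = codon_idx %in% model$catalytic_codons,
       stop_involved = stop_involved)
}

#' Annotate a full SNP set
#'
#' Runs gene assignment, region classification, MAF/missingness computation,
#' the informativeness filter and coding-effect annotation over every site.
#'
#' @param snps A `SnpSet`.
#' @param models List of `GeneModel`s.
#' @param reference `DNAStringSet` covering all scaffolds.
#' @param maf_threshold,miss_threshold Filter cut-offs; see
#'   [is_informative()].
#' @param polarity Amino-acid polarity class map.
#' @return `data.frame` of class `snp_annotation` with one row per site:
#'   gene, scaffold, pos, ref, alt, region, maf, missingness, informative,
#'   effect, ref_aa, alt_aa, polarity_change, catalytic.
#' @export
annotate_snps <- function(snps, models, reference,
                          maf_threshold = 0.08, miss_threshold = 0.42,
                          polarity = default_polarity_classes()) {
  check_reference_coverage(reference, models, snps)
  snps <- assign_genes(snps, models)
  s <- snps$sites
  n <- nrow(s)
  region <- character(n)
  eff <- vector("list", n)
  cds_cache <- lapply(models, function(m)
    if (nrow(m$cds) > 0L) spliced_cds(m, reference) else NULL)
  for (i in seq_len(n)) {
    if (is.na(s$gene_id[i])) {
      region[i] <- "intergenic"
      eff[[i]] <- list(effect = "not_applicable", ref_aa = "", alt_aa = "",
                       polarity_change = FALSE, catalytic = FALSE)
      next
    }
    m <- models[[s$gene_id[i]]]
    region[i] <- classify_region(s$pos[i], m)
    eff[[i]] <- if (region[i] == "exonic")
      annotate_effect(s$scaffold_id[i], s$pos[i], s$ref[i], s$alt[i],
                      m, reference, polarity,
                      cds_seq = cds_cache[[s$gene_id[i]]])
    else list(effect = "not_applicable", ref_aa = "", alt_aa = "",
              polarity_change = FALSE, catalytic = FALSE)
  }
  maf <- site_maf(snps)
  miss <- site_missingness(snps)
  out <- data.frame(
    gene = s$gene_id, scaffold = s$scaffold_id, pos = s$pos,
    ref = s$ref, alt = s$alt, region = region,
    maf = maf, missingness = miss,
    informative = is_informative(maf, miss, maf_threshold, miss_threshold),
    effect = vapply(eff, `[[`, "", "effect"),
    ref_aa = vapply(eff, `[[`, "", "ref_aa"),
    alt_aa = vapply(eff, `[[`, "", "alt_aa"),
    polarity_change = vapply(eff, `[[`, TRUE, "polarity_change"),
    catalytic = vapply(eff, `[[`, TRUE, "catalytic"),
    stringsAsFactors = FALSE)
  class(out) <- c("snp_annotation", "data.frame")
  out
}

#' Write an annotated-SNP table as TSV
#'
#' @param annot Output of [annotate_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pass-through VCF carrying annotations as INFO tags
#'
#' @param snps The `SnpSet` the annotations were computed from.
#' @param annot Output of [annotate_snps()] (same site order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(snps, annot, path) {
  stopifnot(nrow(annot) == n_sites(snps))
  s <- snps$sites
  gt_char <- c("0/0", "0/1", "1/1")
  gmat <- matrix(gt_char[snps$geno + 1L], nrow = nrow(s))
  gmat[is.na(snps$geno)] <- "./."
  info <- sprintf("GENE=%s;REGION=%s;MAF=%.4g;FMISS=%.4g;INFORMATIVE=%d;EFFECT=%s",
                  ifelse(is.na(annot$gene), ".", annot$gene), annot$region,
                  annot$maf, annot$missingness, as.integer(annot$informative),
                  ifelse(annot$effect == "not_applicable", ".", annot$effect))
  body <- cbind(s$scaffold_id, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
                "GT", gmat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=vpepop",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Assigned gene">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="exonic/intronic/intergenic">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
    '##INFO=<ID=FMISS,Number=1,Type=Float,Description="Missingness rate">',
    '##INFO=<ID=INFORMATIVE,Number=1,Type=Integer,Description="Passed filters">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Coding effect">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snps$cohort$individuals), collapse = "\t")), con)
  if (nrow(s) > 0L)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
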