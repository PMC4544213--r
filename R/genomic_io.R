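# Readers and validated in-memory containers for the formats the pipeline
# touches: GFF3 gene models, VCF genotypes, FASTA reference, and the two
# cohort tables (individual -> cluster, cluster -> SSR allelic richness).

# ---------------------------------------------------------------------------
# GeneModel

#' Construct a gene model
#'
#' A `GeneModel` holds the strand-aware exon/CDS structure of one gene on one
#' scaffold, in 1-based inclusive genomic coordinates, together with the
#' CDS codon indices of catalytic residues (for VPEs, the His/Cys dyad).
#'
#' @param gene_id Gene identifier.
#' @param scaffold_id Scaffold/sequence identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (1-based inclusive),
#'   sorted by genomic start, non-overlapping.
#' @param cds `data.frame` with columns `start`, `end`; every CDS interval
#'   must be contained in an exon. Defaults to `exons` (fully coding gene).
#' @param phase Starting phase of the first CDS segment in transcription
#'   order: number of bases to skip before the first complete codon (0, 1 or
#'   2), as in the GFF3 phase column.
#' @param catalytic_codons Integer vector of 1-based CDS codon indices
#'   encoding catalytic residues. Supplied by configuration, not inferred.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, cds = exons,
                       phase = 0L, catalytic_codons = integer(0)) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            is.data.frame(cds), phase %in% 0:2)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  model <- structure(
    list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         exons = exons, cds = NULL, phase = as.integer(phase),
         catalytic_codons = as.integer(catalytic_codons),
         translatable = TRUE),
    class = "GeneModel")
  if (nrow(cds) > 0L) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    rownames(cds) <- NULL
  }
  model$cds <- cds
  validate_gene_model(model)
}

validate_gene_model <- function(model) {
  ex <- model$exons
  if (nrow(ex) == 0L)
    stop("gene model '", model$gene_id, "': no exons", call. = FALSE)
  if (any(ex$end < ex$start))
    stop("gene model '", model$gene_id, "': exon end < start", call. = FALSE)
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop("gene model '", model$gene_id, "': overlapping exons", call. = FALSE)
  cds <- model$cds
  if (nrow(cds) > 0L) {
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
    }, logical(1))
    if (!all(contained))
      stop("gene model '", model$gene_id,
           "': CDS interval not contained in any exon", call. = FALSE)
    len <- sum(cds$end - cds$start + 1L) - model$phase
    if (len %% 3L != 0L) {
      warning("gene model '", model$gene_id,
              "': CDS length not a multiple of 3; flagged non-translatable",
              call. = FALSE)
      model$translatable <- FALSE
    }
  }
  model
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d exons, %d introns, CDS %d nt%s\n",
              x$gene_id, x$scaffold_id, x$strand, nrow(x$exons),
              max(nrow(x$exons) - 1L, 0L),
              sum(x$cds$end - x$cds$start + 1L),
              if (x$translatable) "" else " [non-translatable]"))
  invisible(x)
}

#' Intron intervals of a gene model
#'
#' Introns are the gaps between consecutive exons; a 9-exon model has exactly
#' 8 introns.
#'
#' @param model A `GeneModel`.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   zero rows for a single-exon gene.
#' @export
introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' Genomic span of a gene model
#' @param model A `GeneModel`.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Read gene models from a GFF3 file
#'
#' Expects the usual gene/mRNA/exon/CDS hierarchy. One model is built per
#' gene (first mRNA if several). Catalytic codon indices are supplied
#' externally because they are identified by homology, not by the file.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param catalytic Named list mapping gene id to an integer vector of
#'   catalytic CDS codon indices.
#' @return Named list of `GeneModel` objects.
#' @export
read_gene_models <- function(gff3_path, catalytic = list()) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", gff3_path, call. = FALSE)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  parent_of <- function(rows) vapply(rows$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  df_parent <- parent_of(df)
  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx <- mrna[parent_of(mrna) == gid, , drop = FALSE]
    owner <- if (nrow(tx) > 0L) tx$ID[1L] else gid
    kids <- df[df$type %in% c("exon", "CDS") & !is.na(df_parent) &
                 df_parent == owner, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cd  # exonless annotations: CDS implies exon
    strand <- as.character(genes$strand[i])
    cd <- cd[order(cd$start), , drop = FALSE]
    phase <- 0L
    if (nrow(cd) > 0L && "phase" %in% names(cd)) {
      first <- if (strand == "+") 1L else nrow(cd)  # transcription order
      ph <- suppressWarnings(as.integer(as.character(cd$phase[first])))
      if (!is.na(ph)) phase <- ph
    }
    gene_model(
      gene_id = gid, scaffold_id = as.character(genes$seqnames[i]),
      strand = strand,
      exons = data.frame(start = ex$start, end = ex$end),
      cds = data.frame(start = cd$start, end = cd$end),
      phase = phase,
      catalytic_codons = if (gid %in% names(catalytic))
        catalytic[[gid]] else integer(0))
  })
  names(models) <- genes$ID
  models
}

#' Write gene models to a GFF3 file
#'
#' @param models List of `GeneModel` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    span <- gene_span(m)
    n_cds <- nrow(m$cds)
    # GFF3 phase per CDS segment, accumulated in transcription order
    ph <- integer(n_cds)
    if (n_cds > 0L) {
      ord <- if (m$strand == "+") seq_len(n_cds) else rev(seq_len(n_cds))
      carry <- m$phase
      for (j in ord) {
        ph[j] <- carry
        seg_len <- m$cds$end[j] - m$cds$start[j] + 1L
        carry <- (3L - (seg_len - carry) %% 3L) %% 3L
      }
    }
    data.frame(
      seqid = m$scaffold_id,
      source = "vpepop",
      type = c("gene", "mRNA", rep("exon", nrow(m$exons)), rep("CDS", n_cds)),
      start = c(span[1L], span[1L], m$exons$start, m$cds$start),
      end = c(span[2L], span[2L], m$exons$end, m$cds$end),
      score = ".",
      strand = m$strand,
      phase = c(".", ".", rep(".", nrow(m$exons)), as.character(ph)),
      attributes = c(
        paste0("ID=", m$gene_id),
        paste0("ID=", m$gene_id, ".t1;Parent=", m$gene_id),
        rep(paste0("Parent=", m$gene_id, ".t1"), nrow(m$exons) + n_cds)),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort

#' Construct a cohort
#'
#' @param individuals Character vector of individual ids, in display order.
#' @param clusters Character vector, same length: cluster label per
#'   individual.
#' @return An object of class `Cohort`.
#' @export
cohort <- function(individuals, clusters) {
  stopifnot(length(individuals) == length(clusters),
            !anyDuplicated(individuals), all(nzchar(clusters)))
  cluster_of <- stats::setNames(as.character(clusters),
                                as.character(individuals))
  structure(list(individuals = as.character(individuals),
                 cluster_of = cluster_of,
                 clusters = unique(as.character(clusters))),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals in %d clusters (%s)\n",
              length(x$individuals), length(x$clusters),
              paste(sprintf("%s=%d", x$clusters,
                            tabulate(factor(x$cluster_of, x$clusters))),
                    collapse = ", ")))
  invisible(x)
}

#' Members of one cluster
#' @param cht A `Cohort`.
#' @param cluster Cluster label.
#' @return Character vector of individual ids.
#' @export
cluster_members <- function(cht, cluster) {
  cht$individuals[cht$cluster_of[cht$individuals] == cluster]
}

#' Read an individual-to-cluster assignment table
#'
#' @param tsv_path Two-column TSV: individual, cluster (with or without a
#'   header line `individual<TAB>cluster`).
#' @return A `Cohort`.
#' @export
read_cluster_table <- function(tsv_path) {
  if (!file.exists(tsv_path))
    stop("cluster table not found: ", tsv_path, call. = FALSE)
  tab <- utils::read.delim(tsv_path, header = FALSE,
                           colClasses = "character")
  if (nrow(tab) > 0L && identical(tolower(tab[1L, 1L]), "individual"))
    tab <- tab[-1L, , drop = FALSE]
  if (ncol(tab) < 2L) stop("cluster table needs two columns", call. = FALSE)
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate individual rows in cluster table", call. = FALSE)
  cohort(tab[[1L]], tab[[2L]])
}

#' Write an individual-to-cluster assignment table
#' @param cht A `Cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cht, path) {
  utils::write.table(
    data.frame(individual = cht$individuals,
               cluster = unname(cht$cluster_of[cht$individuals])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a neutral-marker (SSR) allelic richness table
#'
#' @param tsv_path Two-column TSV: cluster, allelic richness (optional
#'   header).
#' @return Named numeric vector, one value per cluster.
#' @export
read_neutral_richness <- function(tsv_path) {
  if (!file.exists(tsv_path))
    stop("richness table not found: ", tsv_path, call. = FALSE)
  tab <- utils::read.delim(tsv_path, header = FALSE,
                           colClasses = "character")
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate cluster rows in richness table", call. = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

#' Write a neutral-richness table
#' @param richness Named numeric vector (cluster -> allelic richness).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neutral_richness <- function(richness, path) {
  utils::write.table(
    data.frame(cluster = names(richness), allelic_richness = richness),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reference

#' Read a genomic reference FASTA
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by scaffold id (first word of
#'   each header).
#' @export
read_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Check that a reference covers all scaffolds used by models and variants
#'
#' @param reference `DNAStringSet` from [read_reference()].
#' @param models Optional list of `GeneModel`s.
#' @param snps Optional `SnpSet`.
#' @return `TRUE`, invisibly; errors on a missing scaffold.
#' @export
check_reference_coverage <- function(reference, models = NULL, snps = NULL) {
  need <- character(0)
  if (!is.null(models))
    need <- c(need, vapply(models, `[[`, "", "scaffold_id"))
  if (!is.null(snps)) need <- c(need, snps$sites$scaffold_id)
  missing <- setdiff(unique(need), names(reference))
  if (length(missing))
    stop("scaffold(s) absent from reference FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# SnpSet

#' Construct a set of biallelic SNP sites with diploid genotypes
#'
#' Genotypes are stored as the count of the alternate allele (0, 1, 2) with
#' `NA` for a missing call; phase is never recorded. This is the container
#' every downstream statistic consumes.
#'
#' @param sites `data.frame` with columns `scaffold_id`, `pos` (1-based),
#'   `ref`, `alt` (single nucleotides), and optionally `gene_id`.
#' @param geno Integer matrix, sites x individuals, entries in `0:2` or `NA`;
#'   column names are individual ids.
#' @param cht A `Cohort`; columns of `geno` must cover its individuals.
#' @return An object of class `SnpSet`.
#' @export
snp_set <- function(sites, geno, cht) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold_id", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites))
  if (!all(cht$individuals %in% colnames(geno)))
    stop("genotype matrix lacks individuals: ",
         paste(setdiff(cht$individuals, colnames(geno)), collapse = ", "),
         call. = FALSE)
  geno <- geno[, cht$individuals, drop = FALSE]
  mode(geno) <- "integer"
  bad_allele <- !(sites$ref %in% c("A", "C", "G", "T")) |
    !(sites$alt %in% c("A", "C", "G", "T")) | sites$ref == sites$alt
  if (any(bad_allele))
    stop("invalid ref/alt alleles at row(s) ",
         paste(which(bad_allele), collapse = ", "), call. = FALSE)
  if (any(!is.na(geno) & (geno < 0L | geno > 2L)))
    stop("genotype dosages must be 0, 1 or 2", call. = FALSE)
  if (nrow(geno) > 0L && any(rowSums(!is.na(geno)) == 0L))
    stop("site(s) with no called genotype: row(s) ",
         paste(which(rowSums(!is.na(geno)) == 0L), collapse = ", "),
         call. = FALSE)
  if (!"gene_id" %in% names(sites)) sites$gene_id <- NA_character_
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, cohort = cht), class = "SnpSet")
}

#' @export
print.SnpSet <- function(x, ...) {
  cat(sprintf("SnpSet: %d biallelic SNVs x %d individuals\n",
              nrow(x$sites), ncol(x$geno)))
  invisible(x)
}

#' Number of sites in a SnpSet
#' @param snps A `SnpSet`.
#' @return Integer count.
#' @export
n_sites <- function(snps) nrow(snps$sites)

parse_gt <- function(gt) {
  # "0/1", "1|0", "./." (phase ignored); NA for missing
  a <- sub("^([^/|]+)[/|].*$", "\\1", gt)
  b <- sub("^[^/|]+[/|](.+)$", "\\1", gt)
  out <- rep(NA_integer_, length(gt))
  miss <- is.na(gt) | a == "." | b == "."
  ok <- !miss & a %in% c("0", "1") & b %in% c("0", "1")
  out[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  bad <- !miss & !ok
  if (any(bad))
    stop("malformed GT field at VCF data line(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(gt[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Read biallelic SNVs from a VCF file
#'
#' Keeps biallelic single-nucleotide variants only; indels and multiallelic
#' sites are dropped and counted (attribute `n_dropped`). Samples are
#' reconciled with the cohort by id, never by column order; missing calls
#' (`./.`) are preserved as `NA`. Phase separators are accepted and ignored.
#'
#' @param vcf_path Path to a VCF 4.x file with GT genotypes.
#' @param cht A `Cohort`; every individual must be a sample in the VCF.
#' @return A `SnpSet` with attribute `n_dropped` (non-SNV records removed).
#' @export
read_variants <- function(vcf_path, cht) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  nuc <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% nuc & fix[, "ALT"] %in% nuc
  n_dropped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  missing_ind <- setdiff(cht$individuals, colnames(gt))
  if (length(missing_ind))
    stop("cohort individual(s) absent from VCF: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  gt <- gt[keep, cht$individuals, drop = FALSE]
  geno <- apply(gt, 2L, parse_gt)
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = sum(keep),
                                       dimnames = list(NULL, cht$individuals))
  sites <- data.frame(scaffold_id = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  out <- snp_set(sites, geno, cht)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a SnpSet as a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes, suitable for round-trip
#' with [read_variants()].
#'
#' @param snps A `SnpSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(snps, path) {
  s <- snps$sites
  gt_char <- c("0/0", "0/1", "1/1")
  gmat <- matrix(gt_char[snps$geno + 1L], nrow = nrow(s))
  gmat[is.na(snps$geno)] <- "./."
  body <- cbind(s$scaffold_id, s$pos, ".", s$ref, s$alt, ".", "PASS", ".",
                "GT", gmat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=vpepop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snps$cohort$individuals), collapse = "\t")), con)
  if (nrow(s) > 0L)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
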