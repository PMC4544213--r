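# Synthetic cohort generator with exact ground-truth bookkeeping.
#
# Emulates the study design the analysis assumes: three 9-exon/8-intron
# genes (two in tandem on one scaffold, one of them on the minus strand),
# 12 diploid individuals in 4 clusters of sizes 4/5/2/1, cluster allele
# frequencies drawn from a Balding-Nichols Beta distribution around a
# uniform ancestral frequency, independent per-genotype missingness, and
# planted synonymous / non-synonymous / intronic variants whose effect class
# is verified by whole-CDS re-translation at generation time. Neutral SSR
# allelic richness is generated to rank-match the clusters' true expected
# polymorphism, so the neutrality-concordance verdict has a known answer.
#
# One RNG stream, seeded from the config; draw order is fixed
# (gene structures -> site placement -> per site: ancestral frequency,
# cluster frequencies, genotypes, missingness mask) so equal seeds give
# byte-identical output files.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], c())

#' Simulation configuration
#'
#' @param n_genes Number of genes (default 3).
#' @param exons_per_gene Exons per gene (default 9, hence 8 introns).
#' @param cds_length Coding length per gene in nt, multiple of 3 (default
#'   810; exon chunk boundaries need not respect codon boundaries, so codons
#'   span splice junctions).
#' @param intron_length Intron length in nt (default 70).
#' @param cluster_sizes Named integer vector of cluster sizes (default
#'   North=4, Center=5, Me=2, Nak=1: a 12-individual cohort).
#' @param individuals Individual ids, in cluster-block order; defaults to
#'   the 12 locality-named trees of the resequencing panel.
#' @param fst Balding-Nichols differentiation coefficient, strictly inside
#'   (0, 1) (default 0.2). May be a vector with one value per cluster
#'   (recycled): a cluster's F controls how far its allele frequencies
#'   drift from the ancestral pool, so per-cluster F doubles as the
#'   per-cluster diversity dial (higher F, more fixation, lower expected
#'   polymorphism).
#' @param missing_rate Independent per-genotype missingness probability
#'   (default 0.1).
#' @param n_syn,n_nonsyn Planted synonymous / non-synonymous exonic SNP
#'   counts across all genes (defaults 7 and 5, assigned round-robin).
#' @param n_intronic Planted intronic SNP count across all genes (default
#'   84, split evenly).
#' @param ancestral_range Range of the uniform ancestral allele frequency
#'   (default `c(0.1, 0.9)`, keeping sites plantable above the MAF filter).
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3L, exons_per_gene = 9L, cds_length = 810L,
                       intron_length = 70L,
                       cluster_sizes = c(North = 4L, Center = 5L,
                                         Me = 2L, Nak = 1L),
                       individuals = NULL,
                       fst = 0.2, missing_rate = 0.1,
                       n_syn = 7L, n_nonsyn = 5L, n_intronic = 84L,
                       ancestral_range = c(0.1, 0.9), seed = 1L) {
  stopifnot(all(fst > 0), all(fst < 1), cds_length %% 3L == 0L,
            length(fst) == 1L || length(fst) == length(cluster_sizes),
            missing_rate >= 0, missing_rate < 1,
            !is.null(names(cluster_sizes)))
  fst <- rep_len(fst, length(cluster_sizes))
  names(fst) <- names(cluster_sizes)
  n_ind <- sum(cluster_sizes)
  if (is.null(individuals)) {
    individuals <- if (identical(unname(cluster_sizes),
                                 c(4L, 5L, 2L, 1L)) && n_ind == 12L)
      c("Tonine", "Ponandou", "Pwicate", "Tchamba",
        "Ba", "Aoupinie", "Boregaou", "Amieu", "Dogny",
        "Me_Ori", "Me_Fomechawa", "Nakada")
    else paste0("ind_", seq_len(n_ind))
  }
  stopifnot(length(individuals) == n_ind)
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 cds_length = as.integer(cds_length),
                 intron_length = as.integer(intron_length),
                 cluster_sizes = cluster_sizes,
                 individuals = individuals,
                 fst = fst, missing_rate = missing_rate,
                 n_syn = as.integer(n_syn), n_nonsyn = as.integer(n_nonsyn),
                 n_intronic = as.integer(n_intronic),
                 ancestral_range = ancestral_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Random sense-codon CDS: ATG start, internal sense codons, TAA stop, with
# the catalytic codon indices forced to His (CAC) and Cys (TGC).
random_cds <- function(n_codons, catalytic_codons) {
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  if (length(catalytic_codons) >= 1L) codons[catalytic_codons[1L]] <- "CAC"
  if (length(catalytic_codons) >= 2L) codons[catalytic_codons[2L]] <- "TGC"
  paste(codons, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Inverse of genomic_to_cds(): 1-based spliced-CDS offset -> genomic pos.
cds_to_genomic <- function(cds_pos, model) {
  ho <- to_halfopen(model$cds$start, model$cds$end)
  lens <- ho$end - ho$start
  total <- sum(lens)
  plus_off <- if (model$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(lens)
  seg <- which(plus_off <= cum)[1L]
  before <- if (seg > 1L) cum[seg - 1L] else 0L
  as.integer(ho$start[seg] + (plus_off - before - 1L) + 1L)
}

# Build one gene: exon/intron layout starting at genomic `offset` (1-based),
# CDS sequence, and the genomic sequence of the gene body.
build_gene <- function(gene_id, scaffold_id, strand, offset, cfg) {
  n_codons <- cfg$cds_length %/% 3L
  # His/Cys dyad placed in the middle third of the protein
  cat_codons <- sort(c(max(2L, round(n_codons * 0.45)),
                       max(3L, round(n_codons * 0.55))))
  cds_seq <- random_cds(n_codons, cat_codons)
  # split the CDS into exon chunks, as equal as possible
  n_ex <- cfg$exons_per_gene
  base_len <- cfg$cds_length %/% n_ex
  chunk_len <- rep(base_len, n_ex)
  extra <- cfg$cds_length - base_len * n_ex
  if (extra > 0L) chunk_len[seq_len(extra)] <- chunk_len[seq_len(extra)] + 1L
  starts <- ends <- integer(n_ex)
  pos <- offset
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + chunk_len[i] - 1L
    pos <- ends[i] + 1L + if (i < n_ex) cfg$intron_length else 0L
  }
  # chunks in transcription order; genomic exon i carries chunk k (+) or
  # revcomp(chunk k) (-), where k counts exons in transcription order
  cum <- cumsum(chunk_len)
  tx_chunks <- substring(cds_seq, c(1L, cum[-n_ex] + 1L), cum)
  exon_seq <- character(n_ex)
  for (i in seq_len(n_ex)) {
    k <- if (strand == "+") i else n_ex - i + 1L
    exon_seq[i] <- if (strand == "+") tx_chunks[k] else revcomp_chr(tx_chunks[k])
  }
  intron_seq <- vapply(seq_len(n_ex - 1L),
                       function(i) random_dna(cfg$intron_length), "")
  body <- character(0)
  for (i in seq_len(n_ex)) {
    body <- c(body, exon_seq[i])
    if (i < n_ex) body <- c(body, intron_seq[i])
  }
  model <- gene_model(gene_id, scaffold_id, strand,
                      exons = data.frame(start = starts, end = ends),
                      phase = 0L, catalytic_codons = cat_codons)
  list(model = model, cds_seq = cds_seq,
       body = paste(body, collapse = ""),
       span = c(offset, ends[n_ex]))
}

# Choose a plantable substitution of the requested class in the spliced CDS.
# Verified by whole-CDS re-translation; returns cds_pos and alt base (CDS
# orientation) or NULL after max_tries failures.
plant_substitution <- function(cds_seq, effect, catalytic_codons,
                               max_tries = 500L) {
  n_codons <- nchar(cds_seq) %/% 3L
  code <- Biostrings::GENETIC_CODE
  ref_protein <- translate_cds(cds_seq)
  for (try in seq_len(max_tries)) {
    codon_idx <- sample(2:(n_codons - 1L), 1L)     # keep start/stop intact
    if (codon_idx %in% catalytic_codons) next      # mirror the real genes
    within <- sample(1:3, 1L)
    cds_pos <- (codon_idx - 1L) * 3L + within
    ref_base <- substr(cds_seq, cds_pos, cds_pos)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
    mutated <- cds_seq
    substr(mutated, cds_pos, cds_pos) <- alt_base
    ref_codon <- substr(cds_seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    alt_codon <- substr(mutated, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    if (code[alt_codon] == "*") next               # keep the ORF intact
    is_syn <- code[ref_codon] == code[alt_codon]
    if ((effect == "synonymous") != is_syn) next
    # generation-time oracle: re-translate the whole mutated CDS
    alt_protein <- translate_cds(mutated)
    if (is_syn && !identical(alt_protein, ref_protein)) next
    if (!is_syn && identical(alt_protein, ref_protein)) next
    return(list(cds_pos = cds_pos, alt_base = alt_base,
                codon_index = codon_idx))
  }
  NULL
}

#' Simulate a cohort with ground truth
#'
#' Writes the five input files the pipeline reads (reference FASTA, GFF3
#' gene models, VCF genotypes, cluster TSV, neutral-richness TSV) plus a
#' truth JSON, and returns the truth bookkeeping in memory.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List of class `cohort_truth`: `config`, `paths` (named file
#'   paths), `cohort` (a `Cohort`), `models`, `sites` (data.frame with gene,
#'   scaffold, pos, ref, alt, region, planted_effect, codon_index, p_anc),
#'   `cluster_freq` (sites x clusters true allele frequencies), `geno`
#'   (sites x individuals alt dosage, NA = missing), `richness`,
#'   `expected_diversity` (per-cluster expected polymorphic proportion),
#'   `proteins` (translated CDS per gene).
#' @export
simulate_cohort <- function(cfg, dir = tempfile("simcohort")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  # --- gene structures and scaffolds -------------------------------------
  scaffold_of <- ifelse(seq_len(cfg$n_genes) <= 2L, "scaffold_1",
                        paste0("scaffold_", seq_len(cfg$n_genes) - 1L))
  strand_of <- rep(c("+", "-"), length.out = cfg$n_genes)
  gene_ids <- paste0("gene_", seq_len(cfg$n_genes))
  flank <- 200L
  models <- list(); cds_of <- character(cfg$n_genes)
  scaffold_parts <- list()
  next_offset <- stats::setNames(rep(flank + 1L,
                                     length(unique(scaffold_of))),
                                 unique(scaffold_of))
  scaffold_seq <- stats::setNames(rep("", length(unique(scaffold_of))),
                                  unique(scaffold_of))
  for (g in seq_len(cfg$n_genes)) {
    sc <- scaffold_of[g]
    if (nchar(scaffold_seq[sc]) == 0L)
      scaffold_seq[sc] <- random_dna(flank)
    built <- build_gene(gene_ids[g], sc, strand_of[g], next_offset[sc], cfg)
    models[[gene_ids[g]]] <- built$model
    cds_of[g] <- built$cds_seq
    scaffold_seq[sc] <- paste0(scaffold_seq[sc], built$body,
                               random_dna(flank))
    next_offset[sc] <- nchar(scaffold_seq[sc]) + 1L
  }
  reference <- Biostrings::DNAStringSet(scaffold_seq)

  # --- cohort -------------------------------------------------------------
  cluster_labels <- rep(names(cfg$cluster_sizes), cfg$cluster_sizes)
  cht <- cohort(cfg$individuals, cluster_labels)
  n_ind <- length(cht$individuals)
  n_clust <- length(cht$clusters)

  # --- site placement -----------------------------------------------------
  site_rows <- list()
  # intronic sites: split evenly over genes, positions sampled per gene
  per_gene_intronic <- rep(cfg$n_intronic %/% cfg$n_genes, cfg$n_genes)
  rem <- cfg$n_intronic - sum(per_gene_intronic)
  if (rem > 0L)
    per_gene_intronic[seq_len(rem)] <- per_gene_intronic[seq_len(rem)] + 1L
  for (g in seq_len(cfg$n_genes)) {
    m <- models[[g]]
    intr <- introns(m)
    pool <- unlist(mapply(seq, intr$start, intr$end, SIMPLIFY = FALSE))
    if (per_gene_intronic[g] > length(pool))
      stop("infeasible plant request: ", per_gene_intronic[g],
           " intronic SNPs exceed intron capacity of ", m$gene_id,
           call. = FALSE)
    pos <- sort(sample(pool, per_gene_intronic[g]))
    ref <- vapply(pos, function(p) as.character(
      Biostrings::subseq(reference[[m$scaffold_id]], p, p)), "")
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1L), "")
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      gene = m$gene_id, scaffold = m$scaffold_id, pos = pos, ref = ref,
      alt = unname(alt), region = "intronic",
      planted_effect = NA_character_, codon_index = NA_integer_,
      stringsAsFactors = FALSE)
  }
  # exonic planted sites, round-robin over genes
  plant_one <- function(g, effect, used_pos) {
    m <- models[[g]]
    repeat {
      pl <- plant_substitution(cds_of[g], effect, m$catalytic_codons)
      if (is.null(pl))
        stop("infeasible plant request: no ", effect,
             " substitution found in ", m$gene_id, call. = FALSE)
      gpos <- cds_to_genomic(pl$cds_pos, m)
      if (gpos %in% used_pos) next
      ref <- as.character(Biostrings::subseq(reference[[m$scaffold_id]],
                                             gpos, gpos))
      alt <- if (m$strand == "+") pl$alt_base else revcomp_chr(pl$alt_base)
      return(data.frame(gene = m$gene_id, scaffold = m$scaffold_id,
                        pos = gpos, ref = ref, alt = alt, region = "exonic",
                        planted_effect = effect,
                        codon_index = pl$codon_index,
                        stringsAsFactors = FALSE))
    }
  }
  effects <- c(rep("synonymous", cfg$n_syn),
               rep("nonsynonymous", cfg$n_nonsyn))
  gene_cycle <- rep(seq_len(cfg$n_genes),
                    length.out = length(effects))
  for (k in seq_along(effects)) {
    used <- unlist(lapply(site_rows, function(d)
      d$pos[d$scaffold == scaffold_of[gene_cycle[k]]]))
    site_rows[[length(site_rows) + 1L]] <-
      plant_one(gene_cycle[k], effects[k], used)
  }
  sites <- do.call(rbind, site_rows)
  ord <- order(sites$scaffold, sites$pos)
  sites <- sites[ord, ]
  rownames(sites) <- NULL
  n_snp <- nrow(sites)

  # --- frequencies, genotypes, missingness --------------------------------
  f <- rep_len(cfg$fst, n_clust)
  p_anc <- numeric(n_snp)
  cluster_freq <- matrix(0, n_snp, n_clust,
                         dimnames = list(NULL, cht$clusters))
  geno <- matrix(NA_integer_, n_snp, n_ind,
                 dimnames = list(NULL, cht$individuals))
  cl_of_ind <- cht$cluster_of[cht$individuals]
  for (i in seq_len(n_snp)) {
    p <- stats::runif(1L, cfg$ancestral_range[1L], cfg$ancestral_range[2L])
    p_anc[i] <- p
    pc <- stats::rbeta(n_clust, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    cluster_freq[i, ] <- pc
    g <- stats::rbinom(n_ind, 2L, pc[match(cl_of_ind, cht$clusters)])
    repeat {
      miss <- stats::runif(n_ind) < cfg$missing_rate
      if (!all(miss)) break
    }
    g[miss] <- NA_integer_
    geno[i, ] <- g
  }
  snps <- snp_set(sites[, c("scaffold", "pos", "ref", "alt", "gene")] |>
                    stats::setNames(c("scaffold_id", "pos", "ref", "alt",
                                      "gene_id")),
                  geno, cht)

  # --- neutral richness, rank-matched to true expected diversity ----------
  sizes <- cfg$cluster_sizes[cht$clusters]
  expected_div <- vapply(seq_len(n_clust), function(c) {
    nall <- 2L * sizes[c]
    mean(1 - cluster_freq[, c]^nall - (1 - cluster_freq[, c])^nall)
  }, 0)
  names(expected_div) <- cht$clusters
  rich_vals <- sort(stats::runif(n_clust, 2, 8))
  richness <- stats::setNames(rich_vals[rank(expected_div)], cht$clusters)

  # --- emit files ----------------------------------------------------------
  paths <- c(reference = file.path(dir, "reference.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             vcf = file.path(dir, "variants.vcf"),
             clusters = file.path(dir, "clusters.tsv"),
             richness = file.path(dir, "richness.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(reference, paths["reference"])
  write_gene_models(models, paths["gff3"])
  write_variants(snps, paths["vcf"])
  write_cluster_table(cht, paths["clusters"])
  write_neutral_richness(richness, paths["richness"])

  proteins <- stats::setNames(
    vapply(cds_of, function(s) sub("\\*$", "", translate_cds(s)), ""),
    gene_ids)

  truth <- structure(
    list(config = cfg, paths = paths, cohort = cht, models = models,
         sites = sites, cluster_freq = cluster_freq, geno = geno,
         richness = richness, expected_diversity = expected_div,
         cds = stats::setNames(cds_of, gene_ids), proteins = proteins),
    class = "cohort_truth")
  jsonlite::write_json(
    list(seed = cfg$seed, fst = cfg$fst,
         missing_rate = cfg$missing_rate,
         sites = sites, cluster_freq = cluster_freq,
         geno = geno, richness = as.list(richness),
         expected_diversity = as.list(expected_div)),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  truth
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d genes, %d individuals in %d clusters, %d SNPs (%d exonic planted)\n",
              length(x$models), length(x$cohort$individuals),
              length(x$cohort$clusters), nrow(x$sites),
              sum(x$sites$region == "exonic")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Brute-force truth summary (deliberately independent of diversity_stats:
# plain loops over individuals and allele sets, used as the end-to-end
# oracle for the pipeline).

#' Brute-force diversity summary from simulator truth
#'
#' Recomputes the same statistics as [summarize_diversity()] directly from
#' the truth genotype matrix by explicit enumeration (no shared code with
#' the pipeline path), applying the same informativeness filter.
#'
#' @param truth Output of [simulate_cohort()].
#' @param maf_threshold,miss_threshold Filter cut-offs, as in
#'   [is_informative()].
#' @return List with `diversity` and `individual_maf` data.frames, shaped
#'   exactly like the output of [summarize_diversity()].
#' @export
truth_summary <- function(truth, maf_threshold = 0.08,
                          miss_threshold = 0.42) {
  cht <- truth$cohort
  geno <- truth$geno
  sites <- truth$sites
  n_ind <- length(cht$individuals)
  genes <- sort(unique(sites$gene))
  classes <- c("exonic", "intronic")

  # per-site filter, by explicit counting
  n_snp <- nrow(sites)
  informative <- logical(n_snp)
  minor_is_alt <- logical(n_snp)
  for (i in seq_len(n_snp)) {
    g <- geno[i, ]
    called <- which(!is.na(g))
    alt_count <- 0L
    for (j in called) alt_count <- alt_count + g[j]
    total <- 2L * length(called)
    f_alt <- alt_count / total
    maf <- min(f_alt, 1 - f_alt)
    minor_is_alt[i] <- f_alt <= 0.5
    miss <- (n_ind - length(called)) / n_ind
    informative[i] <- (maf > maf_threshold) && (miss < miss_threshold)
  }

  div_rows <- list()
  for (gn in genes) for (cl in cht$clusters) for (rc in classes) {
    members <- cht$individuals[cht$cluster_of[cht$individuals] == cl]
    others <- setdiff(cht$individuals, members)
    idx <- which(informative & sites$gene == gn & sites$region == rc)
    n_data <- 0L; n_poly <- 0L; n_priv <- 0L; maf_sum <- 0
    for (i in idx) {
      gm <- geno[i, members]; gm <- gm[!is.na(gm)]
      if (length(gm) == 0L) next
      n_data <- n_data + 1L
      here_ref <- any(gm < 2L); here_alt <- any(gm > 0L)
      if (here_ref && here_alt) n_poly <- n_poly + 1L
      if (length(cht$clusters) >= 2L) {
        go <- geno[i, others]; go <- go[!is.na(go)]
        there_ref <- any(go < 2L); there_alt <- any(go > 0L)
        if ((here_ref && !there_ref) || (here_alt && !there_alt))
          n_priv <- n_priv + 1L
      }
      f_alt_cl <- sum(gm) / (2 * length(gm))
      maf_sum <- maf_sum + min(f_alt_cl, 1 - f_alt_cl)
    }
    div_rows[[length(div_rows) + 1L]] <- data.frame(
      gene = gn, cluster = cl, region_class = rc, n_sites = n_data,
      mean_maf = if (n_data > 0L) maf_sum / n_data else NA_real_,
      prop_polymorphic = if (n_data > 0L) n_poly / n_data else NA_real_,
      prop_private = if (n_data > 0L) n_priv / n_data else NA_real_,
      stringsAsFactors = FALSE)
  }
  diversity <- do.call(rbind, div_rows)
  # fix row order to gene, cluster (cohort order), class
  diversity <- diversity[order(match(diversity$gene, genes),
                               match(diversity$cluster, cht$clusters),
                               match(diversity$region_class, classes)), ]
  rownames(diversity) <- NULL

  ind_rows <- list()
  for (ind in cht$individuals) for (gn in genes) for (rc in classes) {
    idx <- which(informative & sites$gene == gn & sites$region == rc)
    vals <- numeric(0)
    for (i in idx) {
      g <- geno[i, ind]
      if (is.na(g)) next
      dos <- if (minor_is_alt[i]) g else 2L - g
      vals <- c(vals, dos / 2)
    }
    ind_rows[[length(ind_rows) + 1L]] <- data.frame(
      individual = ind, gene = gn, region_class = rc,
      mean_dosage_maf = if (length(vals)) mean(vals) else NA_real_,
      stringsAsFactors = FALSE)
  }
  individual_maf <- do.call(rbind, ind_rows)
  rownames(individual_maf) <- NULL
  list(diversity = diversity, individual_maf = individual_maf)
}

# ---------------------------------------------------------------------------
# Differentiation recovery

#' Weir-style differentiation estimate from genotypes
#'
#' One-way ANOVA estimator of the allele-correlation coefficient within
#' clusters (theta / F\\_ST), treating the two alleles of each called diploid
#' genotype as observations grouped by cluster, combined over sites as a
#' ratio of summed variance components. Under the Balding-Nichols model this
#' estimates the configured differentiation F. A jackknife-over-sites
#' standard error is returned.
#'
#' @param snps A `SnpSet` (or a `cohort_truth`, whose genotypes are used).
#' @return List: `theta`, `se` (jackknife over sites), `n_sites` (sites
#'   contributing).
#' @export
estimate_differentiation <- function(snps) {
  if (inherits(snps, "cohort_truth")) {
    geno <- snps$geno; cht <- snps$cohort
  } else {
    geno <- snps$geno; cht <- snps$cohort
  }
  cl <- cht$cluster_of[colnames(geno)]
  clusters <- cht$clusters
  comp <- matrix(NA_real_, nrow(geno), 2L)  # a_i, b_i per usable site
  for (i in seq_len(nrow(geno))) {
    m_c <- p_c <- numeric(0)
    for (c in clusters) {
      g <- geno[i, cl == c]
      g <- g[!is.na(g)]
      if (length(g) == 0L) next
      m_c <- c(m_c, 2L * length(g))
      p_c <- c(p_c, sum(g) / (2 * length(g)))
    }
    C <- length(m_c)
    if (C < 2L) next
    N <- sum(m_c)
    pbar <- sum(m_c * p_c) / N
    if (pbar == 0 || pbar == 1) next
    msb <- sum(m_c * (p_c - pbar)^2) / (C - 1)
    msw <- sum(m_c * p_c * (1 - p_c)) / (N - C)
    nprime <- (N - sum(m_c^2) / N) / (C - 1)
    comp[i, ] <- c((msb - msw) / nprime, msw)
  }
  ok <- which(!is.na(comp[, 1L]))
  if (length(ok) < 2L) stop("too few polymorphic sites", call. = FALSE)
  a <- comp[ok, 1L]; b <- comp[ok, 2L]
  theta <- sum(a) / sum(a + b)
  # delete-one jackknife over sites
  tot_a <- sum(a); tot_ab <- sum(a + b)
  theta_jk <- (tot_a - a) / (tot_ab - (a + b))
  n <- length(ok)
  se <- sqrt((n - 1) / n * sum((theta_jk - mean(theta_jk))^2))
  list(theta = theta, se = se, n_sites = n)
}
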