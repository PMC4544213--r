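# Per-individual and per-cluster diversity statistics, computed separately
# on the intronic and exonic informative SNP sets, always discarding missing
# data (a genotype enters no numerator or denominator unless called).
#
# Definitions (per gene x cluster x region class):
#   * mean_maf          - mean over sites (with >= 1 called cluster genotype)
#                         of the within-cluster folded minor allele frequency.
#   * prop_polymorphic  - fraction of such sites where the cluster's called
#                         genotypes carry >= 2 distinct alleles (a single
#                         heterozygote suffices).
#   * prop_private      - fraction of such sites carrying >= 1 allele seen in
#                         this cluster's called genotypes and in no other
#                         cluster's.
# Per individual x gene x region class:
#   * mean_dosage_maf   - mean over the individual's called sites of the
#                         carried cohort-minor-allele dosage / 2.

# Indices of annot rows that enter the statistics for one gene/class.
informative_in_class <- function(annot, gene_id, region_class) {
  which(annot$informative & !is.na(annot$gene) & annot$gene == gene_id &
          annot$region == region_class)
}

# Alleles observed among called genotypes of the given columns at site i:
# subset of c("ref", "alt") as a logical pair c(ref_seen, alt_seen).
observed_alleles <- function(geno_row) {
  g <- geno_row[!is.na(geno_row)]
  c(ref = any(g < 2L), alt = any(g > 0L))
}

#' Mean minor-allele dosage of one individual over one gene and region class
#'
#' For each informative site of the gene in the class where the individual
#' has a called genotype, the individual's dosage of the cohort-wide minor
#' allele is counted (0, 1 or 2) and halved; the mean over those sites is
#' returned.
#'
#' @param individual Individual id.
#' @param snps A `SnpSet`.
#' @param annot Matching [annotate_snps()] table.
#' @param gene_id Gene id.
#' @param region_class `"exonic"` or `"intronic"`.
#' @return Fraction in `[0, 1]`, or `NA` if the individual has no called
#'   genotype at any qualifying site.
#' @export
individual_gene_maf <- function(individual, snps, annot, gene_id,
                                region_class) {
  idx <- informative_in_class(annot, gene_id, region_class)
  if (length(idx) == 0L) return(NA_real_)
  minor <- minor_allele(snps)
  g <- snps$geno[idx, individual]
  minor_dosage <- ifelse(minor[idx] == snps$sites$alt[idx], g, 2L - g)
  called <- !is.na(g)
  if (!any(called)) return(NA_real_)
  mean(minor_dosage[called] / 2)
}

#' Proportion of within-cluster polymorphic sites
#'
#' A site is polymorphic within a cluster iff at least two distinct alleles
#' are observed among the cluster's called genotypes (one heterozygote is
#' enough). The denominator is the number of qualifying sites with at least
#' one called cluster genotype.
#'
#' @param cluster Cluster label.
#' @param snps A `SnpSet`.
#' @param annot Matching annotation table.
#' @param gene_id Gene id.
#' @param region_class `"exonic"` or `"intronic"`.
#' @return Fraction in `[0, 1]`, or `NA` when no site has cluster data.
#' @export
cluster_prop_polymorphic <- function(cluster, snps, annot, gene_id,
                                     region_class) {
  idx <- informative_in_class(annot, gene_id, region_class)
  members <- cluster_members(snps$cohort, cluster)
  stopifnot(length(members) >= 1L)
  if (length(idx) == 0L) return(NA_real_)
  poly <- has_data <- logical(length(idx))
  for (k in seq_along(idx)) {
    obs <- observed_alleles(snps$geno[idx[k], members])
    has_data[k] <- any(obs)
    poly[k] <- all(obs)
  }
  if (!any(has_data)) return(NA_real_)
  sum(poly) / sum(has_data)
}

#' Proportion of sites carrying a cluster-private allele
#'
#' An allele is private to a cluster iff it is observed in at least one
#' called genotype of that cluster and in no called genotype of any other
#' cluster. A site counts once if it carries at least one private allele for
#' the cluster; the denominator is the number of qualifying sites with at
#' least one called cluster genotype.
#'
#' @inheritParams cluster_prop_polymorphic
#' @return Fraction in `[0, 1]`, or `NA` when no site has cluster data.
#' @export
cluster_prop_private <- function(cluster, snps, annot, gene_id,
                                 region_class) {
  cht <- snps$cohort
  stopifnot(length(cht$clusters) >= 2L)
  idx <- informative_in_class(annot, gene_id, region_class)
  members <- cluster_members(cht, cluster)
  others <- setdiff(cht$individuals, members)
  if (length(idx) == 0L) return(NA_real_)
  private <- has_data <- logical(length(idx))
  for (k in seq_along(idx)) {
    here <- observed_alleles(snps$geno[idx[k], members])
    there <- observed_alleles(snps$geno[idx[k], others])
    has_data[k] <- any(here)
    private[k] <- any(here & !there)
  }
  if (!any(has_data)) return(NA_real_)
  sum(private) / sum(has_data)
}

# Within-cluster folded MAF at the sites idx, averaged; NA if no data.
cluster_mean_maf <- function(cluster, snps, idx) {
  members <- cluster_members(snps$cohort, cluster)
  vals <- numeric(0)
  for (i in idx) {
    g <- snps$geno[i, members]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    f_alt <- sum(g) / (2 * length(g))
    vals <- c(vals, min(f_alt, 1 - f_alt))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Summarize diversity per gene, cluster and region class
#'
#' Restricts to informative sites and produces the central bookkeeping of
#' the analysis: one `DiversitySummary` row per gene x cluster x region
#' class (deterministic order), plus the per-individual mean minor-allele
#' dosage table behind the individual-level MAF barplots.
#'
#' @param snps A `SnpSet`.
#' @param annot Matching [annotate_snps()] table.
#' @param genes Optional character vector fixing gene order (default: sorted
#'   genes present in `annot`).
#' @return List with two data.frames: `diversity` (gene, cluster,
#'   region_class, n_sites, mean_maf, prop_polymorphic, prop_private) and
#'   `individual_maf` (individual, gene, region_class, mean_dosage_maf).
#' @export
summarize_diversity <- function(snps, annot, genes = NULL) {
  cht <- snps$cohort
  if (is.null(genes)) genes <- sort(unique(annot$gene[!is.na(annot$gene)]))
  classes <- c("exonic", "intronic")
  grid <- expand.grid(region_class = classes, cluster = cht$clusters,
                      gene = genes, stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "cluster", "region_class")]
  grid <- grid[order(match(grid$gene, genes),
                     match(grid$cluster, cht$clusters),
                     match(grid$region_class, classes)), ]
  rownames(grid) <- NULL
  nr <- nrow(grid)
  nsit <- integer(nr); mm <- pp <- pv <- numeric(nr)
  for (r in seq_len(nr)) {
    idx <- informative_in_class(annot, grid$gene[r], grid$region_class[r])
    members <- cluster_members(cht, grid$cluster[r])
    with_data <- if (length(idx)) idx[vapply(idx, function(i) {
      any(!is.na(snps$geno[i, members]))
    }, logical(1))] else integer(0)
    nsit[r] <- length(with_data)
    mm[r] <- cluster_mean_maf(grid$cluster[r], snps, with_data)
    pp[r] <- cluster_prop_polymorphic(grid$cluster[r], snps, annot,
                                      grid$gene[r], grid$region_class[r])
    pv[r] <- if (length(cht$clusters) >= 2L)
      cluster_prop_private(grid$cluster[r], snps, annot, grid$gene[r],
                           grid$region_class[r])
    else if (nsit[r] > 0L) 0 else NA_real_
  }
  diversity <- cbind(grid, n_sites = nsit, mean_maf = mm,
                     prop_polymorphic = pp, prop_private = pv)

  igrid <- expand.grid(region_class = classes, gene = genes,
                       individual = cht$individuals, stringsAsFactors = FALSE)
  igrid <- igrid[, c("individual", "gene", "region_class")]
  igrid$mean_dosage_maf <- mapply(function(ind, g, cl) {
    individual_gene_maf(ind, snps, annot, g, cl)
  }, igrid$individual, igrid$gene, igrid$region_class)
  rownames(igrid) <- NULL
  list(diversity = diversity, individual_maf = igrid)
}

#' Write diversity summaries as TSV
#'
#' @param summary Output of [summarize_diversity()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_diversity_tsv <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "diversity_summary.tsv")
  p2 <- file.path(dir, "individual_maf.tsv")
  utils::write.table(summary$diversity, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$individual_maf, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
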