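# Shared scaffold for diversity tests: a simulated cohort, annotated once.
local({
  cfg <- sim_config(seed = 31)
  dir <- file.path(tempdir(), "vpepop-div-fixture")
  truth <- simulate_cohort(cfg, dir)
  snps <- read_variants(truth$paths[["vcf"]], truth$cohort)
  models <- read_gene_models(truth$paths[["gff3"]])
  ref <- read_reference(truth$paths[["reference"]])
  annot <- annotate_snps(snps, models, ref)
  assign("div_fx", list(truth = truth, snps = snps, annot = annot),
         envir = parent.env(environment()))
})

test_that("individual mean dosage MAF matches per-site hand enumeration", {
  snps <- div_fx$snps; annot <- div_fx$annot
  minor <- minor_allele(snps)
  for (ind in sample(snps$cohort$individuals, 4)) {
    for (rc in c("exonic", "intronic")) {
      got <- individual_gene_maf(ind, snps, annot, "gene_1", rc)
      idx <- which(annot$informative & annot$gene == "gene_1" &
                     annot$region == rc)
      vals <- c()
      for (i in idx) {
        g <- snps$geno[i, ind]
        if (is.na(g)) next
        dos <- if (minor[i] == snps$sites$alt[i]) g else 2 - g
        vals <- c(vals, dos / 2)
      }
      expect_equal(got, if (length(vals)) mean(vals) else NA_real_)
    }
  }
  # degenerate dosages
  cht <- cohort(paste0("i", 1:4), rep("X", 4))
  mk <- function(rows) {
    s <- snp_set(data.frame(scaffold_id = "s", pos = seq_len(nrow(rows)),
                            ref = "A", alt = "G",
                            gene_id = "g"),
                 rows, cht)
    a <- data.frame(gene = "g", region = "exonic",
                    informative = TRUE)
    a <- a[rep(1, nrow(rows)), ]
    s$sites$gene_id <- "g"
    list(s = s, a = a)
  }
  homo_major <- matrix(0L, 4, 4, dimnames = list(NULL, cht$individuals))
  homo_major[, 2] <- 1L  # make sites polymorphic so alt is minor
  f <- mk(homo_major)
  expect_equal(individual_gene_maf("i1", f$s, f$a, "g", "exonic"), 0)
  het <- matrix(1L, 4, 4, dimnames = list(NULL, cht$individuals))
  f2 <- mk(het)
  expect_equal(individual_gene_maf("i1", f2$s, f2$a, "g", "exonic"), 0.5)
})

test_that("within-cluster polymorphism matches a set-based oracle", {
  snps <- div_fx$snps; annot <- div_fx$annot; cht <- snps$cohort
  for (cl in cht$clusters) for (gn in c("gene_1", "gene_3")) {
    got <- cluster_prop_polymorphic(cl, snps, annot, gn, "intronic")
    idx <- which(annot$informative & annot$gene == gn &
                   annot$region == "intronic")
    members <- cluster_members(cht, cl)
    n_poly <- n_data <- 0
    for (i in idx) {
      alleles <- character(0)  # enumerate observed alleles explicitly
      for (m in members) {
        g <- snps$geno[i, m]
        if (is.na(g)) next
        alleles <- c(alleles,
                     c(rep(snps$sites$ref[i], 2 - g),
                       rep(snps$sites$alt[i], g)))
      }
      if (!length(alleles)) next
      n_data <- n_data + 1
      if (length(unique(alleles)) >= 2) n_poly <- n_poly + 1
    }
    expect_equal(got, if (n_data) n_poly / n_data else NA_real_)
  }
  # a lone heterozygous individual is polymorphic within its cluster
  cht1 <- cohort(c("solo", "other"), c("Nak", "X"))
  s <- snp_set(data.frame(scaffold_id = "s", pos = 1L, ref = "A", alt = "G",
                          gene_id = "g"),
               matrix(c(1L, 0L), 1, dimnames = list(NULL,
                                                    c("solo", "other"))),
               cht1)
  a <- data.frame(gene = "g", region = "exonic", informative = TRUE)
  expect_equal(cluster_prop_polymorphic("Nak", s, a, "g", "exonic"), 1)
})

test_that("private alleles match a brute-force cross-cluster scan and are
          disjoint across clusters", {
  snps <- div_fx$snps; annot <- div_fx$annot; cht <- snps$cohort
  idx <- which(annot$informative & annot$gene == "gene_2" &
                 annot$region == "intronic")
  observed <- function(i, inds) {
    g <- snps$geno[i, inds]; g <- g[!is.na(g)]
    out <- character(0)
    if (any(g < 2)) out <- c(out, snps$sites$ref[i])
    if (any(g > 0)) out <- c(out, snps$sites$alt[i])
    out
  }
  private_sets <- list()
  for (cl in cht$clusters) {
    got <- cluster_prop_private(cl, snps, annot, "gene_2", "intronic")
    members <- cluster_members(cht, cl)
    others <- setdiff(cht$individuals, members)
    n_priv <- n_data <- 0
    priv_alleles <- list()
    for (i in idx) {
      here <- observed(i, members)
      if (!length(here)) next
      n_data <- n_data + 1
      priv <- setdiff(here, observed(i, others))
      if (length(priv)) {
        n_priv <- n_priv + 1
        priv_alleles[[as.character(i)]] <- priv
      }
    }
    expect_equal(got, if (n_data) n_priv / n_data else NA_real_)
    private_sets[[cl]] <- priv_alleles
  }
  # per allele, private sets are disjoint between clusters
  for (i in as.character(idx)) {
    claimed <- unlist(lapply(private_sets, function(p) p[[i]]))
    expect_true(!anyDuplicated(claimed))
  }
})

test_that("summary has the full gene x cluster x class grid and survives
          input permutation and individual duplication", {
  snps <- div_fx$snps; annot <- div_fx$annot; cht <- snps$cohort
  sm <- summarize_diversity(snps, annot)
  expect_equal(nrow(sm$diversity), 3 * 4 * 2)        # 24 rows
  expect_equal(nrow(sm$individual_maf), 12 * 3 * 2)  # 72 rows
  ok <- !is.na(sm$diversity$mean_maf)
  expect_true(all(sm$diversity$mean_maf[ok] <= 0.5))
  expect_true(all(sm$diversity$prop_private <= 1, na.rm = TRUE))

  # permuting individual order leaves every statistic unchanged
  set.seed(41)
  perm <- sample(cht$individuals)
  cht_p <- cohort(perm, unname(cht$cluster_of[perm]))
  snps_p <- snp_set(snps$sites, snps$geno[, perm, drop = FALSE], cht_p)
  sm_p <- summarize_diversity(snps_p, annot)
  key <- function(d) d[order(d$gene, d$cluster, d$region_class), ]
  expect_equal(key(sm_p$diversity), key(sm$diversity),
               ignore_attr = TRUE)

  # duplicating every individual leaves all proportions unchanged
  dup_ids <- c(cht$individuals, paste0(cht$individuals, "_b"))
  cht_d <- cohort(dup_ids, unname(cht$cluster_of[c(cht$individuals,
                                                   cht$individuals)]))
  geno_d <- cbind(snps$geno, snps$geno)
  colnames(geno_d) <- dup_ids
  snps_d <- snp_set(snps$sites, geno_d, cht_d)
  annot_d <- annot  # MAF/missingness are invariant under duplication
  sm_d <- summarize_diversity(snps_d, annot_d)
  for (col in c("prop_polymorphic", "prop_private", "mean_maf"))
    expect_equal(sm_d$diversity[[col]], sm$diversity[[col]])

  # merging all clusters into one zeroes prop_private everywhere
  cht_m <- cohort(cht$individuals, rep("all", 12))
  snps_m <- snp_set(snps$sites, snps$geno, cht_m)
  sm_m <- summarize_diversity(snps_m, annot)
  expect_true(all(sm_m$diversity$prop_private == 0 |
                    is.na(sm_m$diversity$prop_private)))
})
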