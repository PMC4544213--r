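test_that("the same seed reproduces byte-identical files", {
  cfg <- sim_config(seed = 99, n_intronic = 30)
  t1 <- simulate_cohort(cfg, withr::local_tempdir())
  t2 <- simulate_cohort(cfg, withr::local_tempdir())
  for (k in names(t1$paths))
    expect_identical(readLines(t1$paths[[k]]), readLines(t2$paths[[k]]))
  # a different seed gives different genotypes
  t3 <- simulate_cohort(sim_config(seed = 100, n_intronic = 30),
                        withr::local_tempdir())
  expect_false(identical(t1$geno, t3$geno))
})

test_that("default design emulates the study: 3 genes of 9 exons, 12
          individuals in clusters of 4/5/2/1", {
  truth <- simulate_cohort(sim_config(seed = 61), withr::local_tempdir())
  expect_length(truth$models, 3)
  for (m in truth$models) {
    expect_equal(nrow(m$exons), 9)
    expect_equal(nrow(introns(m)), 8)
  }
  expect_length(truth$cohort$individuals, 12)
  expect_equal(as.vector(table(truth$cohort$cluster_of)[
    truth$cohort$clusters]), c(4, 5, 2, 1))
  # two genes in tandem on one scaffold, opposite strands
  scafs <- vapply(truth$models, `[[`, "", "scaffold_id")
  expect_equal(sum(scafs == "scaffold_1"), 2)
  # planted counts as configured
  expect_equal(sum(truth$sites$planted_effect == "synonymous",
                   na.rm = TRUE), 7)
  expect_equal(sum(truth$sites$planted_effect == "nonsynonymous",
                   na.rm = TRUE), 5)
  expect_equal(sum(truth$sites$region == "intronic"), 84)
  # catalytic codons encode the His/Cys dyad in the reference protein
  for (g in names(truth$models)) {
    aa <- strsplit(truth$proteins[[g]], "")[[1]]
    dyad <- aa[truth$models[[g]]$catalytic_codons]
    expect_identical(dyad, c("H", "C"))
  }
})

test_that("planted effect classes re-annotate to truth for every site", {
  for (seed in c(71, 72)) {
    truth <- simulate_cohort(sim_config(seed = seed),
                             withr::local_tempdir())
    snps <- read_variants(truth$paths[["vcf"]], truth$cohort)
    models <- read_gene_models(truth$paths[["gff3"]],
                               catalytic = lapply(truth$models, `[[`,
                                                  "catalytic_codons"))
    ref <- read_reference(truth$paths[["reference"]])
    annot <- annotate_snps(snps, models, ref)
    key <- paste(annot$scaffold, annot$pos)
    tkey <- paste(truth$sites$scaffold, truth$sites$pos)
    expect_setequal(key, tkey)
    m <- match(tkey, key)
    expect_identical(annot$region[m], truth$sites$region)
    planted <- !is.na(truth$sites$planted_effect)
    expect_identical(annot$effect[m][planted],
                     truth$sites$planted_effect[planted])
    # none of the planted variants hits a catalytic codon, mirroring the
    # real genes
    expect_false(any(annot$catalytic[m][planted]))
  }
})

test_that("low differentiation keeps cluster frequencies near ancestral
          and makes private alleles rare", {
  p_anc_of <- function(truth) {
    # ancestral frequency is recoverable as the across-cluster expectation
    rowMeans(truth$cluster_freq)
  }
  lo <- simulate_cohort(sim_config(seed = 81, fst = 0.005,
                                   n_intronic = 150),
                        withr::local_tempdir())
  hi <- simulate_cohort(sim_config(seed = 81, fst = 0.6, n_intronic = 150),
                        withr::local_tempdir())
  spread <- function(truth)
    mean(abs(truth$cluster_freq - p_anc_of(truth)))
  expect_lt(spread(lo), 0.05)
  expect_gt(spread(hi), 0.15)
  ts_lo <- truth_summary(lo); ts_hi <- truth_summary(hi)
  expect_lt(mean(ts_lo$diversity$prop_private, na.rm = TRUE),
            mean(ts_hi$diversity$prop_private, na.rm = TRUE))
})

test_that("richness rank-matches true expected diversity and lower
          per-cluster F raises expected polymorphism", {
  truth <- simulate_cohort(sim_config(seed = 91,
                                      fst = c(0.02, 0.45, 0.6, 0.75)),
                           withr::local_tempdir())
  expect_identical(order(truth$richness), order(truth$expected_diversity))
  # the diversity dial: North (F = 0.02) must exceed Nak (F = 0.75)
  expect_gt(truth$expected_diversity[["North"]],
            truth$expected_diversity[["Nak"]])
  # monotonicity of the dial over a small seed batch, scalar F
  mean_poly <- function(f) {
    vals <- vapply(1:3, function(s) {
      tr <- simulate_cohort(sim_config(seed = s, fst = f, n_intronic = 60,
                                       missing_rate = 0),
                            withr::local_tempdir())
      mean(truth_summary(tr)$diversity$prop_polymorphic, na.rm = TRUE)
    }, 0)
    mean(vals)
  }
  expect_gt(mean_poly(0.05), mean_poly(0.7))
})

test_that("truth summary equals the pipeline summary on varied configs", {
  configs <- list(
    sim_config(seed = 101, missing_rate = 0),          # no missing data
    sim_config(seed = 102, missing_rate = 0.3),        # heavy missingness
    sim_config(seed = 103, cluster_sizes = c(All = 12L)))  # single cluster
  for (cfg in configs) {
    truth <- simulate_cohort(cfg, withr::local_tempdir())
    snps <- read_variants(truth$paths[["vcf"]], truth$cohort)
    models <- read_gene_models(truth$paths[["gff3"]])
    ref <- read_reference(truth$paths[["reference"]])
    sm <- summarize_diversity(snps, annotate_snps(snps, models, ref))
    ts <- truth_summary(truth)
    expect_equal(sm$diversity, ts$diversity, tolerance = 1e-12)
    expect_equal(sm$individual_maf, ts$individual_maf, tolerance = 1e-12)
    if (identical(unname(cfg$cluster_sizes), 12L))
      expect_true(all(sm$diversity$prop_private == 0 |
                        is.na(sm$diversity$prop_private)))
  }
})

test_that("differentiation is recovered by the Weir-style estimator", {
  truth <- simulate_cohort(sim_config(seed = 111, n_intronic = 250),
                           withr::local_tempdir())
  snps <- read_variants(truth$paths[["vcf"]], truth$cohort)
  est <- estimate_differentiation(snps)
  expect_gte(est$n_sites, 200)
  expect_lt(abs(est$theta - 0.2), 3 * est$se)
})

test_that("infeasible plant requests error out", {
  expect_error(
    simulate_cohort(sim_config(seed = 1, n_intronic = 10000),
                    withr::local_tempdir()),
    "infeasible")
})
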