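# End-to-end orchestration: read (or simulate) -> filter -> annotate ->
# summarize -> concordance (+ optional similarity / peptide evidence), with
# a run log recording thresholds, seed and counts dropped at each stage.
# All thresholds live in the run configuration; nothing is hard-coded.

#' Build a run configuration
#'
#' Exactly one of `inputs` (paths to real files) or `simulate` (a
#' [sim_config()]) must be given.
#'
#' @param inputs Named list with elements `vcf`, `gff3`, `fasta`,
#'   `clusters`, `richness`, and optionally `catalytic` (named list of
#'   codon-index vectors per gene).
#' @param simulate A [sim_config()].
#' @param maf_threshold,miss_threshold Informativeness filter cut-offs
#'   (defaults 0.08 and 0.42).
#' @param alpha Significance level of the concordance permutation test.
#' @param polarity Amino-acid polarity class map.
#' @param out_dir Output directory for reports.
#' @param peptides Optional character vector of peptides to match against
#'   the translated gene models.
#' @return List of class `run_config`.
#' @export
run_config <- function(inputs = NULL, simulate = NULL,
                       maf_threshold = 0.08, miss_threshold = 0.42,
                       alpha = 0.05,
                       polarity = default_polarity_classes(),
                       out_dir = tempfile("vpepop_run"),
                       peptides = NULL) {
  if (is.null(inputs) == is.null(simulate))
    stop("exactly one of 'inputs' or 'simulate' must be given",
         call. = FALSE)
  structure(list(inputs = inputs, simulate = simulate,
                 maf_threshold = maf_threshold,
                 miss_threshold = miss_threshold, alpha = alpha,
                 polarity = polarity, out_dir = out_dir,
                 peptides = peptides),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Mirrors [run_config()]: top-level keys `inputs:` or `simulate:`,
#' `maf_threshold`, `miss_threshold`, `alpha`, `out_dir`, `peptides`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate)
  run_config(
    inputs = y$inputs, simulate = sim,
    maf_threshold = y$maf_threshold %||% 0.08,
    miss_threshold = y$miss_threshold %||% 0.42,
    alpha = y$alpha %||% 0.05,
    out_dir = y$out_dir %||% tempfile("vpepop_run"),
    peptides = unlist(y$peptides))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes read (or simulate) -> informativeness filter -> annotation ->
#' diversity summary -> neutrality concordance, writing
#' `annotated_snps.tsv`, `diversity_summary.tsv`, `individual_maf.tsv`,
#' `concordance.tsv`, a machine-readable `summary.json` and a `run.log`
#' under `config$out_dir`. Any stage failure aborts with a stage-named
#' error and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: `snps`, `annot`, `summary`,
#'   `concordance`, `similarity` (when >= 2 gene proteins are available),
#'   `peptide_matches` (when peptides were supplied), `truth` (simulated
#'   runs only), `log` (character vector), `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  fail <- function(stage, e) {
    unlink(made)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    fail(name, e))

  truth <- NULL
  if (!is.null(config$simulate)) {
    truth <- stage("simulate", simulate_cohort(
      config$simulate, file.path(out_dir, "simulated_inputs")))
    inputs <- list(vcf = truth$paths[["vcf"]],
                   gff3 = truth$paths[["gff3"]],
                   fasta = truth$paths[["reference"]],
                   clusters = truth$paths[["clusters"]],
                   richness = truth$paths[["richness"]],
                   catalytic = lapply(truth$models, `[[`, "catalytic_codons"))
    fst <- config$simulate$fst
    note("simulate: seed %d, F = %s, missing rate = %g",
         config$simulate$seed,
         if (length(unique(fst)) == 1L) format(fst[[1L]])
         else paste(format(fst), collapse = "/"),
         config$simulate$missing_rate)
  } else inputs <- config$inputs

  read_res <- stage("read", {
    cht <- read_cluster_table(inputs$clusters)
    models <- read_gene_models(inputs$gff3,
                               catalytic = inputs$catalytic %||% list())
    reference <- read_reference(inputs$fasta)
    snps <- read_variants(inputs$vcf, cht)
    richness <- read_neutral_richness(inputs$richness)
    check_reference_coverage(reference, models, snps)
    list(cht = cht, models = models, reference = reference, snps = snps,
         richness = richness)
  })
  snps <- read_res$snps
  note("read: %d individuals, %d clusters, %d genes, %d biallelic SNVs (%d non-SNV records dropped)",
       length(read_res$cht$individuals), length(read_res$cht$clusters),
       length(read_res$models), n_sites(snps),
       attr(snps, "n_dropped") %||% 0L)

  annot <- stage("annotate", annotate_snps(
    snps, read_res$models, read_res$reference,
    maf_threshold = config$maf_threshold,
    miss_threshold = config$miss_threshold,
    polarity = config$polarity))
  note("filter: MAF > %g and missingness < %g -> %d of %d sites informative (%d dropped)",
       config$maf_threshold, config$miss_threshold, sum(annot$informative),
       nrow(annot), sum(!annot$informative))
  note("annotate: %d exonic (%d synonymous, %d nonsynonymous), %d intronic, %d intergenic among informative sites",
       sum(annot$informative & annot$region == "exonic"),
       sum(annot$informative & annot$effect == "synonymous"),
       sum(annot$informative & annot$effect == "nonsynonymous"),
       sum(annot$informative & annot$region == "intronic"),
       sum(annot$informative & annot$region == "intergenic"))

  summary <- stage("summarize", summarize_diversity(snps, annot))
  conc <- stage("concordance", concordance_table(
    summary, read_res$richness, alpha = config$alpha))
  note("concordance: %d of %d gene x class cells concordant with neutrality",
       sum(conc$verdict == "concordant_with_neutrality"), nrow(conc))

  # optional sequence-evidence steps over the translated gene models
  proteins <- stage("translate", {
    vapply(read_res$models, function(m) {
      if (!m$translatable || nrow(m$cds) == 0L) return(NA_character_)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(
        spliced_cds(m, read_res$reference)), if.fuzzy.codon = "solve"))
      sub("\\*$", "", aa)
    }, "")
  })
  proteins <- proteins[!is.na(proteins)]
  similarity <- NULL
  if (length(proteins) >= 2L) {
    similarity <- stage("similarity",
                        similarity_matrix(proteins, level = "protein"))
    note("similarity: %d protein pairs compared", nrow(similarity))
  }
  peptide_matches <- NULL
  if (!is.null(config$peptides) && length(proteins) >= 1L) {
    peptide_matches <- stage("digest-match",
                             match_peptides(config$peptides, proteins))
    note("digest-match: %d peptide occurrences across %d proteins",
         nrow(peptide_matches), length(proteins))
  }

  stage("write", {
    made <<- c(made, write_annotation_tsv(
      annot, file.path(out_dir, "annotated_snps.tsv")))
    made <<- c(made, write_diversity_tsv(summary, out_dir))
    p <- file.path(out_dir, "concordance.tsv")
    utils::write.table(conc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    made <<- c(made, p)
    if (!is.null(similarity)) {
      p <- file.path(out_dir, "similarity.tsv")
      utils::write.table(similarity, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      made <<- c(made, p)
    }
    if (!is.null(peptide_matches)) {
      p <- file.path(out_dir, "peptide_matches.tsv")
      utils::write.table(peptide_matches, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      made <<- c(made, p)
    }
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(thresholds = list(maf = config$maf_threshold,
                             missingness = config$miss_threshold,
                             alpha = config$alpha),
           n_sites = n_sites(snps),
           n_informative = sum(annot$informative),
           diversity = summary$diversity,
           concordance = conc),
      p, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
    made <<- c(made, p)
    writeLines(log, file.path(out_dir, "run.log"))
  })

  structure(list(snps = snps, annot = annot, summary = summary,
                 concordance = conc, similarity = similarity,
                 peptide_matches = peptide_matches, truth = truth,
                 log = log, out_dir = out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("vpepop run report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("  outputs: ", x$out_dir, "\n")
  invisible(x)
}
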