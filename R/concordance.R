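# Concordance of gene-level diversity with neutral-marker richness.
#
# The selection screen asks whether a gene's per-cluster diversity
# (e.g. proportion of polymorphic SNPs) co-varies with the neutral SSR
# allelic richness of the same clusters. It is quantified as a Spearman rank
# correlation with an exact permutation p-value: with <= 8 clusters every
# ordering of one vector is enumerated, so with 4 clusters the smallest
# attainable two-sided p is 1/24.

# All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Rank-concordance of diversity with neutral allelic richness
#'
#' Computes the Spearman rank correlation between a per-cluster diversity
#' statistic and per-cluster neutral (SSR) allelic richness, with an exact
#' two-sided permutation p-value (all orderings of one vector enumerated for
#' up to 8 clusters). The verdict is `"concordant_with_neutrality"` when the
#' correlation is positive and either the two cluster rankings are identical
#' or the permutation p-value is at most `alpha`; otherwise `"deviating"`.
#' If either vector is constant the correlation is undefined and the verdict
#' is `"indeterminate"`.
#'
#' @param diversity Named numeric vector: cluster -> diversity statistic.
#' @param neutral Named numeric vector: cluster -> SSR allelic richness;
#'   must have the same cluster keys.
#' @param alpha Significance level for the permutation test (default 0.05;
#'   with 4 clusters the minimum attainable p is 1/24, so identical rankings
#'   are also accepted directly).
#' @return List of class `concordance_result`: `rho`, `p_value`, `verdict`,
#'   `n_clusters`.
#' @export
concordance <- function(diversity, neutral, alpha = 0.05) {
  stopifnot(!is.null(names(diversity)), !is.null(names(neutral)))
  if (!setequal(names(diversity), names(neutral)))
    stop("diversity and neutral vectors must share cluster keys",
         call. = FALSE)
  n <- length(diversity)
  if (n < 3L) stop("need at least 3 clusters", call. = FALSE)
  x <- as.numeric(diversity)
  y <- as.numeric(neutral[names(diversity)])
  if (anyNA(x) || anyNA(y))
    stop("missing values in diversity or richness", call. = FALSE)
  out <- structure(list(rho = NA_real_, p_value = NA_real_,
                        verdict = "indeterminate", n_clusters = n),
                   class = "concordance_result")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(out)
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 8L) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p)
      stats::cor(x[p], y, method = "spearman"))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    # beyond exact-enumeration range: asymptotic approximation
    p_value <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman")$p.value)
  }
  same_ranking <- identical(rank(x, ties.method = "average"),
                            rank(y, ties.method = "average"))
  out$rho <- rho
  out$p_value <- p_value
  out$verdict <- if (rho > 0 && (same_ranking || p_value <= alpha))
    "concordant_with_neutrality" else "deviating"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, exact permutation p = %.4f (%d clusters): %s\n",
              x$rho, x$p_value, x$n_clusters, x$verdict))
  invisible(x)
}

#' Concordance table over genes and region classes
#'
#' Applies [concordance()] to every gene x region-class cell of a diversity
#' summary, using `prop_polymorphic` (by default) as the diversity
#' statistic.
#'
#' @param summary Output of [summarize_diversity()].
#' @param neutral Named numeric vector: cluster -> allelic richness.
#' @param statistic Column of `summary$diversity` to correlate (default
#'   `"prop_polymorphic"`).
#' @param alpha Significance level passed to [concordance()].
#' @return `data.frame`: gene, region_class, statistic, rho, p_value,
#'   verdict.
#' @export
concordance_table <- function(summary, neutral,
                              statistic = "prop_polymorphic", alpha = 0.05) {
  d <- summary$diversity
  cells <- unique(d[, c("gene", "region_class")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$gene == cells$gene[i] & d$region_class == cells$region_class[i], ]
    vec <- stats::setNames(sub[[statistic]], sub$cluster)
    res <- if (anyNA(vec))
      list(rho = NA_real_, p_value = NA_real_, verdict = "indeterminate")
    else concordance(vec, neutral, alpha)
    data.frame(gene = cells$gene[i], region_class = cells$region_class[i],
               statistic = statistic, rho = res$rho, p_value = res$p_value,
               verdict = res$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
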