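# Pairwise similarity of tandem-duplicated paralogs (nucleotide and protein)
# and in-silico tryptic peptide evidence across near-identical copies.
#
# "Similarity" is percent identity over a global (Needleman-Wunsch, affine
# gap) alignment, with columns inside terminal gap runs excluded so that a
# shorter fragment aligned inside a longer sequence is not penalized for the
# overhang. Alignment parameters are exposed because published similarity
# figures rarely state them.

#' Percent identity between two sequences under global alignment
#'
#' @param seq_a,seq_b Character scalars; nucleotide (ACGT...) or amino-acid
#'   strings depending on `level`.
#' @param level `"nucleotide"` or `"protein"`.
#' @param match,mismatch Substitution scores (identity scoring is used at
#'   both levels; defaults +1/-1).
#' @param gap_open,gap_extend Affine gap penalties as positive costs
#'   (defaults 5 and 1).
#' @return List of class `similarity_report`: `id_a`, `id_b`, `level`,
#'   `percent_similarity` (= 100 x identities / aligned_columns),
#'   `aligned_columns`, `identities`, `score`.
#' @export
percent_similarity <- function(seq_a, seq_b,
                               level = c("nucleotide", "protein"),
                               match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 1) {
  level <- match.arg(level)
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (level == "nucleotide") {
    ok <- "^[ACGTN]+$"
    if (!grepl(ok, seq_a) || !grepl(ok, seq_b))
      stop("non-nucleotide characters in nucleotide-level comparison",
           call. = FALSE)
    xs <- Biostrings::DNAString(seq_a); ys <- Biostrings::DNAString(seq_b)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
  } else {
    aa <- Biostrings::AA_ALPHABET
    letters_ok <- paste0("^[", paste(setdiff(aa, c("-", "+", ".")),
                                     collapse = ""), "]+$")
    if (!grepl(letters_ok, seq_a) || !grepl(letters_ok, seq_b))
      stop("non-amino-acid characters in protein-level comparison",
           call. = FALSE)
    xs <- Biostrings::AAString(seq_a); ys <- Biostrings::AAString(seq_b)
    mat <- matrix(mismatch, length(aa), length(aa), dimnames = list(aa, aa))
    diag(mat) <- match
  }
  aln <- Biostrings::pairwiseAlignment(
    xs, ys, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  # drop columns inside terminal gap runs of either sequence
  core <- function(v) {
    ng <- which(v != "-")
    seq(min(ng), max(ng))
  }
  keep <- intersect(core(pa), core(sa))
  idents <- sum(pa[keep] == sa[keep] & pa[keep] != "-")
  structure(list(id_a = deparse(substitute(seq_a)),
                 id_b = deparse(substitute(seq_b)), level = level,
                 percent_similarity = 100 * idents / length(keep),
                 aligned_columns = length(keep), identities = idents,
                 score = Biostrings::score(aln)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("%s-level global alignment: %.1f%% identity (%d/%d columns), score %.1f\n",
              x$level, x$percent_similarity, x$identities,
              x$aligned_columns, x$score))
  invisible(x)
}

#' Pairwise similarity report over a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param level `"nucleotide"` or `"protein"`.
#' @param ... Alignment parameters passed to [percent_similarity()].
#' @return `data.frame`: id_a, id_b, level, percent_similarity,
#'   aligned_columns, identities (each unordered pair once).
#' @export
similarity_matrix <- function(seqs, level = c("nucleotide", "protein"),
                              ...) {
  level <- match.arg(level)
  ids <- names(seqs)
  stopifnot(!is.null(ids))
  pairs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    r <- percent_similarity(seqs[[a]], seqs[[b]], level = level, ...)
    data.frame(id_a = a, id_b = b, level = level,
               percent_similarity = r$percent_similarity,
               aligned_columns = r$aligned_columns,
               identities = r$identities, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue is
#' proline (P). With `max_missed_cleavages > 0`, peptides spanning up to
#' that many internal uncut sites are added (concatenations of adjacent
#' fully-cleaved peptides).
#'
#' @param protein Amino-acid string.
#' @param max_missed_cleavages Non-negative integer (default 0).
#' @return Character vector of peptides, N- to C-terminal order; fully
#'   cleaved peptides first, then 1-missed, etc.
#' @export
tryptic_digest <- function(protein, max_missed_cleavages = 0L) {
  stopifnot(nzchar(protein), max_missed_cleavages >= 0L)
  res <- strsplit(toupper(protein), "")[[1L]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  base <- substring(protein, starts, ends)
  out <- base
  if (max_missed_cleavages > 0L && length(base) > 1L) {
    for (m in seq_len(min(max_missed_cleavages, length(base) - 1L))) {
      for (i in seq_len(length(base) - m)) {
        out <- c(out, paste(base[i:(i + m)], collapse = ""))
      }
    }
  }
  out
}

#' Match peptides against a proteome by exact substring search
#'
#' Every occurrence of every peptide is reported; a peptide matching more
#' than one protein is flagged as shared (paralog-ambiguous), the situation
#' expected for peptides from near-identical tandem duplicates.
#'
#' @param peptides Character vector of amino-acid strings.
#' @param proteome Named character vector (protein id -> sequence).
#' @return `data.frame`: peptide, protein_id, start (1-based offset in the
#'   protein), shared (logical: peptide matches > 1 distinct protein).
#'   Peptides without any match are absent.
#' @export
match_peptides <- function(peptides, proteome) {
  stopifnot(!is.null(names(proteome)))
  rows <- list()
  for (pep in unique(peptides)) {
    for (pid in names(proteome)) {
      hits <- gregexpr(pep, proteome[[pid]], fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, protein_id = pid, start = as.integer(hits),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(peptide = character(0), protein_id = character(0),
                      start = integer(0), shared = logical(0)))
  out <- do.call(rbind, rows)
  n_prot <- tapply(out$protein_id, out$peptide,
                   function(p) length(unique(p)))
  out$shared <- unname(n_prot[out$peptide] > 1L)
  rownames(out) <- NULL
  out
}

#' Read peptides from a plain-text file, one per line
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of peptides.
#' @export
read_peptides <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
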