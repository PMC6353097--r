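#' Summarize an alignment
#'
#' Computes the quantities a result is judged by: match length `n`, RMSD
#' after optimal superposition, the mirror-image diagnostic RMSD, all five
#' scores (at their default constants, with TM under the requested
#' normalization), the block size multiset, and the number of reverse
#' blocks.
#'
#' @param a a nonempty [as_alignment()].
#' @param chain_a,chain_b the two [protein_chain()]s.
#' @param spec a [score_spec()] supplying the constants and TM
#'   normalization used for the score entries.
#' @return An object of class `alignment_summary`: `list(n, rmsd,
#'   mirror_rmsd, scores, block_sizes, n_reverse_blocks)`.
#' @export
summarize_alignment <- function(a, chain_a, chain_b, spec = score_spec()) {
  a <- as_alignment(a)
  if (n_pairs(a) == 0L) stop("cannot summarize an empty alignment")
  bl <- blocks_of(a)
  funs <- c("DALI", "SP", "SO", "SO_L", "TM")
  scores <- setNames(vapply(funs, function(f) {
    s <- spec
    s$fun <- f
    align_score(a, chain_a, chain_b, s)
  }, numeric(1L)), funs)
  structure(list(
    n = n_pairs(a),
    rmsd = as.numeric(aligned_rmsd(a, chain_a, chain_b)),
    mirror_rmsd = mirror_rmsd(a, chain_a, chain_b),
    scores = scores,
    block_sizes = sort(vapply(bl, `[[`, integer(1L), "size")),
    n_reverse_blocks = sum(vapply(bl, function(b)
      b$orientation == "reverse" && b$size >= 2L, logical(1L)))),
    class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("<alignment_summary> n = %d, rmsd = %.3f A (mirror %.3f A)\n",
              x$n, x$rmsd, x$mirror_rmsd))
  cat(sprintf("  blocks: %s (%d reverse)\n",
              paste(x$block_sizes, collapse = "+"), x$n_reverse_blocks))
  cat(sprintf("  scores: %s\n",
              paste(sprintf("%s=%.4g", names(x$scores), x$scores),
                    collapse = ", ")))
  invisible(x)
}

#' Precision and recall against a reference alignment
#'
#' A test pair is a true positive only when exactly the same `(i, j)` pair
#' occurs in the reference (set intersection; off-by-one near-misses get
#' no credit).  Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`.
#' Degenerate cases: an empty test alignment has precision 0 unless the
#' reference is empty too (then 1); an empty reference gives recall 1 if
#' the test is also empty, else 0.
#'
#' @param test,reference alignments over the same chain pair.
#' @return `c(precision = , recall = )`.
#' @export
precision_recall <- function(test, reference) {
  mt <- pair_matrix(test)
  mr <- pair_matrix(reference)
  kt <- paste(mt[, 1L], mt[, 2L])
  kr <- paste(mr[, 1L], mr[, 2L])
  tp <- length(intersect(kt, kr))
  precision <- if (length(kt) == 0L) as.numeric(length(kr) == 0L)
               else tp / length(kt)
  recall <- if (length(kr) == 0L) as.numeric(length(kt) == 0L)
            else tp / length(kr)
  c(precision = precision, recall = recall)
}

#' Pareto comparison of two alignment summaries
#'
#' One alignment dominates another when it has at least the match length
#' and at most the RMSD, with at least one strict; alignments trading
#' length against RMSD are incomparable.
#'
#' @param s1,s2 [summarize_alignment()] results (or any lists with `n` and
#'   `rmsd`) over the same chain pair.
#' @return `"first_wins"`, `"second_wins"`, `"tie"`, or `"incomparable"`.
#' @export
pareto_compare <- function(s1, s2) {
  stopifnot(is.numeric(s1$n), is.numeric(s1$rmsd),
            is.numeric(s2$n), is.numeric(s2$rmsd))
  if (s1$n == s2$n && s1$rmsd == s2$rmsd) return("tie")
  if (s1$n >= s2$n && s1$rmsd <= s2$rmsd) return("first_wins")
  if (s2$n >= s1$n && s2$rmsd <= s1$rmsd) return("second_wins")
  "incomparable"
}
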