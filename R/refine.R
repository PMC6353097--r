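#' Enumerate admissible refinement moves
#'
#' The refiner's move set, evaluated against the current alignment:
#'
#' * `add_pair` -- any unaligned `(i, j)` whose addition keeps every block
#'   at or above the minimum size (with a minimum block size above 1 this
#'   means extending an existing block; unconstrained when it is 1);
#' * `delete_pair` -- any pair whose removal leaves every resulting block
#'   at or above the minimum size;
#' * `add_block` -- a full run of exactly `min_block_size` pairs, forward
#'   or (when permitted) reverse, at any placement over unaligned residues
#'   (only when the minimum block size is above 1: no single-pair addition
#'   can ever seed a new block there, so without these the refiner could
#'   never grow new aligned regions);
#' * `delete_block` -- an entire block.
#'
#' Each move's `delta` is the score after applying it minus the current
#' score, with a full superposition refit per candidate for the
#' superposition-based scores.  When `touched` is given, only moves sharing
#' a residue (in either chain) with it are enumerated -- the bookkeeping
#' the refinement loop uses after accepting a move.
#'
#' @param a a constraint-satisfying [as_alignment()].
#' @param chain_a,chain_b the two [protein_chain()]s.
#' @param spec a [score_spec()] (an SO objective is evaluated through its
#'   logistic surrogate, like the optimizers).
#' @param c a [constraints()] object.
#' @param touched optional `list(a = <indices in A>, b = <indices in B>)`.
#' @param improving_only drop moves whose delta is not an improvement?
#' @return A data frame with columns `kind`, `delta` and a list column
#'   `pairs` (each an n x 2 matrix), sorted best-first under the
#'   deterministic tie-break (kind order `delete_pair`, `add_pair`,
#'   `delete_block`, `add_block`, then `i`, then `j`).
#' @export
admissible_moves <- function(a, chain_a, chain_b, spec = score_spec(), c,
                             touched = NULL, improving_only = FALSE) {
  stopifnot(inherits(c, "constraints"))
  args <- score_args(a, chain_a, chain_b, objective_spec(spec))
  ta <- if (is.null(touched)) integer() else as.integer(touched$a)
  tb <- if (is.null(touched)) integer() else as.integer(touched$b)
  res <- cpp_moves(args$pairs, args$A, args$B, args$DA, args$DB, args$spec,
                   c$min_block_size, c$allow_reverse, 1e-9, improving_only,
                   ta, tb, !is.null(touched))
  out <- data.frame(kind = res$kind, delta = res$delta,
                    stringsAsFactors = FALSE)
  out$pairs <- res$pairs
  out
}

#' Best-first greedy refinement of an alignment
#'
#' Local optimization by the move-list algorithm: build the list of all
#' score-improving moves with their residues and deltas; repeatedly take
#' the best-delta move, re-evaluate its delta against the current
#' alignment, and accept it only if it still improves; on acceptance,
#' drop list entries sharing a residue with the accepted move and add the
#' newly improving moves among those touching its residues; a move that no
#' longer improves is discarded and the next best tried.  A round ends
#' when the list is empty; because every accepted move changes the global
#' superposition, full move-list rebuilds are repeated until one finds no
#' improving move, so the result is a genuine single-move local optimum.
#'
#' The input is first projected onto the constraint-satisfying set by
#' [enforce_constraints()]; every intermediate alignment satisfies the
#' constraints, and the accepted-score trace is strictly increasing, which
#' guarantees termination.  The final score is never below the (projected)
#' input score.
#'
#' @inheritParams admissible_moves
#' @param a0 the starting [as_alignment()] (any; it is projected first).
#' @param eps smallest score difference counted as an improvement
#'   (floating-point refits oscillate at machine precision).
#' @return An object of class `refinement_result`: `list(alignment, score,
#'   score_trace, n_accepted, n_evaluated)`, where `score` is on the
#'   objective actually optimized (`SO_L` for an SO request; re-evaluate
#'   with [so_score()] for reporting).
#' @examples
#' ch <- make_synthetic_chain("walk", 20, seed = 3)
#' start <- as_alignment(cbind(1:10, 1:10))
#' r <- refine_alignment(start, ch, ch, score_spec("TM"),
#'                       constraints(1, TRUE))
#' r$score   # 1: the full 20-pair identity alignment is recovered
#' @export
refine_alignment <- function(a0, chain_a, chain_b, spec = score_spec(), c,
                             eps = 1e-9) {
  stopifnot(inherits(c, "constraints"))
  a <- enforce_constraints(a0, c, chain_length(chain_a),
                           chain_length(chain_b))
  args <- score_args(a, chain_a, chain_b, objective_spec(spec))
  res <- cpp_refine(args$pairs, args$A, args$B, args$DA, args$DB, args$spec,
                    c$min_block_size, c$allow_reverse, eps)
  structure(list(alignment = as_alignment(res$pairs), score = res$score,
                 score_trace = res$score_trace,
                 n_accepted = res$n_accepted,
                 n_evaluated = res$n_evaluated),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(
    "<refinement_result> score %.6g, %d pairs, %d accepted / %.0f evaluated moves\n",
    x$score, n_pairs(x$alignment), x$n_accepted, x$n_evaluated))
  invisible(x)
}

#' Exhaustive best alignment for tiny chains
#'
#' Enumerates every constraint-satisfying nonempty alignment between two
#' chains of at most 10 residues and returns the best-scoring one.  This
#' is a brute-force global-optimality oracle used to validate the CSA
#' search on small instances; it is far too slow for real chains.
#'
#' @inheritParams admissible_moves
#' @return `list(score, alignment, n_checked)`.
#' @export
best_alignment_exhaustive <- function(chain_a, chain_b, spec = score_spec(),
                                      c) {
  stopifnot(inherits(c, "constraints"))
  empty <- as_alignment(matrix(integer(), 0L, 2L))
  args <- score_args(empty, chain_a, chain_b, objective_spec(spec))
  res <- cpp_enumerate_best(args$A, args$B, args$DA, args$DB, args$spec,
                            c$min_block_size, c$allow_reverse)
  list(score = res$score, alignment = as_alignment(res$pairs),
       n_checked = res$n_checked)
}
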