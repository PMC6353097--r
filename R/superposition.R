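#' Kabsch superposition
#'
#' Least-RMSD proper rigid-body fit of one point set onto another.
#' Reflections are excluded: the rotation determinant is forced to +1 by
#' the usual sign correction on the smallest singular vector, so a chiral
#' set fitted to its mirror image keeps a positive RMSD.  The fitted
#' position of a point `q` of `Q` is `rotation %*% q + translation`.
#'
#' @param P,Q n x 3 coordinate matrices (Q is mapped onto P); `n >= 1`.
#'   Degenerate inputs (1-2 points, collinear sets) return a deterministic
#'   optimal transform with the same minimal RMSD.
#' @return An object of class `superposition`: `list(rotation, translation,
#'   rmsd)`.
#' @examples
#' P <- matrix(rnorm(18), 6, 3)
#' th <- 0.7
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' kabsch(P, P %*% t(R))$rmsd   # exact recovery: 0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q must have the same dimensions")
  if (ncol(P) != 3L) stop("points must be 3D (n x 3)")
  if (nrow(P) < 1L) stop("at least one point is required")
  storage.mode(P) <- "double"
  storage.mode(Q) <- "double"
  f <- cpp_kabsch(P, Q)
  structure(list(rotation = f$rotation, translation = drop(f$translation),
                 rmsd = f$rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' RMSD of an alignment after optimal superposition
#'
#' `aligned_rmsd()` superposes the aligned C-alpha subsets by [kabsch()]
#' and returns the fit.  `mirror_rmsd()` does the same after mirroring
#' chain B; when `mirror_rmsd` is far below `aligned_rmsd`, the alignment
#' matches the reflection of B rather than B itself -- the mirror-image
#' pathology that distance-matrix scores such as DALI cannot see.  Both
#' values are reported together in every run summary for that reason.
#'
#' @param a a nonempty [as_alignment()].
#' @param chain_a,chain_b the two [protein_chain()]s.
#' @return `aligned_rmsd()`: the RMSD in Angstrom, with the full
#'   `superposition` attached as attribute `"superposition"`.
#'   `mirror_rmsd()`: the mirrored-B RMSD in Angstrom.
#' @export
aligned_rmsd <- function(a, chain_a, chain_b) {
  a <- as_alignment(a)
  if (n_pairs(a) == 0L) stop("alignment is empty")
  m <- pair_matrix(a)
  if (max(m[, 1L]) > chain_length(chain_a) ||
      max(m[, 2L]) > chain_length(chain_b))
    stop("alignment indices exceed chain lengths")
  f <- kabsch(chain_a$coords[m[, 1L], , drop = FALSE],
              chain_b$coords[m[, 2L], , drop = FALSE])
  structure(f$rmsd, superposition = f)
}

#' @rdname aligned_rmsd
#' @export
mirror_rmsd <- function(a, chain_a, chain_b) {
  as.numeric(aligned_rmsd(a, chain_a, mirror_chain(chain_b)))
}
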