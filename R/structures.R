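#' Protein chain objects
#'
#' A `protein_chain` holds one chain's ordered C-alpha trace: a coordinate
#' matrix (one row per residue, Angstrom) plus the author residue labels
#' (residue number, insertion code, residue name).  Residues are indexed
#' 1..L in extraction order throughout the package; author residue numbers
#' are metadata only, since insertion codes and gaps make them unsafe as
#' array indices.
#'
#' @param coords numeric L x 3 matrix of C-alpha positions in Angstrom.
#' @param chain_id single character chain identifier.
#' @param residue_labels data frame with columns `resno`, `icode`, `resname`
#'   (one row per residue); generated labels are used when omitted.
#' @return An object of class `protein_chain`.
#' @examples
#' ch <- make_synthetic_chain("helix", 20, seed = 1)
#' chain_length(ch)
#' @export
protein_chain <- function(coords, chain_id = "A", residue_labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  L <- nrow(coords)
  if (L < 1L) stop("a chain needs at least one residue")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (L > 1L) {
    step <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                            coords[-L, , drop = FALSE])^2))
    if (any(step <= 0)) stop("duplicated consecutive C-alpha positions")
  }
  if (is.null(residue_labels)) {
    residue_labels <- data.frame(resno = seq_len(L), icode = "",
                                 resname = "ALA", stringsAsFactors = FALSE)
  }
  if (nrow(residue_labels) != L)
    stop("residue_labels must have one row per residue")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(chain_id = as.character(chain_id)[1L],
                 residue_labels = residue_labels, coords = coords),
            class = "protein_chain")
}

#' @rdname protein_chain
#' @param x a `protein_chain`.
#' @export
chain_length <- function(x) {
  stopifnot(inherits(x, "protein_chain"))
  nrow(x$coords)
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain> chain %s, %d residues\n", x$chain_id,
              chain_length(x)))
  invisible(x)
}

#' Read one chain's C-alpha trace from a PDB file
#'
#' Extracts one C-alpha atom per residue, in chain order, from the selected
#' model.  Residues without a C-alpha are skipped.  When a residue has
#' alternate-location C-alpha records, the highest-occupancy one is taken
#' (ties: first listed), so the parse is deterministic.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier to extract.
#' @param model_index 1-based model number (for multi-model files).
#' @return A [protein_chain()].
#' @export
read_chain <- function(path, chain_id, model_index = 1L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmod)
    stop(sprintf("model %d not present (file has %d model%s)", model_index,
                 nmod, if (nmod == 1L) "" else "s"))
  if (!chain_id %in% unique(atoms$chain))
    stop(sprintf("unknown chain '%s' (available: %s)", chain_id,
                 paste(unique(atoms$chain), collapse = ", ")))
  sel <- which(atoms$chain == chain_id & atoms$elety == "CA" &
                 atoms$type %in% c("ATOM", "HETATM"))
  if (length(sel) == 0L)
    stop(sprintf("chain '%s' has no C-alpha atoms", chain_id))
  a <- atoms[sel, , drop = FALSE]
  a$icode <- ifelse(is.na(a$insert), "", a$insert)
  key <- paste(a$resno, a$icode, sep = "|")
  # keep one CA per residue: highest occupancy, ties by file order
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- unlist(lapply(split(seq_along(key), factor(key, unique(key))),
                        function(rows) rows[which.max(occ[rows])]),
                 use.names = FALSE)
  keep <- sort(keep)
  a <- a[keep, , drop = FALSE]
  idx <- sel[keep]
  xyz <- pdb$xyz[model_index, , drop = TRUE]
  coords <- cbind(xyz[3L * (idx - 1L) + 1L], xyz[3L * (idx - 1L) + 2L],
                  xyz[3L * (idx - 1L) + 3L])
  protein_chain(coords, chain_id = chain_id,
                residue_labels = data.frame(resno = a$resno, icode = a$icode,
                                            resname = a$resid,
                                            stringsAsFactors = FALSE))
}

#' C-alpha distance matrix of a chain
#'
#' @param chain a [protein_chain()].
#' @return Symmetric L x L matrix of C-alpha--C-alpha distances in Angstrom.
#' @export
distance_matrix <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  as.matrix(dist(chain$coords))
}

#' Generate a synthetic C-alpha chain
#'
#' `"helix"` builds an ideal alpha-helical trace (1.5 A rise, 100 degree
#' turn, 2.3 A radius, giving ~3.8 A between consecutive C-alphas);
#' `"walk"` builds a self-avoiding random walk with 3.8 A steps and a
#' minimum non-bonded separation of 3.5 A.  Both are deterministic given
#' `seed`.
#'
#' @param kind `"helix"` or `"walk"`.
#' @param length number of residues (>= 2).
#' @param seed integer seed driving the walk (ignored for helices).
#' @param max_tries retry budget per step for the self-avoiding walk.
#' @return A [protein_chain()].
#' @export
make_synthetic_chain <- function(kind = c("helix", "walk"), length, seed = 1L,
                                 max_tries = 500L) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 2L) stop("length must be at least 2")
  if (kind == "helix") {
    t <- (seq_len(length) - 1L) * 100 * pi / 180
    coords <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(length) - 1L))
    return(protein_chain(coords, chain_id = "A"))
  }
  with_preserved_rng(seed, {
    step <- 3.8
    min_sep <- 3.5
    coords <- matrix(0, length, 3L)
    i <- 2L
    tries <- 0L
    while (i <= length) {
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + step * dir
      ok <- TRUE
      if (i > 2L) {
        d2 <- rowSums((coords[seq_len(i - 2L), , drop = FALSE] -
                         matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
        ok <- all(d2 >= min_sep^2)
      }
      if (ok) {
        coords[i, ] <- cand
        i <- i + 1L
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries >= max_tries) {
          # back up one residue and retry; give up if stuck at the start
          if (i <= 3L) stop("self-avoiding walk failed within retry budget")
          i <- i - 1L
          tries <- 0L
        }
      }
    }
    protein_chain(coords, chain_id = "A")
  })
}

#' Permuted / reversed noisy copy of a chain, with ground truth
#'
#' Builds a second chain whose residue order is the concatenation of the
#' given source segments (each optionally reversed), with i.i.d. Gaussian
#' noise added per coordinate, and returns the ground-truth alignment
#' mapping source residues to their positions in the permuted chain.  This
#' emulates circular permutation, segment swaps and reversed segments --
#' the arrangements a non-sequential aligner must recover.
#'
#' @param chain source [protein_chain()].
#' @param segment_plan data frame with columns `start`, `end` (1-based
#'   inclusive source indices) and logical `reverse`; segments must be
#'   disjoint.  Rows are emitted in order into the new chain.
#' @param noise_sigma Gaussian noise scale per coordinate (Angstrom).
#' @param seed integer seed for the noise.
#' @return `list(chain =` permuted [protein_chain()], `truth =` ground-truth
#'   [as_alignment()] with `i` in the source chain and `j` in the new one`)`.
#' @examples
#' ch <- make_synthetic_chain("walk", 40, seed = 7)
#' plan <- data.frame(start = c(21, 1), end = c(40, 20),
#'                    reverse = c(FALSE, FALSE))
#' pp <- make_permuted_pair(ch, plan, noise_sigma = 0, seed = 1)
#' n_pairs(pp$truth)
#' @export
make_permuted_pair <- function(chain, segment_plan, noise_sigma = 0,
                               seed = 1L) {
  stopifnot(inherits(chain, "protein_chain"))
  sp <- as.data.frame(segment_plan)
  if (!all(c("start", "end", "reverse") %in% names(sp)))
    stop("segment_plan needs columns start, end, reverse")
  L <- chain_length(chain)
  if (any(sp$start < 1L | sp$end > L | sp$start > sp$end))
    stop("segment out of range")
  src <- unlist(mapply(seq, sp$start, sp$end, SIMPLIFY = FALSE))
  if (anyDuplicated(src)) stop("overlapping segments in segment_plan")
  order_src <- unlist(mapply(function(s, e, r) if (r) seq(e, s) else seq(s, e),
                             sp$start, sp$end, sp$reverse, SIMPLIFY = FALSE))
  coords <- chain$coords[order_src, , drop = FALSE]
  if (noise_sigma > 0) {
    coords <- with_preserved_rng(seed, {
      coords + matrix(stats::rnorm(length(coords), sd = noise_sigma),
                      nrow(coords), 3L)
    })
  }
  newchain <- protein_chain(coords, chain_id = "B",
                            residue_labels = chain$residue_labels[order_src, ,
                                                                  drop = FALSE])
  truth <- as_alignment(cbind(i = order_src, j = seq_along(order_src)))
  list(chain = newchain, truth = truth)
}

#' Mirror image of a chain
#'
#' Reflects the coordinates through the yz-plane (x is negated).  Internal
#' distances are unchanged, but the chain's handedness flips -- the
#' construction behind the mirror-image diagnostic of [mirror_rmsd()].
#'
#' @param chain a [protein_chain()].
#' @return The reflected [protein_chain()].
#' @export
mirror_chain <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  coords <- chain$coords
  coords[, 1L] <- -coords[, 1L]
  protein_chain(coords, chain_id = chain$chain_id,
                residue_labels = chain$residue_labels)
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a PDB file for a chain (or a superposed pair)
#'
#' `write_chain_pdb()` writes one chain as standard ATOM records.
#' `write_superposed_pdb()` writes chain A unchanged and chain B after
#' applying a [kabsch()] superposition, as a two-chain PDB file for visual
#' inspection.
#'
#' @param chain,chain_a,chain_b [protein_chain()] objects.
#' @param path output file path.
#' @param superposition a superposition as returned by [kabsch()] or
#'   [aligned_rmsd()]; when `NULL`, the fit over `alignment` is computed.
#' @param alignment alignment used to compute the fit when `superposition`
#'   is `NULL`.
#' @return The path, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "protein_chain"))
  L <- chain_length(chain)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(chain$coords)),
                   resno = chain$residue_labels$resno,
                   resid = chain$residue_labels$resname,
                   insert = chain$residue_labels$icode,
                   chain = rep(chain$chain_id, L),
                   elety = rep("CA", L))
  invisible(path)
}

#' @rdname write_chain_pdb
#' @export
write_superposed_pdb <- function(chain_a, chain_b, path, superposition = NULL,
                                 alignment = NULL) {
  stopifnot(inherits(chain_a, "protein_chain"),
            inherits(chain_b, "protein_chain"))
  if (is.null(superposition)) {
    if (is.null(alignment)) stop("give a superposition or an alignment")
    p <- unclass(alignment)
    superposition <- kabsch(chain_a$coords[p[, 1L], , drop = FALSE],
                            chain_b$coords[p[, 2L], , drop = FALSE])
  }
  bt <- chain_b$coords %*% t(superposition$rotation) +
    matrix(superposition$translation, chain_length(chain_b), 3L, byrow = TRUE)
  la <- chain_length(chain_a)
  lb <- chain_length(chain_b)
  ida <- chain_a$chain_id
  idb <- chain_b$chain_id
  if (identical(substr(idb, 1L, 1L), substr(ida, 1L, 1L)))
    idb <- if (substr(ida, 1L, 1L) == "B") "C" else "B"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(rbind(chain_a$coords, bt))),
                   resno = c(chain_a$residue_labels$resno,
                             chain_b$residue_labels$resno),
                   resid = c(chain_a$residue_labels$resname,
                             chain_b$residue_labels$resname),
                   chain = c(rep(substr(ida, 1L, 1L), la),
                             rep(substr(idb, 1L, 1L), lb)),
                   elety = rep("CA", la + lb))
  invisible(path)
}
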