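#' Non-sequential alignments
#'
#' An alignment is a one-to-one set of residue index pairs `(i, j)` between
#' chains A and B, stored as a two-column integer matrix sorted by `i`
#' (1-based contiguous indices over each chain's extracted C-alpha list).
#' No residue of either chain may appear twice.  Aligned segments need not
#' follow chain order, so the pair set decomposes into maximal *blocks*:
#' forward blocks advance both indices (`(i+1, j+1)`), reverse blocks
#' advance `i` while `j` retreats (`(i+1, j-1)`).
#'
#' @param pairs two-column matrix (or data frame) of residue index pairs,
#'   columns `i` then `j`.
#' @return An object of class `alignment`.
#' @examples
#' a <- as_alignment(cbind(i = 1:4, j = 1:4))
#' n_pairs(a)
#' blocks_of(a)
#' @export
as_alignment <- function(pairs) {
  if (inherits(pairs, "alignment")) return(pairs)
  m <- as.matrix(pairs)
  if (length(m) == 0L) m <- matrix(integer(), 0L, 2L)
  if (ncol(m) != 2L) stop("pairs must have two columns (i, j)")
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 1L)) stop("residue indices must be positive integers")
  if (anyDuplicated(m[, 1L]) || anyDuplicated(m[, 2L]))
    stop("alignment is not one-to-one: a residue index appears twice")
  m <- m[order(m[, 1L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  structure(m, class = "alignment")
}

#' @rdname as_alignment
#' @param a an `alignment`.
#' @export
n_pairs <- function(a) nrow(unclass(as_alignment(a)))

#' @export
print.alignment <- function(x, ...) {
  b <- blocks_of(x)
  cat(sprintf("<alignment> %d pairs in %d block%s\n", n_pairs(x), length(b),
              if (length(b) == 1L) "" else "s"))
  invisible(x)
}

# internal: plain integer matrix of pairs
pair_matrix <- function(a) {
  m <- unclass(as_alignment(a))
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

#' Decompose an alignment into maximal blocks
#'
#' Every pair belongs to exactly one maximal run that is consecutive in
#' both chains.  Runs are grown greedily in increasing `i`, trying forward
#' continuation before reverse, which makes the decomposition
#' deterministic.  Singletons are forward by convention (a single pair has
#' no direction).
#'
#' @param a an [as_alignment()].
#' @return A list of blocks, each `list(pairs = <n x 2 matrix>,
#'   orientation = "forward"|"reverse", size = n)`.
#' @export
blocks_of <- function(a) {
  a <- as_alignment(a)
  if (n_pairs(a) == 0L) return(list())
  bl <- cpp_blocks(pair_matrix(a))
  ids <- bl$block
  lapply(seq_along(bl$size), function(b) {
    list(pairs = bl$pairs[ids == b, , drop = FALSE],
         orientation = if (bl$orientation[b] == -1L) "reverse" else "forward",
         size = bl$size[b])
  })
}

#' Alignment constraints
#'
#' Minimum block size and reverse-alignment permission.  A minimum block
#' size of 4 with reverse alignment allowed mirrors the constraint DALI
#' applies to prevent fragmented, biologically dubious alignments.
#'
#' @param min_block_size smallest permitted block size (>= 1).
#' @param allow_reverse are reverse blocks (size >= 2) permitted?
#' @return An object of class `constraints`.
#' @export
constraints <- function(min_block_size = 4L, allow_reverse = TRUE) {
  min_block_size <- as.integer(min_block_size)
  if (is.na(min_block_size) || min_block_size < 1L)
    stop("min_block_size must be >= 1")
  structure(list(min_block_size = min_block_size,
                 allow_reverse = isTRUE(allow_reverse)),
            class = "constraints")
}

#' @export
print.constraints <- function(x, ...) {
  cat(sprintf("<constraints> min block size %d, reverse %s\n",
              x$min_block_size,
              if (x$allow_reverse) "allowed" else "forbidden"))
  invisible(x)
}

#' Check an alignment against constraints
#'
#' @param a an [as_alignment()].
#' @param c a [constraints()] object.
#' @return Character vector of violation messages; empty when the alignment
#'   satisfies the constraints.  Singleton blocks never count as reverse
#'   violations.
#' @export
validate_alignment <- function(a, c) {
  stopifnot(inherits(c, "constraints"))
  out <- character()
  for (b in blocks_of(a)) {
    if (b$size < c$min_block_size)
      out <- c(out, sprintf("block of size %d at i=%d is below minimum %d",
                            b$size, b$pairs[1L, 1L], c$min_block_size))
    if (!c$allow_reverse && b$orientation == "reverse" && b$size >= 2L)
      out <- c(out, sprintf("reverse block of size %d at i=%d is forbidden",
                            b$size, b$pairs[1L, 1L]))
  }
  out
}

#' Project an alignment onto the constraint-satisfying set
#'
#' Two-step preprocessing used before refinement and after every CSA
#' operator.  (1) If reverse blocks are forbidden, all reverse blocks of
#' size 2 or more are removed; if nothing remains, one pair per *original* block is
#' kept instead, positioned at the block center (C-terminal of the two
#' central pairs for even sizes).  (2) Blocks smaller than the minimum are
#' removed; if nothing remains, every block of the largest block size in
#' the step-2 input is extended to the minimum size, growing symmetrically
#' around the block along its own orientation with the C-terminal side
#' preferred on odd remainders, skipping positions that hit chain ends or
#' one-to-one conflicts.
#'
#' @param a an [as_alignment()].
#' @param c a [constraints()] object.
#' @param l_a,l_b chain lengths of A and B (bounds for block extension).
#' @return A constraint-satisfying [as_alignment()]; errors if both
#'   fallbacks fail to produce one.
#' @export
enforce_constraints <- function(a, c, l_a, l_b) {
  stopifnot(inherits(c, "constraints"))
  a <- as_alignment(a)
  l_a <- as.integer(l_a)
  l_b <- as.integer(l_b)

  # step 1: reverse blocks
  bl <- blocks_of(a)
  if (!c$allow_reverse && length(bl) > 0L) {
    keep <- bl[vapply(bl, function(b)
      b$orientation == "forward" || b$size < 2L, logical(1L))]
    if (length(keep) > 0L) {
      a <- as_alignment(do.call(rbind, lapply(keep, `[[`, "pairs")))
    } else {
      centers <- do.call(rbind, lapply(bl, function(b)
        b$pairs[b$size %/% 2L + 1L, , drop = FALSE]))
      a <- as_alignment(centers)
    }
  }

  # step 2: minimum block size
  bl <- blocks_of(a)
  if (length(bl) > 0L && c$min_block_size > 1L) {
    big <- bl[vapply(bl, function(b) b$size >= c$min_block_size, logical(1L))]
    if (length(big) > 0L) {
      a <- as_alignment(do.call(rbind, lapply(big, `[[`, "pairs")))
    } else {
      mx <- max(vapply(bl, `[[`, integer(1L), "size"))
      grow <- bl[vapply(bl, function(b) b$size == mx, logical(1L))]
      pool <- pair_matrix(a)
      ext <- list()
      for (b in grow) {
        got <- extend_block(b, c$min_block_size, l_a, l_b,
                            rbind(pool, do.call(rbind, c(ext, list(NULL)))))
        ext <- c(ext, list(got))
      }
      aug <- as_alignment(rbind(pool, do.call(rbind, c(ext, list(NULL)))))
      bl2 <- blocks_of(aug)
      ok <- bl2[vapply(bl2, function(b) b$size >= c$min_block_size,
                       logical(1L))]
      if (length(ok) == 0L)
        stop("cannot satisfy constraints: block extension failed")
      a <- as_alignment(do.call(rbind, lapply(ok, `[[`, "pairs")))
    }
  }
  if (n_pairs(a) == 0L)
    stop("cannot satisfy constraints: no pairs remain")
  viol <- validate_alignment(a, c)
  if (length(viol) > 0L)
    stop("cannot satisfy constraints: ", viol[1L])
  a
}

# extension positions for one block, alternating C-terminal first;
# a side closes at its first invalid position (the run must stay contiguous)
extend_block <- function(b, target, l_a, l_b, occupied) {
  need <- target - b$size
  if (need <= 0L) return(NULL)
  dir <- if (b$orientation == "reverse") -1L else 1L
  first <- b$pairs[1L, ]
  last <- b$pairs[b$size, ]
  occ_i <- occupied[, 1L]
  occ_j <- occupied[, 2L]
  out <- matrix(integer(), 0L, 2L)
  c_open <- TRUE
  n_open <- TRUE
  step_c <- 1L
  step_n <- 1L
  side_c <- TRUE
  while (need > 0L && (c_open || n_open)) {
    if (side_c && !c_open) side_c <- FALSE
    if (!side_c && !n_open) side_c <- TRUE
    if (side_c) {
      cand <- c(last[1L] + step_c, last[2L] + dir * step_c)
      if (cand[1L] > l_a || cand[2L] < 1L || cand[2L] > l_b ||
          cand[1L] %in% occ_i || cand[2L] %in% occ_j) {
        c_open <- FALSE
      } else {
        out <- rbind(out, cand)
        occ_i <- c(occ_i, cand[1L])
        occ_j <- c(occ_j, cand[2L])
        step_c <- step_c + 1L
        need <- need - 1L
      }
      side_c <- FALSE
    } else {
      cand <- c(first[1L] - step_n, first[2L] - dir * step_n)
      if (cand[1L] < 1L || cand[2L] < 1L || cand[2L] > l_b ||
          cand[1L] %in% occ_i || cand[2L] %in% occ_j) {
        n_open <- FALSE
      } else {
        out <- rbind(out, cand)
        occ_i <- c(occ_i, cand[1L])
        occ_j <- c(occ_j, cand[2L])
        step_n <- step_n + 1L
        need <- need - 1L
      }
      side_c <- TRUE
    }
  }
  if (nrow(out) == 0L) NULL else out
}

#' Distance between two alignments
#'
#' `1 - |intersection| / max(|a|, |b|)`: 0 for identical pair sets, 1 for
#' disjoint ones.  The distance of any nonempty alignment to the empty
#' alignment is 1 (empty vs empty is 0).  This is the diversity metric the
#' CSA bank anneals over.
#'
#' @param a,b alignments over the same chain pair.
#' @return A number in `[0, 1]`.
#' @export
alignment_distance <- function(a, b) {
  ma <- pair_matrix(a)
  mb <- pair_matrix(b)
  if (nrow(ma) == 0L && nrow(mb) == 0L) return(0)
  if (nrow(ma) == 0L || nrow(mb) == 0L) return(1)
  ka <- paste(ma[, 1L], ma[, 2L])
  kb <- paste(mb[, 1L], mb[, 2L])
  1 - length(intersect(ka, kb)) / max(length(ka), length(kb))
}

#' Alignment TSV files
#'
#' The on-disk format is bit-exact and 0-based: comment lines start with
#' `#`, the header carries `#chainA <id> L=<n>` and `#chainB <id> L=<n>`,
#' then one `i<TAB>j` line per pair.  `read_alignment_tsv()` also accepts
#' 1-based files via `one_based = TRUE`.  In-memory alignments are 1-based;
#' the offset is applied at the file boundary.
#'
#' @param path file path.
#' @param one_based is the file 1-based rather than the default 0-based?
#' @param a an [as_alignment()].
#' @param chain_a_id,chain_b_id,l_a,l_b header metadata (ids and chain
#'   lengths).
#' @return `read_alignment_tsv()`: an [as_alignment()] with attributes
#'   `chain_a_id`, `chain_b_id`, `l_a`, `l_b` when present in the header.
#'   `write_alignment_tsv()`: the path, invisibly.
#' @export
read_alignment_tsv <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^#chain[AB] ", lines, value = TRUE)
  for (h in hdr) {
    parts <- strsplit(sub("^#", "", h), "[ =]+")[[1L]]
    which_chain <- tolower(substr(parts[1L], 6L, 6L))
    meta[[paste0("chain_", which_chain, "_id")]] <- parts[2L]
    meta[[paste0("l_", which_chain)]] <- as.integer(parts[4L])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    a <- as_alignment(matrix(integer(), 0L, 2L))
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) < 2L))
      stop("malformed alignment line (expected i<TAB>j): ", path)
    m <- t(vapply(fields, function(f) as.integer(f[1:2]), integer(2L)))
    if (anyNA(m)) stop("non-integer residue index in ", path)
    if (!one_based) m <- m + 1L
    a <- as_alignment(m)
  }
  for (nm in names(meta)) attr(a, nm) <- meta[[nm]]
  a
}

#' @rdname read_alignment_tsv
#' @export
write_alignment_tsv <- function(a, path, chain_a_id = "A", chain_b_id = "B",
                                l_a = NA_integer_, l_b = NA_integer_) {
  m <- pair_matrix(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#chainA %s L=%d", chain_a_id, as.integer(l_a)),
               sprintf("#chainB %s L=%d", chain_b_id, as.integer(l_b))), con)
  if (nrow(m) > 0L)
    writeLines(sprintf("%d\t%d", m[, 1L] - 1L, m[, 2L] - 1L), con)
  invisible(path)
}
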