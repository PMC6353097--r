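#' CSA configuration
#'
#' Hyper-parameters of the conformational space annealing search.  The
#' annealing variable is the bank distance cutoff `D_cut` (measured with
#' [alignment_distance()], so it lives in `[0, 1]`): it starts at
#' `dcut_start_factor` times the average pairwise bank distance and is
#' multiplied by `dcut_ratio` each round down to `dcut_min`, playing the
#' role of temperature -- large early (diverse bank), small late (members
#' settle into distinct local optima).
#'
#' @param bank_size number of bank members (>= 2).
#' @param n_seeds_per_round seed members picked per round (least recently
#'   used first, for coverage of the bank).
#' @param n_trials_per_seed trial alignments generated per seed per round.
#' @param dcut_start_factor initial `D_cut` as a fraction of the average
#'   pairwise bank distance.
#' @param dcut_ratio per-round multiplicative `D_cut` reduction (in (0,1)).
#' @param dcut_min floor for `D_cut` (> 0).
#' @param n_collect total refined trial alignments to generate before
#'   stopping.
#' @param n_seed_frags fragment-pair superpositions sampled when seeding
#'   the bank.
#' @param rng_seed integer seed; one RNG stream drives all stochastic
#'   choices, so runs with the same seed are identical.
#' @return An object of class `csa_config`.
#' @export
csa_config <- function(bank_size = 30L, n_seeds_per_round = 20L,
                       n_trials_per_seed = 10L, dcut_start_factor = 0.5,
                       dcut_ratio = 0.97, dcut_min = 0.05, n_collect = 100L,
                       n_seed_frags = 200L, rng_seed = 1L) {
  if (bank_size < 2L) stop("bank_size must be >= 2")
  if (dcut_ratio <= 0 || dcut_ratio >= 1) stop("dcut_ratio must be in (0, 1)")
  if (dcut_min <= 0) stop("dcut_min must be > 0")
  structure(list(bank_size = as.integer(bank_size),
                 n_seeds_per_round = as.integer(n_seeds_per_round),
                 n_trials_per_seed = as.integer(n_trials_per_seed),
                 dcut_start_factor = dcut_start_factor,
                 dcut_ratio = dcut_ratio, dcut_min = dcut_min,
                 n_collect = as.integer(n_collect),
                 n_seed_frags = as.integer(n_seed_frags),
                 rng_seed = as.integer(rng_seed)),
            class = "csa_config")
}

#' @export
print.csa_bank <- function(x, ...) {
  sc <- vapply(x$members, `[[`, numeric(1L), "score")
  cat(sprintf(
    "<csa_bank> %d members, best score %.6g, D_cut %.3f, %d trials generated\n",
    length(x$members), max(sc), x$dcut, x$n_generated))
  invisible(x)
}

# internal bank accessors
bank_scores <- function(bank) vapply(bank$members, `[[`, numeric(1L), "score")

#' @rdname csa_search
#' @export
bank_best <- function(bank) {
  stopifnot(inherits(bank, "csa_bank"))
  bank$members[[which.max(bank_scores(bank))]]
}

# greedy one-to-one harvest of residue pairs with small post-fit deviation,
# closest pairs first (ties broken by index for determinism)
harvest_pairs <- function(coords_a, coords_b_fit, cutoff) {
  cross <- outer(rowSums(coords_a^2), rowSums(coords_b_fit^2), "+") -
    2 * tcrossprod(coords_a, coords_b_fit)
  cross[cross < 0] <- 0
  hit <- which(cross <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(integer(), 0L, 2L))
  d <- cross[hit]
  ord <- order(d, hit[, 1L], hit[, 2L])
  hit <- hit[ord, , drop = FALSE]
  used_a <- logical(nrow(coords_a))
  used_b <- logical(nrow(coords_b_fit))
  keep <- logical(nrow(hit))
  for (t in seq_len(nrow(hit))) {
    ii <- hit[t, 1L]; jj <- hit[t, 2L]
    if (!used_a[ii] && !used_b[jj]) {
      keep[t] <- TRUE
      used_a[ii] <- TRUE
      used_b[jj] <- TRUE
    }
  }
  unname(hit[keep, , drop = FALSE])
}

#' Seed the CSA bank
#'
#' Initial solutions come from fragment-pair superpositions: windows of
#' length `max(min_block_size, 6)` in chain A are paired with windows in
#' chain B (forward and, when permitted, reverse; subsampled to
#' `n_seed_frags` by the seeded RNG), each window pair is superposed, and
#' all residue pairs whose post-fit deviation is below `2 * d0_so` are
#' harvested greedily into a one-to-one alignment and projected onto the
#' constraint set.  The `bank_size` mutually most distant high-scoring
#' candidates are then locally refined and form the bank.
#'
#' @inheritParams admissible_moves
#' @param config a [csa_config()]; the caller ([csa_search()]) has already
#'   seeded the RNG stream.
#' @return An object of class `csa_bank`.
#' @export
seed_bank <- function(chain_a, chain_b, spec = score_spec(), c, config) {
  stopifnot(inherits(c, "constraints"), inherits(config, "csa_config"))
  la <- chain_length(chain_a)
  lb <- chain_length(chain_b)
  # fragment window: 6 for real chains, shorter for tiny ones so that
  # several distinct windows exist to seed diversity from
  w <- min(max(c$min_block_size, 6L), max(c$min_block_size, min(la, lb) %/% 2L),
           la, lb)
  w <- max(w, 2L)
  ospec <- objective_spec(spec)
  d_a <- if (ospec$fun == "DALI") distance_matrix(chain_a) else NULL
  d_b <- if (ospec$fun == "DALI") distance_matrix(chain_b) else NULL

  starts_a <- seq_len(la - w + 1L)
  starts_b <- seq_len(lb - w + 1L)
  frags <- expand.grid(ia = starts_a, jb = starts_b,
                       rev = if (c$allow_reverse) c(FALSE, TRUE) else FALSE)
  if (nrow(frags) > config$n_seed_frags)
    frags <- frags[sample.int(nrow(frags), config$n_seed_frags), ,
                   drop = FALSE]

  cutoff <- 2 * spec$d0_so
  cands <- list()
  for (t in seq_len(nrow(frags))) {
    ia <- frags$ia[t]; jb <- frags$jb[t]
    idx_a <- ia:(ia + w - 1L)
    idx_b <- jb:(jb + w - 1L)
    if (frags$rev[t]) idx_b <- rev(idx_b)
    f <- kabsch(chain_a$coords[idx_a, , drop = FALSE],
                chain_b$coords[idx_b, , drop = FALSE])
    b_fit <- chain_b$coords %*% t(f$rotation) +
      matrix(f$translation, lb, 3L, byrow = TRUE)
    m <- harvest_pairs(chain_a$coords, b_fit, cutoff)
    if (nrow(m) == 0L) next
    a <- tryCatch(enforce_constraints(as_alignment(m), c, la, lb),
                  error = function(e) NULL)
    if (is.null(a)) next
    cands[[length(cands) + 1L]] <- a
  }
  if (length(cands) == 0L)
    stop("seed generation found no valid alignment between the chains")

  # dedupe, score cheaply, pick the most mutually distant high scorers
  keys <- vapply(cands, function(a)
    paste(pair_matrix(a)[, 1L], pair_matrix(a)[, 2L], collapse = ";"),
    character(1L))
  cands <- cands[!duplicated(keys)]
  sc <- vapply(cands, function(a)
    align_score(a, chain_a, chain_b, ospec, d_a, d_b), numeric(1L))
  ord <- order(sc, decreasing = TRUE)
  cands <- cands[ord]
  sc <- sc[ord]
  chosen <- 1L
  while (length(chosen) < min(config$bank_size, length(cands))) {
    rest <- setdiff(seq_along(cands), chosen)
    dmin <- vapply(rest, function(t)
      min(vapply(chosen, function(s)
        alignment_distance(cands[[t]], cands[[s]]), numeric(1L))),
      numeric(1L))
    # most distant from the current selection; ties favour higher score
    chosen <- c(chosen, rest[order(-dmin, -sc[rest])[1L]])
  }

  members <- list()
  seen <- character()
  for (t in chosen) {
    r <- refine_alignment(cands[[t]], chain_a, chain_b, spec, c)
    key <- paste(pair_matrix(r$alignment)[, 1L],
                 pair_matrix(r$alignment)[, 2L], collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    members[[length(members) + 1L]] <-
      list(alignment = r$alignment, score = r$score, last_used = 0L)
  }
  structure(list(members = members, dcut = NA_real_,
                 n_generated = length(members)),
            class = "csa_bank")
}

#' CSA crossover and perturbation operators
#'
#' `crossover_alignments()` copies the first parent, transplants a random
#' nonempty subset of the second parent's blocks (deleting first-parent
#' pairs that conflict with the transplanted residues), and projects the
#' result onto the constraint set.  `perturb_alignment()` applies one
#' random structural change -- delete a block, rigidly shift a block by one
#' position in `i` or `j` (dropping collisions), truncate a block end, or
#' relocate a block to a random non-conflicting placement with random
#' orientation (block placement is exactly the degree of freedom a
#' non-sequential alignment has, and relocation lets the annealing escape
#' basins that single-position shifts cannot leave) -- followed by the
#' same projection.  Both draw from the caller's RNG stream.
#'
#' @param p1,p2,p parent [as_alignment()]s over the same chain pair.
#' @param c a [constraints()] object.
#' @param l_a,l_b chain lengths.
#' @return A constraint-satisfying [as_alignment()] (an error if the
#'   projection's fallbacks fail, e.g. after deleting the only block).
#' @export
crossover_alignments <- function(p1, p2, c, l_a, l_b) {
  bl <- blocks_of(p2)
  if (length(bl) == 0L) return(enforce_constraints(p1, c, l_a, l_b))
  take <- runif(length(bl)) < 0.5
  if (!any(take)) take[sample.int(length(bl), 1L)] <- TRUE
  transplant <- do.call(rbind, lapply(bl[take], `[[`, "pairs"))
  m1 <- pair_matrix(p1)
  clash <- m1[, 1L] %in% transplant[, 1L] | m1[, 2L] %in% transplant[, 2L]
  merged <- rbind(m1[!clash, , drop = FALSE], transplant)
  merged <- unique(merged)
  enforce_constraints(as_alignment(merged), c, l_a, l_b)
}

#' @rdname crossover_alignments
#' @export
perturb_alignment <- function(p, c, l_a, l_b) {
  bl <- blocks_of(p)
  if (length(bl) == 0L) return(enforce_constraints(p, c, l_a, l_b))
  op <- sample(c("delete", "shift", "truncate", "relocate"), 1L)
  b <- sample.int(length(bl), 1L)
  m <- pair_matrix(p)
  bp <- bl[[b]]$pairs
  in_block <- paste(m[, 1L], m[, 2L]) %in% paste(bp[, 1L], bp[, 2L])
  if (op == "delete") {
    out <- m[!in_block, , drop = FALSE]
  } else if (op == "relocate") {
    rest <- m[!in_block, , drop = FALSE]
    sz <- nrow(bp)
    rev_new <- c$allow_reverse && runif(1L) < 0.5
    free_i <- setdiff(seq_len(l_a), rest[, 1L])
    free_j <- setdiff(seq_len(l_b), rest[, 2L])
    # starts whose full i- and j-runs are unaligned in the remainder
    ok_i <- free_i[vapply(free_i, function(s)
      s + sz - 1L <= l_a && all((s:(s + sz - 1L)) %in% free_i), logical(1L))]
    ok_j <- free_j[vapply(free_j, function(s)
      s + sz - 1L <= l_b && all((s:(s + sz - 1L)) %in% free_j), logical(1L))]
    if (length(ok_i) == 0L || length(ok_j) == 0L) {
      out <- rest
    } else {
      si <- ok_i[sample.int(length(ok_i), 1L)]
      sj <- ok_j[sample.int(length(ok_j), 1L)]
      jj <- if (rev_new) (sj + sz - 1L):sj else sj:(sj + sz - 1L)
      out <- rbind(rest, cbind(si:(si + sz - 1L), jj))
    }
  } else if (op == "shift") {
    axis <- sample(1:2, 1L)
    dirn <- sample(c(-1L, 1L), 1L)
    shifted <- bp
    shifted[, axis] <- shifted[, axis] + dirn
    rest <- m[!in_block, , drop = FALSE]
    lim <- if (axis == 1L) l_a else l_b
    ok <- shifted[, axis] >= 1L & shifted[, axis] <= lim &
      !(shifted[, 1L] %in% rest[, 1L]) & !(shifted[, 2L] %in% rest[, 2L])
    out <- rbind(rest, shifted[ok, , drop = FALSE])
  } else {
    # truncate one end by a pair, respecting the minimum size when possible
    if (bl[[b]]$size > c$min_block_size) {
      drop_row <- if (runif(1L) < 0.5) 1L else nrow(bp)
      dropped <- bp[drop_row, , drop = FALSE]
      out <- m[!(paste(m[, 1L], m[, 2L]) %in%
                   paste(dropped[, 1L], dropped[, 2L])), , drop = FALSE]
    } else {
      out <- m[!in_block, , drop = FALSE]   # too small to shorten: remove
    }
  }
  enforce_constraints(as_alignment(out), c, l_a, l_b)
}

#' Insert a refined trial into the bank
#'
#' The CSA update rule: find the member closest to the trial under
#' [alignment_distance()]; within `D_cut`, the trial competes with (and
#' may replace) that closest member only; beyond `D_cut`, it competes with
#' the current worst member.  Equal-or-worse trials are discarded.
#'
#' @param bank a `csa_bank`.
#' @param trial a refined, constraint-satisfying [as_alignment()].
#' @param trial_score its score on the optimization objective.
#' @return The updated bank.
#' @export
bank_update <- function(bank, trial, trial_score) {
  stopifnot(inherits(bank, "csa_bank"))
  d <- vapply(bank$members, function(mb)
    alignment_distance(trial, mb$alignment), numeric(1L))
  nearest <- which.min(d)
  if (d[nearest] < bank$dcut) {
    if (trial_score > bank$members[[nearest]]$score) {
      bank$members[[nearest]]$alignment <- trial
      bank$members[[nearest]]$score <- trial_score
    }
  } else {
    worst <- which.min(bank_scores(bank))
    if (trial_score > bank$members[[worst]]$score) {
      bank$members[[worst]]$alignment <- trial
      bank$members[[worst]]$score <- trial_score
    }
  }
  bank
}

#' Global alignment search by conformational space annealing
#'
#' Maintains a bank of locally refined, mutually diverse alignments.  Each
#' round picks the least recently used members as seeds, generates trials
#' from them by crossover with random other members and by perturbation,
#' refines every trial with [refine_alignment()], and inserts it by the
#' [bank_update()] rule; the diversity cutoff `D_cut` then shrinks
#' geometrically.  The run stops once `n_collect` refined trials have been
#' generated.  The best bank score never decreases, every returned
#' alignment satisfies the constraints and is a fixed point of the
#' refiner, and runs with equal `rng_seed` are identical.
#'
#' @inheritParams admissible_moves
#' @param config a [csa_config()].
#' @return The final `csa_bank`, members sorted by score (best first);
#'   inspect the best with [bank_best()].
#' @examples
#' \donttest{
#' ch <- make_synthetic_chain("walk", 30, seed = 5)
#' pp <- make_permuted_pair(ch, data.frame(start = c(16, 1), end = c(30, 15),
#'                                         reverse = FALSE))
#' bank <- csa_search(ch, pp$chain, score_spec("TM"), constraints(4, TRUE),
#'                    csa_config(bank_size = 8, n_collect = 20))
#' precision_recall(bank_best(bank)$alignment, pp$truth)
#' }
#' @export
csa_search <- function(chain_a, chain_b, spec = score_spec(), c, config) {
  stopifnot(inherits(c, "constraints"), inherits(config, "csa_config"))
  la <- chain_length(chain_a)
  lb <- chain_length(chain_b)
  with_preserved_rng(config$rng_seed, {
    bank <- seed_bank(chain_a, chain_b, spec, c, config)
    nm <- length(bank$members)
    if (nm >= 2L) {
      dists <- unlist(lapply(seq_len(nm - 1L), function(s)
        vapply((s + 1L):nm, function(t)
          alignment_distance(bank$members[[s]]$alignment,
                             bank$members[[t]]$alignment), numeric(1L))))
      bank$dcut <- max(config$dcut_min, config$dcut_start_factor * mean(dists))
    } else {
      bank$dcut <- config$dcut_min
    }
    round_no <- 0L
    while (bank$n_generated < config$n_collect) {
      round_no <- round_no + 1L
      nmem <- length(bank$members)
      lu <- vapply(bank$members, `[[`, integer(1L), "last_used")
      seeds <- order(lu, seq_len(nmem))[seq_len(min(config$n_seeds_per_round,
                                                    nmem))]
      for (s in seeds) {
        bank$members[[s]]$last_used <- round_no
        for (t in seq_len(config$n_trials_per_seed)) {
          others <- setdiff(seq_len(nmem), s)
          partner <- if (length(others) > 0L)
            others[sample.int(length(others), 1L)] else s
          # a trial is a crossover (half the time, when a partner exists)
          # followed by a random perturbation depth of 1-3; composing the
          # elementary perturbations lets trials escape basins that a
          # single +/-1 shift, truncation or block deletion cannot leave
          trial0 <- tryCatch({
            tr <- bank$members[[s]]$alignment
            if (nmem > 1L && runif(1L) < 0.5)
              tr <- crossover_alignments(tr,
                                         bank$members[[partner]]$alignment,
                                         c, la, lb)
            for (q in seq_len(sample.int(3L, 1L)))
              tr <- perturb_alignment(tr, c, la, lb)
            tr
          }, error = function(e) NULL)
          if (is.null(trial0)) next
          r <- refine_alignment(trial0, chain_a, chain_b, spec, c)
          bank <- bank_update(bank, r$alignment, r$score)
          bank$n_generated <- bank$n_generated + 1L
          if (bank$n_generated >= config$n_collect) break
        }
        if (bank$n_generated >= config$n_collect) break
      }
      bank$dcut <- max(config$dcut_min, bank$dcut * config$dcut_ratio)
    }
    bank$members <- bank$members[order(bank_scores(bank),
                                       decreasing = TRUE)]
    bank
  })
}
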