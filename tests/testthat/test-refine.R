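test_that("unconstrained add moves cover every free pair", {
  A <- make_synthetic_chain("walk", 6, seed = 61)
  B <- make_synthetic_chain("walk", 6, seed = 62)
  a <- as_alignment(cbind(1:2, 1:2))
  mv <- admissible_moves(a, A, B, score_spec("TM"), constraints(1, TRUE))
  adds <- mv[mv$kind == "add_pair", ]
  expect_equal(nrow(adds), 4 * 4)   # free i in 3:6, free j in 3:6
  dels <- mv[mv$kind == "delete_pair", ]
  expect_equal(nrow(dels), 2)
})

test_that("minimum block size shapes the admissible move set", {
  A <- make_synthetic_chain("walk", 12, seed = 63)
  B <- make_synthetic_chain("walk", 12, seed = 64)
  cst <- constraints(4, TRUE)

  # one size-4 block: no single deletion survives, the whole block may go
  a4 <- as_alignment(cbind(3:6, 3:6))
  mv <- admissible_moves(a4, A, B, score_spec("TM"), cst)
  expect_equal(sum(mv$kind == "delete_pair"), 0)
  expect_equal(sum(mv$kind == "delete_block"), 1)
  # additions only extend the block (2 ends), block seeds appear elsewhere
  adds <- mv[mv$kind == "add_pair", ]
  expect_equal(nrow(adds), 2)
  ends <- t(vapply(adds$pairs, function(p) p[1, ], c(i = 0L, j = 0L)))
  expect_setequal(paste(ends[, 1], ends[, 2]), c("2 2", "7 7"))
  expect_gt(sum(mv$kind == "add_block"), 0)

  # a size-5 block: exactly the two terminal pairs are deletable
  a5 <- as_alignment(cbind(3:7, 3:7))
  mv5 <- admissible_moves(a5, A, B, score_spec("TM"), cst)
  dels <- mv5[mv5$kind == "delete_pair", ]
  expect_equal(nrow(dels), 2)
  delp <- t(vapply(dels$pairs, function(p) p[1, ], c(i = 0L, j = 0L)))
  expect_setequal(paste(delp[, 1], delp[, 2]), c("3 3", "7 7"))
})

test_that("move deltas equal the rescored candidate alignments", {
  A <- make_synthetic_chain("walk", 8, seed = 65)
  B <- make_synthetic_chain("walk", 8, seed = 66)
  cst <- constraints(2, TRUE)
  a <- as_alignment(cbind(2:5, 2:5))
  cur <- tm_score(a, A, B)
  mv <- admissible_moves(a, A, B, score_spec("TM"), cst)
  for (r in sample.int(nrow(mv), min(8, nrow(mv)))) {
    m <- unclass(a)[, , drop = FALSE]
    p <- mv$pairs[[r]]
    cand <- if (mv$kind[r] %in% c("add_pair", "add_block")) rbind(m, p)
            else m[!(paste(m[, 1], m[, 2]) %in% paste(p[, 1], p[, 2])), ,
                   drop = FALSE]
    expect_equal(mv$delta[r], tm_score(as_alignment(cand), A, B) - cur,
                 tolerance = 1e-10)
  }
})

test_that("refinement recovers the full identity alignment from a partial start", {
  ch <- make_synthetic_chain("walk", 20, seed = 3)
  r <- refine_alignment(as_alignment(cbind(1:10, 1:10)), ch, ch,
                        score_spec("TM"), constraints(1, TRUE))
  expect_equal(r$score, 1, tolerance = 1e-12)
  expect_equal(n_pairs(r$alignment), 20L)
  expect_equal(r$n_accepted, 10L)
})

test_that("a full-coverage optimum is a fixed point", {
  ch <- make_synthetic_chain("walk", 15, seed = 71)
  full <- as_alignment(cbind(1:15, 1:15))
  r <- refine_alignment(full, ch, ch, score_spec("TM"), constraints(4, TRUE))
  expect_identical(unclass(r$alignment), unclass(full))
  expect_equal(r$n_accepted, 0L)
  expect_length(r$score_trace, 0L)
})

test_that("refinement never degrades, terminates, and respects constraints", {
  set.seed(81)
  for (t in 1:30) {
    A <- make_synthetic_chain("walk", 10, seed = 700 + t)
    B <- make_synthetic_chain("walk", 10, seed = 800 + t)
    cst <- constraints(sample(1:3, 1), sample(c(TRUE, FALSE), 1))
    spec <- score_spec(sample(c("TM", "DALI", "SP", "SO_L"), 1))
    start <- random_valid_alignment(10, 10, cst)
    s0 <- align_score(start, A, B, spec)
    r <- refine_alignment(start, A, B, spec, cst)
    expect_gte(r$score, s0 - 1e-12)
    expect_length(validate_alignment(r$alignment, cst), 0L)
    if (length(r$score_trace) > 1)
      expect_true(all(diff(r$score_trace) > 0))
    # the objective value of the result matches an independent evaluation
    expect_equal(r$score, align_score(r$alignment, A, B, spec),
                 tolerance = 1e-10)
  }
})

test_that("refinement output is a single-move local optimum", {
  set.seed(82)
  for (t in 1:8) {
    A <- make_synthetic_chain("walk", 8, seed = 900 + t)
    B <- make_synthetic_chain("walk", 8, seed = 950 + t)
    cst <- constraints(2, TRUE)
    r <- refine_alignment(random_valid_alignment(8, 8, cst), A, B,
                          score_spec("TM"), cst)
    improving <- admissible_moves(r$alignment, A, B, score_spec("TM"), cst,
                                  improving_only = TRUE)
    expect_equal(nrow(improving), 0L)
  }
})

test_that("refinement is deterministic", {
  A <- make_synthetic_chain("walk", 12, seed = 83)
  B <- make_synthetic_chain("walk", 12, seed = 84)
  cst <- constraints(2, TRUE)
  start <- as_alignment(cbind(1:4, c(2:4, 6)))
  r1 <- refine_alignment(start, A, B, score_spec("SP"), cst)
  r2 <- refine_alignment(start, A, B, score_spec("SP"), cst)
  expect_identical(unclass(r1$alignment), unclass(r2$alignment))
  expect_identical(r1$score_trace, r2$score_trace)
})

test_that("tiny-instance refinement lands on hill-climbing local optima", {
  # independent oracle: exhaustive single-move hill climbing in plain R,
  # with its own block/validity logic
  r_blocks_ok <- function(m, min_block, allow_reverse) {
    if (nrow(m) == 0) return(TRUE)
    m <- m[order(m[, 1]), , drop = FALSE]
    b_start <- 1
    while (b_start <= nrow(m)) {
      len <- 1
      dir <- 0
      while (b_start + len <= nrow(m)) {
        step_i <- m[b_start + len, 1] - m[b_start + len - 1, 1]
        step_j <- m[b_start + len, 2] - m[b_start + len - 1, 2]
        if (step_i != 1 || abs(step_j) != 1) break
        if (dir == 0) dir <- step_j
        else if (step_j != dir) break
        len <- len + 1
      }
      if (len < min_block) return(FALSE)
      if (!allow_reverse && dir == -1 && len >= 2) return(FALSE)
      b_start <- b_start + len
    }
    TRUE
  }
  climb <- function(m, A, B, min_block, allow_reverse) {
    sc <- function(x) oracle_tm(x, A, B)
    cur <- sc(m)
    repeat {
      best <- cur
      best_m <- NULL
      la <- nrow(A$coords)
      lb <- nrow(B$coords)
      cands <- list()
      for (r in seq_len(nrow(m)))
        cands[[length(cands) + 1]] <- m[-r, , drop = FALSE]
      free_i <- setdiff(seq_len(la), m[, 1])
      free_j <- setdiff(seq_len(lb), m[, 2])
      for (i in free_i) for (j in free_j)
        cands[[length(cands) + 1]] <- rbind(m, c(i, j))
      if (min_block > 1) {
        for (i in seq_len(la - min_block + 1))
          for (j in seq_len(lb - min_block + 1)) {
            ii <- i:(i + min_block - 1)
            jj <- j:(j + min_block - 1)
            if (all(ii %in% c(free_i)) && all(jj %in% free_j)) {
              cands[[length(cands) + 1]] <- rbind(m, cbind(ii, jj))
              cands[[length(cands) + 1]] <- rbind(m, cbind(ii, rev(jj)))
            }
          }
      }
      for (cand in cands) {
        if (nrow(cand) == 0) next
        if (anyDuplicated(cand[, 1]) || anyDuplicated(cand[, 2])) next
        if (!r_blocks_ok(cand, min_block, allow_reverse)) next
        v <- sc(cand)
        if (v > best + 1e-9) {
          best <- v
          best_m <- cand
        }
      }
      if (is.null(best_m)) return(cur)
      m <- best_m
      cur <- best
    }
  }
  set.seed(84)
  for (t in 1:5) {
    A <- make_synthetic_chain("walk", 6, seed = 400 + t)
    B <- make_synthetic_chain("walk", 6, seed = 450 + t)
    cst <- constraints(2, TRUE)
    start <- random_valid_alignment(6, 6, cst)
    r <- refine_alignment(start, A, B, score_spec("TM"), cst)
    # the refiner's endpoint must itself be stable under the oracle's moves
    oracle_end <- climb(unclass(r$alignment)[, , drop = FALSE], A, B, 2, TRUE)
    expect_equal(r$score, oracle_end, tolerance = 1e-9)
  }
})
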