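test_that("self-alignments reproduce the closed forms", {
  for (m in c(10, 25)) {
    ch <- make_synthetic_chain("walk", m, seed = m)
    a <- as_alignment(cbind(seq_len(m), seq_len(m)))
    expect_equal(dali_score(a, ch, ch), 0.2 * m^2, tolerance = 1e-12)
    expect_equal(sp_score(a, ch, ch), (0.8 / 3) * m^0.3, tolerance = 1e-12)
    expect_equal(so_score(a, ch, ch), 1)
    expect_equal(tm_score(a, ch, ch), 1, tolerance = 1e-12)
    expect_equal(tm_score(a, ch, ch, score_spec("TM",
                                                tm_normalization = "A")), 1,
                 tolerance = 1e-12)
  }
  # the mean_distance envelope damps off-diagonal terms, so it must differ
  ch <- make_synthetic_chain("walk", 10, seed = 10)
  a <- as_alignment(cbind(1:10, 1:10))
  md <- dali_score(a, ch, ch,
                   score_spec("DALI", dali_variant = "mean_distance"))
  expect_lt(md, 0.2 * 100)
})

test_that("zero-deviation distance pairs contribute 0.2 each under DALI", {
  # two chains whose two aligned residues are 10 A apart in both: the
  # off-diagonal terms have |dA - dB| = 0, so weight 1 and value 0.2
  A <- protein_chain(rbind(c(0, 0, 0), c(10, 0, 0)))
  B <- protein_chain(rbind(c(5, 5, 0), c(5, 15, 0)))
  a <- as_alignment(cbind(1:2, 1:2))
  expect_equal(dali_score(a, A, B), 2 * 0.2 + 2 * 0.2, tolerance = 1e-12)
})

test_that("scores match the direct-evaluation oracles on random instances", {
  set.seed(101)
  for (t in 1:12) {
    A <- make_synthetic_chain("walk", 14, seed = 200 + t)
    B0 <- make_permuted_pair(A, data.frame(start = c(8, 1), end = c(14, 7),
                                           reverse = FALSE),
                             noise_sigma = 0.8, seed = 300 + t)
    B <- B0$chain
    k <- sample(5:12, 1)
    a <- as_alignment(cbind(sample.int(14, k), sample.int(14, k)))
    DA <- distance_matrix(A)
    DB <- distance_matrix(B)
    m <- unclass(a)[, , drop = FALSE]
    expect_equal(dali_score(a, A, B), oracle_dali(m, DA, DB),
                 tolerance = 1e-10)
    expect_equal(dali_score(a, A, B,
                            score_spec("DALI",
                                       dali_variant = "mean_distance")),
                 oracle_dali(m, DA, DB, variant = "mean_distance"),
                 tolerance = 1e-10)
    expect_equal(sp_score(a, A, B), oracle_sp(m, A, B), tolerance = 1e-10)
    expect_equal(so_score(a, A, B), oracle_so(m, A, B), tolerance = 1e-12)
    expect_equal(so_logistic(a, A, B), oracle_sol(m, A, B),
                 tolerance = 1e-10)
    expect_equal(tm_score(a, A, B), oracle_tm(m, A, B), tolerance = 1e-10)
    expect_equal(tm_score(a, A, B,
                          score_spec("TM", tm_normalization = "B")),
                 oracle_tm(m, A, B, "B"), tolerance = 1e-10)
  }
})

test_that("SP boundary: a pair at exactly 2*d0 is core but not summed", {
  # deviations exactly (0, 0, 8, 8): two pairs sit on the 2*d0 cutoff
  pin <- collinear_pair(c(0, 10, 40, 50), c(0, 10, 48, 42))
  a <- as_alignment(cbind(seq_len(pin$n), seq_len(pin$n)))
  got <- sp_score(a, pin$A, pin$B)
  # boundary pairs are core (<=), so L = 4; they are excluded from the
  # strict sum, which keeps only the two zero-deviation terms of 0.8
  expect_equal(got, 1.6 / (3 * 4^0.7), tolerance = 1e-12)
  # a strict core rule would have given L = 2 (no residue of either chain
  # lies within 3*d0 of the two near pairs)
  expect_false(isTRUE(all.equal(got, 1.6 / (3 * 2^0.7))))
})

test_that("SO boundary and logistic midpoint sit at d0", {
  # deviations exactly (0, 0, 3.5, 3.5): two pairs sit on the d0 cutoff
  pin <- collinear_pair(c(0, 10, 40, 50), c(0, 10, 43.5, 46.5))
  a <- as_alignment(cbind(seq_len(pin$n), seq_len(pin$n)))
  # deviation exactly d0 still counts for SO (<=)
  expect_equal(so_score(a, pin$A, pin$B), 1)
  # and contributes exactly 1/2 under the logistic surrogate
  expect_equal(so_logistic(a, pin$A, pin$B), (2 + 2 * 0.5) / 4,
               tolerance = 1e-9)
  # a near-zero deviation saturates the logistic term
  close <- collinear_pair(c(0, 10, 40, 50), c(0, 10, 40 + 1e-6, 50 - 1e-6))
  expect_equal(so_logistic(as_alignment(cbind(1:4, 1:4)),
                           close$A, close$B), 1, tolerance = 1e-9)
})

test_that("SO_L approximates SO away from the cutoff", {
  set.seed(55)
  for (t in 1:8) {
    A <- make_synthetic_chain("walk", 16, seed = 400 + t)
    B <- make_permuted_pair(A, data.frame(start = 1, end = 16,
                                          reverse = FALSE),
                            noise_sigma = 0.4, seed = 500 + t)$chain
    a <- as_alignment(cbind(1:16, 1:16))
    d <- oracle_devs(unclass(a)[, ], A, B)
    if (all(abs(d - 3.5) > 0.5)) {
      expect_lt(abs(so_logistic(a, A, B) - so_score(a, A, B)),
                0.01 * 16 / 16)
    }
  }
})

test_that("TM d0 follows the chain-length formula with the short-chain clamp", {
  # L_N = 100: d0 = 1.24 * 85^(1/3) - 1.8
  A <- make_synthetic_chain("walk", 100, seed = 3)
  B <- make_permuted_pair(A, data.frame(start = 1, end = 100,
                                        reverse = FALSE),
                          noise_sigma = 1, seed = 4)$chain
  a <- as_alignment(cbind(1:100, 1:100))
  d <- oracle_devs(unclass(a)[, ], A, B)
  d0 <- 1.24 * 85^(1 / 3) - 1.8
  expect_equal(tm_score(a, A, B, score_spec("TM", tm_normalization = "A")),
               sum(1 / (1 + (d / d0)^2)) / 100, tolerance = 1e-10)
  # short chains would get a non-positive d0; the clamp keeps it at 0.5
  S <- make_synthetic_chain("walk", 10, seed = 5)
  noisy <- make_permuted_pair(S, data.frame(start = 1, end = 10,
                                            reverse = FALSE),
                              noise_sigma = 0.7, seed = 6)$chain
  ident <- as_alignment(cbind(1:10, 1:10))
  ds <- oracle_devs(unclass(ident)[, ], S, noisy)
  expect_equal(tm_score(ident, S, noisy,
                        score_spec("TM", tm_normalization = "A")),
               sum(1 / (1 + (ds / 0.5)^2)) / 10, tolerance = 1e-10)
})

test_that("TM(average) is the mean of both normalizations and bounded by 1", {
  set.seed(66)
  A <- make_synthetic_chain("walk", 18, seed = 7)
  B <- make_synthetic_chain("walk", 12, seed = 8)
  for (t in 1:6) {
    k <- sample(4:10, 1)
    a <- as_alignment(cbind(sample.int(18, k), sample.int(12, k)))
    tma <- tm_score(a, A, B, score_spec("TM", tm_normalization = "A"))
    tmb <- tm_score(a, A, B, score_spec("TM", tm_normalization = "B"))
    avg <- tm_score(a, A, B)
    expect_equal(avg, (tma + tmb) / 2, tolerance = 1e-12)
    expect_lte(avg, 1)
    so <- so_score(a, A, B)
    sol <- so_logistic(a, A, B)
    expect_true(so >= 0 && so <= 1)
    expect_true(sol >= 0 && sol <= 1)
  }
})

test_that("empty alignments score zero where defined and error for SP", {
  ch <- make_synthetic_chain("walk", 10, seed = 9)
  empty <- as_alignment(matrix(integer(), 0, 2))
  expect_equal(so_score(empty, ch, ch), 0)
  expect_equal(so_logistic(empty, ch, ch), 0)
  expect_equal(tm_score(empty, ch, ch), 0)
  expect_equal(dali_score(empty, ch, ch), 0)
  expect_error(sp_score(empty, ch, ch), "nonempty")
})

test_that("all scores are invariant under rigid motion; DALI also under mirror", {
  set.seed(202)
  A <- make_synthetic_chain("walk", 15, seed = 31)
  B <- make_permuted_pair(A, data.frame(start = c(8, 1), end = c(15, 7),
                                        reverse = FALSE),
                          noise_sigma = 0.6, seed = 32)$chain
  a <- as_alignment(cbind(1:12, c(9:15, 1:5)))
  vals <- function(Bv) c(dali_score(a, A, Bv), sp_score(a, A, Bv),
                         so_score(a, A, Bv), so_logistic(a, A, Bv),
                         tm_score(a, A, Bv))
  base <- vals(B)
  moved <- protein_chain(B$coords %*% t(random_rotation()) +
                           matrix(rnorm(3, sd = 10), 15, 3, byrow = TRUE))
  expect_equal(vals(moved), base, tolerance = 1e-9)
  # the Table-3 pathology as a property: mirroring is invisible to DALI ...
  expect_equal(dali_score(a, A, mirror_chain(B)), base[1], tolerance = 1e-10)
  # ... but not to the superposition-based scores on a chiral chain
  expect_false(isTRUE(all.equal(tm_score(a, A, mirror_chain(B)), base[5],
                                tolerance = 1e-6)))
})

test_that("align_score dispatches to the per-function implementations", {
  A <- make_synthetic_chain("walk", 12, seed = 41)
  B <- make_synthetic_chain("walk", 12, seed = 42)
  a <- as_alignment(cbind(1:8, c(3:8, 1:2)))
  expect_equal(align_score(a, A, B, score_spec("DALI")), dali_score(a, A, B))
  expect_equal(align_score(a, A, B, score_spec("SP")), sp_score(a, A, B))
  expect_equal(align_score(a, A, B, score_spec("SO")), so_score(a, A, B))
  expect_equal(align_score(a, A, B, score_spec("SO_L")),
               so_logistic(a, A, B))
  expect_equal(align_score(a, A, B, score_spec("TM")), tm_score(a, A, B))
  bad <- score_spec("TM")
  bad$fun <- "nope"
  expect_error(align_score(a, A, B, bad), "unknown scoring function")
})
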