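# Independent reference implementations used as oracles: plain-R score
# evaluation (direct loops over the definitions), a quaternion-grid +
# Nelder-Mead RMSD minimizer, and small fixture builders.

# --- rotations ------------------------------------------------------------

quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() quat_rotation(rnorm(4))

# brute-force least-RMSD over proper rotations: random quaternion grid,
# refined by Nelder-Mead on the best grid point
oracle_rmsd <- function(P, Q, n_grid = 2000) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  f <- function(q) {
    R <- quat_rotation(q)
    sqrt(mean(rowSums((Pc - Qc %*% t(R))^2)))
  }
  qs <- rbind(c(1, 0, 0, 0), matrix(rnorm(4 * n_grid), ncol = 4))
  vals <- apply(qs, 1, f)
  o <- optim(qs[which.min(vals), ], f, method = "Nelder-Mead",
             control = list(reltol = 1e-16, maxit = 50000))
  o$value
}

# --- direct score evaluation ----------------------------------------------

oracle_devs <- function(pairs, A, B) {
  P <- A$coords[pairs[, 1], , drop = FALSE]
  Q <- B$coords[pairs[, 2], , drop = FALSE]
  f <- kabsch(P, Q)
  Qf <- Q %*% t(f$rotation) +
    matrix(f$translation, nrow(Q), 3, byrow = TRUE)
  sqrt(rowSums((P - Qf)^2))
}

oracle_dali <- function(pairs, DA, DB, d0 = 20, variant = "deviation") {
  n <- nrow(pairs)
  tot <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) {
        tot <- tot + 0.2
        next
      }
      da <- DA[pairs[a, 1], pairs[b, 1]]
      db <- DB[pairs[a, 2], pairs[b, 2]]
      w <- if (variant == "deviation") exp(-(da - db)^2 / d0^2)
           else exp(-((da + db) / 2)^2 / d0^2)
      tot <- tot + (0.2 - abs(da - db) / ((da + db) / 2)) * w
    }
  }
  tot
}

oracle_sp <- function(pairs, A, B, d0 = 4, alpha = 0.3) {
  d <- oracle_devs(pairs, A, B)
  s <- sum(1 / (1 + (d[d < 2 * d0] / d0)^2) - 0.2)
  core <- d <= 2 * d0
  core_a <- pairs[core, 1]
  core_b <- pairs[core, 2]
  nbr <- function(coords, core_idx) {
    noncore <- setdiff(seq_len(nrow(coords)), core_idx)
    sum(vapply(noncore, function(r)
      any(sqrt(rowSums((coords[core_idx, , drop = FALSE] -
                          matrix(coords[r, ], length(core_idx), 3,
                                 byrow = TRUE))^2)) <= 3 * d0),
      logical(1)))
  }
  L <- sum(core) + (nbr(A$coords, core_a) + nbr(B$coords, core_b)) / 2
  if (L <= 0) return(0)
  s / (3 * L^(1 - alpha))
}

oracle_so <- function(pairs, A, B, d0 = 3.5) {
  d <- oracle_devs(pairs, A, B)
  sum(d <= d0) / min(nrow(A$coords), nrow(B$coords))
}

oracle_sol <- function(pairs, A, B, d0 = 3.5, k = 10) {
  d <- oracle_devs(pairs, A, B)
  sum(1 - 1 / (1 + exp(-k * (d - d0)))) / min(nrow(A$coords), nrow(B$coords))
}

oracle_tm <- function(pairs, A, B, normalization = "average") {
  d <- oracle_devs(pairs, A, B)
  one <- function(L) {
    cbrt <- sign(L - 15) * abs(L - 15)^(1 / 3)
    d0 <- max(0.5, 1.24 * cbrt - 1.8)
    sum(1 / (1 + (d / d0)^2)) / L
  }
  la <- nrow(A$coords)
  lb <- nrow(B$coords)
  switch(normalization, A = one(la), B = one(lb),
         average = (one(la) + one(lb)) / 2)
}

# --- fixtures -------------------------------------------------------------

# two collinear chains with equal centroids: the optimal superposition
# leaves the x-axis fixed, so post-fit deviations are |xA - xB| computed
# in exact floating-point arithmetic -- used to place deviations exactly
# on a score cutoff
collinear_pair <- function(x_a, x_b) {
  stopifnot(length(x_a) == length(x_b), mean(x_a) == mean(x_b))
  A <- protein_chain(cbind(x_a, 0, 0))
  B <- protein_chain(cbind(x_b, 0, 0))
  d <- cpp_devs_check(length(x_a), A, B)
  stopifnot(all(d == abs(x_a - x_b)))
  list(A = A, B = B, n = length(x_a))
}

cpp_devs_check <- function(n, A, B) {
  oracle_devs(cbind(seq_len(n), seq_len(n)), A, B)
}

# a random constraint-satisfying alignment (retries until the projection
# succeeds)
random_valid_alignment <- function(la, lb, cst, n_target = NULL) {
  for (try in 1:50) {
    k <- if (is.null(n_target)) sample(seq_len(min(la, lb)), 1) else n_target
    a0 <- as_alignment(cbind(sample.int(la, k), sample.int(lb, k)))
    a <- tryCatch(enforce_constraints(a0, cst, la, lb),
                  error = function(e) NULL)
    if (!is.null(a)) return(a)
  }
  stop("could not generate a valid random alignment")
}

# minimal PDB text writer for parser tests (fixed-width ATOM records)
pdb_line <- function(serial, resno, xyz, chain = "A", alt = " ", occ = 1,
                     icode = " ", resname = "ALA", name = " CA ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, 0, " C")
}

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
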